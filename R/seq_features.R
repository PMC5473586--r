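# Sequence-only kernels: the ping-pong motif pair (U1|A10) and the wildcard
# k-mer family (pattern generation, PSO subset selection, frequency and
# first-position vectorisation).

#' Binary presence/absence of fixed motifs
#'
#' Encodes the ping-pong signature: entry i is 1 iff the sequence carries
#' `base` at the given 1-based `pos` (0 when the position lies beyond the
#' sequence end).  "U" in a spec is matched as the stored "T".
#'
#' @param seq a single DNA string.
#' @param specs `data.frame` with columns `base` and `pos`; default is the
#'   `{U,1}`, `{A,10}` pair.
#' @return integer 0/1 vector, one entry per spec row.
#' @examples
#' encode_fixed_motifs("TAAAAAAAAA")  # c(1, 1)
#' @export
encode_fixed_motifs <- function(seq,
                                specs = data.frame(base = c("T", "A"),
                                                   pos = c(1L, 10L))) {
  stopifnot(all(specs$pos >= 1))
  seq <- chartr("U", "T", toupper(seq))
  base <- chartr("U", "T", toupper(specs$base))
  out <- as.integer(substring(seq, specs$pos, specs$pos) == base)
  names(out) <- paste0(specs$base, specs$pos)
  out
}

#' Enumerate wildcard k-mer patterns
#'
#' All strings over `{A,C,G,T,X}` of length `kmin..kmax` in which the
#' wildcard `X` (matching any base) makes up at most `max_x_fraction` of the
#' positions.  With the defaults this yields 3588 patterns
#' (4 + 16 + 112 + 512 + 2944 for k = 1..5).
#'
#' @param kmin,kmax pattern length range.
#' @param max_x_fraction maximum `count(X)/k` per pattern.
#' @return character vector, lexicographically ordered (C locale), no
#'   duplicates.
#' @export
wildcard_patterns <- function(kmin = 1L, kmax = 5L, max_x_fraction = 0.4) {
  stopifnot(kmin >= 1, kmin <= kmax)
  alph <- c(.DNA_ALPHABET, "X")
  out <- lapply(kmin:kmax, function(k) {
    grid <- do.call(expand.grid,
                    c(rep(list(alph), k),
                      list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
    pats <- do.call(paste0, grid)
    nx <- nchar(pats) - nchar(gsub("X", "", pats, fixed = TRUE))
    pats[nx / k <= max_x_fraction + 1e-12]
  })
  sort(unlist(out), method = "radix")
}

pattern_regex <- function(pattern) gsub("X", ".", pattern, fixed = TRUE)

#' Count overlapping matches of a wildcard pattern
#'
#' @param pattern string over `{A,C,G,T,X}`; `X` matches any base.
#' @param seq DNA string.
#' @return number of (possibly overlapping) offsets at which the pattern
#'   matches.
#' @export
count_matches <- function(pattern, seq) {
  if (nchar(pattern) > nchar(seq)) return(0L)
  hits <- gregexpr(paste0("(?=", pattern_regex(pattern), ")"), seq,
                   perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

#' First match position of a wildcard pattern
#'
#' Returns the 1-based offset of the leftmost match, keeping the convention
#' that 0 encodes absence.
#'
#' @inheritParams count_matches
#' @export
first_position <- function(pattern, seq) {
  hit <- regexpr(pattern_regex(pattern), seq)
  if (hit == -1L) 0L else as.integer(hit)
}

# Wildcard masks (column index sets to replace by X) admissible for each k.
.x_masks <- function(k, max_x_fraction = 0.4) {
  jmax <- floor(max_x_fraction * k + 1e-9)
  out <- list(integer(0))
  if (jmax >= 1)
    for (j in seq_len(jmax))
      out <- c(out, asplit(utils::combn(k, j), 2L))
  out
}

#' Match-count and first-position profiles over a pattern set
#'
#' For every sequence and every pattern, the number of overlapping matches
#' and the 1-based first match position (0 if absent).  Equivalent to
#' calling [count_matches()] / [first_position()] per pair but computed by
#' enumerating each sequence's substrings and their admissible wildcard
#' maskings, which is much faster on full pattern sets.
#'
#' @param seqs character vector of DNA strings.
#' @param patterns character vector of wildcard patterns (lengths 1..5).
#' @param max_x_fraction wildcard fraction bound used to enumerate maskings;
#'   must be at least the fraction present in `patterns`.
#' @return list with integer matrices `counts` and `firstpos`
#'   (`length(seqs)` x `length(patterns)`).
#' @export
kmer_profile <- function(seqs, patterns, max_x_fraction = 0.4) {
  P <- length(patterns)
  stopifnot(P >= 1)
  ks <- sort(unique(nchar(patterns)))
  masks <- setNames(lapply(ks, .x_masks, max_x_fraction = max_x_fraction),
                    as.character(ks))
  counts <- matrix(0L, length(seqs), P,
                   dimnames = list(names(seqs), patterns))
  firstpos <- matrix(0L, length(seqs), P,
                     dimnames = list(names(seqs), patterns))
  for (s in seq_along(seqs)) {
    ch <- strsplit(seqs[[s]], "")[[1]]
    L <- length(ch)
    vars <- list(); offs <- list()
    for (k in ks) {
      if (L < k) next
      m <- L - k + 1L
      sub <- matrix(ch[outer(seq_len(m), 0:(k - 1L), "+")], nrow = m)
      for (mask in masks[[as.character(k)]]) {
        v <- sub
        if (length(mask)) v[, mask] <- "X"
        vars[[length(vars) + 1L]] <-
          if (k == 1L) as.vector(v) else do.call(paste0, asplit(v, 2L))
        offs[[length(offs) + 1L]] <- seq_len(m)
      }
    }
    if (!length(vars)) next
    vars <- unlist(vars); offs <- unlist(offs)
    idx <- match(vars, patterns)
    keep <- !is.na(idx)
    idx <- idx[keep]; off <- offs[keep]
    if (!length(idx)) next
    counts[s, ] <- tabulate(idx, nbins = P)
    o <- order(off)
    fseen <- !duplicated(idx[o])
    firstpos[s, idx[o][fseen]] <- off[o][fseen]
  }
  list(counts = counts, firstpos = firstpos)
}

#' Frequency vector over selected k-mers
#'
#' Entry i is the overlapping match count of pattern i divided by the
#' sequence length.
#'
#' @param seq DNA string.
#' @param selected character vector of wildcard patterns.
#' @export
freq_vector <- function(seq, selected) {
  stopifnot(length(selected) >= 1)
  setNames(vapply(selected, count_matches, integer(1), seq = seq) /
             nchar(seq), selected)
}

#' First-position vector over selected k-mers
#'
#' @inheritParams freq_vector
#' @export
pos_vector <- function(seq, selected) {
  stopifnot(length(selected) >= 1)
  setNames(vapply(selected, first_position, integer(1), seq = seq), selected)
}

#' Particle-swarm parameters for k-mer subset selection
#'
#' Defaults follow common binary-PSO practice: inertia 0.72, cognitive and
#' social coefficients 1.49, velocity clamp 4.
#'
#' @param swarm_size,iterations swarm geometry.
#' @param inertia,cognitive,social velocity update coefficients.
#' @param v_max velocity clamp.
#' @param seed RNG seed making the selection reproducible.
#' @export
pso_params <- function(swarm_size = 30L, iterations = 50L, inertia = 0.72,
                       cognitive = 1.49, social = 1.49, v_max = 4,
                       seed = 1L) {
  stopifnot(swarm_size > 0, iterations > 0, inertia > 0, cognitive > 0,
            social > 0, v_max > 0)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations), inertia = inertia,
                 cognitive = cognitive, social = social, v_max = v_max,
                 seed = as.integer(seed)), class = "pso_params")
}

# Stratified fold ids (1..k) for a label vector, given an RNG already seeded.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Wrapper fitness: stratified 3-fold accuracy of a nearest-centroid
# classifier restricted to the candidate feature columns.
ncc_cv_accuracy <- function(X, y, fold) {
  acc <- 0
  for (f in unique(fold)) {
    tr <- fold != f; te <- !tr
    mpos <- colMeans(X[tr & y, , drop = FALSE])
    mneg <- colMeans(X[tr & !y, , drop = FALSE])
    Xt <- X[te, , drop = FALSE]
    dpos <- rowSums(sweep(Xt, 2, mpos)^2)
    dneg <- rowSums(sweep(Xt, 2, mneg)^2)
    acc <- acc + mean((dpos < dneg) == y[te])
  }
  acc / length(unique(fold))
}

#' Select a k-mer subset
#'
#' Supervised selection of `n` patterns out of a candidate set, given the
#' per-sequence discriminative information (match frequencies or first
#' positions) as a matrix.  Two selectors are provided:
#'
#' * `"pso"` (default): a binary particle swarm with particles repaired to
#'   exactly `n` active patterns; the wrapper fitness is the stratified
#'   3-fold accuracy of a nearest-centroid classifier on the candidate
#'   columns.  Reproducible given `params$seed`.
#' * `"rank"`: a deterministic filter ranking patterns by the absolute
#'   difference of class-mean values and keeping the top `n`.
#'
#' @param X numeric matrix, sequences x patterns (e.g. `counts` or
#'   `firstpos` from [kmer_profile()], frequencies recommended for counts).
#' @param labels `"positive"`/`"negative"` per row of `X`.
#' @param n number of patterns to keep (`n <= ncol(X)`).
#' @param method `"pso"` or `"rank"`.
#' @param params a [pso_params()] object.
#' @return integer vector of `n` distinct column indices, named by pattern.
#' @export
select_kmers <- function(X, labels, n, method = c("pso", "rank"),
                         params = pso_params()) {
  method <- match.arg(method)
  P <- ncol(X)
  stopifnot(n >= 1, n <= P)
  y <- labels == "positive"
  if (!any(y) || all(y))
    stop("k-mer selection needs both positive and negative sequences")
  cols <- colnames(X)
  if (n == P) return(setNames(seq_len(P), cols))
  if (method == "rank") {
    gap <- abs(colMeans(X[y, , drop = FALSE]) -
                 colMeans(X[!y, , drop = FALSE]))
    idx <- order(gap, seq_len(P), decreasing = c(TRUE, FALSE),
                 method = "radix")[seq_len(n)]
    return(setNames(sort(idx), cols[sort(idx)]))
  }
  ## binary PSO with repair to exactly n ones
  p <- params
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(p$seed)
  fold <- stratified_folds(ifelse(y, "p", "n"), 3L)
  fitness <- function(bits)
    ncc_cv_accuracy(X[, bits, drop = FALSE], y, fold)
  repair <- function(prob) {
    # exactly n ones: keep the n positions with the highest activation
    # probability, random tie-break via jitter drawn from the seeded RNG
    ord <- order(prob + runif(P, 0, 1e-9), decreasing = TRUE)
    bits <- logical(P); bits[ord[seq_len(n)]] <- TRUE
    bits
  }
  pos <- t(vapply(seq_len(p$swarm_size), function(i) {
    bits <- logical(P); bits[sample.int(P, n)] <- TRUE; bits
  }, logical(P)))
  vel <- matrix(runif(p$swarm_size * P, -p$v_max / 2, p$v_max / 2),
                p$swarm_size, P)
  fit <- apply(pos, 1, fitness)
  pbest <- pos; pbest_fit <- fit
  gi <- which.max(fit); gbest <- pos[gi, ]; gbest_fit <- fit[gi]
  for (it in seq_len(p$iterations)) {
    r1 <- matrix(runif(p$swarm_size * P), p$swarm_size, P)
    r2 <- matrix(runif(p$swarm_size * P), p$swarm_size, P)
    gmat <- matrix(gbest, p$swarm_size, P, byrow = TRUE)
    vel <- p$inertia * vel +
      p$cognitive * r1 * (pbest - pos) +
      p$social * r2 * (gmat - pos)
    vel <- pmin(pmax(vel, -p$v_max), p$v_max)
    s <- 1 / (1 + exp(-vel))
    for (i in seq_len(p$swarm_size)) {
      pos[i, ] <- repair(s[i, ])
      fit[i] <- fitness(pos[i, ])
      if (fit[i] > pbest_fit[i]) { pbest[i, ] <- pos[i, ]; pbest_fit[i] <- fit[i] }
      if (fit[i] > gbest_fit) { gbest <- pos[i, ]; gbest_fit <- fit[i] }
    }
  }
  idx <- which(gbest)
  setNames(idx, cols[idx])
}

#' Write / read a selected-pattern list
#'
#' Plain text, one pattern per line, with a header line recording the k
#' range and wildcard fraction.
#'
#' @param patterns character vector of patterns.
#' @param path file path.
#' @export
write_patterns <- function(patterns, path) {
  ks <- range(nchar(patterns))
  nx <- max((nchar(patterns) -
               nchar(gsub("X", "", patterns, fixed = TRUE))) /
              nchar(patterns))
  writeLines(c(sprintf("# kmin=%d kmax=%d max_x_fraction=%.2f",
                       ks[1], ks[2], nx), patterns), path)
  invisible(path)
}

#' @rdname write_patterns
#' @param path file path.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  lines[!grepl("^#", lines) & nzchar(lines)]
}
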