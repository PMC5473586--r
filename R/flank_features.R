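# "Motifs around" kernels: scans of the genomic flanks of each mapped
# position.  All extractors are strand-aware (upstream = 5' side of the
# oriented sequence), clip at chromosome ends, and use the flank size D as
# the absence sentinel for distances so features stay bounded.

.IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
                  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                  H = "[ACT]", V = "[ACG]", N = "[ACGT]", X = "[ACGT]")

iupac_to_regex <- function(motif) {
  ch <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(ch, names(.IUPAC_REGEX))
  if (length(bad)) stop("not an IUPAC motif: ", motif)
  paste0(.IUPAC_REGEX[ch], collapse = "")
}

#' Upstream promoter-motif features
#'
#' Scans the D bp upstream of the 5' end of each mapped position for the
#' given consensus motifs (IUPAC), keeping the match closest to the
#' sequence.  Three values describe the hit: the motif length L, the
#' distance from the sequence 5' end to the motif 3' edge (1 when directly
#' adjacent), and the score `4^L / distance`, which favours close and long
#' motifs.  Among several genomic positions the one with the highest score
#' is kept; with no match within D the vector is `(0, D, 0)`.
#'
#' @param positions the sequence's positions (`chrom`, `start`, `end`,
#'   `strand`).
#' @param genome a [genome_context()].
#' @param motifs character vector of IUPAC consensus strings.
#' @param d upstream scan distance in bp.
#' @return numeric vector `(length, dist, prob)`.
#' @export
promoter_features <- function(positions, genome, motifs, d) {
  stopifnot(d > 0)
  if (length(motifs) == 0L) stop("empty promoter motif set")
  absent <- c(length = 0, dist = d, prob = 0)
  if (nrow(positions) == 0L) return(absent)
  best <- absent
  for (i in seq_len(nrow(positions))) {
    up <- extract_flank(genome, positions$chrom[i], positions$start[i],
                        positions$end[i], positions$strand[i], d)$upstream
    W <- nchar(up)
    if (W == 0L) next
    for (m in motifs) {
      L <- nchar(m)
      hits <- gregexpr(paste0("(?=", iupac_to_regex(m), ")"), up,
                       perl = TRUE)[[1]]
      if (hits[1] == -1L) next
      ends <- as.integer(hits) + L - 1L
      ends <- ends[ends <= W]
      if (!length(ends)) next
      dist <- W - max(ends) + 1L
      prob <- 4^L / dist
      if (prob > best[["prob"]])
        best <- c(length = L, dist = dist, prob = prob)
    }
  }
  best
}

#' Transposable-element copy identity
#'
#' `identity = 1 - RM - RD - RS` from the mismatch, deletion and
#' substitution ratios of an annotated TE copy.
#'
#' @param rm,rd,rs ratios in `[0, 1]` with `rm + rd + rs <= 1`.
#' @export
te_identity <- function(rm, rd, rs) {
  if (any(c(rm, rd, rs) < 0) || any(c(rm, rd, rs) > 1))
    stop("TE ratios must lie in [0, 1]")
  if (any(rm + rd + rs > 1 + 1e-9))
    stop("TE ratios must satisfy rm + rd + rs <= 1")
  1 - rm - rd - rs
}

#' Transposon context features
#'
#' For each TE class, the cumulated identity and cumulated length (bp) of
#' annotated copies overlapping `[pos - D, pos + D]`, each multiplied by the
#' class weight.  When a sequence maps to several positions, the position
#' with the highest total cumulated identity is kept.
#'
#' @param positions the sequence's positions.
#' @param genome a [genome_context()] carrying `te_annotations`.
#' @param classes ordered character vector of TE classes.
#' @param d flank distance in bp.
#' @param weights named per-class weights; defaults to 1.
#' @return numeric vector of length `2 * length(classes)`, interleaved
#'   `(identity, length)` per class.
#' @export
te_flank_features <- function(positions, genome, classes, d,
                              weights = NULL) {
  stopifnot(length(classes) >= 1, d > 0)
  if (is.null(weights)) weights <- setNames(rep(1, length(classes)), classes)
  nm <- as.vector(rbind(paste0(classes, "_identity"),
                        paste0(classes, "_length")))
  zero <- setNames(numeric(2L * length(classes)), nm)
  if (nrow(positions) == 0L) return(zero)
  te <- genome$te_annotations
  best <- zero; best_total <- -Inf
  for (i in seq_len(nrow(positions))) {
    w0 <- positions$start[i] - d; w1 <- positions$end[i] + d
    hit <- te[te$chrom == positions$chrom[i] & te$start < w1 & te$end > w0,
              , drop = FALSE]
    v <- zero; total <- 0
    for (ci in seq_along(classes)) {
      rows <- hit[hit$te_class == classes[ci], , drop = FALSE]
      if (!nrow(rows)) next
      ident <- sum(te_identity(rows$rm, rows$rd, rows$rs))
      len <- sum(rows$end - rows$start)
      total <- total + ident
      v[2L * ci - 1L] <- weights[[classes[ci]]] * ident
      v[2L * ci] <- weights[[classes[ci]]] * len
    }
    if (total > best_total) { best <- v; best_total <- total }
  }
  best
}

## ---- inverted repeats -----------------------------------------------------

# Greedy extension of a seed run along one diagonal of the window-vs-
# reverse-complement comparison.  `match` is the logical match vector along
# the diagonal, `a:b` the current interval (endpoints are matches).  At each
# step the extension (left or right, to the next matching position) keeping
# the higher identity is accepted while identity stays > min_ident.
ir_extend <- function(match, a, b, min_ident) {
  cs <- cumsum(match)
  nmatch <- function(a, b) cs[b] - if (a > 1L) cs[a - 1L] else 0L
  mpos <- which(match)
  repeat {
    lcand <- mpos[mpos < a]; rcand <- mpos[mpos > b]
    l <- if (length(lcand)) max(lcand) else NA_integer_
    r <- if (length(rcand)) min(rcand) else NA_integer_
    il <- if (!is.na(l)) nmatch(l, b) / (b - l + 1L) else -1
    ir <- if (!is.na(r)) nmatch(a, r) / (r - a + 1L) else -1
    if (il <= min_ident && ir <= min_ident) break
    if (il >= ir) a <- l else b <- r
  }
  c(a = a, b = b, matches = nmatch(a, b))
}

seq_codes <- function(s) {
  tbl <- integer(128L)
  tbl[utf8ToInt("ACGT") + 1L] <- 0:3
  tbl[utf8ToInt(s) + 1L]
}

rolling_hash <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(0))
  h <- integer(n - k + 1L)
  for (t in 0:(k - 1L))
    h <- h + codes[(1L + t):(n - k + 1L + t)] * as.integer(4^t)
  h
}

#' Detect inverted repeats in a window
#'
#' Compares the window with its reverse complement and reports gapless
#' local alignments longer than `min_len` bases with identity above
#' `min_ident` (both strict).  Candidate diagonals are found by exact
#' k-mer seeding (`seed_len`) and grown by greedy ungapped extension;
#' mirror-image duplicates across the palindrome diagonal are removed
#' (one orientation kept).
#'
#' @param window DNA string.
#' @param min_len minimum alignment length (strict, default 20).
#' @param min_ident minimum identity (strict, default 0.9).
#' @param seed_len exact seed length (default 12).
#' @return `data.frame` with the two arm coordinates (1-based, inclusive,
#'   in window coordinates), alignment `length`, number of `matches` and
#'   `identity`.
#' @export
find_inverted_repeats <- function(window, min_len = 20, min_ident = 0.9,
                                  seed_len = 12L) {
  stopifnot(nzchar(window))
  n <- nchar(window)
  empty <- data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      length = integer(0), matches = integer(0),
                      identity = numeric(0))
  if (n <= min_len || n < seed_len) return(empty)
  s <- seq_codes(window)
  r <- seq_codes(revcomp(window))
  hs <- rolling_hash(s, seed_len)
  hr <- rolling_hash(r, seed_len)
  ord <- order(hr, method = "radix")
  sorted <- hr[ord]
  cand <- which(hs %in% sorted)          # cheap hash prefilter
  if (!length(cand)) return(empty)
  lo <- findInterval(hs[cand] - 0.5, sorted)
  hi <- findInterval(hs[cand], sorted)
  cnt <- hi - lo
  si <- rep.int(cand, cnt)
  rj <- ord[unlist(lapply(seq_along(cand), function(i)
    if (cnt[i] > 0) (lo[i] + 1L):hi[i]), use.names = FALSE)]
  if (!length(si)) return(empty)
  diag_id <- si - rj
  radius <- 2000L   # greedy extension is confined near the seed
  out <- list()
  for (dg in unique(diag_id)) {
    ## positions p on the window align with p - dg on the reverse complement
    p0 <- max(1L, 1L + dg); p1 <- min(n, n + dg)
    ## merge overlapping / near-adjacent seeds into runs (repetitive
    ## sequence otherwise triggers one extension per seed position)
    sa_all <- sort(unique(si[diag_id == dg]))
    gaps <- which(diff(sa_all) > seed_len)
    run_from <- sa_all[c(1L, gaps + 1L)]
    run_to <- sa_all[c(gaps, length(sa_all))] + seed_len - 1L
    hits <- list()
    for (ri in seq_along(run_from)) {
      sa <- run_from[ri]; sb <- run_to[ri]
      lo <- max(p0, sa - radius)
      hi <- min(p1, sb + radius)
      match <- s[lo:hi] == r[(lo:hi) - dg]
      ext <- ir_extend(match, sa - lo + 1L, sb - lo + 1L, min_ident)
      len <- ext[["b"]] - ext[["a"]] + 1L
      if (len > min_len && ext[["matches"]] / len > min_ident)
        hits[[length(hits) + 1L]] <- c(ext[["a"]] + lo - 1L,
                                       ext[["b"]] + lo - 1L,
                                       ext[["matches"]])
    }
    if (!length(hits)) next
    hits <- unique(do.call(rbind, hits))
    for (k in seq_len(nrow(hits))) {
      a <- hits[k, 1L]; b <- hits[k, 2L]
      ja <- a - dg; jb <- b - dg             # on reverse complement
      out[[length(out) + 1L]] <-
        c(start1 = a, end1 = b, start2 = n - jb + 1L, end2 = n - ja + 1L,
          length = b - a + 1L, matches = unname(hits[k, 3L]))
    }
  }
  if (!length(out)) return(empty)
  res <- as.data.frame(do.call(rbind, out))
  ## mirror dedup: each alignment also appears with the two arms swapped;
  ## canonicalise (first arm = lower coordinate) and drop duplicates
  swap <- res$start2 < res$start1 |
    (res$start2 == res$start1 & res$end2 < res$end1)
  if (any(swap))
    res[swap, c("start1", "end1", "start2", "end2")] <-
      res[swap, c("start2", "end2", "start1", "end1")]
  res <- unique(res)
  res$identity <- res$matches / res$length
  res <- res[order(res$start1, res$start2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Inverted-repeat summary features
#'
#' Over the qualifying alignments found in the window made of the D bp
#' upstream flank, the sequence and the D bp downstream flank: the mean
#' alignment length and the cumulated number of matching bases.  With no
#' qualifying alignment, `(0, 0)`.  Among several genomic positions the one
#' with the largest cumulated matches is kept.
#'
#' @inheritParams promoter_features
#' @param d flank distance in bp.
#' @param min_len,min_ident,seed_len see [find_inverted_repeats()].
#' @return numeric vector `(mean_length, cum_matches)`.
#' @export
invrep_features <- function(positions, genome, d, min_len = 20,
                            min_ident = 0.9, seed_len = 12L) {
  stopifnot(d > 0)
  zero <- c(mean_length = 0, cum_matches = 0)
  if (nrow(positions) == 0L) return(zero)
  best <- zero
  for (i in seq_len(nrow(positions))) {
    win <- extract_flank(genome, positions$chrom[i], positions$start[i],
                         positions$end[i], positions$strand[i], d)$window
    irs <- find_inverted_repeats(win, min_len, min_ident, seed_len)
    if (!nrow(irs)) next
    v <- c(mean_length = mean(irs$length), cum_matches = sum(irs$matches))
    if (v[["cum_matches"]] > best[["cum_matches"]]) best <- v
  }
  best
}

## ---- G-quadruplexes -------------------------------------------------------

.G4_PATTERN <- "G{3,}[ACGT]{1,7}G{3,}[ACGT]{1,7}G{3,}[ACGT]{1,7}G{3,}"
.G4_PATTERN_MINUS <- gsub("G", "C", .G4_PATTERN, fixed = TRUE)

#' Find G-quadruplex motifs on both strands
#'
#' Maximal non-overlapping (leftmost-longest, POSIX semantics) matches of
#' the canonical pattern — four runs of three or more G separated by three
#' loops of 1 to 7 bases — on the given strand, and of its C-run mirror for
#' quadruplexes on the opposite strand.
#'
#' @param seq DNA string.
#' @return `data.frame` with `start`, `end` (1-based inclusive) and
#'   `strand` (`"+"` = strand of `seq`).
#' @export
find_g4 <- function(seq) {
  scan <- function(pattern, strand) {
    hits <- gregexpr(pattern, seq)[[1]]
    if (hits[1] == -1L)
      return(data.frame(start = integer(0), end = integer(0),
                        strand = character(0)))
    data.frame(start = as.integer(hits),
               end = as.integer(hits) + attr(hits, "match.length") - 1L,
               strand = strand, stringsAsFactors = FALSE)
  }
  out <- rbind(scan(.G4_PATTERN, "+"), scan(.G4_PATTERN_MINUS, "-"))
  out[order(out$start), , drop = FALSE]
}

# gap in bases between an element [a, b] and the sequence occupying
# [seq_from, seq_to] (all 1-based inclusive window coordinates); 0 = overlap
.window_gap <- function(a, b, seq_from, seq_to) {
  ifelse(b < seq_from, seq_from - b - 1L,
         ifelse(a > seq_to, a - seq_to - 1L, 0L))
}

#' G-quadruplex context features
#'
#' Five values per sequence, computed on the window of D bp upstream, the
#' sequence and D bp downstream: distance to the nearest quadruplex on the
#' sequence's strand, distance to the nearest one on the opposite strand,
#' the counts of quadruplexes on each strand, and the cumulated length of
#' all quadruplexes (both strands pooled).  Absent quadruplexes contribute
#' the sentinel distance D and zero counts/length.  Among several genomic
#' positions, the one with the nearest same-strand quadruplex is kept.
#'
#' @inheritParams promoter_features
#' @param d flank distance in bp.
#' @return numeric 5-vector.
#' @export
g4_features <- function(positions, genome, d) {
  stopifnot(d > 0)
  absent <- c(dist_same = d, dist_opp = d, n_same = 0, n_opp = 0,
              cum_length = 0)
  if (nrow(positions) == 0L) return(absent)
  best <- absent
  for (i in seq_len(nrow(positions))) {
    fl <- extract_flank(genome, positions$chrom[i], positions$start[i],
                        positions$end[i], positions$strand[i], d)
    g4 <- find_g4(fl$window)
    if (!nrow(g4)) next
    sfrom <- nchar(fl$upstream) + 1L
    sto <- nchar(fl$upstream) + nchar(fl$sequence)
    gaps <- .window_gap(g4$start, g4$end, sfrom, sto)
    same <- g4$strand == "+"
    v <- c(dist_same = if (any(same)) min(gaps[same]) else d,
           dist_opp = if (any(!same)) min(gaps[!same]) else d,
           n_same = sum(same), n_opp = sum(!same),
           cum_length = sum(g4$end - g4$start + 1L))
    if (v[["dist_same"]] < best[["dist_same"]] ||
        (best[["n_same"]] + best[["n_opp"]] == 0 && nrow(g4) > 0))
      best <- v
  }
  best
}

## ---- CpG islands ----------------------------------------------------------

#' Detect CpG islands by sliding-window scan
#'
#' Windows of `window` bp advanced by `shift` with GC fraction at least
#' `min_gc` and observed/expected CpG ratio
#' `count(CG) * len / (count(C) * count(G))` at least `min_oe` are merged
#' when overlapping; merged regions shorter than `min_len` are discarded and
#' the reported statistics are recomputed on each merged span.
#'
#' @param seq DNA string.
#' @param min_len minimum island length.
#' @param min_gc,min_oe window admission thresholds.
#' @param window,shift scan geometry.
#' @return `data.frame` with `start`, `end` (1-based inclusive), `length`,
#'   `obs_exp`, `gc`, `cg_count` (number of C plus G bases).
#' @export
find_cpg_islands <- function(seq, min_len = 100, min_gc = 0.5,
                             min_oe = 0.6, window = 100, shift = 1) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), obs_exp = numeric(0),
                      gc = numeric(0), cg_count = numeric(0))
  L <- nchar(seq)
  if (L < window) return(empty)
  ch <- strsplit(seq, "")[[1]]
  isC <- ch == "C"; isG <- ch == "G"
  isCG <- c(isC[-L] & isG[-1], FALSE)
  cC <- c(0, cumsum(isC)); cG <- c(0, cumsum(isG)); cCG <- c(0, cumsum(isCG))
  span_stats <- function(a, b) {      # 1-based inclusive
    nC <- cC[b + 1] - cC[a]; nG <- cG[b + 1] - cG[a]
    nCG <- cCG[b] - cCG[a]            # CG dinucleotides fully inside
    len <- b - a + 1
    list(nC = nC, nG = nG, nCG = nCG, len = len,
         gc = (nC + nG) / len,
         oe = if (nC * nG > 0) nCG * len / (nC * nG) else 0)
  }
  starts <- seq(1L, L - window + 1L, by = shift)
  nC <- cC[starts + window] - cC[starts]
  nG <- cG[starts + window] - cG[starts]
  nCG <- cCG[starts + window - 1L] - cCG[starts]
  gc <- (nC + nG) / window
  oe <- ifelse(nC * nG > 0, nCG * window / (nC * nG), 0)
  ok <- which(gc >= min_gc & oe >= min_oe)
  if (!length(ok)) return(empty)
  ## merge overlapping qualifying windows
  a <- starts[ok]; b <- starts[ok] + window - 1L
  merged <- list(); ca <- a[1]; cb <- b[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] <= cb) cb <- max(cb, b[i])
    else { merged[[length(merged) + 1L]] <- c(ca, cb); ca <- a[i]; cb <- b[i] }
  }
  merged[[length(merged) + 1L]] <- c(ca, cb)
  rows <- lapply(merged, function(z) {
    if (z[2] - z[1] + 1 < min_len) return(NULL)
    st <- span_stats(z[1], z[2])
    data.frame(start = z[1], end = z[2], length = st$len, obs_exp = st$oe,
               gc = st$gc, cg_count = st$nC + st$nG)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' CpG-island context features
#'
#' Computed on the upstream-only flank of D bp: distance from the sequence
#' 5' end to the nearest island, number of islands, mean observed/expected
#' ratio, mean island length and mean C+G count per island.  With no island
#' the vector is `(D, 0, 0, 0, 0)`.  Among several genomic positions, the
#' one with the lowest distance to an upstream island is kept.
#'
#' @inheritParams promoter_features
#' @param d upstream flank in bp.
#' @param min_len,min_gc,min_oe,window,shift see [find_cpg_islands()].
#' @return numeric 5-vector.
#' @export
cpg_features <- function(positions, genome, d, min_len = 100, min_gc = 0.5,
                         min_oe = 0.6, window = 100, shift = 1) {
  stopifnot(d > 0)
  absent <- c(dist = d, n = 0, mean_obs_exp = 0, mean_length = 0,
              mean_cg = 0)
  if (nrow(positions) == 0L) return(absent)
  best <- absent
  for (i in seq_len(nrow(positions))) {
    up <- extract_flank(genome, positions$chrom[i], positions$start[i],
                        positions$end[i], positions$strand[i], d)$upstream
    isl <- find_cpg_islands(up, min_len, min_gc, min_oe, window, shift)
    if (!nrow(isl)) next
    W <- nchar(up)
    v <- c(dist = W - max(isl$end), n = nrow(isl),
           mean_obs_exp = mean(isl$obs_exp),
           mean_length = mean(isl$length), mean_cg = mean(isl$cg_count))
    if (v[["dist"]] < best[["dist"]]) best <- v
  }
  best
}
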