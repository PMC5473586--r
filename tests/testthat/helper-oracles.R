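# Independent brute-force oracles used to freeze expected values.

# full product-set enumeration of wildcard patterns, filtered on X fraction
oracle_patterns <- function(kmin, kmax, max_x = 0.4) {
  alph <- c("A", "C", "G", "T", "X")
  out <- character(0)
  for (k in kmin:kmax) {
    grid <- do.call(expand.grid, c(rep(list(alph), k),
                                   list(stringsAsFactors = FALSE)))
    pats <- do.call(paste0, grid)
    nx <- vapply(strsplit(pats, ""), function(ch) sum(ch == "X"),
                 numeric(1))
    out <- c(out, pats[nx / k <= max_x + 1e-12])
  }
  sort(unique(out), method = "radix")
}

# character-by-character sliding-window match oracle
oracle_count <- function(pattern, seq) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  k <- length(p)
  if (k > length(s)) return(0L)
  hits <- 0L
  for (o in seq_len(length(s) - k + 1L))
    if (all(p == "X" | p == s[o:(o + k - 1L)])) hits <- hits + 1L
  hits
}

oracle_first <- function(pattern, seq) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  k <- length(p)
  if (k > length(s)) return(0L)
  for (o in seq_len(length(s) - k + 1L))
    if (all(p == "X" | p == s[o:(o + k - 1L)])) return(o)
  0L
}

# exhaustive O(n^2) diagonal scan for inverted repeats: every maximal
# exact-match run on every diagonal is a seed; the same greedy extension
# rule as the production scanner is applied, so the two must agree
# whenever every qualifying alignment contains a long enough exact run
oracle_inverted_repeats <- function(window, min_len = 20, min_ident = 0.9) {
  n <- nchar(window)
  s <- pirmkl:::seq_codes(window)
  r <- pirmkl:::seq_codes(revcomp(window))
  out <- list()
  for (dg in (1L - n):(n - 1L)) {
    p0 <- max(1L, 1L + dg); p1 <- min(n, n + dg)
    if (p1 - p0 + 1L <= min_len) next
    pr <- p0:p1
    match <- s[pr] == r[pr - dg]
    rl <- rle(match)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    runs <- cbind(starts[rl$values], ends[rl$values])
    for (k in seq_len(nrow(runs))) {
      ext <- pirmkl:::ir_extend(match, runs[k, 1L], runs[k, 2L], min_ident)
      len <- ext[["b"]] - ext[["a"]] + 1L
      if (len > min_len && ext[["matches"]] / len > min_ident) {
        a <- ext[["a"]] + p0 - 1L; b <- ext[["b"]] + p0 - 1L
        ja <- a - dg; jb <- b - dg
        out[[length(out) + 1L]] <- c(start1 = a, end1 = b,
                                     start2 = n - jb + 1L,
                                     end2 = n - ja + 1L,
                                     length = len,
                                     matches = ext[["matches"]])
      }
    }
  }
  if (!length(out))
    return(data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      length = integer(0), matches = integer(0),
                      identity = numeric(0)))
  res <- as.data.frame(do.call(rbind, out))
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

# exhaustive all-offsets duplex oracle (Watson-Crick + G.U wobble)
oracle_duplex <- function(seq, target) {
  s <- strsplit(seq, "")[[1]]
  t <- strsplit(revcomp(target), "")[[1]]
  pair_ok <- function(a, b)
    a == b || (a == "G" && b == "A") || (a == "T" && b == "C")
  n <- length(s); m <- length(t)
  best_score <- -1L; best <- NULL
  for (off in (1L - n):(m - 1L)) {
    paired <- logical(n)
    for (i in seq_len(n)) {
      j <- i + off
      if (j >= 1L && j <= m) paired[i] <- pair_ok(s[i], t[j])
    }
    if (sum(paired) > best_score) {
      best_score <- sum(paired); best <- paired
    }
  }
  list(structure = paste(ifelse(best, "(", "."), collapse = ""),
       score = best_score)
}

# delta computed directly in an explicit feature space (for the linear-
# kernel sanity check k(x,y) = <x,y>)
oracle_delta_linear <- function(X, labels) {
  y <- labels == "positive"
  mpos <- colMeans(X[y, , drop = FALSE])
  mneg <- colMeans(X[!y, , drop = FALSE])
  dpos <- sqrt(rowSums(sweep(X[y, , drop = FALSE], 2, mneg)^2))
  dneg <- sqrt(rowSums(sweep(X[!y, , drop = FALSE], 2, mpos)^2))
  (sum(dpos) + sum(dneg)) / nrow(X)
}
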