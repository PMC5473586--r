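test_that("fixed-motif encoding follows the ping-pong definition", {
  expect_equal(unname(encode_fixed_motifs("TAAAAAAAAA")), c(1L, 1L))
  expect_equal(unname(encode_fixed_motifs("GCGCGCGCGC")), c(0L, 0L))
  ## position beyond the sequence end encodes 0
  expect_equal(unname(encode_fixed_motifs("TAAAA")), c(1L, 0L))
  ## U specs match the stored T
  expect_equal(unname(encode_fixed_motifs(
    "TGGG", specs = data.frame(base = "U", pos = 1))), 1L)
})

test_that("wildcard enumeration matches the brute-force product-set oracle", {
  for (k in 1:3)
    expect_identical(wildcard_patterns(k, k), oracle_patterns(k, k))
  p2 <- wildcard_patterns(2, 2)
  expect_length(p2, 16L)               # no X admissible at k = 2
  expect_false(any(grepl("X", p2)))
  expect_length(wildcard_patterns(5, 5), 2944L)
  full <- wildcard_patterns()
  expect_false(anyDuplicated(full) > 0)
  expect_identical(full, sort(full, method = "radix"))
})

test_that("match counting and first positions agree with the scan oracle", {
  expect_equal(count_matches("AXA", "AAAAA"), 3L)
  expect_equal(count_matches("GGGGG", "ACA"), 0L)
  expect_equal(count_matches("X", "ACGT"), 4L)
  expect_equal(first_position("AXA", "GAAAT"), 2L)
  expect_equal(first_position("CCC", "ATAT"), 0L)
  expect_equal(first_position("A", "A"), 1L)
  set.seed(7)
  pats <- c("A", "TX", "AXA", "GXXT", "XACGX", "CCC")
  for (i in 1:20) {
    s <- rand_dna(sample(5:40, 1))
    for (p in pats) {
      expect_equal(count_matches(p, s), oracle_count(p, s), info = p)
      expect_equal(first_position(p, s), oracle_first(p, s), info = p)
    }
  }
})

test_that("profile matrices equal per-pattern regex matching", {
  set.seed(13)
  seqs <- setNames(vapply(1:8, function(i) rand_dna(sample(20:35, 1)),
                          character(1)), paste0("s", 1:8))
  pats <- wildcard_patterns(1, 3)
  prof <- kmer_profile(seqs, pats)
  pick <- sample(length(pats), 40)
  for (j in pick) {
    expect_equal(unname(prof$counts[, j]),
                 vapply(seqs, function(s) oracle_count(pats[j], s),
                        integer(1), USE.NAMES = FALSE))
    expect_equal(unname(prof$firstpos[, j]),
                 vapply(seqs, function(s) oracle_first(pats[j], s),
                        integer(1), USE.NAMES = FALSE))
  }
  ## profiles also work on arbitrary pattern subsets
  sub <- kmer_profile(seqs, c("AXA", "GG"))
  expect_equal(unname(sub$counts[, "AXA"]),
               vapply(seqs, function(s) oracle_count("AXA", s), integer(1),
                      USE.NAMES = FALSE))
})

test_that("frequency and position vectors follow their definitions", {
  seq30 <- paste0(strrep("ACT", 9), "ACA")   # 30 nt, "AXA" matches 3 times?
  n <- count_matches("AXA", seq30)
  fv <- freq_vector(seq30, c("AXA", "GGGGG"))
  expect_equal(unname(fv), c(n / 30, 0))
  expect_true(all(fv >= 0 & fv <= 1))
  pv <- pos_vector("GAAAT", c("AXA", "CCC", "G"))
  expect_equal(unname(pv), c(2L, 0L, 1L))
})

test_that("match counts are superadditive up to overlap slack", {
  set.seed(3)
  for (i in 1:15) {
    s1 <- rand_dna(sample(10:30, 1)); s2 <- rand_dna(sample(10:30, 1))
    p <- sample(c("AX", "AXA", "GXXT", "TT"), 1)
    k <- nchar(p)
    both <- count_matches(p, paste0(s1, s2))
    expect_gte(both, count_matches(p, s1) + count_matches(p, s2))
    expect_lte(both, count_matches(p, s1) + count_matches(p, s2) + k - 1)
  }
})

test_that("self-concatenation changes frequencies by at most (k-1)/(2 len)", {
  set.seed(4)
  pats <- c("A", "AXA", "GXXT", "CC")
  for (i in 1:10) {
    s <- rand_dna(sample(15:30, 1))
    f1 <- freq_vector(s, pats)
    f2 <- freq_vector(paste0(s, s), pats)
    for (j in seq_along(pats))
      expect_lte(abs(f2[j] - f1[j]),
                 (nchar(pats[j]) - 1) / (2 * nchar(s)) + 1e-12)
  }
})

test_that("k-mer selection is reproducible and recovers a planted pattern", {
  ## dataset where exactly one candidate pattern separates the classes
  set.seed(99)
  n <- 30
  labels <- rep(c("positive", "negative"), each = n)
  seqs <- vapply(seq_len(2 * n), function(i) {
    s <- rand_dna(28, 0.4)                # G-poor background
    if (labels[i] == "positive") substr(s, 10, 15) <- "GGGGGG"
    s
  }, character(1))
  pats <- c("GGGGG", "AXA", "TT", "CXG", "ACGT", "XTX", "CA", "GAT")
  prof <- kmer_profile(setNames(seqs, paste0("q", seq_along(seqs))), pats)
  X <- prof$counts / nchar(seqs)
  hits <- 0L
  for (sd in 1:10) {
    sel <- select_kmers(X, labels, 1, "pso", pso_params(seed = sd))
    if (names(sel) == "GGGGG") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  ## determinism given the seed
  s1 <- select_kmers(X, labels, 3, "pso", pso_params(seed = 5))
  s2 <- select_kmers(X, labels, 3, "pso", pso_params(seed = 5))
  expect_identical(s1, s2)
  ## rank filter finds the planted pattern deterministically
  expect_equal(names(select_kmers(X, labels, 1, "rank")), "GGGGG")
  ## n = all patterns returns everything
  expect_length(select_kmers(X, labels, ncol(X), "pso"), ncol(X))
  expect_error(select_kmers(X, rep("positive", nrow(X)), 2), "both")
})

test_that("pattern lists round-trip through their text format", {
  pats <- c("AXA", "GG", "TTTXX")
  path <- withr::local_tempfile(fileext = ".txt")
  write_patterns(pats, path)
  expect_identical(read_patterns(path), pats)
})
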