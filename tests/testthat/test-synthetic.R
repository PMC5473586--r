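small_cfg <- function(...) {
  sim_config(n_pos = 24, n_neg = 24, n_chrom = 2, chrom_length = 5e5, ...)
}

test_that("generation is fully deterministic given the seed", {
  g1 <- generate_genome(small_cfg(seed = 5))
  g2 <- generate_genome(small_cfg(seed = 5))
  expect_identical(g1, g2)
  d1 <- plant_dataset(small_cfg(seed = 5))
  d2 <- plant_dataset(small_cfg(seed = 5))
  expect_identical(d1$records, d2$records)
  expect_identical(d1$genome$chromosomes, d2$genome$chromosomes)
  g3 <- generate_genome(small_cfg(seed = 6))
  expect_false(identical(g1$chromosomes, g3$chromosomes))
})

test_that("background composition matches the GC parameter", {
  g <- generate_genome(sim_config(n_chrom = 1, chrom_length = 1e6,
                                  gc = 0.5, seed = 2))
  ch <- strsplit(g$chromosomes[[1]], "")[[1]]
  gc <- mean(ch %in% c("G", "C"))
  expect_gte(gc, 0.49); expect_lte(gc, 0.51)
  ## CpG dinucleotides are depleted relative to i.i.d. expectation
  cg <- sum(ch[-length(ch)] == "C" & ch[-1] == "G") / (length(ch) - 1)
  expect_lt(cg, 0.5 * (gc / 2)^2 / 0.9)
})

test_that("telomeres cover the first and last 1% of each chromosome", {
  cfg <- small_cfg(seed = 3)
  g <- generate_genome(cfg)
  tl <- g$tracks$telomere
  for (cn in names(g$chromosomes)) {
    L <- nchar(g$chromosomes[[cn]])
    rows <- tl[tl$chrom == cn, ]
    expect_equal(rows$start, c(0, L - round(0.01 * L)))
    expect_equal(rows$end, c(round(0.01 * L), L))
  }
  expect_true("centromere" %in% names(g$tracks))
  expect_length(g$te_targets, cfg$n_te_targets)
})

test_that("ping-pong planting rates are honoured", {
  d <- plant_dataset(small_cfg(seed = 7, p_u1 = 1, p_a10 = 1))
  pos <- d$records$seq[d$records$label == "positive"]
  expect_true(all(substring(pos, 1, 1) == "T"))
  expect_true(all(substring(pos, 10, 10) == "A"))
  d0 <- plant_dataset(small_cfg(seed = 7, p_u1 = 0, p_a10 = 0))
  pos0 <- d0$records$seq[d0$records$label == "positive"]
  expect_lt(mean(substring(pos0, 1, 1) == "T"), 0.7)
})

test_that("records carry their true genomic slice", {
  d <- plant_dataset(small_cfg(seed = 9))
  r <- d$records
  for (i in sample(length(r), 10)) {
    id <- r$id[i]
    p <- r$positions[r$positions$id == id, ]
    chrom <- d$genome$chromosomes[[p$chrom]]
    piece <- substr(chrom, p$start + 1, p$end)
    if (p$strand == "-") piece <- revcomp(piece)
    expect_equal(unname(r$seq[id]), piece, info = id)
  }
})

test_that("planted flank elements appear at close to the configured rate", {
  cfg <- small_cfg(seed = 13, p_g4 = 1, p_cpg = 0, p_promoter = 0,
                   p_invrep = 0, p_te = 0, p_histone = 0)
  d <- plant_dataset(cfg)
  posl <- pirmkl:::split_positions(d$records)
  pos_ids <- d$records$id[d$records$label == "positive"]
  near <- vapply(pos_ids, function(id) {
    v <- g4_features(posl[[id]], d$genome, d = 1000)
    v[["dist_same"]] <= cfg$g4_dist[2]
  }, logical(1))
  expect_gte(mean(near), 0.9)   # rate 1, allowing rare overwrites
  neg_ids <- d$records$id[d$records$label == "negative"]
  near_neg <- vapply(neg_ids, function(id) {
    v <- g4_features(posl[[id]], d$genome, d = 1000)
    v[["dist_same"]] <= cfg$g4_dist[2]
  }, logical(1))
  expect_lte(mean(near_neg), 0.2)
})

test_that("cluster placement concentrates positives, not negatives", {
  d <- plant_dataset(small_cfg(seed = 15))
  pos <- d$records$positions
  starts <- split(pos$start[grepl("^pos", pos$id)],
                  pos$chrom[grepl("^pos", pos$id)])
  nn_gap <- unlist(lapply(starts, function(s) diff(sort(s))))
  expect_lt(median(nn_gap), 5000)   # clustered within the 10 kb windows
  neg_starts <- split(pos$start[grepl("^neg", pos$id)],
                      pos$chrom[grepl("^neg", pos$id)])
  neg_gap <- unlist(lapply(neg_starts, function(s) diff(sort(s))))
  expect_gt(median(neg_gap), median(nn_gap))
})

test_that("dataset fixtures round-trip through the plain-text layout", {
  d <- plant_dataset(small_cfg(seed = 21, n_pos = 8, n_neg = 8))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  back <- read_dataset(dir)
  expect_equal(back$records$seq, d$records$seq)
  expect_equal(back$records$label, d$records$label)
  expect_equal(back$genome$chromosomes, d$genome$chromosomes)
  expect_setequal(names(back$genome$tracks), names(d$genome$tracks))
  ro <- back$records$positions[order(back$records$positions$id), ]
  rd <- d$records$positions[order(d$records$positions$id), ]
  expect_equal(ro$start, rd$start)
  expect_equal(ro$strand, rd$strand)
  expect_equal(back$genome$te_targets, d$genome$te_targets)
})
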