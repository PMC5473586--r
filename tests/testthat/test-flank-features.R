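test_that("promoter scan reports length, distance and 4^L/D score", {
  ## motif of length 6 ending 100 bp upstream of the sequence 5' end
  bg <- strrep("A", 600)
  chrom <- bg
  substr(chrom, 396, 401) <- "CGTCGT"
  g <- toy_genome(chrom)
  v <- promoter_features(one_pos(500, 530), g, motifs = "CGTCGT", d = 500)
  expect_equal(unname(v), c(6, 100, 4^6 / 100))
  ## no match within D
  v0 <- promoter_features(one_pos(500, 530), toy_genome(bg), "CGTCGT", 500)
  expect_equal(unname(v0), c(0, 500, 0))
  ## length-1 motif directly adjacent: distance 1, score 4
  chrom1 <- bg; substr(chrom1, 500, 500) <- "G"
  v1 <- promoter_features(one_pos(500, 530), toy_genome(chrom1), "G", 500)
  expect_equal(unname(v1), c(1, 1, 4))
  ## IUPAC degeneracy honoured
  vR <- promoter_features(one_pos(500, 530), g, "CGTCRT", 500)
  expect_equal(vR[["length"]], 6)
  expect_error(promoter_features(one_pos(500, 530), g, character(0), 500),
               "empty")
  ## unmapped: absence vector
  expect_equal(unname(promoter_features(one_pos(1, 2)[0, ], g, "CGT", 500)),
               c(0, 500, 0))
})

test_that("TE identity follows 1 - RM - RD - RS with its domain checks", {
  expect_equal(te_identity(0, 0, 0), 1.0)
  expect_equal(te_identity(0.1, 0.05, 0.05), 0.8)
  expect_error(te_identity(0.6, 0.3, 0.2), "<= 1")
  expect_error(te_identity(-0.1, 0, 0), "\\[0, 1\\]")
})

test_that("transposon context cumulates identity and length per class", {
  te <- cbind(genomic_intervals("chrA", 2000, 2500),
              te_class = "LINE", family = "f",
              rm = 0.1, rd = 0, rs = 0)
  g <- toy_genome(strrep("A", 10000), te_annotations = te)
  v <- te_flank_features(one_pos(3000, 3030), g,
                         classes = c("LINE", "SINE", "LTR"), d = 2000,
                         weights = c(LINE = 1, SINE = 1, LTR = 1))
  expect_length(v, 6L)
  expect_equal(unname(v), c(0.9, 500, 0, 0, 0, 0))
  ## nothing within D
  far <- te_flank_features(one_pos(8000, 8030), g,
                           classes = c("LINE", "SINE"), d = 1000)
  expect_equal(unname(far), rep(0, 4))
  ## class weights scale both entries
  vw <- te_flank_features(one_pos(3000, 3030), g, classes = "LINE",
                          d = 2000, weights = c(LINE = 3))
  expect_equal(unname(vw), c(2.7, 1500))
  ## among several positions the highest cumulated identity wins
  two <- rbind(one_pos(3000, 3030), one_pos(8000, 8030))
  v2 <- te_flank_features(two, g, classes = "LINE", d = 1000,
                          weights = c(LINE = 1))
  expect_equal(unname(v2), c(0.9, 500))
})

test_that("inverted-repeat detection finds planted arms, not noise", {
  set.seed(5)
  arm21 <- rand_dna(21, 0.8)   # GC-rich arm in a poly-A background
  win <- paste0(strrep("A", 200), arm21, strrep("A", 50), revcomp(arm21),
                strrep("A", 200))
  hit <- find_inverted_repeats(win)
  expect_equal(nrow(hit), 1L)
  expect_gte(hit$matches, 21)
  expect_gt(hit$identity, 0.9)
  ## alignments of length exactly 20 are excluded (strict inequality)
  arm20 <- substr(arm21, 1, 20)
  win20 <- paste0(strrep("A", 200), arm20, strrep("A", 50),
                  revcomp(arm20), strrep("A", 200))
  expect_equal(nrow(find_inverted_repeats(win20)), 0L)
  ## random windows: empty with high probability
  for (i in 1:5)
    expect_equal(nrow(find_inverted_repeats(rand_dna(500, 0.5))), 0L)
})

test_that("seeded scanner agrees with the exhaustive diagonal-scan oracle", {
  set.seed(17)
  for (i in 1:6) {
    win <- rand_dna(sample(300:2000, 1), 0.5)
    if (i %% 2 == 0) {                   # plant an inverted repeat
      arm <- rand_dna(sample(25:60, 1), 0.6)
      at <- sample(50:150, 1)
      win <- paste0(substr(win, 1, at), arm, substr(win, at + 1, at + 120),
                    revcomp(arm), substr(win, at + 121, nchar(win)))
    }
    impl <- find_inverted_repeats(win)
    orac <- oracle_inverted_repeats(win)
    expect_equal(impl, orac, info = paste("case", i))
  }
})

test_that("inverted-repeat features summarise mean length and matches", {
  arm <- strrep("GCCGT", 8)               # 40 bp
  chrom <- paste0(strrep("A", 300), arm, strrep("T", 60), revcomp(arm),
                  strrep("A", 300), strrep("C", 30), strrep("A", 300))
  g <- toy_genome(chrom)
  pos <- one_pos(700, 730)
  v <- invrep_features(pos, g, d = 700)
  expect_gte(v[["cum_matches"]], 40)
  expect_gte(v[["mean_length"]], 40)
  ## no qualifying alignment
  v0 <- invrep_features(one_pos(100, 130), toy_genome(strrep("A", 2000)),
                        d = 500)
  expect_equal(unname(v0), c(0, 0))
})

test_that("G-quadruplex regex matches quadparser-style patterns", {
  plus <- find_g4("GGGTTAGGGTTAGGGTTAGGG")
  expect_equal(nrow(plus), 1L)
  expect_equal(c(plus$start, plus$end, plus$strand), c("1", "21", "+"))
  minus <- find_g4("CCCTAACCCTAACCCTAACCC")
  expect_equal(minus$strand, "-")
  expect_equal(nrow(find_g4("ATATATATAT")), 0L)
  ## leftmost-longest: extended G runs are absorbed
  long <- find_g4("GGGGTTAGGGTTAGGGTTAGGGG")
  expect_equal(long$end - long$start + 1L, 23L)
})

test_that("G4 context features follow the five-value contract", {
  bg <- strrep("A", 2000)
  chrom <- bg
  substr(chrom, 930, 950) <- "GGGTTAGGGTTAGGGTTAGGG"  # ends 50 bp upstream
  g <- toy_genome(chrom)
  v <- g4_features(one_pos(1000, 1030), g, d = 500)
  expect_length(v, 5L)
  expect_equal(unname(v), c(50, 500, 1, 0, 21))
  ## empty window: sentinel distances, zero counts
  v0 <- g4_features(one_pos(1000, 1030), toy_genome(bg), d = 500)
  expect_equal(unname(v0), c(500, 500, 0, 0, 0))
  ## minus-strand sequence sees the C-run mirror as same-strand
  chromC <- bg
  substr(chromC, 1081, 1101) <- "CCCTAACCCTAACCCTAACCC"
  vm <- g4_features(one_pos(1000, 1030, strand = "-"),
                    toy_genome(chromC), d = 500)
  expect_equal(vm[["n_same"]], 1)
  expect_equal(vm[["dist_same"]], 50)
})

test_that("CpG island scan reproduces hand-computed cases", {
  isl <- find_cpg_islands(strrep("CG", 100))
  expect_equal(nrow(isl), 1L)
  expect_equal(c(isl$length, isl$obs_exp, isl$gc, isl$cg_count),
               c(200, 2.0, 1.0, 200))
  expect_equal(nrow(find_cpg_islands(strrep("AT", 200))), 0L)
  ## merged span shorter than the minimum length is discarded: a 44 bp
  ## CG block with 50 bp windows merges to a 94 bp span < 100
  short <- find_cpg_islands(paste0(strrep("AT", 100), strrep("CG", 22),
                                   strrep("AT", 100)),
                            min_len = 100, window = 50)
  expect_equal(nrow(short), 0L)
})

test_that("CpG features are computed on the upstream flank only", {
  ## block "CG"x100 at window positions 101..300 of a 500 bp upstream
  ## flank over an AT background: qualifying windows merge to [51, 350],
  ## hence length 300, O/E = 100*300/(100*100) = 3, GC = 2/3, dist = 150
  up <- paste0(strrep("AT", 50), strrep("CG", 100), strrep("AT", 100))
  chrom <- paste0(up, strrep("A", 100))
  g <- toy_genome(chrom)
  v <- cpg_features(one_pos(500, 530), g, d = 500)
  expect_length(v, 5L)
  expect_equal(unname(v), c(150, 1, 3.0, 300, 200))
  ## islands downstream are invisible
  chrom2 <- paste0(strrep("A", 600), strrep("CG", 100))
  v2 <- cpg_features(one_pos(500, 530), toy_genome(chrom2), d = 500)
  expect_equal(unname(v2), c(500, 0, 0, 0, 0))
})

test_that("flank features are invariant under genome offset and strand flip", {
  set.seed(31)
  ## a 3 kb local context: promoter motif, G4, CpG block, inverted repeat
  arm <- rand_dna(40, 0.7)
  ctx <- paste0(rand_dna(300, 0.4), "TAACGGTC", rand_dna(150, 0.4),
                "GGGTTAGGGTTAGGGTTAGGG", rand_dna(100, 0.4),
                strrep("CG", 80), rand_dna(200, 0.4), arm,
                rand_dna(80, 0.4), revcomp(arm), rand_dna(120, 0.4),
                "TACGTTACGTTACGTTACGTTACGTTACGT", rand_dna(1000, 0.4))
  seq_at <- function(offset) offset + 300 + 8 + 150 + 21 + 100 + 160 +
    200 + 40 + 80 + 40 + 120
  feats <- function(genome, pos) {
    d <- 900
    list(promoter_features(pos, genome, "TAACGGTC", d),
         g4_features(pos, genome, d),
         cpg_features(pos, genome, d),
         invrep_features(pos, genome, d))
  }
  offsets <- c(500, 4000)
  got <- lapply(offsets, function(off) {
    chrom <- paste0(strrep("A", off), ctx, strrep("A", 6000 - off))
    st <- seq_at(off)
    feats(toy_genome(chrom), one_pos(st, st + 30))
  })
  expect_equal(got[[1]], got[[2]])
  ## strand flip: reverse-complement the genome, mirror the coordinates
  off <- 500
  chrom <- paste0(strrep("A", off), ctx, strrep("A", 5500))
  L <- nchar(chrom)
  st <- seq_at(off)
  plus <- feats(toy_genome(chrom), one_pos(st, st + 30))
  minus <- feats(toy_genome(revcomp(chrom)),
                 one_pos(L - (st + 30), L - st, strand = "-"))
  expect_equal(plus, minus)
})
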