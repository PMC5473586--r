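# Seeded generator of a miniature genome with planted piRNA-like positives:
# clustered placement, ping-pong signature, upstream promoter motif,
# flanking G-quadruplex / CpG island / transposable elements / inverted
# repeat, histone-peak overlap, and reverse-complementarity to transposon
# targets for a subset.  Negatives are unplanted genome slices of the same
# length range.  Everything is deterministic given the seed, so the whole
# pipeline is testable offline.

#' Configuration of the synthetic piRNA dataset generator
#'
#' Defaults describe a reduced but realistically proportioned study: a
#' 20 Mb four-chromosome genome, CpG-depleted like vertebrate sequence,
#' 1000 positives in clusters of 4 within 10 kb (mostly pericentromeric /
#' telomeric) versus 1000 unplanted negatives of the same 25-33 nt length
#' range, ping-pong signature planted at rate 0.9 and flanking elements at
#' rate 0.8.
#'
#' @param ... named overrides of the defaults listed in the source.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chrom = 4L, chrom_length = 5e6, gc = 0.42,
    n_pos = 1000L, n_neg = 1000L, len_range = c(25L, 33L),
    p_u1 = 0.9, p_a10 = 0.9,
    cluster_size = 4L, cluster_span = 10000,
    centrotelo_fraction = 0.7,
    telomere_frac = 0.01, centromere_frac = 0.02,
    p_promoter = 0.8, promoter_motif = "TAACGGTC",
    promoter_dist = c(100, 1000),
    p_g4 = 0.8, g4_motif = "GGGTTAGGGTTAGGGTTAGGG",
    g4_dist = c(50, 500),
    p_cpg = 0.8, cpg_dist = c(100, 2000), cpg_block_len = 300,
    p_te = 0.8, n_te_plant = 2L, te_dist = c(500, 5000),
    te_len = c(500, 1500),
    p_invrep = 0.8, invrep_arm = 60L, invrep_dist = c(200, 2000),
    p_histone = 0.8,
    p_binding = 0.6,
    n_te_targets = 50L, te_target_len = c(35L, 100L),
    te_background_per_mb = 20, histone_background_per_mb = 10,
    plant_sequences = TRUE,
    seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  probs <- unlist(cfg[c("p_u1", "p_a10", "p_promoter", "p_g4", "p_cpg",
                        "p_te", "p_invrep", "p_histone", "p_binding",
                        "centrotelo_fraction")])
  stopifnot(all(probs >= 0 & probs <= 1), cfg$n_pos >= 1, cfg$n_neg >= 1,
            cfg$chrom_length > 10 * cfg$cluster_span,
            cfg$len_range[1] <= cfg$len_range[2])
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Deplete CpG dinucleotides by swapping a sampled fraction of CG
# occurrences to GC (composition-preserving); two passes keep the residual
# from swap-created CGs small.  Emulates the CpG depletion of methylated
# genomes so background observed/expected CpG stays well below islands.
cpg_deplete <- function(ch, p = 0.8, passes = 2L) {
  for (i in seq_len(passes)) {
    idx <- which(ch[-length(ch)] == "C" & ch[-1] == "G")
    idx <- idx[runif(length(idx)) < p]
    if (length(idx)) {
      ch[idx] <- "G"
      ch[idx + 1L] <- "C"
    }
  }
  ch
}

# CG-rich block emulating a CpG island (high GC, high observed/expected).
cpg_block <- function(len) {
  toks <- sample(c("CG", "A", "T", "C", "G"), len, replace = TRUE,
                 prob = c(0.3, 0.175, 0.175, 0.175, 0.175))
  substr(paste(toks, collapse = ""), 1, len)
}

iupac_instantiate <- function(motif) {
  opts <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(toupper(motif), "")[[1]], function(c)
    sample(opts[[c]], 1), character(1)), collapse = "")
}

#' Generate the background genome and annotation tracks
#'
#' Chromosomes are i.i.d. sequence at the configured GC content with CpG
#' dinucleotides depleted (composition-preserving CG-to-GC swaps), so that
#' background observed/expected CpG resembles a methylated genome.
#' Telomere tracks cover the first and last 1% of each chromosome and a
#' centromere track its middle 2%; background histone-mark peaks and
#' transposable-element annotations are scattered at the configured
#' densities, and a random transposon target set is drawn.  Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [genome_context()].
#' @export
generate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- config$chrom_length
  chroms <- setNames(vector("list", config$n_chrom),
                     paste0("chr", seq_len(config$n_chrom)))
  telo <- centro <- list()
  hist_bg <- list(H3K9me3 = list(), H3K27me3 = list())
  te_bg <- list()
  for (cn in names(chroms)) {
    ch <- sample(c("A", "T", "C", "G"), L, replace = TRUE,
                 prob = c((1 - config$gc) / 2, (1 - config$gc) / 2,
                          config$gc / 2, config$gc / 2))
    chroms[[cn]] <- cpg_deplete(ch)
    tl <- round(config$telomere_frac * L)
    cl <- round(config$centromere_frac * L / 2)
    telo[[cn]] <- data.frame(chrom = cn, start = c(0, L - tl),
                             end = c(tl, L), strand = "+")
    centro[[cn]] <- data.frame(chrom = cn,
                               start = round(L / 2) - cl,
                               end = round(L / 2) + cl, strand = "+")
    for (mark in names(hist_bg)) {
      np <- round(L / 1e6 * config$histone_background_per_mb)
      if (np > 0) {
        w <- sample(1000:3000, np, replace = TRUE)
        s <- sample.int(L - max(w) - 1L, np)
        hist_bg[[mark]][[cn]] <- data.frame(chrom = cn, start = s,
                                            end = s + w, strand = "+")
      }
    }
    nt <- round(L / 1e6 * config$te_background_per_mb)
    if (nt > 0) {
      w <- sample(200:1000, nt, replace = TRUE)
      s <- sample.int(L - max(w) - 1L, nt)
      r <- matrix(runif(3L * nt, 0.05, 0.25), ncol = 3)
      te_bg[[cn]] <- data.frame(
        chrom = cn, start = s, end = s + w,
        strand = sample(c("+", "-"), nt, replace = TRUE),
        te_class = sample(c("LINE", "SINE", "LTR"), nt, replace = TRUE,
                          prob = c(0.5, 0.3, 0.2)),
        family = "background", rm = r[, 1], rd = r[, 2], rs = r[, 3],
        stringsAsFactors = FALSE)
    }
  }
  targets <- setNames(vapply(seq_len(config$n_te_targets), function(i)
    random_dna(sample(config$te_target_len[1]:config$te_target_len[2], 1),
               0.5), character(1)),
    paste0("te_target_", seq_len(config$n_te_targets)))
  genome_context(
    chromosomes = vapply(chroms, paste, character(1), collapse = ""),
    tracks = list(telomere = do.call(rbind, telo),
                  centromere = do.call(rbind, centro),
                  H3K9me3 = do.call(rbind, hist_bg$H3K9me3),
                  H3K27me3 = do.call(rbind, hist_bg$H3K27me3)),
    te_annotations = do.call(rbind, te_bg),
    te_targets = targets)
}

# Write an oriented element into the chromosome char vector, `dist` bases
# 5' (side = "up") or 3' (side = "down") of the oriented sequence at
# [start, end).  Returns the modified vector; writes falling off the
# chromosome are skipped.
write_oriented <- function(ch, start, end, strand, elem, dist,
                           side = c("up", "down")) {
  side <- match.arg(side)
  len <- nchar(elem)
  left <- (side == "up") == (strand == "+")
  if (strand == "-") elem <- revcomp(elem)
  if (left) {
    a <- start - dist - len + 1L   # 1-based
    b <- start - dist
  } else {
    a <- end + dist + 1L
    b <- end + dist + len
  }
  if (a < 1L || b > length(ch)) return(ch)
  ch[a:b] <- strsplit(elem, "")[[1]]
  ch
}

#' Generate a genome with planted piRNA positives and unplanted negatives
#'
#' Positives are placed in clusters (fixed-span windows, mostly near
#' centromeres/telomeres), given the ping-pong signature at the configured
#' rates, and each planted feature — upstream promoter motif,
#' G-quadruplex, CpG island, flanking transposable elements, bracketing
#' inverted repeat, histone-peak overlap — is written into the genome or
#' its annotation with its own probability; a configurable fraction of
#' positive sequences is made reverse-complementary to a transposon target
#' (binding signal).  Negatives are uniform genome slices away from the
#' planted clusters.  Every record carries its true genomic position.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [genome_context()]) and `records` (a
#'   labeled [pirna_set()]).
#' @export
plant_dataset <- function(config = sim_config()) {
  genome <- generate_genome(config)
  set.seed(config$seed %% 1000000L + 1000003L)
  L <- config$chrom_length
  span <- config$cluster_span
  margin <- 45000 + span
  n_clusters <- ceiling(config$n_pos / config$cluster_size)
  total_len <- config$n_chrom * L
  if (n_clusters * span > 0.8 * total_len)
    stop("genome too small for the requested number of positives")
  chars <- lapply(genome$chromosomes, function(s) strsplit(s, "")[[1]])
  chrom_names <- names(chars)
  rint <- function(rng) sample(rng[1]:rng[2], 1L)

  ## ---- cluster windows ----------------------------------------------------
  anchors <- rbind(genome$tracks$telomere, genome$tracks$centromere)
  clusters <- data.frame(chrom = character(n_clusters), start = numeric(n_clusters),
                         strand = character(n_clusters), stringsAsFactors = FALSE)
  for (ci in seq_len(n_clusters)) {
    cn <- sample(chrom_names, 1L)
    if (runif(1) < config$centrotelo_fraction) {
      av <- anchors[anchors$chrom == cn, , drop = FALSE]
      a <- av[sample.int(nrow(av), 1L), ]
      ws <- round(mean(c(a$start, a$end))) + sample(-20000:20000, 1L)
    } else {
      ws <- sample.int(L - 2L * margin, 1L) + margin
    }
    clusters$chrom[ci] <- cn
    clusters$start[ci] <- min(max(ws, margin), L - margin - span)
    clusters$strand[ci] <- sample(c("+", "-"), 1L)
  }

  ## ---- positive placements ------------------------------------------------
  slot_by <- max(60, floor(span / (2 * config$cluster_size)))
  slots <- seq(0, span - 60, by = slot_by)
  pos_tab <- do.call(rbind, lapply(seq_len(n_clusters), function(ci) {
    off <- sort(sample(slots, config$cluster_size))
    data.frame(chrom = clusters$chrom[ci],
               start = clusters$start[ci] + off,
               strand = clusters$strand[ci], stringsAsFactors = FALSE)
  }))[seq_len(config$n_pos), ]
  pos_tab$len <- sample(config$len_range[1]:config$len_range[2],
                        config$n_pos, replace = TRUE)
  pos_tab$end <- pos_tab$start + pos_tab$len

  te_add <- list(); hist_add <- list(H3K9me3 = list(), H3K27me3 = list())
  bodies <- character(config$n_pos)
  for (i in seq_len(config$n_pos)) {
    cn <- pos_tab$chrom[i]; st <- pos_tab$start[i]; en <- pos_tab$end[i]
    sd <- pos_tab$strand[i]; len <- pos_tab$len[i]
    ## sequence body
    body <- if (runif(1) < config$p_binding) {
      tg <- genome$te_targets[[sample.int(length(genome$te_targets), 1L)]]
      a <- sample.int(nchar(tg) - len + 1L, 1L)
      revcomp(substr(tg, a, a + len - 1L))
    } else random_dna(len, 0.45)
    if (runif(1) < config$p_u1) substr(body, 1, 1) <- "T"
    if (len >= 10L && runif(1) < config$p_a10) substr(body, 10, 10) <- "A"
    bodies[i] <- body
    ## planted flanking elements
    if (runif(1) < config$p_promoter)
      chars[[cn]] <- write_oriented(chars[[cn]], st, en, sd,
                                    iupac_instantiate(config$promoter_motif),
                                    rint(config$promoter_dist), "up")
    if (runif(1) < config$p_g4)
      chars[[cn]] <- write_oriented(chars[[cn]], st, en, sd,
                                    config$g4_motif,
                                    rint(config$g4_dist), "up")
    if (runif(1) < config$p_cpg)
      chars[[cn]] <- write_oriented(chars[[cn]], st, en, sd,
                                    cpg_block(config$cpg_block_len),
                                    rint(config$cpg_dist), "up")
    if (runif(1) < config$p_invrep) {
      arm <- random_dna(config$invrep_arm, 0.5)
      chars[[cn]] <- write_oriented(chars[[cn]], st, en, sd, arm,
                                    rint(config$invrep_dist), "up")
      chars[[cn]] <- write_oriented(chars[[cn]], st, en, sd, revcomp(arm),
                                    rint(config$invrep_dist), "down")
    }
    if (runif(1) < config$p_te)
      for (k in seq_len(config$n_te_plant)) {
        w <- rint(config$te_len)
        offs <- rint(config$te_dist) * sample(c(-1, 1), 1L)
        a <- max(0, st + offs - round(w / 2))
        te_add[[length(te_add) + 1L]] <- data.frame(
          chrom = cn, start = a, end = min(a + w, L),
          strand = sample(c("+", "-"), 1L), te_class = "LINE",
          family = "planted", rm = runif(1, 0, 0.034),
          rd = runif(1, 0, 0.033), rs = runif(1, 0, 0.033),
          stringsAsFactors = FALSE)
      }
    for (mark in names(hist_add))
      if (runif(1) < config$p_histone)
        hist_add[[mark]][[length(hist_add[[mark]]) + 1L]] <- data.frame(
          chrom = cn, start = max(0, st - rint(c(200, 1000))),
          end = min(L, en + rint(c(200, 1000))), strand = "+",
          stringsAsFactors = FALSE)
  }
  ## write the bodies last so no planting overwrites a piRNA
  if (config$plant_sequences)
    for (i in seq_len(config$n_pos)) {
      cn <- pos_tab$chrom[i]
      elem <- if (pos_tab$strand[i] == "+") bodies[i] else
        revcomp(bodies[i])
      chars[[cn]][(pos_tab$start[i] + 1L):pos_tab$end[i]] <-
        strsplit(elem, "")[[1]]
    }
  else
    for (i in seq_len(config$n_pos)) {
      cn <- pos_tab$chrom[i]
      piece <- paste(chars[[cn]][(pos_tab$start[i] + 1L):pos_tab$end[i]],
                     collapse = "")
      bodies[i] <- if (pos_tab$strand[i] == "+") piece else revcomp(piece)
    }

  ## ---- negatives ----------------------------------------------------------
  excl <- lapply(chrom_names, function(cn) {
    cl <- clusters[clusters$chrom == cn, , drop = FALSE]
    cbind(cl$start - 5000, cl$start + span + 5000)
  })
  names(excl) <- chrom_names
  neg_tab <- data.frame(chrom = character(0), start = numeric(0),
                        strand = character(0), len = integer(0))
  tries <- 0L
  while (nrow(neg_tab) < config$n_neg) {
    tries <- tries + 1L
    if (tries > 200L * config$n_neg)
      stop("genome too small to place the requested negatives")
    cn <- sample(chrom_names, 1L)
    st <- sample.int(L - 2L * margin, 1L) + margin
    ex <- excl[[cn]]
    if (nrow(ex) && any(st >= ex[, 1] & st <= ex[, 2])) next
    neg_tab <- rbind(neg_tab, data.frame(
      chrom = cn, start = st, strand = sample(c("+", "-"), 1L),
      len = sample(config$len_range[1]:config$len_range[2], 1L),
      stringsAsFactors = FALSE))
  }
  neg_tab$end <- neg_tab$start + neg_tab$len
  neg_bodies <- vapply(seq_len(config$n_neg), function(i) {
    piece <- paste(chars[[neg_tab$chrom[i]]][(neg_tab$start[i] + 1L):
                                               neg_tab$end[i]],
                   collapse = "")
    if (neg_tab$strand[i] == "+") piece else revcomp(piece)
  }, character(1))

  ## ---- assemble -----------------------------------------------------------
  tracks <- genome$tracks
  for (mark in names(hist_add))
    tracks[[mark]] <- rbind(tracks[[mark]], do.call(rbind, hist_add[[mark]]))
  te_ann <- rbind(genome$te_annotations, do.call(rbind, te_add))
  new_genome <- genome_context(
    chromosomes = vapply(chars, paste, character(1), collapse = ""),
    tracks = tracks, te_annotations = te_ann,
    te_targets = genome$te_targets)
  ids <- c(sprintf("pos_%04d", seq_len(config$n_pos)),
           sprintf("neg_%04d", seq_len(config$n_neg)))
  positions <- genomic_intervals(
    chrom = c(pos_tab$chrom, neg_tab$chrom),
    start = c(pos_tab$start, neg_tab$start),
    end = c(pos_tab$end, neg_tab$end),
    strand = c(pos_tab$strand, neg_tab$strand),
    id = ids)
  records <- pirna_set(c(bodies, neg_bodies), ids,
                       rep(c("positive", "negative"),
                           c(config$n_pos, config$n_neg)), positions)
  list(genome = new_genome, records = records)
}
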