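# Assembly of the twelve per-kernel feature blocks.  The expensive
# per-sequence extractions (k-mer profiles, flank scans, duplex folding)
# depend only on the sequence and the genome, never on labels or on the
# training split, so they are computed once into a cache and reused across
# cross-validation folds; only the k-mer subset, the cluster context
# (which references the training positions) and the kernel bandwidths are
# re-derived per fold.

split_positions <- function(records) {
  pos <- records$positions
  setNames(lapply(records$id, function(i)
    pos[pos$id == i, , drop = FALSE]), records$id)
}

#' Precompute the label-free per-sequence features
#'
#' Runs every training-independent extractor over the dataset once:
#' fixed-motif bits, full wildcard k-mer count/position profiles, duplex
#' binding triplet vectors, track distances, and the five flank scans.
#'
#' @param records a [pirna_set()].
#' @param genome a [genome_context()].
#' @param config a [kernel_config()].
#' @param patterns optional wildcard pattern list; defaults to the full
#'   enumeration for the configured k range.
#' @param verbose print progress per extractor.
#' @return a `"pirna_feature_cache"` list of per-sequence matrices keyed by
#'   id, reusable across folds via [pirna_mkl()] and [cross_validate()].
#' @export
pirna_feature_cache <- function(records, genome, config = kernel_config(),
                                patterns = NULL, verbose = FALSE) {
  stopifnot(inherits(records, "pirna_set"))
  kn <- config$kernels
  ids <- records$id
  n <- length(ids)
  posl <- split_positions(records)
  say <- function(...) if (verbose) message(...)
  cache <- list(ids = ids, seq_len = setNames(nchar(records$seq), ids))
  rows <- function(x) { rownames(x) <- ids; x }

  if ("U1A10" %in% kn) {
    say("fixed motifs")
    cache$fixed <- rows(t(vapply(records$seq, encode_fixed_motifs,
                                 numeric(nrow(config$motifs)),
                                 specs = config$motifs)))
  }
  if (any(c("KmerFreq", "KmerPos") %in% kn)) {
    say("k-mer profiles")
    if (is.null(patterns))
      patterns <- wildcard_patterns(config$kmin, config$kmax,
                                    config$max_x_fraction)
    cache$patterns <- patterns
    prof <- kmer_profile(records$seq, patterns, config$max_x_fraction)
    cache$counts <- rows(prof$counts)
    cache$firstpos <- rows(prof$firstpos)
  }
  if ("TEbinding" %in% kn) {
    say("duplex binding")
    if (is.null(genome$te_targets) || length(genome$te_targets) == 0L)
      stop("TEbinding kernel requires genome$te_targets")
    tg <- genome$te_targets
    attr(tg, "rc_split") <- strsplit(revcomp(toupper(tg)), "")
    cache$binding <- rows(t(vapply(records$seq, te_binding_features,
                                   numeric(32L), te_targets = tg,
                                   top_m = config$binding_top_m)))
  }
  per_record <- function(fun, width) {
    rows(t(vapply(posl, fun, numeric(width))))
  }
  if ("CentroTelo" %in% kn) {
    say("centromere/telomere distances")
    cache$centrotelo <- per_record(function(p)
      min_distance_features(p, config$tracks_centrotelo, genome),
      length(config$tracks_centrotelo))
  }
  if ("Histone" %in% kn) {
    say("histone-mark distances")
    cache$histone <- per_record(function(p)
      min_distance_features(p, config$tracks_histone, genome),
      length(config$tracks_histone))
  }
  if ("AMyb" %in% kn) {
    say("promoter scan")
    cache$promoter <- per_record(function(p)
      promoter_features(p, genome, config$promoter_motifs,
                        config$d_promoter), 3L)
  }
  if ("G4" %in% kn) {
    say("G-quadruplex scan")
    cache$g4 <- per_record(function(p)
      g4_features(p, genome, config$d_g4), 5L)
  }
  if ("CpG" %in% kn) {
    say("CpG-island scan")
    cache$cpg <- per_record(function(p)
      cpg_features(p, genome, config$d_cpg, config$cpg_min_len,
                   config$cpg_min_gc, config$cpg_min_oe,
                   config$cpg_window, config$cpg_shift), 5L)
  }
  if ("TEflank" %in% kn) {
    say("transposon context")
    cache$teflank <- per_record(function(p)
      te_flank_features(p, genome, config$te_classes, config$d_te,
                        config$te_weights), 2L * length(config$te_classes))
  }
  if ("InvRep" %in% kn) {
    say("inverted repeats")
    cache$invrep <- per_record(function(p)
      invrep_features(p, genome, config$d_invrep, config$invrep_min_len,
                      config$invrep_min_ident, config$invrep_seed), 2L)
  }
  class(cache) <- "pirna_feature_cache"
  cache
}

cache_subset <- function(cache, ids) {
  out <- cache
  for (nm in setdiff(names(cache), c("ids", "patterns", "seq_len")))
    out[[nm]] <- cache[[nm]][ids, , drop = FALSE]
  out$seq_len <- cache$seq_len[ids]
  out$ids <- ids
  out
}

# Training-position index: one row per mapped position of the given records.
position_index <- function(records) {
  p <- records$positions
  data.frame(id = p$id, chrom = p$chrom, start = p$start,
             stringsAsFactors = FALSE)
}

#' Assemble per-kernel feature blocks
#'
#' Builds the enabled kernels' [feature_block()]s from a precomputed cache,
#' a selected k-mer subset and a training-position index (for the cluster
#' context).
#'
#' @param records the sequences to represent (rows of the result).
#' @param cache a [pirna_feature_cache()] covering `records`.
#' @param genome a [genome_context()].
#' @param config a [kernel_config()].
#' @param sel_freq,sel_pos integer indices into `cache$patterns` for the
#'   k-mer frequency / position kernels.
#' @param train_positions `data.frame` (`id`, `chrom`, `start`) of the
#'   training-set positions used for neighbour search.
#' @param kernels optional subset of kernel names to build.
#' @return named list of [feature_block()]s.
#' @export
assemble_feature_blocks <- function(records, cache, genome, config,
                                    sel_freq = NULL, sel_pos = NULL,
                                    train_positions = NULL,
                                    kernels = NULL) {
  kn <- if (is.null(kernels)) config$kernels else kernels
  ids <- records$id
  cc <- cache_subset(cache, ids)
  blocks <- list()
  if ("U1A10" %in% kn)
    blocks$U1A10 <- feature_block("U1A10", cc$fixed)
  if ("KmerFreq" %in% kn) {
    stopifnot(!is.null(sel_freq))
    blocks$KmerFreq <- feature_block(
      "KmerFreq", cc$counts[, sel_freq, drop = FALSE] / cc$seq_len)
  }
  if ("KmerPos" %in% kn) {
    stopifnot(!is.null(sel_pos))
    blocks$KmerPos <- feature_block(
      "KmerPos", cc$firstpos[, sel_pos, drop = FALSE])
  }
  if ("TEbinding" %in% kn)
    blocks$TEbinding <- feature_block("TEbinding", cc$binding)
  if ("CentroTelo" %in% kn)
    blocks$CentroTelo <- feature_block("CentroTelo", cc$centrotelo)
  if ("Histone" %in% kn)
    blocks$Histone <- feature_block("Histone", cc$histone)
  if ("Cluster" %in% kn) {
    stopifnot(!is.null(train_positions))
    k <- config$n_neighbors
    posl <- split_positions(records)
    mats <- t(vapply(ids, function(i)
      as.vector(cluster_context(posl[[i]], train_positions, k, genome,
                                self_id = i)), numeric((k + 1L)^2)))
    rownames(mats) <- ids
    blocks$Cluster <- feature_block("Cluster", mats, metric = "frobenius",
                                    shape = c(k + 1L, k + 1L))
  }
  if ("AMyb" %in% kn)
    blocks$AMyb <- feature_block("AMyb", cc$promoter)
  if ("G4" %in% kn)
    blocks$G4 <- feature_block("G4", cc$g4)
  if ("CpG" %in% kn)
    blocks$CpG <- feature_block("CpG", cc$cpg)
  if ("TEflank" %in% kn)
    blocks$TEflank <- feature_block("TEflank", cc$teflank)
  if ("InvRep" %in% kn)
    blocks$InvRep <- feature_block("InvRep", cc$invrep)
  blocks[intersect(kn, names(blocks))]
}
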