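# Kernels built from mapped genomic positions: cluster context relative to
# the training set, and minimum distances to annotation tracks (centromere/
# telomere, histone-mark peaks).
#
# Conventions (part of the feature contract, the Frobenius metric is
# ordering sensitive): distances between sequences are |difference of
# interval starts|, strand is ignored, neighbours are restricted to the same
# chromosome, and missing neighbours / unmapped sequences are filled with a
# sentinel distance equal to the chromosome length.

#' K nearest training sequences on the same chromosome
#'
#' Neighbours are ranked by `|start_target - start_other|`; ties are broken
#' by lower coordinate, then id.  The target's own record is excluded via
#' `exclude_id`.  Labels are never consulted.
#'
#' @param chrom,start target position.
#' @param train_positions `data.frame` with columns `id`, `chrom`, `start`.
#' @param k number of neighbours (`k >= 0`).
#' @param exclude_id id whose positions are never returned (the target's own
#'   record).
#' @return `data.frame` of up to `k` rows: `id`, `chrom`, `start`, `dist`.
#' @export
nearest_neighbors <- function(chrom, start, train_positions, k,
                              exclude_id = NULL) {
  stopifnot(k >= 0)
  cand <- train_positions[train_positions$chrom == chrom, , drop = FALSE]
  if (!is.null(exclude_id))
    cand <- cand[cand$id != exclude_id, , drop = FALSE]
  if (k == 0L || nrow(cand) == 0L)
    return(data.frame(id = character(0), chrom = character(0),
                      start = numeric(0), dist = numeric(0)))
  d <- abs(cand$start - start)
  ord <- order(d, cand$start, cand$id, method = "radix")
  sel <- cand[head(ord, k), c("id", "chrom", "start"), drop = FALSE]
  sel$dist <- abs(sel$start - start)
  rownames(sel) <- NULL
  sel
}

#' Genomic cluster-context matrix of a sequence
#'
#' The density context: a `(k+1) x (k+1)` matrix of pairwise genomic
#' distances (bp, start-to-start) among the target position and its k
#' nearest training neighbours, ordered target first, then neighbours by
#' increasing distance.  Missing neighbours are padded with a sentinel
#' distance (the chromosome length); an unmapped sequence yields an
#' all-sentinel matrix with a zero diagonal.  When a sequence maps to
#' several positions, the densest context (smallest sum of neighbour
#' distances) is used.
#'
#' @param positions the sequence's positions (`data.frame` with `chrom`,
#'   `start`; may have zero rows).
#' @param train_positions training-set positions (`id`, `chrom`, `start`).
#' @param k number of neighbours.
#' @param genome a [genome_context()] providing sentinel lengths.
#' @param self_id id of the sequence itself, excluded from its neighbours.
#' @return numeric `(k+1) x (k+1)` matrix.
#' @export
cluster_context <- function(positions, train_positions, k, genome,
                            self_id = NULL) {
  m <- k + 1L
  build <- function(chrom, start) {
    sentinel <- chrom_length(genome, chrom)
    nb <- nearest_neighbors(chrom, start, train_positions, k, self_id)
    starts <- c(start, nb$start)
    mat <- matrix(sentinel, m, m)
    n <- length(starts)
    mat[seq_len(n), seq_len(n)] <- abs(outer(starts, starts, "-"))
    diag(mat) <- 0
    mat
  }
  if (nrow(positions) == 0L) {
    mat <- matrix(max_chrom_length(genome), m, m)
    diag(mat) <- 0
    return(mat)
  }
  mats <- lapply(seq_len(nrow(positions)), function(i)
    build(positions$chrom[i], positions$start[i]))
  density <- vapply(mats, function(mt) sum(mt[1, -1, drop = FALSE]),
                    numeric(1))
  mats[[which.min(density)]]
}

#' Minimum distances from a sequence to annotation tracks
#'
#' For each named track, the smallest gap in bp between any of the
#' sequence's positions and any track interval on the same chromosome
#' (0 when overlapping).  When no interval exists on any chromosome the
#' sequence maps to, the entry is a sentinel equal to the chromosome length
#' (maximum chromosome length for unmapped sequences).
#'
#' @param positions the sequence's positions (`chrom`, `start`, `end`).
#' @param track_names ordered character vector of track names.
#' @param genome a [genome_context()] whose `tracks` contain every name.
#' @return numeric vector, one entry per track.
#' @export
min_distance_features <- function(positions, track_names, genome) {
  missing_tracks <- setdiff(track_names, names(genome$tracks))
  if (length(missing_tracks))
    stop("unknown track name(s): ", paste(missing_tracks, collapse = ", "))
  out <- vapply(track_names, function(tn) {
    tr <- genome$tracks[[tn]]
    if (nrow(positions) == 0L) return(max_chrom_length(genome))
    best <- Inf
    for (i in seq_len(nrow(positions))) {
      iv <- tr[tr$chrom == positions$chrom[i], , drop = FALSE]
      if (nrow(iv) == 0L) next
      gap <- pmax(0, pmax(iv$start - positions$end[i],
                          positions$start[i] - iv$end))
      best <- min(best, gap)
    }
    if (is.infinite(best))
      best <- max(vapply(unique(positions$chrom), chrom_length,
                         numeric(1), genome = genome))
    best
  }, numeric(1))
  setNames(out, track_names)
}
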