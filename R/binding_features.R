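# "Binding with targets" kernel: antiparallel duplex prediction between a
# candidate sequence and transposon targets, summarised as 32 triplet
# structure-sequence elements.

# Watson-Crick plus G.U wobble, expressed on (sequence base, reverse-
# complemented target base): WC pairs become equal letters; the wobbles
# G.U and U.G become (G,A) and (T,C).
.PAIR_OK <- local({
  m <- diag(4) == 1
  dimnames(m) <- list(.DNA_ALPHABET, .DNA_ALPHABET)
  m["G", "A"] <- TRUE
  m["T", "C"] <- TRUE
  m
})

#' Predict the best gapless duplex of a sequence against one target
#'
#' The default duplex engine: the sequence is slid along the reverse
#' complement of the target at every offset with at least one aligned
#' base; aligned positions that can pair (Watson-Crick or G-U wobble)
#' count towards the score, and the offset with the most paired bases
#' wins (ties: smallest offset).  The result is a bracket-dot string on
#' the sequence: `"("` for paired, `"."` for unpaired positions.
#'
#' Externally computed structures (e.g. from a thermodynamic tool) can be
#' substituted via [read_duplex_structures()].
#'
#' @param seq DNA string (the candidate small RNA).
#' @param target DNA string (the transposon target).
#' @param target_id optional id stored in the result.
#' @return list with `structure`, `score` (number of paired bases) and
#'   `target_id`.
#' @export
duplex_fold <- function(seq, target, target_id = NA_character_) {
  stopifnot(nzchar(seq), nzchar(target))
  .duplex_core(strsplit(toupper(seq), "")[[1]],
               strsplit(revcomp(toupper(target)), "")[[1]],
               target_id)
}

# Core on pre-split characters (target already reverse complemented), so
# batch callers pay the Biostrings reverse-complement cost only once.
.duplex_core <- function(s, t, target_id = NA_character_) {
  n <- length(s); m <- length(t)
  ok <- .PAIR_OK[s, t, drop = FALSE]          # n x m, s[i] vs revcomp-target[j]
  offs <- col(ok) - row(ok)                   # j - i per cell
  score_by_off <- tabulate(offs[ok] + n, nbins = n + m - 1L)
  best_off <- which.max(score_by_off) - n     # smallest offset on ties
  i <- seq_len(n)
  j <- i + best_off
  paired <- logical(n)
  valid <- j >= 1L & j <= m
  paired[valid] <- ok[cbind(i[valid], j[valid])]
  list(structure = paste(ifelse(paired, "(", "."), collapse = ""),
       score = as.integer(sum(paired)), target_id = target_id)
}

.TRIPLET_NAMES <- local({
  states <- vapply(0:7, function(s)
    paste(ifelse(bitwAnd(s, c(4L, 2L, 1L)) > 0, "(", "."), collapse = ""),
    character(1))
  as.vector(t(outer(.DNA_ALPHABET, states, paste, sep = "")))
})

#' Triplet structure-sequence element frequencies
#'
#' Slides a 3-position window along the sequence and its bracket-dot
#' structure; each window is one of 32 elements (middle nucleotide among
#' A,C,G,T times the 8 pairing-state compositions of the three positions,
#' enumerated as 3-bit numbers `"..."` = 0 to `"((("` = 7).  Counts are
#' normalised by the number of windows, so the result is a probability
#' vector.
#'
#' @param seq DNA string of length at least 3.
#' @param structure bracket-dot string of the same length.
#' @return named numeric 32-vector summing to 1.
#' @export
triplet_vector <- function(seq, structure) {
  n <- nchar(seq)
  if (nchar(structure) != n)
    stop("structure length differs from sequence length")
  if (n < 3L) stop("sequence shorter than 3")
  if (grepl("[^(.]", structure))
    stop("structure must use only '(' and '.'")
  s <- strsplit(toupper(seq), "")[[1]]
  p <- strsplit(structure, "")[[1]] == "("
  w <- seq_len(n - 2L)
  state <- 4L * p[w] + 2L * p[w + 1L] + p[w + 2L]
  base <- .CODE[s[w + 1L]]
  counts <- tabulate(8L * base + state + 1L, nbins = 32L)
  setNames(counts / (n - 2L), .TRIPLET_NAMES)
}

#' Binding features of a sequence against a transposon target set
#'
#' Folds the sequence against every target with [duplex_fold()], keeps the
#' best-scoring target (ties: first in input order) and featurises its
#' bracket string with [triplet_vector()].  Setting `top_m > 1` averages
#' the triplet vectors of the `top_m` best-scoring targets instead.
#'
#' @param seq DNA string.
#' @param te_targets named character vector of target sequences.
#' @param top_m number of top-scoring targets to average over (default 1).
#' @param structures optional named list/vector of externally computed
#'   bracket strings (id of `seq` -> structure); when the sequence id is
#'   present there, the external structure is featurised directly.
#' @param seq_id id used to look up `structures`.
#' @return named numeric 32-vector.
#' @export
te_binding_features <- function(seq, te_targets, top_m = 1L,
                                structures = NULL, seq_id = NULL) {
  if (!is.null(structures) && !is.null(seq_id) &&
      !is.null(structures[[seq_id]]))
    return(triplet_vector(seq, structures[[seq_id]]))
  if (length(te_targets) == 0L) stop("empty target set")
  rc <- attr(te_targets, "rc_split")
  if (is.null(rc))
    rc <- strsplit(revcomp(toupper(te_targets)), "")
  s <- strsplit(toupper(seq), "")[[1]]
  folds <- lapply(seq_along(te_targets), function(k)
    .duplex_core(s, rc[[k]], names(te_targets)[k]))
  scores <- vapply(folds, `[[`, integer(1), "score")
  top_m <- min(top_m, length(folds))
  keep <- order(-scores, seq_along(scores))[seq_len(top_m)]
  vecs <- vapply(folds[keep], function(f)
    triplet_vector(seq, f$structure), numeric(32L))
  rowMeans(matrix(vecs, nrow = 32L,
                  dimnames = list(.TRIPLET_NAMES, NULL)))
}

#' Read externally computed duplex structures
#'
#' Two-column whitespace-separated text: sequence id and bracket-dot
#' string.  The result can be passed to [te_binding_features()] (plug-in
#' duplex engine contract).
#'
#' @param path file path.
#' @return named character vector id -> structure.
#' @export
read_duplex_structures <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("id", "structure"))
  setNames(tab$structure, tab$id)
}
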