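# Core domain containers: sequence sets, genomic intervals, genome context.
# All genomic coordinates are 0-based half-open internally (BED-native on
# disk); RNA and DNA are unified on the DNA alphabet, so the 5' "U" feature
# tests for "T" at position 1 of the stored string.

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement on plain character vectors over
#' \code{A,C,G,T} (and IUPAC codes, via [Biostrings::reverseComplement()]).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open, the BED convention.  Used for sequence
#' positions and for annotation tracks (histone-mark peaks, centromeres,
#' telomeres, transposable elements).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param strand `"+"` or `"-"`, recycled; defaults to `"+"`.
#' @param id optional identifier column (e.g. the sequence each position
#'   belongs to).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (and `id` when given).
#' @export
genomic_intervals <- function(chrom = character(0), start = integer(0),
                              end = integer(0), strand = "+", id = NULL) {
  n <- length(chrom)
  strand <- rep_len(as.character(strand), n)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = strand, stringsAsFactors = FALSE)
  if (!is.null(id)) df <- cbind(data.frame(id = as.character(id),
                                           stringsAsFactors = FALSE), df)
  validate_intervals(df)
}

#' @rdname genomic_intervals
#' @param x a candidate interval `data.frame`.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end", "strand") %in% names(x)))
  if (nrow(x)) {
    if (any(is.na(x$start)) || any(is.na(x$end)))
      stop("interval coordinates must be non-missing integers")
    if (any(x$start != floor(x$start)) || any(x$end != floor(x$end)))
      stop("interval coordinates must be integers")
    if (any(x$start < 0)) stop("interval start must be >= 0")
    if (any(x$start >= x$end)) stop("intervals must satisfy start < end")
    if (!all(x$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  }
  x
}

#' Assemble and validate a set of candidate sequences
#'
#' The central sequence container: identifiers, DNA sequences (U is stored
#' as T), class labels and zero or more mapped genomic positions per
#' sequence.
#'
#' @param seq character vector of sequences over `A,C,G,T,U` (case
#'   insensitive).
#' @param id unique identifiers; defaults to `names(seq)`.
#' @param label per-sequence labels among `"positive"`, `"negative"`,
#'   `"unknown"` (recycled).
#' @param positions interval `data.frame` as built by [genomic_intervals()]
#'   with an `id` column mapping each interval to a sequence; may be `NULL`.
#' @return an object of class `"pirna_set"`.
#' @seealso [validate_pirna_set()]
#' @export
pirna_set <- function(seq, id = names(seq), label = "unknown",
                      positions = NULL) {
  if (length(seq) == 0L) stop("empty dataset: at least one sequence required")
  if (is.null(id)) id <- paste0("seq", seq_along(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  seq <- chartr("u", "U", toupper(as.character(seq)))
  seq <- chartr("U", "T", seq)
  if (any(!nzchar(seq))) stop("empty sequence for id ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  bad <- grepl("[^ACGT]", seq)
  if (any(bad))
    stop("illegal characters in sequence(s): ",
         paste(head(id[bad], 5), collapse = ", "))
  label <- rep_len(as.character(label), length(seq))
  if (!all(label %in% c("positive", "negative", "unknown")))
    stop("labels must be 'positive', 'negative' or 'unknown'")
  if (is.null(positions)) {
    positions <- genomic_intervals(id = character(0))
  } else {
    positions <- validate_intervals(positions)
    if (!"id" %in% names(positions)) stop("positions need an 'id' column")
    if (!all(positions$id %in% id))
      stop("positions refer to unknown sequence ids")
  }
  structure(list(id = id, seq = setNames(seq, id),
                 label = setNames(label, id), positions = positions),
            class = "pirna_set")
}

#' Validate (or re-validate) a sequence dataset
#'
#' Idempotent: applying it to an already valid set returns an identical
#' object.
#'
#' @param x a `"pirna_set"` or anything accepted by [pirna_set()].
#' @return a validated `"pirna_set"`.
#' @export
validate_pirna_set <- function(x) {
  if (inherits(x, "pirna_set"))
    return(pirna_set(x$seq, x$id, x$label, x$positions))
  stop("not a pirna_set")
}

#' @export
length.pirna_set <- function(x) length(x$id)

#' @export
`[.pirna_set` <- function(x, i, ...) {
  ids <- x$id[i]
  pos <- x$positions[x$positions$id %in% ids, , drop = FALSE]
  rownames(pos) <- NULL
  pirna_set(x$seq[ids], ids, x$label[ids], pos)
}

#' @export
print.pirna_set <- function(x, ...) {
  tab <- table(factor(x$label, levels = c("positive", "negative", "unknown")))
  cat("pirna_set with", length(x$id), "sequences (",
      tab[["positive"]], "positive,", tab[["negative"]], "negative,",
      tab[["unknown"]], "unknown ),", nrow(x$positions),
      "mapped positions\n")
  invisible(x)
}

positions_of <- function(x, id) {
  x$positions[x$positions$id == id, , drop = FALSE]
}

#' Bundle a reference genome with its annotation tracks
#'
#' @param chromosomes named character vector (or `DNAStringSet`) of
#'   chromosome sequences.
#' @param tracks named list of interval `data.frame`s (see
#'   [genomic_intervals()]), e.g. `"H3K9me3"`, `"centromere"`.
#' @param te_annotations transposable-element annotation `data.frame` with
#'   columns `chrom`, `start`, `end`, `strand`, `te_class`, `family`, `rm`,
#'   `rd`, `rs` (the per-copy mismatch/deletion/substitution ratios).
#' @param te_targets named character vector of transposon target sequences
#'   used by the binding kernel.
#' @return an object of class `"genome_context"`.
#' @export
genome_context <- function(chromosomes, tracks = list(),
                           te_annotations = NULL, te_targets = NULL) {
  if (methods::is(chromosomes, "DNAStringSet"))
    chromosomes <- setNames(as.character(chromosomes), names(chromosomes))
  chromosomes <- setNames(toupper(as.character(chromosomes)),
                          names(chromosomes))
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("chromosomes must be named")
  lens <- nchar(chromosomes)
  check_track <- function(tr, nm) {
    tr <- validate_intervals(tr)
    unknown <- setdiff(unique(tr$chrom), names(chromosomes))
    if (length(unknown))
      stop("track '", nm, "' refers to unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
    if (nrow(tr) && any(tr$end > lens[tr$chrom]))
      stop("track '", nm, "' has intervals beyond chromosome bounds")
    tr
  }
  tracks <- if (length(tracks))
    setNames(lapply(names(tracks), function(nm)
      check_track(tracks[[nm]], nm)), names(tracks)) else list()
  if (is.null(te_annotations)) {
    te_annotations <- cbind(genomic_intervals(),
                            data.frame(te_class = character(0),
                                       family = character(0),
                                       rm = numeric(0), rd = numeric(0),
                                       rs = numeric(0)))
  } else {
    te_annotations <- check_track(te_annotations, "te_annotations")
    need <- c("te_class", "rm", "rd", "rs")
    if (!all(need %in% names(te_annotations)))
      stop("te_annotations needs columns: ", paste(need, collapse = ", "))
    if (!"family" %in% names(te_annotations))
      te_annotations$family <- te_annotations$te_class
    with(te_annotations, {
      if (any(rm < 0 | rd < 0 | rs < 0 | rm + rd + rs > 1 + 1e-9))
        stop("TE ratios must be in [0,1] with rm + rd + rs <= 1")
    })
  }
  if (!is.null(te_targets)) {
    te_targets <- chartr("U", "T", toupper(as.character(te_targets)))
    if (is.null(names(te_targets)))
      names(te_targets) <- paste0("te", seq_along(te_targets))
  }
  structure(list(chromosomes = chromosomes, tracks = tracks,
                 te_annotations = te_annotations, te_targets = te_targets),
            class = "genome_context")
}

#' @export
print.genome_context <- function(x, ...) {
  cat("genome_context:", length(x$chromosomes), "chromosome(s),",
      sum(nchar(x$chromosomes)), "bp;",
      length(x$tracks), "track(s);",
      nrow(x$te_annotations), "TE annotation(s);",
      length(x$te_targets), "TE target sequence(s)\n")
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  if (!chrom %in% names(genome$chromosomes))
    stop("unknown chromosome: ", chrom)
  nchar(genome$chromosomes[[chrom]])
}

max_chrom_length <- function(genome) max(nchar(genome$chromosomes))

#' Extract strand-aware flanks around a genomic interval
#'
#' Upstream means the 5' side of the oriented sequence: left of `start` on
#' the plus strand, right of `end` (reverse complemented) on the minus
#' strand.  Flanks are clipped at chromosome ends, never an error.  The
#' returned strings are oriented 5' to 3' with respect to the sequence, so
#' the last base of `upstream` abuts the sequence's first base.
#'
#' @param genome a [genome_context()].
#' @param chrom,start,end,strand one genomic interval (0-based half-open).
#' @param d flank size in bp.
#' @return list with `upstream`, `downstream`, `sequence` and `window`
#'   (upstream + sequence + downstream).
#' @export
extract_flank <- function(genome, chrom, start, end, strand = "+", d) {
  stopifnot(d > 0)
  chromseq <- genome$chromosomes[[chrom]]
  if (is.null(chromseq) || is.na(chromseq)) stop("unknown chromosome: ", chrom)
  L <- nchar(chromseq)
  left <- substr(chromseq, max(1, start - d + 1), start)        # [start-d, start)
  right <- substr(chromseq, end + 1, min(L, end + d))           # [end, end+d)
  body <- substr(chromseq, start + 1, end)
  if (strand == "+") {
    list(upstream = left, downstream = right, sequence = body,
         window = paste0(left, body, right))
  } else {
    up <- revcomp(right); dn <- revcomp(left); bd <- revcomp(body)
    list(upstream = up, downstream = dn, sequence = bd,
         window = paste0(up, bd, dn))
  }
}

#' Default kernel configuration
#'
#' Encodes the standard instantiation of the twelve kernels: the `{U,1}`,
#' `{A,10}` motif pair, 32 selected k-mers, 4 cluster neighbours, 40 kb
#' flanks (20 kb for CpG islands), CpG minimum length 100, and the
#' LINE/SINE/LTR transposon classes.
#'
#' @param ... named overrides of any default listed below.
#' @return a list of class `"kernel_config"`.
#' @export
kernel_config <- function(...) {
  cfg <- list(
    # specific motifs inside: ping-pong signature
    motifs = data.frame(base = c("T", "A"), pos = c(1L, 10L),
                        stringsAsFactors = FALSE),
    # wildcard k-mers
    kmin = 1L, kmax = 5L, max_x_fraction = 0.4,
    n_kmers = 32L, selector = "pso", pso = pso_params(),
    # cluster context
    n_neighbors = 4L,
    # flank scans (bp)
    d_promoter = 40000, d_g4 = 40000, d_invrep = 40000,
    d_te = 40000, d_cpg = 20000,
    promoter_motifs = "TAACGGTC",   # synthetic 8-mer consensus placeholder
    cpg_min_len = 100, cpg_min_gc = 0.5, cpg_min_oe = 0.6,
    cpg_window = 100, cpg_shift = 1,
    invrep_min_len = 20, invrep_min_ident = 0.9, invrep_seed = 12L,
    te_classes = c("LINE", "SINE", "LTR"),
    te_weights = c(LINE = 3, SINE = 2, LTR = 1),
    tracks_centrotelo = c("centromere", "telomere"),
    tracks_histone = c("H3K9me3", "H3K27me3"),
    binding_top_m = 1L,
    kernels = c("U1A10", "KmerFreq", "KmerPos", "TEbinding", "CentroTelo",
                "Histone", "Cluster", "AMyb", "G4", "CpG", "TEflank",
                "InvRep"))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown kernel_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_kmers >= 1, cfg$n_neighbors >= 0,
            cfg$d_promoter > 0, cfg$d_g4 > 0, cfg$d_invrep > 0,
            cfg$d_te > 0, cfg$d_cpg > 0, cfg$cpg_min_len > 0)
  class(cfg) <- "kernel_config"
  cfg
}
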