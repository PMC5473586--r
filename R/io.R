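# File formats: FASTA via Biostrings, BED via rtracklayer, plus the
# plain-text dataset fixture layout shared by the generator and the
# command-line interface.

#' Read sequences from a FASTA file
#'
#' Identifiers are taken from the headers up to the first whitespace;
#' wrapped and unwrapped records are both accepted, lowercase and U are
#' normalised.
#'
#' @param path FASTA file.
#' @param label label assigned to all records (default `"unknown"`).
#' @return a [pirna_set()] without positions.
#' @export
read_fasta <- function(path, label = "unknown") {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  pirna_set(as.character(ss), ids, label = label)
}

#' @rdname read_fasta
#' @param x a [pirna_set()] or named character vector of sequences.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "pirna_set")) x$seq else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Standard 0-based half-open BED (3 or more columns); the strand is taken
#' from column 6 when present (else `"+"`), the name column (when present)
#' becomes the `id`.
#'
#' @param path BED file.
#' @return an interval `data.frame` as from [genomic_intervals()].
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  strand <- as.character(df$strand)
  strand[!strand %in% c("+", "-")] <- "+"
  genomic_intervals(chrom = as.character(df$seqnames),
                    start = df$start - 1L, end = df$end, strand = strand,
                    id = if ("name" %in% names(df) &&
                             !all(is.na(df$name))) df$name else NULL)
}

#' @rdname read_bed
#' @param intervals an interval `data.frame`.
#' @export
write_bed <- function(intervals, path) {
  intervals <- validate_intervals(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    strand = intervals$strand)
  if ("id" %in% names(intervals)) names(gr) <- intervals$id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write / read the full dataset fixture layout
#'
#' One directory holding the genome FASTA, one BED per annotation track, a
#' 9-column TE annotation table, the transposon target FASTA, the candidate
#' sequences FASTA, their positions BED and a label TSV — everything the
#' pipeline needs, in plain text.
#'
#' @param dataset list with `genome` and `records`, as returned by
#'   [plant_dataset()].
#' @param dir target directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE,
             recursive = TRUE)
  g <- dataset$genome
  write_fasta(g$chromosomes, file.path(dir, "genome.fa"))
  for (nm in names(g$tracks))
    write_bed(g$tracks[[nm]], file.path(dir, "tracks", paste0(nm, ".bed")))
  write.table(g$te_annotations, file.path(dir, "te_annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(g$te_targets))
    write_fasta(g$te_targets, file.path(dir, "te_targets.fa"))
  r <- dataset$records
  write_fasta(r, file.path(dir, "sequences.fa"))
  if (nrow(r$positions))
    write_bed(r$positions, file.path(dir, "positions.bed"))
  write.table(data.frame(id = r$id, label = unname(r$label)),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  chroms <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(chroms) <- sub("\\s.*$", "", names(chroms))
  track_files <- list.files(file.path(dir, "tracks"), pattern = "\\.bed$",
                            full.names = TRUE)
  tracks <- setNames(lapply(track_files, read_bed),
                     sub("\\.bed$", "", basename(track_files)))
  te_path <- file.path(dir, "te_annotations.tsv")
  te_ann <- if (file.exists(te_path))
    read.table(te_path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE) else NULL
  tt_path <- file.path(dir, "te_targets.fa")
  targets <- if (file.exists(tt_path)) {
    tt <- Biostrings::readDNAStringSet(tt_path)
    setNames(as.character(tt), sub("\\s.*$", "", names(tt)))
  } else NULL
  genome <- genome_context(chroms, tracks, te_ann, targets)
  recs <- read_fasta(file.path(dir, "sequences.fa"))
  pos_path <- file.path(dir, "positions.bed")
  positions <- if (file.exists(pos_path)) read_bed(pos_path) else NULL
  lab_path <- file.path(dir, "labels.tsv")
  labels <- if (file.exists(lab_path)) {
    lt <- read.table(lab_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    setNames(lt$label, lt$id)[recs$id]
  } else "unknown"
  records <- pirna_set(recs$seq, recs$id, labels, positions)
  list(genome = genome, records = records)
}

#' Read promoter consensus motifs
#'
#' One IUPAC string per line; blank lines and `#` comments are skipped.
#'
#' @param path motif file.
#' @return character vector of motifs.
#' @export
read_motifs <- function(path) {
  lines <- trimws(readLines(path))
  toupper(lines[nzchar(lines) & !grepl("^#", lines)])
}

#' Read a key-value run configuration
#'
#' Plain text `key = value` lines (comments start with `#`); keys must be
#' [kernel_config()] fields.  Comma-separated values become vectors and
#' numeric strings are coerced.
#'
#' @param path configuration file.
#' @return a [kernel_config()] with the overrides applied.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(strsplit(trimws(kv[2]), ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    over[[key]] <- if (!anyNA(num)) num else val
  }
  do.call(kernel_config, over)
}
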