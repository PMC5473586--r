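# The user-facing model: fit the twelve-kernel MKL SVM on a labeled
# sequence set, predict new sequences, inspect kernel weights.

#' Fit the integrative piRNA MKL classifier
#'
#' End-to-end training: per-sequence feature extraction for every enabled
#' kernel, supervised k-mer subset selection, Gaussian kernel construction
#' with per-kernel bandwidth selection, and multiple-kernel-learning SVM
#' optimisation of the kernel weights.
#'
#' @param records a labeled [pirna_set()] (both classes present).
#' @param genome a [genome_context()].
#' @param config a [kernel_config()].
#' @param C SVM soft-margin cost.
#' @param seed seed for the stochastic k-mer selection stage (the only
#'   random stage of training).
#' @param cache optional [pirna_feature_cache()] covering `records`,
#'   to avoid re-extracting features (as in cross-validation).
#' @param kernels optional subset of `config$kernels` to train on.
#' @return an object of class `"pirna_mkl"` with `print`, `summary`,
#'   `coef`, `predict` and `plot` methods.
#' @examples
#' \donttest{
#' sim <- plant_dataset(sim_config(n_pos = 30, n_neg = 30,
#'                                 chrom_length = 300000, seed = 7))
#' fit <- pirna_mkl(sim$records, sim$genome, C = 1, seed = 7)
#' coef(fit)
#' }
#' @export
pirna_mkl <- function(records, genome, config = kernel_config(), C = 1,
                      seed = 1L, cache = NULL, kernels = NULL) {
  stopifnot(inherits(records, "pirna_set"),
            inherits(genome, "genome_context"))
  kn <- if (is.null(kernels)) config$kernels else
    match.arg(kernels, config$kernels, several.ok = TRUE)
  labels <- unname(records$label)
  if (!all(labels %in% c("positive", "negative")) ||
      length(unique(labels)) < 2L)
    stop("training requires labeled sequences of both classes")
  if (is.null(cache))
    cache <- pirna_feature_cache(records, genome, config)
  sel_freq <- sel_pos <- NULL
  if (any(c("KmerFreq", "KmerPos") %in% kn)) {
    params <- config$pso
    params$seed <- as.integer(seed)
    freq <- cache_subset(cache, records$id)$counts / nchar(records$seq)
    if ("KmerFreq" %in% kn)
      sel_freq <- select_kmers(freq, labels, config$n_kmers,
                               config$selector, params)
    if ("KmerPos" %in% kn) {
      fp <- cache_subset(cache, records$id)$firstpos
      sel_pos <- select_kmers(fp, labels, config$n_kmers,
                              config$selector, params)
    }
  }
  train_positions <- position_index(records)
  blocks <- assemble_feature_blocks(records, cache, genome, config,
                                    sel_freq, sel_pos, train_positions,
                                    kernels = kn)
  built <- lapply(blocks, build_kernel, labels = labels)
  mkl <- mkl_train(built, labels, C = C)
  structure(list(mkl = mkl, config = config, kernels = names(blocks),
                 selected_freq = cache$patterns[sel_freq],
                 selected_pos = cache$patterns[sel_pos],
                 train_blocks = blocks,
                 train_positions = train_positions,
                 labels = setNames(labels, records$id),
                 seed = seed, call = match.call()),
            class = "pirna_mkl")
}

# Feature blocks for new sequences under a fitted model: the k-mer kernels
# use the patterns selected at training time, the cluster kernel the stored
# training positions.
test_feature_blocks <- function(object, newdata, genome) {
  cfg <- object$config
  kn <- object$kernels
  cfg$kernels <- kn
  patterns <- unique(c(object$selected_freq, object$selected_pos))
  cache <- pirna_feature_cache(newdata, genome, cfg,
                               patterns = if (length(patterns)) patterns
                               else NULL)
  sel_freq <- if (length(object$selected_freq))
    match(object$selected_freq, cache$patterns)
  sel_pos <- if (length(object$selected_pos))
    match(object$selected_pos, cache$patterns)
  assemble_feature_blocks(newdata, cache, genome, cfg, sel_freq, sel_pos,
                          object$train_positions, kernels = kn)
}

#' Predict method for fitted piRNA MKL models
#'
#' Extracts the test sequences' feature blocks (position-dependent kernels
#' fall back to their absence sentinels for unmapped sequences), computes
#' the rectangular kernels against the training set under the stored
#' bandwidths, and evaluates the SVM decision function on the weighted
#' combination.
#'
#' @param object a [pirna_mkl()] fit.
#' @param newdata a [pirna_set()] of candidate sequences.
#' @param genome the [genome_context()] the new positions refer to.
#' @param type `"class"`, `"score"`, or `"both"`.
#' @param ... unused.
#' @return character labels, numeric scores, or a `data.frame` with both.
#' @export
predict.pirna_mkl <- function(object, newdata, genome,
                              type = c("class", "score", "both"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "pirna_set"))
  if (length(newdata) && nrow(newdata$positions) == 0L &&
      any(c("Cluster", "CentroTelo", "Histone", "AMyb", "G4", "CpG",
            "TEflank", "InvRep") %in% object$kernels))
    warning("no genomic positions supplied: position-dependent kernels ",
            "use their absence sentinels")
  blocks <- test_feature_blocks(object, newdata, genome)
  cross <- Map(function(te, tr, g) cross_kernel(te, tr, g),
               blocks, object$train_blocks[names(blocks)],
               object$mkl$gamma[names(blocks)])
  out <- mkl_predict(object$mkl, cross)
  switch(type,
         class = setNames(out$label, newdata$id),
         score = setNames(out$score, newdata$id),
         both = out)
}

#' @export
print.pirna_mkl <- function(x, ...) {
  cat("Integrative piRNA MKL classifier\n")
  cat("  kernels:", paste(x$kernels, collapse = ", "), "\n")
  cat("  training set:", length(x$labels), "sequences (",
      sum(x$labels == "positive"), "positive /",
      sum(x$labels == "negative"), "negative )\n")
  cat("  support vectors:", x$mkl$n_sv, " C:", x$mkl$C, "\n")
  invisible(x)
}

#' @export
summary.pirna_mkl <- function(object, ...) {
  rep <- kernel_weight_report(object)
  rep$gamma <- unname(object$mkl$gamma[rep$kernel])
  structure(list(weights = rep[order(-rep$weight), ],
                 n_train = length(object$labels),
                 n_sv = object$mkl$n_sv, C = object$mkl$C,
                 objective = object$mkl$objective,
                 selected_freq = object$selected_freq,
                 selected_pos = object$selected_pos),
            class = "summary.pirna_mkl")
}

#' @export
print.summary.pirna_mkl <- function(x, ...) {
  cat("Integrative piRNA MKL classifier —", nrow(x$weights),
      "kernels,", x$n_train, "training sequences,", x$n_sv,
      "support vectors\n\nKernel weights (L2-normalised):\n")
  print(x$weights, row.names = FALSE, digits = 4)
  if (length(x$selected_freq))
    cat("\nSelected frequency k-mers:",
        paste(head(x$selected_freq, 8), collapse = " "),
        if (length(x$selected_freq) > 8) "...", "\n")
  invisible(x)
}

#' @export
coef.pirna_mkl <- function(object, ...) object$mkl$weights

#' @export
plot.pirna_mkl <- function(x, ...) {
  w <- sort(coef(x), decreasing = TRUE)
  op <- par(mar = c(7, 4, 2, 1))
  on.exit(par(op))
  barplot(w, las = 2, ylab = "kernel weight (L2-normalised)",
          main = "MKL kernel weights", ...)
  invisible(x)
}

## ---- model persistence (plain-text directory) -----------------------------

#' Persist a fitted model as a plain-text directory
#'
#' Weights, dual coefficients, bias, per-kernel bandwidths, selected k-mer
#' patterns, training feature blocks and positions are written as
#' tab-separated text so a model can be reloaded (and inspected) without
#' binary serialisation.
#'
#' @param object a [pirna_mkl()] fit.
#' @param dir target directory (created if needed).
#' @export
save_pirna_mkl <- function(object, dir) {
  stopifnot(inherits(object, "pirna_mkl"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mkl <- object$mkl
  write.table(data.frame(kernel = names(mkl$weights),
                         weight = unname(mkl$weights),
                         gamma = unname(mkl$gamma),
                         metric = unname(mkl$metric)),
              file.path(dir, "kernels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(id = names(object$labels),
                         label = unname(object$labels),
                         coef = mkl$coef),
              file.path(dir, "dual.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c(sprintf("b\t%.17g", mkl$b), sprintf("C\t%.17g", mkl$C),
               sprintf("seed\t%d", object$seed)),
             file.path(dir, "scalars.tsv"))
  if (length(object$selected_freq))
    write_patterns(object$selected_freq, file.path(dir, "kmers_freq.txt"))
  if (length(object$selected_pos))
    write_patterns(object$selected_pos, file.path(dir, "kmers_pos.txt"))
  write.table(object$train_positions, file.path(dir, "train_positions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(file.path(dir, "blocks"), showWarnings = FALSE)
  for (nm in names(object$train_blocks)) {
    bl <- object$train_blocks[[nm]]
    hdr <- sprintf("# kernel=%s metric=%s shape=%s", nm, bl$metric,
                   if (is.null(bl$shape)) "" else
                     paste(bl$shape, collapse = "x"))
    path <- file.path(dir, "blocks", paste0(nm, ".tsv"))
    writeLines(hdr, path)
    suppressWarnings(write.table(bl$x, path, sep = "\t", quote = FALSE,
                                 col.names = NA, append = TRUE))
  }
  writeLines(deparse(object$config[setdiff(names(object$config), "pso")]),
             file.path(dir, "config.R"))
  invisible(dir)
}

#' @rdname save_pirna_mkl
#' @export
load_pirna_mkl <- function(dir) {
  kern <- read.table(file.path(dir, "kernels.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  dual <- read.table(file.path(dir, "dual.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  scal <- read.table(file.path(dir, "scalars.tsv"), sep = "\t",
                     stringsAsFactors = FALSE)
  scalars <- setNames(scal$V2, scal$V1)
  blocks <- list()
  for (nm in kern$kernel) {
    path <- file.path(dir, "blocks", paste0(nm, ".tsv"))
    hdr <- readLines(path, n = 1)
    x <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                              row.names = 1, skip = 1,
                              check.names = FALSE))
    shape <- sub(".*shape=", "", hdr)
    if (nzchar(shape)) {
      shp <- as.integer(strsplit(shape, "x")[[1]])
      blocks[[nm]] <- feature_block(nm, x, metric = "frobenius",
                                    shape = shp)
    } else {
      blocks[[nm]] <- feature_block(nm, x)
    }
  }
  cfg_src <- file.path(dir, "config.R")
  config <- kernel_config()
  if (file.exists(cfg_src)) {
    vals <- eval(parse(text = paste(readLines(cfg_src), collapse = "\n")))
    config[names(vals)] <- vals
  }
  sel_freq <- if (file.exists(file.path(dir, "kmers_freq.txt")))
    read_patterns(file.path(dir, "kmers_freq.txt")) else character(0)
  sel_pos <- if (file.exists(file.path(dir, "kmers_pos.txt")))
    read_patterns(file.path(dir, "kmers_pos.txt")) else character(0)
  mkl <- structure(list(weights = setNames(kern$weight, kern$kernel),
                        coef = dual$coef, b = unname(scalars[["b"]]),
                        C = unname(scalars[["C"]]),
                        n_sv = sum(dual$coef != 0),
                        gamma = setNames(kern$gamma, kern$kernel),
                        metric = setNames(kern$metric, kern$kernel),
                        ids = dual$id, labels = dual$label,
                        objective = NA_real_, trace = NA_real_),
                   class = "mkl_model")
  structure(list(mkl = mkl, config = config, kernels = kern$kernel,
                 selected_freq = sel_freq, selected_pos = sel_pos,
                 train_blocks = blocks,
                 train_positions = read.table(
                   file.path(dir, "train_positions.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE),
                 labels = setNames(dual$label, dual$id),
                 seed = as.integer(scalars[["seed"]]),
                 call = quote(load_pirna_mkl(dir))),
            class = "pirna_mkl")
}
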