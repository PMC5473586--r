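# Confusion-matrix metrics, stratified k-fold cross-validation with the
# full pipeline refit inside each fold (k-mer selection, bandwidths and
# kernel weights are supervised and would leak otherwise), per-kernel
# pertinence, ROC points.

#' Confusion counts
#'
#' @param truth,pred label vectors (`"positive"`/`"negative"`) of equal
#'   length; positive = piRNA.
#' @return named integer vector `(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred lengths differ")
  t_pos <- truth == "positive"; p_pos <- pred == "positive"
  c(TP = sum(t_pos & p_pos), FP = sum(!t_pos & p_pos),
    TN = sum(!t_pos & !p_pos), FN = sum(t_pos & !p_pos))
}

#' Classification metrics on the percentage scale
#'
#' Accuracy, sensitivity, specificity, precision and F1 score, each times
#' 100.  A `0/0` denominator yields 0, the convention under which an
#' all-negative predictor on balanced data scores
#' `Acc 50, Se 0, Sp 100, Pre 0, F1 0`.
#'
#' @param tp,fp,tn,fn confusion counts (or a single named vector as
#'   returned by [confusion_counts()] passed as `tp`).
#' @return named numeric vector `(Acc, Se, Sp, Pre, F1)`.
#' @export
classification_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && length(tp) == 4L) {
    fp <- tp[["FP"]]; tn <- tp[["TN"]]; fn <- tp[["FN"]]; tp <- tp[["TP"]]
  }
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("negative confusion counts")
  if (sum(counts) == 0) stop("all confusion counts are zero")
  frac <- function(num, den) if (den == 0) 0 else num / den
  c(Acc = 100 * (tp + tn) / (tp + tn + fp + fn),
    Se = 100 * frac(tp, tp + fn),
    Sp = 100 * frac(tn, tn + fp),
    Pre = 100 * frac(tp, tp + fp),
    F1 = 100 * frac(2 * tp, 2 * tp + fp + fn))
}

#' ROC-space point of a metrics vector
#'
#' `(FPR, TPR) = (100 - Sp, Se)` on the percentage scale.
#'
#' @param metrics a named vector containing `Se` and `Sp`.
#' @export
roc_point <- function(metrics) {
  c(FPR = 100 - metrics[["Sp"]], TPR = metrics[["Se"]])
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits each class into k folds after a seeded shuffle; inside each fold
#' the supervised stages (k-mer selection, bandwidth selection, kernel
#' weights, SVM) are refit on the training part only and applied to the
#' held-out part.  The expensive label-free feature extraction is shared
#' across folds via [pirna_feature_cache()].
#'
#' @param records a labeled [pirna_set()] with at least k members per
#'   class.
#' @param genome a [genome_context()].
#' @param config a [kernel_config()].
#' @param k number of folds.
#' @param seed seed for the fold shuffle and the per-fold k-mer selection.
#' @param C SVM cost.
#' @param cache optional precomputed [pirna_feature_cache()].
#' @param kernels optional subset of kernels (single names give the
#'   per-kernel pertinence entries).
#' @param verbose print per-fold progress.
#' @return object of class `"pirna_cv"`: per-fold metrics, their mean and
#'   standard deviation across folds, and pooled confusion counts.
#' @export
cross_validate <- function(records, genome, config = kernel_config(),
                           k = 5L, seed = 1L, C = 1, cache = NULL,
                           kernels = NULL, verbose = FALSE) {
  labels <- unname(records$label)
  if (!all(labels %in% c("positive", "negative")))
    stop("cross-validation requires fully labeled data")
  if (min(table(labels)) < k)
    stop("each class needs at least k members")
  if (is.null(cache))
    cache <- pirna_feature_cache(records, genome, config,
                                 verbose = verbose)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  fold <- stratified_folds(labels, k)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  per_fold <- matrix(NA_real_, k, 5,
                     dimnames = list(paste0("fold", seq_len(k)),
                                     c("Acc", "Se", "Sp", "Pre", "F1")))
  pooled <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (f in seq_len(k)) {
    if (verbose) message("fold ", f, "/", k)
    tr <- records[fold != f]
    te <- records[fold == f]
    fit <- pirna_mkl(tr, genome, config, C = C,
                     seed = (seed %% 2000000L) * 1000L + f,
                     cache = cache, kernels = kernels)
    pred <- predict(fit, te, genome, type = "class")
    cm <- confusion_counts(unname(te$label), unname(pred))
    pooled <- pooled + cm
    per_fold[f, ] <- classification_metrics(cm)
  }
  structure(list(folds = as.data.frame(per_fold),
                 mean = colMeans(per_fold),
                 sd = apply(per_fold, 2, sd),
                 confusion = pooled, k = k, seed = seed,
                 kernels = if (is.null(kernels)) config$kernels else
                   kernels),
            class = "pirna_cv")
}

#' @export
print.pirna_cv <- function(x, digits = 2, ...) {
  cat(x$k, "-fold cross-validation (kernels: ",
      paste(x$kernels, collapse = ", "), ")\n\n", sep = "")
  tab <- rbind(format(round(x$folds, digits), nsmall = digits),
               `mean +- sd` = sprintf(paste0("%.", digits, "f+-%.",
                                             digits, "f"),
                                      x$mean, x$sd))
  print(tab, right = TRUE)
  invisible(x)
}

#' Write a cross-validation report as a tab-separated table
#'
#' Columns in the conventional order `Acc, Se, Sp, Pre, F1`; the last row
#' holds `mean +- sd` across folds.
#'
#' @param cv a [cross_validate()] result.
#' @param path output file.
#' @export
write_cv_report <- function(cv, path) {
  tab <- cv$folds
  tab <- rbind(tab, mean = cv$mean, sd = cv$sd)
  write.table(cbind(fold = rownames(tab), round(tab, 2)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-kernel pertinence
#'
#' Cross-validates each enabled kernel on its own and reports the mean
#' accuracies sorted decreasingly — the computational read-out of how well
#' each biological feature characterises piRNAs in the dataset at hand.
#'
#' @inheritParams cross_validate
#' @return object of class `"pirna_pertinence"`: a `data.frame` with one
#'   row per kernel (`kernel`, `Acc`, `sd`), sorted by accuracy.
#' @export
per_kernel_pertinence <- function(records, genome,
                                  config = kernel_config(), k = 5L,
                                  seed = 1L, C = 1, cache = NULL,
                                  verbose = FALSE) {
  if (is.null(cache))
    cache <- pirna_feature_cache(records, genome, config,
                                 verbose = verbose)
  rows <- lapply(config$kernels, function(kn) {
    if (verbose) message("kernel ", kn)
    cv <- cross_validate(records, genome, config, k = k, seed = seed,
                         C = C, cache = cache, kernels = kn)
    data.frame(kernel = kn, Acc = cv$mean[["Acc"]], sd = cv$sd[["Acc"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$Acc), ]
  rownames(out) <- NULL
  class(out) <- c("pirna_pertinence", "data.frame")
  out
}

#' @export
print.pirna_pertinence <- function(x, ...) {
  cat("Per-kernel pertinence (single-kernel CV accuracy, %):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
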