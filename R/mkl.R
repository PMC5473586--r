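# Multiple kernel learning: an SVM on the weighted kernel combination
# K(w) = sum_m w_m K_m, with nonnegative weights constrained to the unit
# L2 sphere, optimised by spectral projected gradient descent (Barzilai-
# Borwein step lengths, Armijo acceptance).  The inner SVM solve uses
# kernlab's precomputed-kernel C-SVC.

#' Train a C-SVM on a precomputed kernel
#'
#' Thin wrapper around [kernlab::ksvm()] with a precomputed kernel matrix,
#' returning the full signed dual coefficient vector (`alpha_i * y_i` per
#' training sample, zero for non-support-vectors) and the bias with the
#' decision-function convention `f(x) = sum_i coef_i k(x_i, x) + b`.
#'
#' @param kernel numeric N x N kernel matrix.
#' @param labels `"positive"`/`"negative"`, or a numeric +1/-1 vector.
#' @param C soft-margin cost.
#' @return list with `coef` (length N, `= alpha * y`), `b`, `n_sv` and
#'   `objective` (the attained dual objective
#'   `sum alpha - 1/2 coef' K coef`).
#' @export
svm_train_precomputed <- function(kernel, labels, C = 1) {
  y <- if (is.numeric(labels)) sign(labels) else
    ifelse(labels == "positive", 1, -1)
  if (length(unique(y)) < 2L) stop("both classes are required")
  stopifnot(nrow(kernel) == length(y), ncol(kernel) == length(y))
  fit <- ksvm(as.kernelMatrix(kernel), y, type = "C-svc", C = C,
              scaled = FALSE)
  n <- length(y)
  idx <- SVindex(fit)
  co <- numeric(n)
  co[idx] <- unlist(alpha(fit)) * y[idx]
  ## kernlab's internal class coding can flip the decision sign; align it
  ## with our +1 = positive convention on the training decision values
  f <- as.vector(kernel %*% co) - b(fit)
  if (mean(sign(f) == y) >= 0.5) {
    bias <- -b(fit)
  } else {
    co <- -co
    bias <- b(fit)
  }
  list(coef = co, b = bias, n_sv = length(idx),
       objective = sum(co * y) - 0.5 * drop(crossprod(co, kernel %*% co)))
}

# Projection onto {w >= 0, ||w||_2 = 1}.
.proj_simplex_l2 <- function(w) {
  w <- pmax(w, 0)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) rep(1 / sqrt(length(w)), length(w)) else w / nrm
}

# MKL objective J(w) = dual value of the SVM on K(w), plus its gradient
# g_m = -1/2 coef' K_m coef (Danskin).
.mkl_eval <- function(kmats, w, y, C) {
  K <- Reduce(`+`, Map(`*`, kmats, w))
  svm <- svm_train_precomputed(K, y, C)
  grad <- vapply(kmats, function(Km)
    -0.5 * drop(crossprod(svm$coef, Km %*% svm$coef)), numeric(1))
  list(f = svm$objective, grad = grad, svm = svm)
}

#' Learn an optimal kernel combination with an SVM
#'
#' Alternates an exact SVM solve on the current combination
#' `K(w) = sum_m w_m K_m` with a spectral projected-gradient step on the
#' weights (gradient `g_m = -1/2 (alpha o y)' K_m (alpha o y)`, projection
#' onto the nonnegative unit L2 sphere, Barzilai-Borwein step lengths,
#' Armijo backtracking).  The objective is non-increasing across accepted
#' steps; iteration stops when its change falls below `tol` or after
#' `max_outer` steps.  Deterministic for fixed inputs.
#'
#' @param kernels list of [build_kernel()] results (or plain matrices)
#'   sharing the same training ids and order.
#' @param labels training labels.
#' @param C soft-margin cost.
#' @param tol relative objective-change tolerance.
#' @param max_outer maximum number of outer weight updates.
#' @return object of class `"mkl_model"`: kernel `weights` (L2-normalised),
#'   signed dual coefficients `coef`, bias `b`, per-kernel `gamma` and
#'   `metric`, training `ids` and `labels`, `C`, and the objective trace.
#' @export
mkl_train <- function(kernels, labels, C = 1, tol = 1e-4, max_outer = 50L) {
  stopifnot(length(kernels) >= 1)
  if (is.null(names(kernels)))
    names(kernels) <- vapply(kernels, function(k)
      if (inherits(k, "kernel_matrix")) k$name else "", character(1))
  kmats <- lapply(kernels, function(k)
    if (inherits(k, "kernel_matrix")) k$values else as.matrix(k))
  meta <- lapply(kernels, function(k)
    if (inherits(k, "kernel_matrix"))
      list(gamma = k$gamma, metric = k$metric, ids = k$ids)
    else list(gamma = NA_real_, metric = NA_character_, ids = rownames(k)))
  if (any(vapply(kmats, function(K) all(K == 0), logical(1))))
    stop("all-zero kernel matrix")
  y <- if (is.numeric(labels)) sign(labels) else
    ifelse(labels == "positive", 1, -1)
  M <- length(kmats)
  w <- rep(1 / sqrt(M), M)
  ev <- .mkl_eval(kmats, w, y, C)
  trace <- ev$f
  if (M > 1L) {
    w_prev <- NULL; g_prev <- NULL
    for (it in seq_len(max_outer)) {
      step <- if (is.null(w_prev)) {
        1 / max(abs(ev$grad), 1e-12)
      } else {
        s <- w - w_prev; yv <- ev$grad - g_prev
        sy <- sum(s * yv)
        if (sy > 1e-12) min(max(sum(s * s) / sy, 1e-8), 1e8)
        else 1 / max(abs(ev$grad), 1e-12)
      }
      w_trial <- .proj_simplex_l2(w - step * ev$grad)
      dirn <- w_trial - w
      gd <- sum(ev$grad * dirn)
      if (sqrt(sum(dirn^2)) < 1e-10 || gd > -1e-12) break
      lambda <- 1; accepted <- FALSE
      for (ls in 1:20) {
        w_new <- .proj_simplex_l2(w + lambda * dirn)
        ev_new <- .mkl_eval(kmats, w_new, y, C)
        if (ev_new$f <= ev$f + 1e-4 * lambda * gd) { accepted <- TRUE; break }
        lambda <- lambda / 2
      }
      if (!accepted) break
      w_prev <- w; g_prev <- ev$grad
      converged <- abs(ev$f - ev_new$f) < tol * (1 + abs(ev_new$f))
      w <- w_new; ev <- ev_new
      trace <- c(trace, ev$f)
      if (converged) break
    }
  }
  structure(list(weights = setNames(w, names(kernels)),
                 coef = ev$svm$coef, b = ev$svm$b, C = C,
                 n_sv = ev$svm$n_sv,
                 gamma = setNames(vapply(meta, `[[`, numeric(1), "gamma"),
                                  names(kernels)),
                 metric = setNames(vapply(meta, `[[`, character(1),
                                          "metric"), names(kernels)),
                 ids = meta[[1]]$ids, labels = y,
                 objective = ev$f, trace = trace),
            class = "mkl_model")
}

#' Decision scores of an MKL model on precomputed cross-kernels
#'
#' `score(x) = sum_i coef_i sum_m w_m k_m(x_i, x) + b`; the predicted label
#' is the sign of the score.
#'
#' @param model an [mkl_train()] result.
#' @param cross_kernels named list of `n_test x n_train` matrices, one per
#'   trained kernel, in the trained order.
#' @return `data.frame` with `score` and `label`
#'   (`"positive"`/`"negative"`).
#' @export
mkl_predict <- function(model, cross_kernels) {
  stopifnot(inherits(model, "mkl_model"))
  missing_k <- setdiff(names(model$weights), names(cross_kernels))
  if (length(missing_k))
    stop("missing kernel block(s): ", paste(missing_k, collapse = ", "))
  cross_kernels <- cross_kernels[names(model$weights)]
  nte <- nrow(cross_kernels[[1]])
  if (nte == 0L)
    return(data.frame(score = numeric(0), label = character(0)))
  Kc <- Reduce(`+`, Map(`*`, cross_kernels, model$weights))
  if (ncol(Kc) != length(model$coef))
    stop("cross-kernel column count does not match the training set")
  score <- as.vector(Kc %*% model$coef) + model$b
  data.frame(score = score,
             label = ifelse(score >= 0, "positive", "negative"),
             row.names = rownames(cross_kernels[[1]]),
             stringsAsFactors = FALSE)
}

#' Per-kernel weight report
#'
#' The learned kernel weights in training order with normalised
#' (sum-to-one) and percentage views.
#'
#' @param model an `"mkl_model"` or `"pirna_mkl"` object.
#' @return `data.frame` with `kernel`, `weight`, `fraction`, `percent`.
#' @export
kernel_weight_report <- function(model) {
  if (inherits(model, "pirna_mkl")) model <- model$mkl
  stopifnot(inherits(model, "mkl_model"))
  w <- model$weights
  data.frame(kernel = names(w), weight = unname(w),
             fraction = unname(w / sum(w)),
             percent = unname(100 * w / sum(w)),
             stringsAsFactors = FALSE)
}

#' @export
print.mkl_model <- function(x, ...) {
  cat("MKL SVM:", length(x$weights), "kernel(s),", length(x$coef),
      "training samples,", x$n_sv, "support vectors, C =", x$C, "\n")
  w <- sort(x$weights, decreasing = TRUE)
  cat("kernel weights:",
      paste(sprintf("%s=%.3f", names(w), w), collapse = ", "), "\n")
  invisible(x)
}
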