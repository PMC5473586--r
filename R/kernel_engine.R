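# Gaussian kernel machinery: one feature block (vectors or flattened
# matrices) -> pairwise distances -> bandwidth selection (Jaakkola median
# heuristic refined by the inter-cluster distance criterion) -> N x N
# kernel matrix  k(x, y) = exp(-gamma ||x - y||^2).

#' Construct a feature block
#'
#' One per-sequence representation for one kernel: a numeric matrix with
#' one row per sequence.  Matrix-valued representations (the cluster
#' context) are stored flattened with `metric = "frobenius"` and their
#' original dimension in `shape`; since the row/column ordering convention
#' is fixed, the Frobenius distance between matrices equals the Euclidean
#' distance between their flattened vectors.
#'
#' @param name kernel name.
#' @param x numeric matrix (sequences x features), rownames = sequence ids.
#' @param metric `"euclidean"` for vector representations, `"frobenius"`
#'   for flattened matrices.
#' @param shape integer 2-vector, required iff `metric = "frobenius"`.
#' @return object of class `"feature_block"`.
#' @export
feature_block <- function(name, x, metric = c("euclidean", "frobenius"),
                          shape = NULL) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty feature block")
  if (anyNA(x)) stop("feature block '", name, "' contains NA")
  if (metric == "frobenius") {
    if (is.null(shape) || length(shape) != 2L || prod(shape) != ncol(x))
      stop("frobenius blocks need a matching 'shape'")
  } else if (!is.null(shape)) {
    stop("'shape' is only meaningful for frobenius blocks")
  }
  structure(list(name = name, x = x, metric = metric, shape = shape),
            class = "feature_block")
}

#' Pairwise distance matrix of a feature block
#'
#' Euclidean distance for vector blocks; Frobenius distance (entrywise
#' Euclidean norm of the matrix difference) for matrix blocks, computed on
#' the flattened representation.
#'
#' @param block a [feature_block()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distances <- function(block) {
  stopifnot(inherits(block, "feature_block"))
  as.matrix(dist(block$x))
}

#' Jaakkola bandwidth heuristic
#'
#' `gamma = 1 / (2 * median(distMat)^2)`, the median taken over the
#' off-diagonal distances.  Should duplicated points drive that median to
#' zero, the median of the nonzero off-diagonal distances is used instead;
#' if every distance is zero the block is degenerate and an error is
#' raised.
#'
#' @param distmat symmetric distance matrix.
#' @return positive scalar `gamma`.
#' @export
jaakkola_gamma <- function(distmat) {
  off <- distmat[upper.tri(distmat)]
  if (length(off) == 0L || all(off == 0))
    stop("degenerate feature block: all pairwise distances are zero")
  med <- median(off)
  if (med == 0) med <- median(off[off > 0])
  1 / (2 * med^2)
}

#' Candidate bandwidth grid
#'
#' The nine values `exp(i) * gamma` for integer `i` in `[-4, 4]`,
#' increasing.
#'
#' @param gamma_jaak the Jaakkola value.
#' @export
candidate_gammas <- function(gamma_jaak) {
  stopifnot(gamma_jaak > 0)
  exp(-4:4) * gamma_jaak
}

#' Inter-cluster distance in the kernel-induced feature space
#'
#' The average, over all points, of the induced-space distance from each
#' positive point to the negative class mean and from each negative point
#' to the positive class mean:
#' `delta = (sum d(x+, mean-) + sum d(x-, mean+)) / (l+ + l-)`,
#' with `d(x, mean_S)^2 = k(x,x) - (2/l) sum_i k(x, x_i) +
#' (1/l^2) sum_ij k(x_i, x_j)` expanded through the kernel trick.
#'
#' @param kernel numeric N x N kernel matrix.
#' @param labels `"positive"`/`"negative"` (or logical) per row.
#' @return nonnegative scalar `delta`.
#' @export
intercluster_distance <- function(kernel, labels) {
  y <- if (is.logical(labels)) labels else labels == "positive"
  if (!any(y) || all(y)) stop("both classes are required")
  d_to_mean <- function(idx_x, idx_s) {
    l <- length(idx_s)
    kxx <- diag(kernel)[idx_x]
    kxs <- rowSums(kernel[idx_x, idx_s, drop = FALSE]) / l
    kss <- sum(kernel[idx_s, idx_s]) / l^2
    sqrt(pmax(0, kxx - 2 * kxs + kss))
  }
  pos <- which(y); neg <- which(!y)
  (sum(d_to_mean(pos, neg)) + sum(d_to_mean(neg, pos))) /
    (length(pos) + length(neg))
}

#' Build the Gaussian kernel of a feature block
#'
#' Computes the pairwise distances, the Jaakkola bandwidth and its nine
#' candidate refinements, evaluates the inter-cluster distance for each
#' candidate, and returns the kernel with the largest separation (ties:
#' smallest gamma).
#'
#' @param block a [feature_block()].
#' @param labels training labels (`"positive"`/`"negative"`).
#' @return object of class `"kernel_matrix"`: list with `values` (N x N),
#'   `gamma`, `name`, `ids`, `metric` and the `delta` attained.
#' @export
build_kernel <- function(block, labels) {
  dmat <- pairwise_distances(block)
  if (all(dmat == 0)) {
    ## constant feature block: no geometry to tune, the kernel carries no
    ## information; fall back to a unit bandwidth and a constant kernel
    n <- nrow(dmat)
    return(structure(list(values = matrix(1, n, n,
                                          dimnames = dimnames(dmat)),
                          gamma = 1, name = block$name,
                          ids = rownames(block$x), metric = block$metric,
                          delta = 0),
                     class = "kernel_matrix"))
  }
  d2 <- dmat^2
  gammas <- candidate_gammas(jaakkola_gamma(dmat))
  best <- NULL
  for (g in gammas) {            # increasing, strict improvement keeps ties low
    K <- exp(-g * d2)
    delta <- intercluster_distance(K, labels)
    if (is.null(best) || delta > best$delta + 1e-12)
      best <- list(values = K, gamma = g, delta = delta)
  }
  structure(list(values = best$values, gamma = best$gamma,
                 name = block$name, ids = rownames(block$x),
                 metric = block$metric, delta = best$delta),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("kernel_matrix '", x$name, "': ", nrow(x$values), " x ",
      ncol(x$values), ", gamma = ", signif(x$gamma, 4),
      ", delta = ", signif(x$delta, 4), "\n", sep = "")
  invisible(x)
}

#' Persist / restore a kernel matrix as a dense text file
#'
#' One header line records the kernel name, the selected bandwidth and the
#' ordered training ids; the matrix follows as tab-separated values.
#'
#' @param kernel a `"kernel_matrix"` (see [build_kernel()]).
#' @param path file path.
#' @export
write_kernel_matrix <- function(kernel, path) {
  stopifnot(inherits(kernel, "kernel_matrix"))
  hdr <- sprintf("# kernel=%s gamma=%.17g delta=%.17g metric=%s ids=%s",
                 kernel$name, kernel$gamma, kernel$delta, kernel$metric,
                 paste(kernel$ids, collapse = ","))
  writeLines(hdr, path)
  suppressWarnings(write.table(kernel$values, path, sep = "\t",
                               quote = FALSE, row.names = FALSE,
                               col.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_kernel_matrix
#' @export
read_kernel_matrix <- function(path) {
  hdr <- readLines(path, n = 1L)
  field <- function(key) sub(paste0(".*", key, "=([^ ]+).*"), "\\1", hdr)
  ids <- strsplit(field("ids"), ",", fixed = TRUE)[[1]]
  values <- as.matrix(read.table(path, sep = "\t", skip = 1L))
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, gamma = as.numeric(field("gamma")),
                 name = field("kernel"), ids = ids,
                 metric = field("metric"),
                 delta = as.numeric(field("delta"))),
            class = "kernel_matrix")
}

#' Rectangular kernel between test and training blocks
#'
#' `k(test_i, train_j)` under a stored bandwidth; used by the prediction
#' path.
#'
#' @param test_block,train_block [feature_block()]s with identical feature
#'   dimension and metric.
#' @param gamma the bandwidth selected at training time.
#' @return `nrow(test) x nrow(train)` matrix.
#' @export
cross_kernel <- function(test_block, train_block, gamma) {
  stopifnot(inherits(test_block, "feature_block"),
            inherits(train_block, "feature_block"),
            gamma > 0)
  if (ncol(test_block$x) != ncol(train_block$x))
    stop("feature dimension mismatch between test and training blocks")
  if (test_block$metric != train_block$metric)
    stop("metric mismatch between test and training blocks")
  a <- test_block$x; b <- train_block$x
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}
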