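test_that("pairwise distances: Euclidean for vectors, Frobenius for matrices", {
  b <- feature_block("v", rbind(a = c(0, 0), b = c(3, 4)))
  expect_equal(unname(pairwise_distances(b)),
               matrix(c(0, 5, 5, 0), 2))
  ## two 2x2 matrices, flattened; entrywise norm of the difference
  m1 <- as.vector(matrix(c(0, 1, 1, 0), 2))
  m2 <- as.vector(matrix(c(0, 3, 3, 0), 2))
  bm <- feature_block("m", rbind(m1, m2), metric = "frobenius",
                      shape = c(2, 2))
  expect_equal(pairwise_distances(bm)[1, 2], sqrt(8))
  expect_equal(pairwise_distances(bm)[1, 1], 0)
  expect_error(feature_block("m", rbind(m1, m2), metric = "frobenius"),
               "shape")
  expect_error(feature_block("v", rbind(c(0, 0)), shape = c(1, 2)),
               "frobenius")
})

test_that("Jaakkola heuristic uses the off-diagonal median", {
  d1 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(jaakkola_gamma(d1), 0.5)
  d2 <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(jaakkola_gamma(d2), 0.125)
  expect_error(jaakkola_gamma(matrix(0, 3, 3)), "degenerate")
  ## duplicated points do not zero the bandwidth
  d3 <- matrix(0, 3, 3); d3[1, 2] <- d3[2, 1] <- 0; d3[1, 3] <- d3[3, 1] <-
    2; d3[2, 3] <- d3[3, 2] <- 2
  expect_equal(jaakkola_gamma(d3), 0.125)
})

test_that("candidate grid is exp(i) * gamma for i in -4..4", {
  g <- candidate_gammas(0.5)
  expect_length(g, 9L)
  expect_equal(g[5], 0.5)
  expect_true(all(diff(g) > 0))
  expect_equal(g, exp(-4:4) * 0.5)
  expect_error(candidate_gammas(0))
})

test_that("inter-cluster distance matches the induced-space hand case", {
  ## X+ = {0}, X- = {1}, gamma = 1: delta = sqrt(2 - 2/e)
  K <- exp(-1 * as.matrix(dist(c(0, 1)))^2)
  expect_equal(intercluster_distance(K, c("positive", "negative")),
               sqrt(2 - 2 * exp(-1)), tolerance = 1e-12)
  ## coincident classes: zero separation
  Kc <- matrix(1, 4, 4)
  expect_equal(intercluster_distance(Kc, rep(c("positive", "negative"),
                                             2)), 0)
  expect_error(intercluster_distance(Kc, rep("positive", 4)), "classes")
})

test_that("delta grows when the classes move apart at fixed gamma", {
  set.seed(8)
  base <- c(rnorm(10, 0, 0.2), rnorm(10, 1, 0.2))
  labels <- rep(c("positive", "negative"), each = 10)
  deltas <- vapply(c(0, 1, 3), function(shift) {
    x <- base + shift * (labels == "negative")
    K <- exp(-0.5 * as.matrix(dist(x))^2)
    intercluster_distance(K, labels)
  }, numeric(1))
  expect_true(all(diff(deltas) > 0))
})

test_that("kernel-trick delta equals the explicit-map linear-kernel delta", {
  set.seed(14)
  X <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 2), 10))
  labels <- rep(c("positive", "negative"), each = 10)
  K <- tcrossprod(X)
  expect_equal(intercluster_distance(K, labels),
               oracle_delta_linear(X, labels))
})

test_that("bandwidth selection maximises delta over the nine candidates", {
  set.seed(15)
  X <- rbind(matrix(rnorm(24, 0, 0.5), ncol = 2),
             matrix(rnorm(24, 4, 0.5), ncol = 2))
  labels <- rep(c("positive", "negative"), each = 12)
  b <- feature_block("x", X)
  km <- build_kernel(b, labels)
  ## exhaustive sweep as its own oracle
  D2 <- pairwise_distances(b)^2
  cand <- candidate_gammas(jaakkola_gamma(sqrt(D2)))
  deltas <- vapply(cand, function(g)
    intercluster_distance(exp(-g * D2), labels), numeric(1))
  expect_equal(km$gamma, cand[which.max(deltas)])
  expect_equal(km$delta, max(deltas))
  ## Gaussian kernel invariants
  expect_equal(unname(diag(km$values)), rep(1, nrow(X)))
  expect_true(isSymmetric(km$values))
  expect_gte(min(eigen(km$values, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  ## entries decrease with distance at fixed gamma
  ord <- order(D2[1, -1])
  expect_equal(order(km$values[1, -1], decreasing = TRUE), ord)
})

test_that("a constant feature block degrades to an uninformative kernel", {
  X <- matrix(2, 10, 4, dimnames = list(paste0("s", 1:10), NULL))
  km <- build_kernel(feature_block("const", X),
                     rep(c("positive", "negative"), 5))
  expect_true(all(km$values == 1))
  expect_equal(km$delta, 0)
  ## the downstream SVM stays usable and predicts a constant class
  fit <- svm_train_precomputed(km$values, rep(c("positive", "negative"),
                                              5), C = 1)
  scores <- as.vector(km$values %*% fit$coef) + fit$b
  expect_length(unique(sign(scores)), 1L)
})

test_that("kernel matrices round-trip through their text format", {
  set.seed(19)
  X <- matrix(rnorm(16), 8, dimnames = list(paste0("s", 1:8), NULL))
  km <- build_kernel(feature_block("toy", X),
                     rep(c("positive", "negative"), 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kernel_matrix(km, path)
  back <- read_kernel_matrix(path)
  expect_equal(back$gamma, km$gamma)
  expect_equal(back$name, km$name)
  expect_equal(back$ids, km$ids)
  expect_equal(unname(back$values), unname(km$values), tolerance = 1e-12)
})

test_that("cross kernels are consistent with the square kernel", {
  set.seed(16)
  X <- matrix(rnorm(30), ncol = 3)
  b <- feature_block("x", X)
  km <- build_kernel(b, rep(c("positive", "negative"), each = 5))
  cr <- cross_kernel(b, b, km$gamma)
  expect_equal(cr, km$values, tolerance = 1e-9, ignore_attr = TRUE)
  ## a test point equal to a training point gives a unit entry there
  bt <- feature_block("x", X[3, , drop = FALSE])
  expect_equal(cross_kernel(bt, b, km$gamma)[1, 3], 1)
  expect_error(cross_kernel(feature_block("x", X[, 1:2]), b, km$gamma),
               "dimension")
})
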