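sep_kernel <- function(n = 20, gap = 3, sd = 0.3, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n / 2, 0, sd), rnorm(n / 2, gap, sd))
  list(K = exp(-as.matrix(dist(x))^2),
       labels = rep(c("positive", "negative"), each = n / 2))
}

test_that("precomputed-kernel SVM separates well-separated clusters", {
  sk <- sep_kernel()
  fit <- svm_train_precomputed(sk$K, sk$labels, C = 1)
  y <- ifelse(sk$labels == "positive", 1, -1)
  f <- as.vector(sk$K %*% fit$coef) + fit$b
  expect_equal(sign(f), y)
  ## KKT box: 0 <= alpha_i = coef_i * y_i <= C
  expect_true(all(fit$coef * y >= -1e-8))
  expect_true(all(fit$coef * y <= 1 + 1e-8))
  ## flipped labels negate the decision values
  fit2 <- svm_train_precomputed(sk$K, rev(sk$labels), C = 1)
  f2 <- as.vector(sk$K %*% fit2$coef) + fit2$b
  expect_equal(f2, -f, tolerance = 5e-3)   # up to solver tolerance
})

test_that("a duplicated point with both labels saturates its alphas", {
  K <- exp(-as.matrix(dist(c(0, 0, 3, 3.2)))^2)
  labels <- c("positive", "negative", "negative", "negative")
  fit <- svm_train_precomputed(K, labels, C = 2)
  y <- c(1, -1, -1, -1)
  a <- fit$coef * y
  expect_true(all(a >= -1e-6 & a <= 2 + 1e-6))
  expect_equal(a[1], 2, tolerance = 1e-6)   # the contradictory pair is bounded
  expect_error(svm_train_precomputed(K, rep("positive", 4)), "classes")
})

test_that("single-kernel MKL reduces to the plain SVM", {
  sk <- sep_kernel()
  m <- mkl_train(list(k1 = sk$K), sk$labels, C = 1)
  expect_equal(unname(m$weights), 1)
  svm <- svm_train_precomputed(sk$K, sk$labels, C = 1)
  expect_equal(m$coef, svm$coef)
  expect_equal(m$b, svm$b)
})

test_that("objective never rises across accepted MKL steps", {
  sk <- sep_kernel(n = 30, gap = 1.5, sd = 0.6, seed = 2)
  set.seed(3)
  noise <- exp(-as.matrix(dist(rnorm(30)))^2)
  m <- mkl_train(list(a = sk$K, b = noise), sk$labels, C = 1)
  expect_true(all(diff(m$trace) <= 1e-8))
  expect_lte(m$objective, m$trace[1] + 1e-8)
  ## weights live on the nonnegative unit sphere
  expect_true(all(m$weights >= 0))
  expect_equal(sum(m$weights^2), 1, tolerance = 1e-6)
})

test_that("byte-identical kernels give a swap-invariant objective", {
  sk <- sep_kernel()
  m <- mkl_train(list(a = sk$K, b = sk$K), sk$labels, C = 1)
  swapped <- rev(m$weights)
  Ks <- m$weights[1] * sk$K + m$weights[2] * sk$K
  Kr <- swapped[1] * sk$K + swapped[2] * sk$K
  expect_equal(Ks, Kr)
  expect_equal(svm_train_precomputed(Ks, sk$labels, 1)$objective,
               svm_train_precomputed(Kr, sk$labels, 1)$objective)
})

test_that("the informative kernel outweighs a label-permuted control", {
  wins <- 0L
  for (sd in 1:10) {
    set.seed(sd)
    n <- 40
    x <- c(rnorm(n / 2, 0, 0.5), rnorm(n / 2, 2.5, 0.5))
    labels <- rep(c("positive", "negative"), each = n / 2)
    Ki <- exp(-as.matrix(dist(x))^2)
    perm <- sample(n)
    Kn <- Ki[perm, perm]          # same spectrum, label link destroyed
    m <- mkl_train(list(info = Ki, noise = Kn), labels, C = 1)
    if (m$weights[["info"]] > m$weights[["noise"]]) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("MKL prediction follows the weighted decision function", {
  sk <- sep_kernel()
  m <- mkl_train(list(k1 = sk$K), sk$labels, C = 1)
  pred <- mkl_predict(m, list(k1 = sk$K))
  expect_equal(pred$label, sk$labels)
  ## unbounded support vectors sit on the correct margin side
  y <- ifelse(sk$labels == "positive", 1, -1)
  a <- m$coef * y
  unbounded <- a > 1e-6 & a < 1 - 1e-6
  expect_true(all(sign(pred$score[unbounded]) == y[unbounded]))
  ## empty test set, missing kernels
  expect_equal(nrow(mkl_predict(m, list(k1 = sk$K[0, , drop = FALSE]))),
               0L)
  expect_error(mkl_predict(m, list(other = sk$K)), "missing kernel")
  expect_error(mkl_train(list(z = matrix(0, 4, 4)),
                         rep(c("positive", "negative"), 2)), "all-zero")
})

test_that("weight report offers normalised and percentage views", {
  sk <- sep_kernel()
  m1 <- mkl_train(list(only = sk$K), sk$labels, C = 1)
  rep1 <- kernel_weight_report(m1)
  expect_equal(rep1$percent, 100)
  set.seed(4)
  noise <- exp(-as.matrix(dist(rnorm(20)))^2)
  m2 <- mkl_train(list(a = sk$K, b = noise), sk$labels, C = 1)
  rep2 <- kernel_weight_report(m2)
  expect_equal(sum(rep2$weight^2), 1, tolerance = 1e-6)
  expect_equal(sum(rep2$fraction), 1)
})
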