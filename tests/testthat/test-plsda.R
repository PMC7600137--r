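test_that("well-separated clusters are perfectly classified in training", {
  cl <- two_clusters(n_per = 8, sep = 8)
  fit <- fit_plsda(cl$X, cl$y, A = 1)
  expect_equal(fit$fitted_class, cl$y)
  expect_equal(mcc(truth = cl$y, pred = fit$fitted_class), 1)
})

test_that("one-feature PLS-DA reduces to the sign of the centered feature", {
  set.seed(21)
  x <- c(rnorm(10, 0), rnorm(10, 3))
  tab <- matrix(x, 20, 1, dimnames = list(paste0("s", 1:20), "f1"))
  y <- rep(c("a", "b"), each = 10)
  fit <- fit_plsda(tab, y, A = 1)
  expect_equal(fit$fitted_class,
               ifelse(x - mean(x) >= -fit$y_center / fit$coef, "b", "a"))
  # fitted response is an affine, sign-consistent map of the feature
  expect_gt(stats::cor(fit$fitted, x), 0.999999)
})

test_that("full-rank PLS reproduces the least-squares fit", {
  set.seed(22)
  X <- rand_table(30, 8)
  y <- rep(c("a", "b"), each = 15)
  X[y == "b", 1:2] <- X[y == "b", 1:2] + 1
  fit <- fit_plsda(X, y, A = 8)
  ols <- stats::lm.fit(cbind(1, X), ifelse(y == "b", 1, -1))
  expect_lt(max(abs(fit$fitted - ols$fitted.values)), 1e-6)
})

test_that("model structure invariants hold", {
  set.seed(23)
  X <- rand_table(24, 10)
  y <- rep(c("a", "b"), each = 12)
  X[y == "b", 1:3] <- X[y == "b", 1:3] + 1.5
  fit <- fit_plsda(X, y, A = 3)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)    # orthogonal scores
  # class centroids land on the correct side of the threshold
  for (lv in fit$levels) {
    centroid <- colMeans(X[y == lv, , drop = FALSE])
    expect_equal(unname(predict(fit, centroid)), lv)
  }
  expect_error(fit_plsda(X, y, A = 24), "min\\(n - 1, p\\)")
  expect_error(fit_plsda(X, rep("a", 24), A = 2), "two classes")
})

test_that("VIP satisfies its identities and ranks informative features first", {
  # identical columns share the single weight vector: all VIP = 1
  y <- rep(c(-1, 1), each = 6)
  base <- y + rnorm(12, sd = 0.1)
  X <- matrix(base, 12, 4, dimnames = list(paste0("s", 1:12),
                                           paste0("f", 1:4)))
  fit <- fit_plsda(X, rep(c("a", "b"), each = 6), A = 1)
  expect_equal(unname(vip(fit)), rep(1, 4), tolerance = 1e-12)

  set.seed(24)
  hits <- vapply(1:40, function(i) {
    X <- rand_table(20, 15)
    yy <- rep(c("a", "b"), each = 10)
    X[yy == "b", 1] <- X[yy == "b", 1] + 3
    f <- fit_plsda(X, yy, A = 2)
    v <- vip(f)
    expect_equal(sum(v^2), 15, tolerance = 1e-8)  # sum VIP^2 = p
    names(which.max(v)) == "f1"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("VIP and scores agree with an established PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(25)
  X <- rand_table(30, 8)
  y <- rep(c("a", "b"), each = 15)
  X[y == "b", 1:2] <- X[y == "b", 1:2] + 1
  fit <- fit_plsda(X, y, A = 2)
  mo <- mixOmics::plsda(X, factor(y), ncomp = 2, scale = FALSE)
  mo_vip <- mixOmics::vip(mo)[, 2]
  expect_equal(unname(vip(fit)), unname(mo_vip), tolerance = 1e-8)
  expect_equal(abs(stats::cor(fit$scores[, 1], mo$variates$X[, 1])), 1,
               tolerance = 1e-10)
  expect_equal(abs(stats::cor(fit$scores[, 2], mo$variates$X[, 2])), 1,
               tolerance = 1e-10)
})

test_that("post-transformation rotates without changing the model", {
  set.seed(26)
  X <- rand_table(30, 12)
  y <- rep(c("a", "b"), each = 15)
  X[y == "b", 1:4] <- X[y == "b", 1:4] + 2
  fit <- fit_plsda(X, y, A = 3)
  pt <- post_transform(fit)
  # rotation is orthonormal and reconstructs the original score space
  R <- pt$rotation
  expect_equal(crossprod(R), diag(3), tolerance = 1e-10)
  TR <- cbind(pt$predictive_scores, pt$orthogonal_scores)
  expect_lt(max(abs(TR %*% t(R) - fit$scores)), 1e-10)
  # orthogonal scores carry no class information
  expect_lt(max(abs(stats::cor(pt$orthogonal_scores, fit$y))), 1e-8)
  expect_identical(pt$model$fitted, fit$fitted)

  fit1 <- fit_plsda(X, y, A = 1)
  expect_warning(pt1 <- post_transform(fit1), "identity")
  expect_equal(unname(pt1$predictive_scores), unname(fit1$scores[, 1]))
})

test_that("post-transformation isolates a structured-noise direction", {
  set.seed(27)
  n <- 40
  y <- rep(c(-1, 1), each = n / 2)
  noise_factor <- rnorm(n)               # class-unrelated structure
  d1 <- c(rep(1, 5), rep(0, 5))
  d2 <- c(rep(0, 5), rep(1, 5))
  X <- 2 * outer(y, d1) + 2 * outer(noise_factor, d2) +
    matrix(rnorm(n * 10, sd = 0.2), n, 10)
  dimnames(X) <- list(paste0("s", 1:n), paste0("f", 1:10))
  fit <- fit_plsda(X, ifelse(y > 0, "b", "a"), A = 2)
  pt <- post_transform(fit)
  sep <- pt$predictive_scores
  expect_gt(abs(stats::cor(sep, y)), 0.9)
  expect_gt(abs(stats::cor(pt$orthogonal_scores[, 1], noise_factor)), 0.9)
})

test_that("MCC handles worked examples and degenerate margins", {
  expect_equal(mcc(5, 4, 2, 1), 18 / sqrt(1260))
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(0, 0, 10, 10), -1)
  expect_equal(mcc(5, 0, 5, 0), 0)      # zero marginal convention
  expect_error(mcc(0, 0, 0, 0), "positive total")
  truth <- c("a", "a", "b", "b", "a")
  pred <- c("a", "b", "b", "b", "a")
  tab <- table(truth, pred)
  expect_equal(mcc(truth = truth, pred = pred, positive = "a"),
               mcc(tp = 2, tn = 2, fp = 0, fn = 1))
})
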