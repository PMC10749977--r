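test_that("Gaussian kernel has the stated geometry", {
  set.seed(1)
  Z <- matrix(runif(10 * 20), 10)
  Z[2, ] <- Z[1, ]                       # identical rows
  K <- gaussian_kernel(Z)
  expect_equal(unname(K[1, 2]), 1)
  expect_equal(unname(diag(K)), rep(1, 10))
  expect_equal(K, t(K))
  # d2 = q gives exp(-1)
  q <- attr(K, "bandwidth")
  d2 <- as.matrix(dist(Z))^2
  ij <- which(abs(d2 - q) == min(abs(d2 - q)[d2 > 0]), arr.ind = TRUE)[1, ]
  expect_equal(unname(K[ij[1], ij[2]]),
               exp(-d2[ij[1], ij[2]] / q), tolerance = 1e-12)
  # positive semidefinite
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_error(gaussian_kernel(Z, 0), "positive")
})

test_that("SVM gamma is 1/(p var(Z)) and scales inversely with c^2", {
  Z <- matrix(rnorm(500), 5, 100)
  v <- var(as.vector(Z))
  expect_equal(svm_gamma(Z), 1 / (100 * v))
  expect_equal(svm_gamma(3 * Z), svm_gamma(Z) / 9)
  expect_equal(svm_gamma(matrix(c(0, 2), 1, 2)), 1 / (2 * 2))
  expect_error(svm_gamma(matrix(1, 4, 3)), "constant")
})

test_that("prediction metrics match hand-computed values", {
  m <- prediction_metrics(c(0, 1, 2), c(0, 1, 4))
  expect_equal(m$mse, 4 / 3)
  expect_equal(m$pa, cor(c(0, 1, 2), c(0, 1, 4)))
  expect_equal(round(m$pa, 4), 0.9608)

  y <- c(1, 3, 2, 5)
  expect_equal(prediction_metrics(y, y)$pa, 1)
  expect_equal(prediction_metrics(y, y)$mse, 0)
  expect_equal(prediction_metrics(y, -y)$pa, -1)
  expect_warning(m0 <- prediction_metrics(y, rep(1, 4)), "constant")
  expect_equal(m0$pa, 0)
  expect_true(m0$degenerate)

  # PA is invariant to positive affine maps of predictions; MSE is not
  p <- c(0.9, 3.2, 1.8, 5.1)
  expect_equal(prediction_metrics(y, 2 * p + 1)$pa,
               prediction_metrics(y, p)$pa)
  expect_false(isTRUE(all.equal(prediction_metrics(y, 2 * p + 1)$mse,
                                prediction_metrics(y, p)$mse)))
})

test_that("BRR posterior mean matches the ridge closed form when variances are fixed", {
  set.seed(7)
  n <- 40; p <- 60
  Z <- scale(matrix(runif(n * p), n), scale = FALSE)
  y <- drop(Z %*% rnorm(p, 0, 0.2)) + rnorm(n, 0, 0.4)
  y <- y - mean(y)
  s2b <- 0.04; s2e <- 0.16
  spec <- model_spec("BRR", n_iter = 8000L, burn_in = 1000L, thin = 5L,
                     fix_variances = TRUE, sigma2_b = s2b, sigma2_e = s2e,
                     include_mu = FALSE)
  fit <- brr_posterior(spec, Z, y, seed = 3)
  bhat <- solve(crossprod(Z) + diag(s2e / s2b, p), crossprod(Z, y))
  expect_lt(sqrt(mean((fit$beta - bhat)^2)), 0.02)
})

test_that("RKHS posterior mean matches the kernel-ridge closed form", {
  set.seed(8)
  n <- 40
  Z <- matrix(runif(n * 30), n)
  y <- rnorm(n); y <- y - mean(y)
  K <- gaussian_kernel(Z)
  s2u <- 1; s2e <- 0.25
  spec <- model_spec("RKHS", n_iter = 20000L, burn_in = 2000L, thin = 5L,
                     fix_variances = TRUE, sigma2_u = s2u, sigma2_e = s2e,
                     include_mu = FALSE)
  fit <- rkhs_posterior(spec, K, y, seed = 3)
  uhat <- drop(K %*% solve(K + diag(s2e / s2u, n), y))
  expect_lt(sqrt(mean((fit$u - uhat)^2)), 0.02)
})

test_that("all six engines produce deterministic finite predictions", {
  st <- small_geno()
  Z <- st$Z[, 1:150]; y <- st$Y[, 1]
  tr <- 1:40; te <- 41:50
  fast <- list(RKHS = list(n_iter = 1500L, burn_in = 300L),
               BRR = list(n_iter = 1500L, burn_in = 300L))
  for (nm in c("RKHS", "BRR", "SVM", "RF", "AB", "MLP")) {
    spec <- do.call(model_spec, c(list(nm), fast[[nm]]))
    p1 <- fit_predict(spec, Z[tr, ], y[tr], Z[te, ], seed = 5)
    p2 <- fit_predict(spec, Z[tr, ], y[tr], Z[te, ], seed = 5)
    expect_identical(p1, p2)
    expect_true(all(is.finite(p1)))
    expect_length(p1, 10)
  }
  expect_error(fit_predict(model_spec("RF"), Z[tr, ], rep(1, 40), Z[te, ]),
               "degenerate")
})

test_that("random forest interpolates a dominant-marker signal", {
  set.seed(9)
  Z <- matrix(runif(50 * 20), 50)
  y <- 3 * Z[, 5]
  p <- fit_predict(model_spec("RF"), Z, y, Z, seed = 2)
  expect_gt(cor(y, p), 0.9)
})

test_that("cross-validation partitions correctly and is honest on noise", {
  st <- small_geno()
  Z <- st$Z[, 1:100]
  expect_error(cross_validate(model_spec("RF"), Z, st$Y[, 1], k = 60),
               "exceeds")
  # oracle-strength signal: PA near 1 each repetition
  y <- 2 * Z[, 3] + 0.01 * rnorm(50)
  cv <- cross_validate(model_spec("RF"), Z[, 1:5], y, k = 5,
                       repetitions = 3, seed = 11)
  expect_equal(nrow(cv), 3)
  expect_true(all(cv$pa > 0.9))
  # determinism
  cv2 <- cross_validate(model_spec("RF"), Z[, 1:5], y, k = 5,
                        repetitions = 3, seed = 11)
  expect_identical(cv, cv2)
  # pure-noise responses: repetitions share the data, so a single noise
  # draw keeps its own chance offset; the null centers on zero across
  # independent draws
  set.seed(12)
  null_means <- vapply(1:10, function(d) {
    ynull <- rnorm(50)
    mean(cross_validate(model_spec("SVM"), Z, ynull, k = 5,
                        repetitions = 10, seed = 100 + d)$pa)
  }, numeric(1))
  expect_lt(abs(mean(null_means)), 0.15)
  # per-fold mode runs and stays in range
  cvf <- cross_validate(model_spec("SVM"), Z, y, k = 5, repetitions = 2,
                        seed = 14, pa_mode = "per_fold_mean")
  expect_true(all(cvf$pa >= -1 & cvf$pa <= 1))
})

test_that("Tukey letters separate scenarios as the q-distribution dictates", {
  set.seed(15)
  # clearly separated pair
  v <- list(A = rnorm(100, 0.9, 0.001), B = rnorm(100, 0.5, 0.001))
  res <- compare_scenarios(v, metric = "PA")
  expect_equal(res$letters, c("a", "b"))
  expect_equal(res$best, c(TRUE, FALSE))
  # same data judged as MSE: lower mean is better, last letter wins
  resm <- compare_scenarios(v, metric = "MSE")
  expect_equal(resm$best[resm$scenario == "B"], TRUE)
  expect_equal(resm$best[resm$scenario == "A"], FALSE)
  # three groups, two tied at the top
  v3 <- list(A = rnorm(100, 0.9, 0.002), B = rnorm(100, 0.9, 0.002),
             C = rnorm(100, 0.5, 0.002))
  res3 <- compare_scenarios(v3, metric = "PA")
  expect_setequal(res3$letters[res3$scenario %in% c("A", "B")], "a")
  expect_equal(res3$letters[res3$scenario == "C"], "b")
  # identical distributions collapse to a single letter
  v0 <- list(A = rep(0.8, 10), B = rep(0.8, 10))
  res0 <- compare_scenarios(v0, metric = "PA")
  expect_equal(res0$letters, c("a", "a"))
  expect_true(all(res0$best))
})

test_that("AdaBoost.R2 and the MLP learn a smooth signal", {
  set.seed(16)
  Z <- matrix(runif(60 * 10), 60)
  y <- 2 * Z[, 1] - Z[, 2] + 0.05 * rnorm(60)
  fit_ab <- adaboost_r2(Z, y)
  expect_gt(cor(y, predict_adaboost_r2(fit_ab, Z)), 0.9)
  expect_lte(length(fit_ab$trees), 50)
  fit_mlp <- mlp_fit(Z, y, seed = 4)
  expect_gt(cor(y, mlp_predict(fit_mlp, Z)), 0.9)
})
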