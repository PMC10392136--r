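# centered orthonormal design: columns orthogonal to the intercept with
# crossprod(X)/n = I, so the elastic net has a closed form
orthonormal_design <- function(n, p, seed = 5) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1, drop = FALSE]
  X <- sqrt(n) * Q
  colnames(X) <- sprintf("f%02d", seq_len(p))
  X
}

test_that("the solver matches closed forms on orthonormal designs", {
  n <- 40; p <- 8
  X <- orthonormal_design(n, p)
  set.seed(6)
  y <- rnorm(n)
  rho <- drop(crossprod(X, y)) / n
  for (alpha in c(1, 0.5, 0.1)) {
    lam <- 0.07
    fit <- fit_elastic_net(X, y, alpha, lam)
    oracle <- sign(rho) * pmax(abs(rho) - alpha * lam, 0) /
      (1 + lam * (1 - alpha))
    expect_equal(unname(fit$coefficients), unname(oracle),
                 tolerance = 1e-6)
  }
})

test_that("all coefficients vanish beyond the critical lambda (KKT)", {
  set.seed(7)
  X <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(NULL, sprintf("f%02d", 1:20)))
  y <- rnorm(50)
  for (alpha in c(1, 0.5)) {
    lam_max <- max(abs(crossprod(X, y - mean(y)))) / (nrow(X) * alpha)
    fit <- fit_elastic_net(X, y, alpha, lam_max * 1.000001)
    expect_lt(max(abs(fit$coefficients)), 1e-6)
    expect_equal(fit$intercept, mean(y), tolerance = 1e-6)
    just_below <- fit_elastic_net(X, y, alpha, lam_max * 0.95)
    expect_gt(max(abs(just_below$coefficients)), 0)
  }
})

test_that("the unpenalized limit recovers OLS", {
  set.seed(8)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- drop(X %*% c(1, -2, 0.5, 0)) + rnorm(60, 0, 0.3)
  fit <- fit_elastic_net(X, y, alpha = 0.5, lambda = 0)
  ols <- unname(coef(lm(y ~ X)))
  expect_equal(unname(c(fit$intercept, fit$coefficients)), ols,
               tolerance = 1e-6)
})

test_that("the returned solution beats trivial competitors on the objective", {
  set.seed(9)
  X <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- drop(X[, 1:3] %*% c(1, 1, -1)) + rnorm(50, 0, 0.5)
  ols <- lm(y ~ X)
  for (alpha in c(1, 0.4)) for (lambda in c(0.01, 0.1, 0.5)) {
    fit <- fit_elastic_net(X, y, alpha, lambda)
    obj_fit <- elastic_net_objective(X, y, fit$intercept,
                                     fit$coefficients, alpha, lambda)
    obj_zero <- elastic_net_objective(X, y, mean(y), numeric(10),
                                      alpha, lambda)
    obj_ols <- elastic_net_objective(X, y, coef(ols)[1], coef(ols)[-1],
                                     alpha, lambda)
    expect_lte(obj_fit, obj_zero + 1e-10)
    expect_lte(obj_fit, obj_ols + 1e-10)
  }
})

test_that("coefficients shrink monotonically in lambda on orthonormal designs", {
  n <- 40
  X <- orthonormal_design(n, 6, seed = 10)
  set.seed(10)
  y <- drop(X %*% rnorm(6)) + rnorm(n, 0, 0.2)
  lams <- c(0.01, 0.05, 0.1, 0.3, 0.6)
  paths <- sapply(lams, function(l)
    abs(fit_elastic_net(X, y, 1, l)$coefficients))
  expect_true(all(apply(paths, 1, function(z) all(diff(z) <= 1e-8))))
})

test_that("degenerate designs fall back to the intercept-only model", {
  y <- c(1, 2, 3, 4)
  fit <- fit_elastic_net(matrix(numeric(0), 4, 0), y, 1, 0.1)
  expect_equal(fit$intercept, 2.5)
  expect_length(fit$coefficients, 0L)
})

test_that("hyperparameter tuning returns a trivial grid unchanged", {
  set.seed(12)
  X <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(40)
  cfg <- en_config("fast", alpha_grid = 0.6, nlambda = 1L)
  tuned <- tune_hyperparams(X, y, cfg)
  expect_equal(tuned$alpha, 0.6)
  expect_length(tuned$lambda, 1L)
})

test_that("tuned models approach the irreducible error on sparse truth", {
  # 5 true predictors of 200, sigma = 0.5, n = 60
  set.seed(13)
  n <- 60; p <- 200; sigma <- 0.5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- drop(X[, 1:5] %*% rep(1, 5)) + rnorm(n, 0, sigma)
  set.seed(14)
  tuned <- tune_hyperparams(X, y, en_config("fast"))
  expect_lt(tuned$cv_mse, 2 * sigma^2 * 4)  # within a small factor of sigma^2
  expect_gt(tuned$cv_mse, sigma^2 / 2)
})

test_that("bootstrap averaging reduces to a single fit when degenerate", {
  set.seed(15)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- drop(X[, 1] * 2) + rnorm(30, 0, 0.1)
  cfg <- en_config("fast", n_boot = 1L, subsample_fraction = 1)
  boot <- bootstrap_coefficients(X, y, alpha = 1, lambda = 0.05, cfg)
  st <- proteodyn:::std_fit(X)
  single <- fit_elastic_net(proteodyn:::std_apply(X, st), y, 1, 0.05)
  expect_equal(unname(boot$mean_coefficients),
               unname(single$coefficients), tolerance = 1e-4)

  # all-zero response -> all-zero mean coefficients
  boot0 <- bootstrap_coefficients(X, rep(0, 30), 1, 0.05,
                                  en_config("fast", n_boot = 5L))
  expect_equal(max(abs(boot0$mean_coefficients)), 0)

  expect_error(bootstrap_coefficients(X[1:3, ], y[1:3], 1, 0.05,
                                      en_config("fast",
                                                subsample_fraction = 0.5)),
               "subsample smaller than 3")
})

test_that("planted predictors dominate the bootstrap ranking", {
  set.seed(16)
  hits <- replicate(10, {
    n <- 60; p <- 300
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%03d", 1:p)))
    planted <- sample(colnames(X), 5)
    y <- drop(X[, planted] %*% rep(1, 5)) + rnorm(n, 0, 0.5)
    boot <- bootstrap_coefficients(X, y, alpha = 1, lambda = 0.1,
                                   en_config("fast"))
    sum(planted %in% boot$ranking[1:10])
  })
  expect_gte(mean(hits >= 5), 0.9)
})

test_that("the one-standard-error rule selects the smallest defensible k", {
  set.seed(17)
  n <- 60
  X <- matrix(rnorm(n * 100), n, 100,
              dimnames = list(NULL, sprintf("f%03d", 1:100)))
  # low-noise planted truth on the first five ranked features
  y <- drop(X[, 1:5] %*% rep(1, 5)) + rnorm(n, 0, 0.1)
  ks <- replicate(10, select_top_k(X, y, colnames(X), en_config("fast"))$k)
  expect_true(all(ks >= 4 & ks <= 7))

  # k = 1 sufficient -> k = 1
  y1 <- X[, 1] * 3 + rnorm(n, 0, 0.05)
  set.seed(18)
  expect_equal(select_top_k(X, y1, colnames(X), en_config("fast"))$k, 1L)
})

test_that("k_max is capped by the sample size", {
  set.seed(19)
  X <- matrix(rnorm(20 * 50), 20, 50,
              dimnames = list(NULL, sprintf("f%03d", 1:50)))
  y <- rnorm(20)
  sel <- select_top_k(X, y, colnames(X), en_config("fast", k_max = 50L))
  expect_lte(max(sel$cv$k), 18L)
})
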