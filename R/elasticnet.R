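#' Elastic-net tuning configuration
#'
#' Hyperparameter grids and resampling sizes for the nested
#' cross-validated elastic-net pipeline. Two presets share one code
#' path: `"paper"` uses the full design (alpha grid 0.1-1.0 in steps of
#' 0.1, 10 replicates of 10-fold cross-validation, 200 subsample fits),
#' `"fast"` is a desk-scale setting (alpha grid \{0.2, 0.6, 1.0\},
#' 3 replicates of 5-fold cross-validation, 50 subsample fits) for
#' testing and exploration.
#'
#' @param preset `"fast"` or `"paper"`.
#' @param ... named overrides of `alpha_grid`, `nlambda`, `cv_folds`,
#'   `cv_reps`, `n_boot`, `subsample_fraction`, `k_max`.
#' @return list of class `en_config`.
#' @export
en_config <- function(preset = c("fast", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    paper = list(alpha_grid = seq(0.1, 1, 0.1), nlambda = 100L,
                 cv_folds = 10L, cv_reps = 10L, n_boot = 200L,
                 subsample_fraction = 0.9, k_max = 50L),
    fast = list(alpha_grid = c(0.2, 0.6, 1.0), nlambda = 30L,
                cv_folds = 5L, cv_reps = 3L, n_boot = 50L,
                subsample_fraction = 0.9, k_max = 50L))
  cfg$preset <- preset
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown en_config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$subsample_fraction <= 0 || cfg$subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  if (any(cfg$alpha_grid <= 0 | cfg$alpha_grid > 1))
    stop("alpha must be in (0, 1]")
  structure(cfg, class = "en_config")
}

# training-set standardization: intensity columns to mean 0 / sd 1,
# binary (mutation) columns untouched. Zero-variance columns get scale 1.
std_fit <- function(X, binary = NULL) {
  if (is.null(binary)) binary <- rep(FALSE, ncol(X))
  n <- nrow(X)
  center <- colMeans(X)
  scale <- sqrt(pmax(colSums(X^2) - n * center^2, 0) / (n - 1))
  scale[scale == 0 | is.na(scale)] <- 1
  center[binary] <- 0
  scale[binary] <- 1
  list(center = center, scale = scale)
}

std_apply <- function(X, st) {
  n <- nrow(X)
  (X - rep(st$center, each = n)) * rep(1 / st$scale, each = n)
}

#' Fit a single elastic net
#'
#' Minimizes `(1/2n) * sum((y - b0 - X b)^2) + lambda * (alpha*||b||_1 +
#' (1-alpha)/2 * ||b||_2^2)`; deterministic for fixed inputs. A design
#' with zero columns yields the intercept-only model.
#'
#' @param X complete numeric matrix (n x p).
#' @param y numeric response of length n.
#' @param alpha elastic-net mixing parameter in (0, 1\].
#' @param lambda penalty strength (>= 0).
#' @return list with `intercept` and named `coefficients`.
#' @export
fit_elastic_net <- function(X, y, alpha, lambda) {
  stopifnot(!anyNA(X), all(is.finite(y)), length(y) >= 2L)
  p <- ncol(X)
  if (is.null(p) || p == 0L)
    return(list(intercept = mean(y), coefficients = numeric(0)))
  if (stats::var(y) == 0 && lambda > 0)
    return(list(intercept = mean(y),
                coefficients = stats::setNames(numeric(p), colnames(X))))
  if (p == 1L) {
    # closed form for a single predictor
    xc <- X[, 1L] - mean(X[, 1L]); yc <- y - mean(y)
    n <- length(y)
    rho <- sum(xc * yc) / n
    denom <- sum(xc^2) / n + lambda * (1 - alpha)
    st <- sign(rho) * max(abs(rho) - lambda * alpha, 0)
    b <- if (denom == 0) 0 else st / denom
    return(list(intercept = mean(y) - b * mean(X[, 1L]),
                coefficients = stats::setNames(b, colnames(X))))
  }
  # glmnet standardizes y internally, which rescales the ridge part of
  # the penalty by sd(y); remap (alpha, lambda) so the solver minimizes
  # exactly the objective stated above
  al <- alpha; lam <- lambda
  if (alpha < 1 && lambda > 0) {
    sy <- sqrt(mean((y - mean(y))^2))
    if (sy > 0) {
      lam <- lambda * alpha + lambda * (1 - alpha) * sy
      al <- lambda * alpha / lam
    }
  }
  fit <- glmnet::glmnet(X, y, alpha = al, lambda = lam,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-12, maxit = 10^6)
  cf <- as.numeric(stats::coef(fit))
  list(intercept = cf[1L],
       coefficients = stats::setNames(cf[-1L], colnames(X)))
}

#' Elastic-net objective value
#'
#' @param X,y design and response.
#' @param intercept,beta model parameters.
#' @param alpha,lambda penalty parameters.
#' @return the penalized least-squares objective.
#' @export
elastic_net_objective <- function(X, y, intercept, beta, alpha, lambda) {
  r <- y - intercept - if (length(beta)) drop(X %*% beta) else 0
  sum(r^2) / (2 * length(y)) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# common lambda path per alpha, computed on the standardized full
# training data by glmnet's default geometric path
lambda_path <- function(Xs, y, alpha, nlambda) {
  glmnet::glmnet(Xs, y, alpha = alpha, nlambda = nlambda,
                 standardize = FALSE)$lambda
}

#' Tune elastic-net hyperparameters by replicated cross-validation
#'
#' Grid search over the alpha grid and a per-alpha geometric lambda
#' path; CV mean squared error is averaged over `cv_reps` independent
#' `cv_folds`-fold partitions. Standardization parameters are computed
#' on each training fold only. Ties are broken toward the larger lambda,
#' then the larger alpha (the sparser model).
#'
#' @param X complete numeric matrix (unstandardized).
#' @param y response.
#' @param config an [en_config()].
#' @param binary logical vector marking binary (mutation) columns.
#' @return list with `alpha`, `lambda`, and the CV error `cv_mse` at the
#'   chosen point.
#' @export
tune_hyperparams <- function(X, y, config = en_config(), binary = NULL) {
  n <- length(y)
  folds <- config$cv_folds
  if (n < folds) {
    warning("fewer observations than folds; using leave-one-out")
    folds <- n
  }
  st_full <- std_fit(X, binary)
  Xs <- std_apply(X, st_full)
  paths <- lapply(config$alpha_grid, function(a)
    lambda_path(Xs, y, a, config$nlambda))
  cv_sum <- lapply(paths, function(p) numeric(length(p)))
  cv_cnt <- 0L
  for (rep in seq_len(config$cv_reps)) {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    for (fo in seq_len(folds)) {
      te <- fold_id == fo
      st <- std_fit(X[!te, , drop = FALSE], binary)
      Xtr <- std_apply(X[!te, , drop = FALSE], st)
      Xte <- std_apply(X[te, , drop = FALSE], st)
      for (ai in seq_along(config$alpha_grid)) {
        fit <- glmnet::glmnet(Xtr, y[!te], alpha = config$alpha_grid[ai],
                              lambda = paths[[ai]], standardize = FALSE)
        pr <- as.matrix(Xte %*% fit$beta) +
          rep(fit$a0, each = sum(te))
        if (ncol(pr) < length(paths[[ai]]))   # path truncated by glmnet
          pr <- cbind(pr, matrix(pr[, ncol(pr)],
                                 sum(te), length(paths[[ai]]) - ncol(pr)))
        cv_sum[[ai]] <- cv_sum[[ai]] +
          colSums((pr - y[te])^2)
      }
    }
    cv_cnt <- cv_cnt + n
  }
  grid <- do.call(rbind, lapply(seq_along(config$alpha_grid), function(ai)
    data.frame(alpha = config$alpha_grid[ai], lambda = paths[[ai]],
               mse = cv_sum[[ai]] / cv_cnt)))
  best <- grid[order(grid$mse, -grid$lambda, -grid$alpha), ][1L, ]
  list(alpha = best$alpha, lambda = best$lambda, cv_mse = best$mse)
}

#' Bootstrap-averaged elastic-net coefficients
#'
#' Fits the tuned elastic net `n_boot` times, each on a random subset of
#' `floor(subsample_fraction * n)` lines drawn without replacement;
#' coefficients (on the standardized-feature scale) are averaged
#' elementwise and features ranked by decreasing absolute mean
#' coefficient, ties broken by feature id.
#'
#' @param X,y complete design and response.
#' @param alpha,lambda tuned penalty parameters.
#' @param config an [en_config()].
#' @param binary logical vector marking binary columns.
#' @return list with `mean_coefficients` (named), `runs` (n_boot x p
#'   matrix) and `ranking` (feature ids, best first).
#' @export
bootstrap_coefficients <- function(X, y, alpha, lambda,
                                   config = en_config(), binary = NULL) {
  n <- length(y)
  m <- floor(config$subsample_fraction * n)
  if (m < 3L) stop("subsample smaller than 3")
  runs <- matrix(0, config$n_boot, ncol(X),
                 dimnames = list(NULL, colnames(X)))
  for (b in seq_len(config$n_boot)) {
    idx <- if (m == n) seq_len(n) else sample(n, m)
    st <- std_fit(X[idx, , drop = FALSE], binary)
    Xs <- std_apply(X[idx, , drop = FALSE], st)
    if (stats::var(y[idx]) == 0) next     # constant response: all-zero fit
    if (ncol(Xs) >= 2L) {
      fit <- glmnet::glmnet(Xs, y[idx], alpha = alpha, lambda = lambda,
                            standardize = FALSE)
      runs[b, ] <- as.numeric(fit$beta)
    } else {
      runs[b, ] <- fit_elastic_net(Xs, y[idx], alpha, lambda)$coefficients
    }
  }
  mean_cf <- colMeans(runs)
  ranking <- colnames(X)[order(-abs(mean_cf), colnames(X))]
  list(mean_coefficients = mean_cf, runs = runs, ranking = ranking)
}

#' Select the predictor count by the one-standard-error rule
#'
#' For k = 1..k_max, ordinary least squares on the top-k ranked features
#' is scored by 10-fold cross-validated MSE with its standard error
#' (over folds); the smallest k whose CV error is within one standard
#' error of the minimum is returned.
#'
#' @param X,y complete design and response.
#' @param ranking feature ids, best first.
#' @param config an [en_config()] (uses `k_max`).
#' @param cv_folds folds for the OLS cross-validation.
#' @return list with `k`, `top_features`, and the per-k `cv` table.
#' @export
select_top_k <- function(X, y, ranking, config = en_config(),
                         cv_folds = 10L) {
  n <- length(y)
  k_max <- min(config$k_max, length(ranking), n - 2L)
  folds <- min(cv_folds, n)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  Xk <- cbind(`(Intercept)` = 1, X[, ranking[seq_len(k_max)], drop = FALSE])
  fold_mse <- matrix(NA_real_, folds, k_max)
  for (fo in seq_len(folds)) {
    te <- fold_id == fo
    # OLS for all nested top-k models from one crossproduct, solved by
    # growing Cholesky factorizations; singular fits fall back to the
    # pivoting QR of lm.fit
    A <- crossprod(Xk[!te, , drop = FALSE])
    b <- crossprod(Xk[!te, , drop = FALSE], y[!te])
    for (k in seq_len(k_max)) {
      idx <- seq_len(k + 1L)
      cf <- tryCatch(drop(chol2inv(chol(A[idx, idx])) %*% b[idx]),
                     error = function(e) {
                       fit <- stats::lm.fit(Xk[!te, idx, drop = FALSE],
                                            y[!te])
                       ifelse(is.na(fit$coefficients), 0, fit$coefficients)
                     })
      pr <- drop(Xk[te, idx, drop = FALSE] %*% cf)
      fold_mse[fo, k] <- mean((pr - y[te])^2)
    }
  }
  cv_mean <- colMeans(fold_mse)
  cv_se <- apply(fold_mse, 2L, stats::sd) / sqrt(folds)
  k_min <- which.min(cv_mean)
  k <- which(cv_mean <= cv_mean[k_min] + cv_se[k_min])[1L]
  list(k = k, top_features = ranking[seq_len(k)],
       cv = data.frame(k = seq_len(k_max), cv_mse = cv_mean, se = cv_se))
}

# one pass of the inner pipeline (tune -> bootstrap -> rank -> top-k ->
# OLS refit); returns the refit model and bookkeeping
inner_en_pipeline <- function(X, y, config, binary = NULL) {
  tuned <- tune_hyperparams(X, y, config, binary)
  boot <- bootstrap_coefficients(X, y, tuned$alpha, tuned$lambda,
                                 config, binary)
  sel <- select_top_k(X, y, boot$ranking, config)
  feats <- sel$top_features
  fit <- stats::lm.fit(cbind(1, X[, feats, drop = FALSE]), y)
  cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  list(tuned = tuned, boot = boot, sel = sel,
       ols = list(intercept = cf[1L],
                  coefficients = stats::setNames(cf[-1L], feats)))
}
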