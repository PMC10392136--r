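#' Assemble a multi-omics design matrix
#'
#' Builds the cell-lines x features design from a chosen combination of
#' omics layers. Intensity layers are kNN-imputed if they still contain
#' missing values; mutation features stay binary and are never
#' standardized downstream. Feature ids are prefixed with their layer
#' tag (e.g. `D:P0123`) so layers cannot collide.
#'
#' @param layers named list of cell-line-level [omics_matrix()] objects
#'   (typical names `M`, `D`, `E`, `R`).
#' @param combo character vector of layer names, or a single string of
#'   one-letter tags (e.g. `"DE"`).
#' @param lines cell lines (rows) to use; default the lines common to
#'   the chosen layers.
#' @param impute_k neighbours for [knn_impute()].
#' @return list with `x` (numeric matrix, lines x features) and `binary`
#'   (logical per feature, `TRUE` for mutation features).
#' @export
assemble_features <- function(layers, combo, lines = NULL, impute_k = 10) {
  if (length(combo) == 1L && !combo %in% names(layers))
    combo <- strsplit(combo, "")[[1L]]
  miss <- setdiff(combo, names(layers))
  if (length(miss)) stop("unknown layer(s): ", paste(miss, collapse = ", "))
  if (is.null(lines))
    lines <- Reduce(intersect, lapply(layers[combo], sample_ids))
  if (!length(lines)) stop("no cell lines shared by the chosen layers")
  blocks <- lapply(combo, function(tag) {
    m <- layers[[tag]]
    absent <- setdiff(lines, sample_ids(m))
    if (length(absent)) stop("layer ", tag, " lacks line(s): ",
                             paste(absent, collapse = ", "))
    is_binary <- identical(m$layer_name, "mutation")
    if (!is_binary) {
      all_missing <- rowSums(!is.na(m$values)) == 0L
      if (any(all_missing)) {
        warning(sum(all_missing), " all-missing feature(s) dropped from ",
                tag)
        m <- subset_omics(m, features = which(!all_missing))
      }
      if (anyNA(m$values)) m <- knn_impute(m, impute_k)
    }
    x <- t(m$values[, lines, drop = FALSE])
    colnames(x) <- paste0(tag, ":", colnames(x))
    list(x = x, binary = rep(is_binary, ncol(x)))
  })
  list(x = do.call(cbind, lapply(blocks, `[[`, "x")),
       binary = unlist(lapply(blocks, `[[`, "binary")))
}

#' Fit and evaluate a drug-response model by nested leave-one-out CV
#'
#' The core estimator: for each cell line with an observed response, the
#' line is held out and the entire inner pipeline -- hyperparameter
#' tuning by replicated cross-validation, bootstrap coefficient
#' averaging, ranking by absolute mean coefficient, one-standard-error
#' top-k selection, and OLS refit on the top-k features -- is re-run on
#' the remaining lines to predict the held-out response, so no
#' information leaks into the evaluation. Predictive power is the
#' Pearson correlation between observed and predicted responses over all
#' held-out lines. The reported hyperparameters, ranking, top-k set and
#' coefficients come from one final run on all lines.
#'
#' @param x numeric design matrix (cell lines x features), complete; or
#'   the list returned by [assemble_features()].
#' @param y numeric response (log10 IC50) with names matching rows of
#'   `x`; `NA` responses drop the line.
#' @param config an [en_config()].
#' @param seed integer seed; the whole nested procedure is reproducible
#'   from it.
#' @param drug optional drug label stored in the result.
#' @param min_lines minimum observed responses for a valid model.
#' @return object of class `en_result`; see [summary.en_result()].
#'   If fewer than `min_lines` responses are observed the object is
#'   returned with `valid = FALSE` and no fit.
#' @examples
#' \donttest{
#' set.seed(1)
#' X <- matrix(rnorm(30 * 40), 30, 40,
#'             dimnames = list(sprintf("l%02d", 1:30), sprintf("f%02d", 1:40)))
#' y <- setNames(drop(X[, 1:3] %*% c(1, 1, -1)) + rnorm(30, 0, 0.3),
#'               rownames(X))
#' fit <- fit_drug_response(X, y, en_config("fast", n_boot = 10L), seed = 1)
#' print(fit)
#' }
#' @export
fit_drug_response <- function(x, y, config = en_config(), seed = 1L,
                              drug = NA_character_, min_lines = 10L) {
  binary <- NULL
  if (is.list(x) && !is.null(x$x)) { binary <- x$binary; x <- x$x }
  if (!is.null(names(y))) y <- y[rownames(x)]
  obs <- !is.na(y)
  if (sum(obs) < min_lines) {
    return(structure(list(drug = drug, valid = FALSE,
                          n_lines_used = sum(obs)),
                     class = "en_result"))
  }
  X <- x[obs, , drop = FALSE]
  yy <- as.numeric(y[obs])
  if (stats::sd(yy) == 0) stop("constant response: predictive r undefined")
  n <- length(yy)
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, n + 1L)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(fold_seeds[i])
    inner <- inner_en_pipeline(X[-i, , drop = FALSE], yy[-i], config, binary)
    feats <- names(inner$ols$coefficients)
    pred[i] <- inner$ols$intercept +
      sum(X[i, feats] * inner$ols$coefficients)
  }
  set.seed(fold_seeds[n + 1L])
  final <- inner_en_pipeline(X, yy, config, binary)
  structure(list(
    drug = drug,
    valid = TRUE,
    alpha = final$tuned$alpha,
    lambda = final$tuned$lambda,
    mean_coefficients = final$boot$mean_coefficients,
    ranking = final$boot$ranking,
    k = final$sel$k,
    top_features = final$sel$top_features,
    ols = final$ols,
    loo = data.frame(line = rownames(X), observed = yy, predicted = pred),
    predictive_power = stats::cor(yy, pred),
    n_lines_used = n,
    config = config,
    seed = seed), class = "en_result")
}

#' @export
print.en_result <- function(x, ...) {
  if (!isTRUE(x$valid)) {
    cat(sprintf("en_result '%s': invalid (%d observed responses)\n",
                x$drug, x$n_lines_used))
    return(invisible(x))
  }
  cat(sprintf(
    "en_result '%s': alpha %.2f, lambda %.4g, k = %d, LOO predictive r = %.3f (n = %d)\n",
    x$drug, x$alpha, x$lambda, x$k, x$predictive_power, x$n_lines_used))
  invisible(x)
}

#' Summarize a fitted drug-response model
#'
#' @param object an `en_result` from [fit_drug_response()].
#' @param ... unused.
#' @return `object`, invisibly, after printing the tuned parameters,
#'   top-k predictors with their averaged coefficients, and the LOO
#'   predictive correlation.
#' @export
summary.en_result <- function(object, ...) {
  print(object)
  if (isTRUE(object$valid)) {
    cat("top predictors (bootstrap-averaged coefficients):\n")
    cf <- object$mean_coefficients[object$top_features]
    print(round(cf, 4))
  }
  invisible(object)
}

#' @export
coef.en_result <- function(object, type = c("bootstrap", "ols"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$valid)) stop("invalid model")
  if (type == "bootstrap") object$mean_coefficients
  else c("(Intercept)" = unname(object$ols$intercept),
         object$ols$coefficients)
}

#' Predict drug response for new cell lines
#'
#' Uses the final top-k OLS refit (fitted on all lines).
#'
#' @param object an `en_result`.
#' @param newdata numeric matrix (lines x features) containing the
#'   model's top-k feature columns.
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.en_result <- function(object, newdata, ...) {
  if (!isTRUE(object$valid)) stop("invalid model")
  feats <- names(object$ols$coefficients)
  miss <- setdiff(feats, colnames(newdata))
  if (length(miss)) stop("newdata lacks feature(s): ",
                         paste(miss, collapse = ", "))
  drop(object$ols$intercept +
         newdata[, feats, drop = FALSE] %*% object$ols$coefficients)
}

#' @export
residuals.en_result <- function(object, ...) {
  if (!isTRUE(object$valid)) stop("invalid model")
  stats::setNames(object$loo$observed - object$loo$predicted,
                  object$loo$line)
}

#' @export
plot.en_result <- function(x, ...) {
  if (!isTRUE(x$valid)) stop("invalid model")
  plot(x$loo$observed, x$loo$predicted,
       xlab = "observed log10 IC50", ylab = "LOO predicted log10 IC50",
       main = sprintf("%s (r = %.2f)", x$drug, x$predictive_power), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Compare predictive power across omics-layer combinations
#'
#' Runs [fit_drug_response()] for every (drug, layer-combination) pair
#' and returns the long-format table of LOO predictive correlations.
#'
#' @param layers named list of cell-line-level [omics_matrix()] objects.
#' @param response a [drug_response_table()].
#' @param combos character vector of layer combinations (e.g.
#'   `c("M", "D", "E", "DE", "MDE")`).
#' @param drugs drugs to model (default all columns of `response`).
#' @param config an [en_config()].
#' @param seed integer seed (each (drug, combo) run derives its own).
#' @return data.frame of class `combo_comparison` with columns `drug`,
#'   `combo`, `predictive_power`, `n_lines`, `valid`.
#' @export
compare_layer_combos <- function(layers, response, combos,
                                 drugs = colnames(response),
                                 config = en_config(), seed = 1L) {
  if (!length(combos)) stop("need at least one layer combination")
  rows <- list()
  for (combo in combos) {
    asm <- tryCatch(assemble_features(layers, combo),
                    error = function(e) {
                      warning("combo ", combo, " skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(asm)) next
    for (d in drugs) {
      y <- stats::setNames(response[, d], rownames(response))
      fit <- fit_drug_response(asm, y, config,
                               seed = seed + 7919L * match(d, drugs) +
                                 131L * match(combo, combos),
                               drug = d)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, combo = combo,
        predictive_power = if (isTRUE(fit$valid)) fit$predictive_power
                           else NA_real_,
        n_lines = fit$n_lines_used,
        valid = isTRUE(fit$valid))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("combo_comparison", "data.frame")
  out
}

#' Paired test between two layer combinations
#'
#' Paired t test of predictive power over the drugs modeled validly by
#' both combinations.
#'
#' @param table a [compare_layer_combos()] result.
#' @param combo_a,combo_b combination labels present in `table`.
#' @return the `htest` object of [stats::t.test()].
#' @export
compare_combos <- function(table, combo_a, combo_b) {
  a <- table[table$combo == combo_a & table$valid, ]
  b <- table[table$combo == combo_b & table$valid, ]
  shared <- intersect(a$drug, b$drug)
  if (length(shared) < 2L) stop("fewer than 2 drugs shared by both combos")
  stats::t.test(a$predictive_power[match(shared, a$drug)],
                b$predictive_power[match(shared, b$drug)], paired = TRUE)
}
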