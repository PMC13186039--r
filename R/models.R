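# Predictive models of intestinal-phase bioaccessible Cd content:
# p-value-driven stepwise linear regression and a grid-searched random
# forest, both on the natural-log response scale, with evaluation metrics,
# impurity importances and Shapley attributions.

#' Build the modelling frame from a soil-sample table
#'
#' Log-transforms the response (`ba_content_ip`) and total Cd, keeps the
#' remaining covariates on their original scales, and drops rows without a
#' positive response.
#'
#' @param samples Soil-sample `data.frame`.
#' @param covariates Covariate columns to carry along (besides `log_cd`).
#' @return A `data.frame` with `log_ba_ip`, `log_cd` and the covariates.
#' @export
prepare_model_frame <- function(samples,
                                covariates = c("ph", "som", "clay", "silt",
                                               "sand")) {
  keep <- !is.na(samples$ba_content_ip) & samples$ba_content_ip > 0 &
    samples$cd_total > 0
  out <- data.frame(log_ba_ip = log(samples$ba_content_ip[keep]),
                    log_cd = log(samples$cd_total[keep]))
  for (nm in intersect(covariates, names(samples))) {
    out[[nm]] <- samples[[nm]][keep]
  }
  out
}

#' Reproducible train/test split
#'
#' @param samples `data.frame` with >= 10 rows.
#' @param test_fraction Fraction held out, in (0, 1); the test-set size is
#'   `round(test_fraction * n)`.
#' @param seed Optional integer seed.
#' @return A list with `train` and `test` data frames (disjoint,
#'   exhaustive).
#' @export
split_data <- function(samples, test_fraction = 0.2, seed = NULL) {
  n <- nrow(samples)
  if (n < 10) stop("need n >= 10 to split", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_test <- max(1L, round(test_fraction * n))
  idx <- sample.int(n, n_test)
  list(train = samples[-idx, , drop = FALSE],
       test = samples[idx, , drop = FALSE])
}

#' Stepwise linear regression with p-value entry and removal
#'
#' Forward step: among candidates not yet in the model, fit each added to
#' the current model and take the one with the smallest partial-F p-value;
#' it enters if p < `alpha_enter`. Backward step: any included variable
#' whose p-value rises to >= `alpha_remove` is dropped (worst first).
#' Iterates to a fixpoint. Aliased (rank-deficient) candidates are skipped,
#' which makes the procedure safe for compositional covariates.
#'
#' @param train Modelling frame (see [prepare_model_frame()]).
#' @param response Response column (already log-transformed upstream).
#' @param candidates Candidate predictor columns.
#' @param alpha_enter,alpha_remove Entry / removal significance levels.
#' @return An object of class `cd_stepwise_model` wrapping the final
#'   [stats::lm()] fit with the selection history.
#' @export
stepwise_fit <- function(train, response = "log_ba_ip",
                         candidates = c("log_cd", "ph", "som", "clay",
                                        "sand"),
                         alpha_enter = 0.05, alpha_remove = 0.05) {
  candidates <- intersect(candidates, names(train))
  selected <- character(0)
  history <- character(0)

  coef_p <- function(vars) {
    fml <- if (length(vars)) stats::reformulate(vars, response)
    else stats::as.formula(paste(response, "~ 1"))
    fit <- stats::lm(fml, data = train)
    sm <- summary(fit)$coefficients
    list(fit = fit, p = sm[setdiff(rownames(sm), "(Intercept)"), 4])
  }

  for (pass in seq_len(50L)) {
    changed <- FALSE
    # forward
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      p_enter <- vapply(pool, function(v) {
        fit <- stats::lm(stats::reformulate(c(selected, v), response),
                         data = train)
        cf <- summary(fit)$coefficients
        if (!v %in% rownames(cf)) return(NA_real_)  # aliased
        cf[v, 4]
      }, numeric(1))
      if (any(!is.na(p_enter)) && min(p_enter, na.rm = TRUE) < alpha_enter) {
        best <- pool[which.min(p_enter)]
        selected <- c(selected, best)
        history <- c(history, paste0("+", best))
        changed <- TRUE
      }
    }
    # backward
    repeat {
      if (!length(selected)) break
      p_cur <- coef_p(selected)$p
      if (max(p_cur) >= alpha_remove) {
        worst <- names(which.max(p_cur))
        selected <- setdiff(selected, worst)
        history <- c(history, paste0("-", worst))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  final <- coef_p(selected)
  if (!length(selected)) {
    warning("no candidate reached alpha_enter; returning intercept-only model")
  }
  structure(list(fit = final$fit, selected = selected,
                 p_values = final$p, history = history,
                 response = response, candidates = candidates,
                 alpha_enter = alpha_enter, alpha_remove = alpha_remove),
            class = "cd_stepwise_model")
}

#' @export
predict.cd_stepwise_model <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, newdata = newdata))
}

#' @export
print.cd_stepwise_model <- function(x, ...) {
  cat("Stepwise linear model of", x$response, "\n")
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n")
  print(stats::coef(x$fit))
  invisible(x)
}

.default_rf_grid <- function() {
  data.frame(n_estimators = 100, max_features = 7, min_samples_leaf = 2,
             min_samples_split = 6, max_depth = NA_real_)
}

.fit_ranger <- function(x, y, hp, seed) {
  mtry <- min(hp$max_features, ncol(x))
  max_depth <- if (is.na(hp$max_depth)) 0 else hp$max_depth
  ranger::ranger(x = x, y = y,
                 num.trees = hp$n_estimators,
                 mtry = mtry,
                 min.node.size = hp$min_samples_split,
                 max.depth = max_depth,
                 importance = "impurity",
                 seed = seed)
}

#' Random-forest regression with grid search and k-fold cross-validation
#'
#' Evaluates every hyperparameter combination by mean out-of-fold R2 over
#' `k_folds` folds, selects the best (ties broken by smaller ensemble then
#' grid order), and refits on the full training set. Hyperparameters use
#' the `n_estimators` / `max_features` / `min_samples_leaf` /
#' `min_samples_split` / `max_depth` naming (`max_depth = NA` means
#' unlimited); the default grid is the single published optimum.
#'
#' @param train Modelling frame.
#' @param response Response column.
#' @param predictors Predictor columns.
#' @param grid `data.frame` of hyperparameter rows.
#' @param k_folds Number of CV folds.
#' @param seed Optional integer seed.
#' @return An object of class `cd_forest_model` with the fitted ensemble,
#'   the selected hyperparameters and `cv_r2`.
#' @export
rf_grid_fit <- function(train, response = "log_ba_ip",
                        predictors = setdiff(names(train), response),
                        grid = .default_rf_grid(), k_folds = 5,
                        seed = NULL) {
  if (nrow(grid) == 0L) stop("`grid` must be nonempty", call. = FALSE)
  n <- nrow(train)
  if (k_folds > n) stop("`k_folds` cannot exceed n", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- train[, predictors, drop = FALSE]
  y <- train[[response]]

  folds <- sample(rep(seq_len(k_folds), length.out = n))
  fit_seeds <- sample.int(.Machine$integer.max, nrow(grid) * k_folds + 1L)

  cv_r2 <- vapply(seq_len(nrow(grid)), function(gi) {
    r2s <- vapply(seq_len(k_folds), function(f) {
      tr <- folds != f
      fit <- .fit_ranger(x[tr, , drop = FALSE], y[tr], grid[gi, ],
                         fit_seeds[(gi - 1L) * k_folds + f])
      pred <- stats::predict(fit, data = x[!tr, , drop = FALSE])$predictions
      obs <- y[!tr]
      1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    }, numeric(1))
    mean(r2s)
  }, numeric(1))

  ord <- order(-cv_r2, grid$n_estimators, seq_len(nrow(grid)))
  best <- ord[1]
  fit <- .fit_ranger(x, y, grid[best, ], fit_seeds[length(fit_seeds)])
  structure(list(fit = fit, hyperparameters = as.list(grid[best, ]),
                 grid = grid, cv_r2 = cv_r2[best], cv_r2_all = cv_r2,
                 response = response, predictors = predictors),
            class = "cd_forest_model")
}

#' @export
predict.cd_forest_model <- function(object, newdata, ...) {
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing)) {
    stop("newdata lacks predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stats::predict(object$fit,
                 data = newdata[, object$predictors, drop = FALSE])$predictions
}

#' @export
print.cd_forest_model <- function(x, ...) {
  cat("Random-forest model of", x$response, "\n")
  hp <- x$hyperparameters
  cat(sprintf("  n_estimators=%d max_features=%d min_samples_split=%d cv R2=%.3f\n",
              hp$n_estimators, hp$max_features, hp$min_samples_split,
              x$cv_r2))
  invisible(x)
}

#' Coefficient of determination and RMSE of a model on a data split
#'
#' `R2 = 1 - SS_res / SS_tot`; RMSE on the modelling (log) scale.
#'
#' @param model A `cd_stepwise_model` or `cd_forest_model` (anything with a
#'   `predict` method returning log-scale predictions).
#' @param data Evaluation frame containing the response and all features.
#' @param response Response column name.
#' @return A list with `r2`, `rmse` and `n`.
#' @export
evaluate_model <- function(model, data, response = "log_ba_ip") {
  if (nrow(data) < 2L) stop("need >= 2 rows to evaluate", call. = FALSE)
  regression_metrics(data[[response]], stats::predict(model, data))
}

#' R2 and RMSE of predictions against observations
#'
#' @param obs Observed values.
#' @param pred Predicted values.
#' @return List with `r2` (`1 - SS_res/SS_tot`), `rmse`, `n`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 4))  # r2 = 0.5, rmse = sqrt(1/3)
regression_metrics <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(mean((obs - pred)^2)),
       n = length(obs))
}

#' Normalised impurity-decrease feature importances
#'
#' @param model A trained `cd_forest_model`.
#' @return Named numeric vector of per-feature fractions summing to 1.
#' @export
feature_importances <- function(model) {
  if (!inherits(model, "cd_forest_model") || is.null(model$fit)) {
    stop("invalid-state: `model` must be a trained forest", call. = FALSE)
  }
  imp <- model$fit$variable.importance
  imp / sum(imp)
}

#' Back-transform model output to bioaccessible content and percent
#'
#' Exponentiates the log-scale prediction, caps the content at the physical
#' bound `cd_total`, and reports bioaccessibility as
#' `100 * content / cd_total`, lying in (0, 100].
#'
#' @param model Fitted model (log-scale predictor).
#' @param newdata Feature frame; if it lacks `log_cd` it is derived from
#'   `cd_total`.
#' @param cd_total Total Cd (mg/kg, > 0); defaults to `newdata$cd_total`
#'   or `exp(newdata$log_cd)`.
#' @return A `data.frame` with `ba_content` (mg/kg) and `ba_percent`.
#' @export
predict_bioaccessibility <- function(model, newdata, cd_total = NULL) {
  if (is.null(cd_total)) {
    cd_total <- if ("cd_total" %in% names(newdata)) newdata$cd_total
    else if ("log_cd" %in% names(newdata)) exp(newdata$log_cd)
    else stop("`cd_total` not supplied and not derivable", call. = FALSE)
  }
  if (any(cd_total <= 0, na.rm = TRUE)) {
    stop("`cd_total` must be > 0", call. = FALSE)
  }
  if (!"log_cd" %in% names(newdata)) newdata$log_cd <- log(cd_total)
  content <- pmin(exp(stats::predict(model, newdata)), cd_total)
  data.frame(ba_content = content,
             ba_percent = pmin(100 * content / cd_total, 100))
}

#' Collect train/test/CV metrics for a fitted model
#'
#' @param model Fitted model.
#' @param train,test Modelling frames.
#' @param response Response column.
#' @return A list of class `model_metrics` with `r2_train`, `r2_test`,
#'   `r2_cv` (forests only), `rmse_train`, `rmse_test`, `delta_r2`.
#' @export
model_metrics <- function(model, train, test, response = "log_ba_ip") {
  tr <- evaluate_model(model, train, response)
  te <- evaluate_model(model, test, response)
  structure(list(r2_train = tr$r2, r2_test = te$r2,
                 r2_cv = if (inherits(model, "cd_forest_model"))
                   model$cv_r2 else NA_real_,
                 rmse_train = tr$rmse, rmse_test = te$rmse,
                 delta_r2 = tr$r2 - te$r2),
            class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("R2 train %.3f | test %.3f | CV %s | dR2 %.3f\n",
              x$r2_train, x$r2_test,
              ifelse(is.na(x$r2_cv), "-", sprintf("%.3f", x$r2_cv)),
              x$delta_r2))
  cat(sprintf("RMSE train %.4f | test %.4f (log scale)\n",
              x$rmse_train, x$rmse_test))
  invisible(x)
}
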