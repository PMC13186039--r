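# Shapley attribution of model predictions.
#
# Interventional Shapley values against a background sample: the value of a
# coalition S is the mean prediction with the features in S taken from the
# explained row and the remainder from each background row. For k features
# the 2^k coalition values are enumerated exactly (so the efficiency /
# local-accuracy identity holds to machine precision); above
# `max_exact_features` a permutation-sampling estimator is used instead.

.shapley_weights <- function(k) {
  # w(s) = s! (k-1-s)! / k! for coalition size s = 0..k-1
  s <- 0:(k - 1)
  exp(lfactorial(s) + lfactorial(k - 1 - s) - lfactorial(k))
}

.shapley_exact_row <- function(model, x_row, background, features) {
  k <- length(features)
  n_bg <- nrow(background)
  n_mask <- bitwShiftL(1L, k)
  # stack all 2^k masked background copies into one predict call
  big <- background[rep(seq_len(n_bg), times = n_mask), , drop = FALSE]
  for (m in seq_len(n_mask) - 1L) {
    rows <- m * n_bg + seq_len(n_bg)
    for (f in seq_len(k)) {
      if (bitwAnd(m, bitwShiftL(1L, f - 1L)) != 0L) {
        big[rows, features[f]] <- x_row[[features[f]]]
      }
    }
  }
  pred <- stats::predict(model, big)
  v <- vapply(seq_len(n_mask) - 1L, function(m)
    mean(pred[m * n_bg + seq_len(n_bg)]), numeric(1))
  w <- .shapley_weights(k)
  phi <- numeric(k)
  masks <- seq_len(n_mask) - 1L
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0L),
                  numeric(1))
  for (f in seq_len(k)) {
    bit <- bitwShiftL(1L, f - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    phi[f] <- sum(w[sizes[without + 1L] + 1L] *
                    (v[without + bit + 1L] - v[without + 1L]))
  }
  list(phi = phi, baseline = v[1], fx = v[n_mask])
}

.shapley_perm_row <- function(model, x_row, background, features, n_perm,
                              seed_offset = 0L) {
  k <- length(features)
  n_bg <- nrow(background)
  phi <- numeric(k)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(k)
    cur <- background
    prev_pred <- mean(stats::predict(model, cur))
    for (f in ord) {
      cur[, features[f]] <- x_row[[features[f]]]
      new_pred <- mean(stats::predict(model, cur))
      phi[f] <- phi[f] + (new_pred - prev_pred)
      prev_pred <- new_pred
    }
  }
  list(phi = phi / n_perm,
       baseline = mean(stats::predict(model, background)),
       fx = stats::predict(model, x_row))
}

#' Shapley attributions of model predictions
#'
#' Computes per-sample, per-feature additive attributions relative to the
#' background-mean baseline, satisfying local accuracy:
#' `baseline + sum(values[i, ]) = prediction(i)`.
#'
#' @param model Fitted model with a `predict(model, data)` method.
#' @param data Rows to explain.
#' @param background Background (reference) rows; nonempty.
#' @param features Feature columns; defaults to the model's predictors.
#' @param max_exact_features Largest k for exact coalition enumeration.
#' @param n_perm Permutations per row for the sampling fallback.
#' @return An object of class `shap_attribution`: list with matrix
#'   `values` (rows of `data` x features), `baseline`, `predictions`, and
#'   `method` (`"exact-enumeration"` or `"permutation-sampling"`).
#' @export
shapley_attributions <- function(model, data, background,
                                 features = NULL, max_exact_features = 12,
                                 n_perm = 64) {
  if (is.null(features)) {
    features <- if (inherits(model, "cd_forest_model")) model$predictors
    else if (inherits(model, "cd_stepwise_model")) model$candidates
    else stop("supply `features` for this model type", call. = FALSE)
  }
  if (nrow(background) == 0L) {
    stop("`background` must be nonempty", call. = FALSE)
  }
  missing <- setdiff(features, names(data))
  if (length(missing)) {
    stop("feature mismatch: data lacks ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  background <- background[, union(features,
                                   intersect(names(background), names(data))),
                           drop = FALSE]
  k <- length(features)
  exact <- k <= max_exact_features
  vals <- matrix(NA_real_, nrow(data), k,
                 dimnames = list(NULL, features))
  preds <- numeric(nrow(data))
  baseline <- NA_real_
  for (i in seq_len(nrow(data))) {
    row <- data[i, , drop = FALSE]
    res <- if (exact) {
      .shapley_exact_row(model, row, background, features)
    } else {
      .shapley_perm_row(model, row, background, features, n_perm)
    }
    vals[i, ] <- res$phi
    preds[i] <- res$fx
    baseline <- res$baseline
  }
  structure(list(values = vals, baseline = baseline, predictions = preds,
                 method = if (exact) "exact-enumeration"
                 else "permutation-sampling"),
            class = "shap_attribution")
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat("Shapley attributions (", x$method, "), baseline ",
      format(x$baseline), "\n", sep = "")
  cat("mean |value| per feature:\n")
  print(sort(colMeans(abs(x$values)), decreasing = TRUE))
  invisible(x)
}
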