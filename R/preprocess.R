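# Screening statistics, unit conversion, random-forest imputation,
# influence-based outlier filtering and rank-correlation analysis.

#' Convert total organic carbon to soil organic matter
#'
#' Applies the van Bemmelen convention TOC = factor x SOM, i.e.
#' SOM = TOC / factor with the conventional factor 0.58.
#'
#' @param toc Total organic carbon, g/kg (>= 0).
#' @param factor Conversion factor (TOC per unit SOM).
#' @return Soil organic matter, g/kg.
#' @export
#' @examples
#' toc_to_som(5.8)  # 10
toc_to_som <- function(toc, factor = 0.58) {
  if (any(toc < 0, na.rm = TRUE)) {
    stop("`toc` must be non-negative", call. = FALSE)
  }
  toc / factor
}

.screen_result <- function(statistic, p_value, n_per_group, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_per_group = n_per_group, method = method),
            class = "screen_test")
}

#' @export
print.screen_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format.pval(x$p_value), "\n")
  invisible(x)
}

#' Kruskal-Wallis rank test across method groups
#'
#' Tie-corrected H statistic with a chi-square approximation on k - 1
#' degrees of freedom, used to screen for overall differences among
#' in-vitro extraction methods.
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @return A `screen_test` with the H statistic, p-value and group sizes.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))$statistic  # 2.4
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of >= 2 numeric vectors", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) {
    stop("every group must be nonempty", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  .screen_result(unname(kt$statistic), kt$p.value, lengths(groups),
                 "Kruskal-Wallis rank sum test")
}

# exact two-sided Mann-Whitney p by enumeration over group assignments,
# with midranks so tied data are handled identically to the approximation
.mwu_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U test for pairwise method comparison
#'
#' Reports the U statistic of the first sample (number of pairs with
#' x > y, ties counted as 1/2). The two-sided p-value comes from exact
#' enumeration with midranks when `length(x) * length(y) <= exact_limit`,
#' otherwise from the tie-corrected normal approximation.
#'
#' @param x,y Nonempty numeric vectors.
#' @param exact_limit Largest `n_x * n_y` for which enumeration is used.
#' @return A `screen_test` with U, p-value and sample sizes.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 100) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("`x` and `y` must be nonempty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  p <- if (nx * ny <= exact_limit) {
    .mwu_exact_p(x, y)
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    )
  }
  .screen_result(unname(u), min(1, p), c(n_x = nx, n_y = ny),
                 "Mann-Whitney U test")
}

#' Iterative random-forest imputation of missing covariates
#'
#' missForest-style single completion: initialise missing cells with column
#' medians, then cycle through incomplete columns in order of increasing
#' missingness, refitting a random forest of each column on all others and
#' replacing only the originally missing cells, until the relative change
#' of the imputed values drops below `tol` or `max_iter` is reached.
#' Observed cells are never altered and `exclude` columns (e.g. the
#' response) are neither imputed nor used as predictors.
#'
#' @param samples `data.frame` with missing values in numeric columns.
#' @param exclude Character vector of columns to leave untouched.
#' @param max_iter Maximum sweeps over the columns.
#' @param tol Relative-change stopping threshold.
#' @param num_trees Trees per forest.
#' @param seed Optional integer seed.
#' @return The completed `data.frame`.
#' @export
rf_impute <- function(samples, exclude = c("ba_content_gp", "ba_content_ip"),
                      max_iter = 10, tol = 1e-3, num_trees = 100,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  num_cols <- names(samples)[vapply(samples, is.numeric, logical(1))]
  work_cols <- setdiff(num_cols, exclude)
  n_miss <- vapply(samples[work_cols], function(v) sum(is.na(v)), integer(1))
  if (any(n_miss == nrow(samples))) {
    stop("column(s) entirely missing: ",
         paste(work_cols[n_miss == nrow(samples)], collapse = ", "),
         call. = FALSE)
  }
  target_cols <- work_cols[n_miss > 0]
  if (length(target_cols) == 0L) return(samples)
  target_cols <- target_cols[order(n_miss[target_cols])]

  completed <- samples
  for (cl in target_cols) {
    completed[[cl]][is.na(completed[[cl]])] <-
      stats::median(samples[[cl]], na.rm = TRUE)
  }
  miss_idx <- lapply(target_cols, function(cl) which(is.na(samples[[cl]])))
  names(miss_idx) <- target_cols

  prev <- unlist(lapply(target_cols, function(cl)
    completed[[cl]][miss_idx[[cl]]]))
  for (iter in seq_len(max_iter)) {
    for (cl in target_cols) {
      preds <- setdiff(work_cols, cl)
      dat <- completed[, c(cl, preds)]
      obs <- setdiff(seq_len(nrow(dat)), miss_idx[[cl]])
      fit <- ranger::ranger(
        x = dat[obs, preds, drop = FALSE], y = dat[obs, cl],
        num.trees = num_trees, respect.unordered.factors = TRUE,
        seed = sample.int(.Machine$integer.max, 1)
      )
      completed[[cl]][miss_idx[[cl]]] <- stats::predict(
        fit, data = dat[miss_idx[[cl]], preds, drop = FALSE]
      )$predictions
    }
    cur <- unlist(lapply(target_cols, function(cl)
      completed[[cl]][miss_idx[[cl]]]))
    delta <- sum((cur - prev)^2) / max(sum(cur^2), .Machine$double.eps)
    prev <- cur
    if (delta < tol) break
  }
  completed
}

#' Filter influential observations by Cook's distance
#'
#' Fits one ordinary least-squares regression of `response` on
#' `predictors`, computes each observation's Cook's distance
#' \eqn{D_i = e_i^2 h_{ii} / (p s^2 (1-h_{ii})^2)} and removes the rows
#' with `D_i > threshold`.
#'
#' @param samples `data.frame`.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @param threshold Flagging threshold on D (default 1).
#' @return A list with `samples` (filtered table) and `diagnostics`
#'   (`cooks_d`, `leverage`, `flagged`, row indices into the input).
#' @export
cooks_filter <- function(samples, response, predictors, threshold = 1) {
  fml <- stats::reformulate(predictors, response)
  cc <- stats::complete.cases(samples[, c(response, predictors)])
  dat <- samples[cc, , drop = FALSE]
  if (nrow(dat) <= length(predictors) + 1L) {
    stop("need n > p + 1 complete rows for the OLS fit", call. = FALSE)
  }
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("numerical-error: singular design matrix in Cook's-distance fit",
         call. = FALSE)
  }
  d <- unname(stats::cooks.distance(fit))
  h <- unname(stats::hatvalues(fit))
  flagged <- which(d > threshold)
  flagged_orig <- which(cc)[flagged]
  filtered <- if (length(flagged_orig))
    samples[-flagged_orig, , drop = FALSE] else samples
  list(
    samples = filtered,
    diagnostics = list(cooks_d = d, leverage = h,
                       flagged = flagged_orig,
                       flagged_ids = if ("sample_id" %in% names(dat))
                         dat$sample_id[flagged] else as.character(flagged))
  )
}

#' Pairwise Spearman correlation matrix with significance stars
#'
#' Pairwise-complete Spearman rho with midranks; p-values from
#' [stats::cor.test()]; stars `*` for p < 0.05 and `**` for p < 0.01.
#' Constant columns yield `NA` entries with a warning.
#'
#' @param samples `data.frame`.
#' @param columns Columns to correlate.
#' @return A list of class `spearman_matrix` with matrices `rho`, `p` and
#'   character matrix `stars`.
#' @export
spearman_matrix <- function(samples, columns) {
  k <- length(columns)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  stars <- matrix("", k, k, dimnames = list(columns, columns))
  warned <- FALSE
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- samples[[columns[i]]]
      y <- samples[[columns[j]]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 4L) {
        stop("need >= 4 complete pairs for ", columns[i], " vs ", columns[j],
             call. = FALSE)
      }
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warned <- TRUE
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
      )
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      s <- if (ct$p.value < 0.01) "**" else if (ct$p.value < 0.05) "*" else ""
      stars[i, j] <- stars[j, i] <- s
    }
  }
  if (warned) warning("constant column(s): correlation undefined, set to NA")
  structure(list(rho = rho, p = p, stars = stars), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 3, ...) {
  m <- matrix(paste0(format(round(x$rho, digits)), x$stars),
              nrow = nrow(x$rho), dimnames = dimnames(x$rho))
  print(m, quote = FALSE)
  invisible(x)
}
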