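# Probabilistic health-risk engine: average daily doses by ingestion,
# inhalation and dermal contact, hazard quotient and carcinogenic risk,
# Monte Carlo propagation of exposure-parameter distributions with
# bioaccessibility adjustment, and contribution-to-variance sensitivity.

.dose_params <- c("C", "BA", "IngR", "InhR", "EF", "ED", "BW", "AT",
                  "PEF", "SA", "AF", "ABF")

#' Fit a lognormal distribution to positive samples
#'
#' Maximum-likelihood on the log scale: `p1 = mean(log x)`,
#' `p2 = sd(log x)`, with a normality report on the logged values
#' (Q-Q correlation against theoretical normal quantiles and a
#' Shapiro-Wilk p-value).
#'
#' @param samples Positive values, n >= 2.
#' @param name Parameter name recorded in the spec.
#' @param lower,upper Optional truncation bounds for later sampling.
#' @return A one-row distribution-spec `data.frame` with attribute
#'   `normality` (list with `qq_correlation`, `shapiro_p`).
#' @export
fit_lognormal <- function(samples, name = "C", lower = NA_real_,
                          upper = NA_real_) {
  if (length(samples) < 2) stop("need n >= 2", call. = FALSE)
  if (any(samples <= 0)) stop("samples must be > 0", call. = FALSE)
  lx <- log(samples)
  p1 <- mean(lx)
  p2 <- stats::sd(lx)
  qq <- if (p2 > 0) {
    sx <- sort(lx)
    q <- stats::qnorm(stats::ppoints(length(sx)))
    stats::cor(sx, q)
  } else NA_real_
  sh <- if (p2 > 0 && length(lx) >= 3) {
    sub <- if (length(lx) > 5000) sample(lx, 5000) else lx
    stats::shapiro.test(sub)$p.value
  } else NA_real_
  out <- data.frame(parameter = name, population = NA_character_,
                    region = NA_character_, law = "lognormal",
                    p1 = p1, p2 = p2, p3 = NA_real_,
                    lower = lower, upper = upper, units = "",
                    stringsAsFactors = FALSE)
  attr(out, "normality") <- list(qq_correlation = qq, shapiro_p = sh)
  out
}

#' Average daily doses for the three exposure pathways
#'
#' \deqn{ADD_{ing} = \frac{C \cdot BA \cdot IngR \cdot CF \cdot EF \cdot ED}{BW \cdot AT}}
#' \deqn{ADD_{inh} = \frac{C \cdot InhR \cdot EF \cdot ED}{PEF \cdot BW \cdot AT}}
#' \deqn{ADD_{derm} = \frac{C \cdot SA \cdot AF \cdot ABF \cdot EF \cdot ED \cdot 10^{-6}}{BW \cdot AT}}
#' with C in mg/kg, doses in mg/(kg d). `cf_ing` (default 1e-6 kg/mg for
#' IngR in mg/d) makes the ingestion dose dimensionally consistent;
#' `cf_ing = 1` reproduces the unconverted formula.
#'
#' @param ctx List or `data.frame` (vectorised) with elements `C`, `BA`,
#'   `IngR`, `InhR`, `EF`, `ED`, `BW`, `AT`, `PEF`, `SA`, `AF`, `ABF`.
#'   `BA` is a fraction in `[0, 1]`.
#' @param cf_ing Ingestion unit-conversion factor (kg/mg).
#' @return A list with vectors `ADD_ing`, `ADD_inh`, `ADD_dermal`.
#' @export
#' @examples
#' ctx <- list(C = 1, BA = 1, IngR = 100, InhR = 14.5, EF = 350, ED = 6,
#'             BW = 15, AT = 2190, PEF = 1.36e9, SA = 2000, AF = 0.2,
#'             ABF = 0.001)
#' compute_daily_doses(ctx)$ADD_ing  # 6.3927e-06
compute_daily_doses <- function(ctx, cf_ing = 1e-6) {
  missing <- setdiff(.dose_params, names(ctx))
  if (length(missing)) {
    stop("missing exposure parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(ctx$BW <= 0) || any(ctx$AT <= 0) || any(ctx$PEF <= 0)) {
    stop("BW, AT and PEF must be > 0", call. = FALSE)
  }
  if (any(ctx$BA < 0 | ctx$BA > 1)) {
    stop("`BA` must lie in [0, 1]", call. = FALSE)
  }
  base <- ctx$C * ctx$EF * ctx$ED / (ctx$BW * ctx$AT)
  list(ADD_ing = base * ctx$BA * ctx$IngR * cf_ing,
       ADD_inh = base * ctx$InhR / ctx$PEF,
       ADD_dermal = base * ctx$SA * ctx$AF * ctx$ABF * 1e-6)
}

#' Default pathway toxicity values (synthetic stand-ins)
#'
#' Reference doses and slope factors per pathway for Cd. These are
#' plausible literature-style defaults, not the study-specific table;
#' replace them with authoritative values for real assessments. A missing
#' (`NA`) entry excludes that pathway from the corresponding sum.
#'
#' @return `data.frame` with `pathway`, `rfd` (mg/(kg d)), `sf`
#'   ((kg d)/mg).
#' @export
default_toxicity_values <- function() {
  data.frame(pathway = c("ingestion", "inhalation", "dermal"),
             rfd = c(1e-3, 1e-3, 1e-5),
             sf = c(6.1, 6.3, NA_real_),
             stringsAsFactors = FALSE)
}

#' Hazard quotient and carcinogenic risk from dose triples
#'
#' `HQ = sum_i ADD_i / RfD_i` over pathways with an RfD;
#' `CR = sum_i ADD_i * SF_i` over pathways with a slope factor.
#'
#' @param doses List with `ADD_ing`, `ADD_inh`, `ADD_dermal` (vectors).
#' @param tox Toxicity table as in [default_toxicity_values()].
#' @return A list with vectors `HQ` and `CR`.
#' @export
compute_risk_indices <- function(doses, tox = default_toxicity_values()) {
  path_map <- c(ingestion = "ADD_ing", inhalation = "ADD_inh",
                dermal = "ADD_dermal")
  if (any(tox$rfd <= 0, na.rm = TRUE)) {
    stop("RfD values must be > 0", call. = FALSE)
  }
  if (!any(is.finite(tox$rfd)) && !any(is.finite(tox$sf))) {
    stop("at least one pathway needs toxicity values", call. = FALSE)
  }
  hq <- cr <- 0
  for (i in seq_len(nrow(tox))) {
    add <- doses[[path_map[[tox$pathway[i]]]]]
    if (is.finite(tox$rfd[i])) hq <- hq + add / tox$rfd[i]
    if (is.finite(tox$sf[i])) cr <- cr + add * tox$sf[i]
  }
  list(HQ = hq, CR = cr)
}

# sample one distribution spec; truncation by rejection
.sample_spec <- function(spec, n) {
  rfun <- switch(spec$law,
    point = function(m) rep(spec$p1, m),
    normal = function(m) stats::rnorm(m, spec$p1, spec$p2),
    lognormal = function(m) {
      if (is.na(spec$p2) || spec$p2 < 0)
        stop("lognormal requires p2 >= 0 for `", spec$parameter, "`",
             call. = FALSE)
      stats::rlnorm(m, spec$p1, spec$p2)
    },
    uniform = function(m) stats::runif(m, spec$p1, spec$p2),
    triangular = function(m) {
      a <- spec$p1; c <- spec$p2; b <- spec$p3
      u <- stats::runif(m)
      fc <- (c - a) / (b - a)
      ifelse(u < fc, a + sqrt(u * (b - a) * (c - a)),
             b - sqrt((1 - u) * (b - a) * (b - c)))
    },
    stop("unknown law `", spec$law, "` for `", spec$parameter, "`",
         call. = FALSE))
  out <- rfun(n)
  lo <- if (is.na(spec$lower)) -Inf else spec$lower
  hi <- if (is.na(spec$upper)) Inf else spec$upper
  if (is.finite(lo) || is.finite(hi)) {
    bad <- which(out < lo | out > hi)
    tries <- 0L
    n_drawn <- n
    n_rejected <- length(bad)
    while (length(bad) > 0L && tries < 1000L) {
      out[bad] <- rfun(length(bad))
      n_drawn <- n_drawn + length(bad)
      bad <- bad[out[bad] < lo | out[bad] > hi]
      n_rejected <- n_rejected + length(bad)
      tries <- tries + 1L
      if (tries >= 20L && n_rejected / n_drawn > 0.99) {
        stop("rejection rate > 99% for `", spec$parameter,
             "`: bounds incompatible with the law", call. = FALSE)
      }
    }
    if (length(bad) > 0L) {
      stop("truncation failed for `", spec$parameter, "`", call. = FALSE)
    }
  }
  out
}

#' Monte Carlo propagation of exposure distributions to HQ and CR
#'
#' Samples every exposure parameter independently from its distribution
#' spec (truncation by rejection), resolves the derived averaging time law
#' `ed365` (`AT = ED * 365`), and evaluates the dose and risk equations per
#' iteration.
#'
#' @param specs Distribution-spec `data.frame`; must cover `C`, `BA`,
#'   `IngR`, `InhR`, `EF`, `ED`, `BW`, `AT`, `PEF`, `SA`, `AF`, `ABF`.
#' @param tox Toxicity table.
#' @param n_iter Iterations (>= 100; the reference configuration is
#'   10,000).
#' @param seed Optional integer seed (one global stream).
#' @param cf_ing Ingestion unit conversion, see [compute_daily_doses()].
#' @return A `data.frame` of class `risk_draws` with one row per iteration:
#'   the sampled parameters, `ADD_ing`, `ADD_inh`, `ADD_dermal`, `HQ`,
#'   `CR`. Attributes `n_iter` and `seed`.
#' @export
run_monte_carlo <- function(specs, tox = default_toxicity_values(),
                            n_iter = 10000, seed = NULL, cf_ing = 1e-6) {
  if (n_iter < 100) stop("`n_iter` must be >= 100", call. = FALSE)
  missing <- setdiff(.dose_params, specs$parameter)
  if (length(missing)) {
    stop("missing distribution spec(s) for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- list()
  for (p in .dose_params) {
    spec <- specs[match(p, specs$parameter), ]
    draws[[p]] <- if (spec$law == "ed365") rep(NA_real_, n_iter)
    else .sample_spec(spec, n_iter)
  }
  at_spec <- specs[match("AT", specs$parameter), ]
  if (at_spec$law == "ed365") draws$AT <- draws$ED * 365
  ctx <- as.data.frame(draws)
  doses <- compute_daily_doses(ctx, cf_ing = cf_ing)
  idx <- compute_risk_indices(doses, tox)
  out <- cbind(ctx, ADD_ing = doses$ADD_ing, ADD_inh = doses$ADD_inh,
               ADD_dermal = doses$ADD_dermal, HQ = idx$HQ, CR = idx$CR)
  attr(out, "n_iter") <- as.integer(n_iter)
  attr(out, "seed") <- seed
  class(out) <- c("risk_draws", "data.frame")
  out
}

#' Summarise Monte Carlo risk draws
#'
#' Moments, coefficient of variation, percentiles (linear interpolation
#' between closest ranks, [stats::quantile()] type 7) and exceedance
#' probabilities against HQ = 1 and CR = 1e-6.
#'
#' @param draws A `risk_draws` object (or data.frame with `HQ`, `CR`).
#' @param probs Percentile levels; the 95th is always included.
#' @return `data.frame` of class `risk_summary`, one row per index.
#' @export
summarize_risk <- function(draws, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  if (is.null(nrow(draws)) || nrow(draws) < 100) {
    stop("need >= 100 draws", call. = FALSE)
  }
  probs <- sort(unique(c(probs, 0.95)))
  one <- function(x, threshold) {
    q <- stats::quantile(x, probs, type = 7, names = FALSE)
    out <- data.frame(mean = mean(x), sd = stats::sd(x),
                      cv = 100 * stats::sd(x) / mean(x))
    for (i in seq_along(probs)) {
      out[[sprintf("p%02d", round(100 * probs[i]))]] <- q[i]
    }
    out$p_exceed <- mean(x > threshold)
    out
  }
  out <- rbind(cbind(index = "HQ", one(draws$HQ, 1)),
               cbind(index = "CR", one(draws$CR, 1e-6)))
  class(out) <- c("risk_summary", "data.frame")
  out
}

#' Effect of bioaccessibility adjustment on risk estimates
#'
#' Runs a paired Monte Carlo with common random numbers: both arms share
#' every non-BA draw; the unadjusted arm fixes BA = 1, the adjusted arm
#' samples BA from `ba_spec` (support within (0, 1]). Reports the
#' fold-reduction of the mean and 95th percentile and the percent decrease
#' of the 95th percentile for HQ and CR.
#'
#' @param specs Distribution-spec table for all non-BA parameters (a `BA`
#'   row, if present, is replaced).
#' @param tox Toxicity table.
#' @param ba_spec One-row spec for BA.
#' @param n_iter Iterations.
#' @param seed Optional integer seed.
#' @param cf_ing Ingestion unit conversion.
#' @return A list of class `ba_adjustment` with `unadjusted`, `adjusted`
#'   (both `risk_draws`) and `report` (per-index ratios and decreases).
#' @export
compare_adjustment <- function(specs, tox = default_toxicity_values(),
                               ba_spec, n_iter = 10000, seed = NULL,
                               cf_ing = 1e-6) {
  law_lo <- switch(ba_spec$law, point = ba_spec$p1, lognormal = 0,
                   uniform = ba_spec$p1, triangular = ba_spec$p1,
                   normal = -Inf, -Inf)
  law_hi <- switch(ba_spec$law, point = ba_spec$p1, lognormal = Inf,
                   uniform = ba_spec$p2, triangular = ba_spec$p3,
                   normal = Inf, Inf)
  lo <- max(law_lo, if (is.na(ba_spec$lower)) -Inf else ba_spec$lower)
  hi <- min(law_hi, if (is.na(ba_spec$upper)) Inf else ba_spec$upper)
  if (lo < 0 || hi <= 0 || hi > 1 ||
      (ba_spec$law %in% c("normal", "lognormal") && !is.finite(hi))) {
    stop("BA support must lie in (0, 1]", call. = FALSE)
  }
  specs <- specs[specs$parameter != "BA", , drop = FALSE]
  unit_ba <- specs[1, ]
  unit_ba$parameter <- "BA"; unit_ba$law <- "point"; unit_ba$p1 <- 1
  unit_ba[c("p2", "p3", "lower", "upper")] <- NA_real_

  # common random numbers: the shared stream draws the non-BA parameters,
  # BA is drawn afterwards from the same generator state in both arms
  unadj <- run_monte_carlo(rbind(specs, unit_ba), tox, n_iter, seed, cf_ing)
  ba_spec$parameter <- "BA"
  ba <- .sample_spec(ba_spec, n_iter)
  adj <- unadj
  adj$BA <- ba
  doses <- compute_daily_doses(adj[, .dose_params], cf_ing = cf_ing)
  idx <- compute_risk_indices(doses, tox)
  adj$ADD_ing <- doses$ADD_ing; adj$ADD_inh <- doses$ADD_inh
  adj$ADD_dermal <- doses$ADD_dermal
  adj$HQ <- idx$HQ; adj$CR <- idx$CR

  rep_one <- function(u, a) {
    q_u <- stats::quantile(u, 0.95, type = 7, names = FALSE)
    q_a <- stats::quantile(a, 0.95, type = 7, names = FALSE)
    data.frame(mean_ratio = mean(u) / mean(a),
               p95_ratio = q_u / q_a,
               p95_decrease_pct = 100 * (q_u - q_a) / q_u,
               cv_unadjusted = 100 * stats::sd(u) / mean(u),
               cv_adjusted = 100 * stats::sd(a) / mean(a))
  }
  report <- rbind(cbind(index = "HQ", rep_one(unadj$HQ, adj$HQ)),
                  cbind(index = "CR", rep_one(unadj$CR, adj$CR)))
  structure(list(unadjusted = unadj, adjusted = adj, report = report),
            class = "ba_adjustment")
}

#' Contribution-to-variance sensitivity analysis
#'
#' Spearman rank correlation `r_k` of each input parameter with the output,
#' converted to percent contributions `100 * r_k^2 / sum_j r_j^2`; the
#' correlation signs are reported separately. Constant inputs contribute 0
#' (with a warning).
#'
#' @param inputs `data.frame`/matrix of per-iteration parameter draws.
#' @param output Output vector (HQ or CR draws) from the same run.
#' @return `data.frame` of class `sensitivity_result` with `parameter`,
#'   `contribution` (percent, sums to 100), `rank_correlation`, `sign`.
#' @export
variance_contributions <- function(inputs, output) {
  inputs <- as.data.frame(inputs)
  if (nrow(inputs) != length(output)) {
    stop("inputs and output must come from the same run", call. = FALSE)
  }
  r <- vapply(inputs, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    suppressWarnings(stats::cor(v, output, method = "spearman"))
  }, numeric(1))
  if (anyNA(r)) {
    warning("constant input column(s): contribution set to 0 for ",
            paste(names(r)[is.na(r)], collapse = ", "))
  }
  r2 <- ifelse(is.na(r), 0, r^2)
  contrib <- if (sum(r2) > 0) 100 * r2 / sum(r2) else r2
  out <- data.frame(parameter = names(inputs),
                    contribution = unname(contrib),
                    rank_correlation = unname(ifelse(is.na(r), 0, r)),
                    sign = unname(ifelse(is.na(r) | r == 0, "0",
                                         ifelse(r > 0, "+", "-"))),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$contribution), ]
  row.names(out) <- NULL
  class(out) <- c("sensitivity_result", "data.frame")
  out
}
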