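test_that("lognormal fitting matches hand and recovery computations", {
  # degenerate: all samples equal
  fit <- fit_lognormal(rep(3, 10))
  expect_equal(fit$p1, log(3))
  expect_equal(fit$p2, 0)
  # {e, e^3}: mean/sd of logs {1, 3}
  fit2 <- fit_lognormal(c(exp(1), exp(3)), name = "X")
  expect_equal(fit2$p1, 2)
  expect_equal(fit2$p2, sqrt(2))
  # parameter recovery on a large exact lognormal sample
  set.seed(1)
  x <- rlnorm(1e4, meanlog = 0.7, sdlog = 0.4)
  fit3 <- fit_lognormal(x)
  expect_lt(abs(fit3$p1 - 0.7) / 0.7, 0.02)
  expect_lt(abs(fit3$p2 - 0.4) / 0.4, 0.02)
  norm <- attr(fit3, "normality")
  expect_gt(norm$qq_correlation, 0.999)
  expect_error(fit_lognormal(c(1, -1, 2)), "> 0")
  expect_error(fit_lognormal(3), "n >= 2")
})

test_that("daily doses follow the exposure equations", {
  ctx <- full_ctx()
  d <- compute_daily_doses(ctx)
  expect_equal(d$ADD_ing, (1 * 1 * 100 * 1e-6 * 350 * 6) / (15 * 2190),
               tolerance = 1e-12)
  expect_equal(d$ADD_inh, (1 * 14.5 * 350 * 6) / (1.36e9 * 15 * 2190),
               tolerance = 1e-12)
  expect_equal(d$ADD_dermal,
               (1 * 2000 * 0.2 * 0.001 * 350 * 6 * 1e-6) / (15 * 2190),
               tolerance = 1e-12)
  # BA = 0 zeroes ingestion only
  ctx0 <- ctx; ctx0$BA <- 0
  d0 <- compute_daily_doses(ctx0)
  expect_equal(d0$ADD_ing, 0)
  expect_equal(d0$ADD_inh, d$ADD_inh)
  expect_equal(d0$ADD_dermal, d$ADD_dermal)
  # degree-1 homogeneity in C
  ctx2 <- ctx; ctx2$C <- 2 * ctx$C
  d2 <- compute_daily_doses(ctx2)
  for (p in names(d)) expect_equal(d2[[p]], 2 * d[[p]], tolerance = 1e-12)
  # literal (unconverted) formula via cf_ing = 1
  expect_equal(compute_daily_doses(ctx, cf_ing = 1)$ADD_ing,
               d$ADD_ing * 1e6, tolerance = 1e-9)
  expect_error(compute_daily_doses(modifyList(ctx, list(BW = 0))), "BW")
  expect_error(compute_daily_doses(ctx[-1]), "missing")
})

test_that("HQ and CR sum pathway ratios and products", {
  tox <- default_toxicity_values()
  doses <- list(ADD_ing = tox$rfd[1], ADD_inh = 0, ADD_dermal = 0)
  idx <- compute_risk_indices(doses, tox)
  expect_equal(idx$HQ, 1)  # dose at the reference dose
  idx2 <- compute_risk_indices(list(ADD_ing = 1e-4, ADD_inh = 0,
                                    ADD_dermal = 0), ingestion_only_tox())
  expect_equal(idx2$CR, 6.1e-4, tolerance = 1e-12)
  idx0 <- compute_risk_indices(list(ADD_ing = 0, ADD_inh = 0,
                                    ADD_dermal = 0), tox)
  expect_equal(idx0$HQ, 0)
  expect_equal(idx0$CR, 0)
  bad <- tox; bad$rfd[1] <- -1
  expect_error(compute_risk_indices(doses, bad), "RfD")
})

test_that("point-mass Monte Carlo collapses to the deterministic result", {
  specs <- point_specs()
  d <- run_monte_carlo(specs, ingestion_only_tox(), n_iter = 200, seed = 2)
  det <- compute_daily_doses(full_ctx())
  expect_equal(unique(d$ADD_ing),
               (1 * 1 * 100 * 1e-6 * 350 * 6) / (15 * 2190))
  expect_equal(unique(d$HQ), unique(d$ADD_ing) / 1e-3)
  expect_equal(unique(d$CR), unique(d$ADD_ing) * 6.1)
  # determinism and missing-parameter guard
  d2 <- run_monte_carlo(specs, ingestion_only_tox(), n_iter = 200, seed = 2)
  expect_identical(d, d2)
  expect_error(run_monte_carlo(specs[-3, ], ingestion_only_tox(), 200, 1),
               "IngR")
  expect_error(run_monte_carlo(specs, ingestion_only_tox(), n_iter = 50),
               "n_iter")
  # impossible truncation is detected
  bad <- specs
  bad[bad$parameter == "C", c("law", "p1", "p2", "lower", "upper")] <-
    list("lognormal", 0, 0.01, 1e6, 1e7)
  expect_error(run_monte_carlo(bad, ingestion_only_tox(), 200, 1),
               "rejection")
})

test_that("the derived averaging-time law ties AT to ED", {
  specs <- point_specs()
  specs[specs$parameter == "ED", c("law", "p1", "p2")] <-
    list("uniform", 2, 10)
  specs[specs$parameter == "AT", "law"] <- "ed365"
  d <- run_monte_carlo(specs, ingestion_only_tox(), n_iter = 300, seed = 3)
  expect_equal(d$AT, d$ED * 365)
  expect_true(all(d$AT >= d$ED * 365 - 1e-9))
})

test_that("risk indices scale linearly in C and in BA", {
  specs <- point_specs(make_spec("C", "lognormal", log(1), 0.6))
  d1 <- run_monte_carlo(specs, ingestion_only_tox(), n_iter = 500, seed = 4)
  sc <- specs
  sc[sc$parameter == "C", "p1"] <- log(3)  # C scaled by 3
  d3 <- run_monte_carlo(sc, ingestion_only_tox(), n_iter = 500, seed = 4)
  expect_equal(d3$CR, 3 * d1$CR, tolerance = 1e-12)
  expect_equal(d3$HQ, 3 * d1$HQ, tolerance = 1e-12)
  sb <- specs
  sb[sb$parameter == "BA", "p1"] <- 0.25
  db <- run_monte_carlo(sb, ingestion_only_tox(), n_iter = 500, seed = 4)
  expect_equal(db$CR, 0.25 * d1$CR, tolerance = 1e-12)
})

test_that("Monte Carlo matches the closed-form lognormal quantile", {
  mu <- log(2); sigma <- 0.5
  specs <- point_specs(make_spec("C", "lognormal", mu, sigma))
  d <- run_monte_carlo(specs, ingestion_only_tox(), n_iter = 10000,
                       seed = 5)
  K <- (1 * 100 * 1e-6 * 350 * 6) / (15 * 2190) * 6.1
  analytic_p95 <- K * exp(mu + qnorm(0.95) * sigma)
  emp_p95 <- quantile(d$CR, 0.95, type = 7, names = FALSE)
  expect_lt(abs(emp_p95 - analytic_p95) / analytic_p95, 0.02)
  # MC mean converges to the product of means (lognormal mean formula)
  analytic_mean <- K * exp(mu + sigma^2 / 2)
  se <- sd(d$CR) / sqrt(nrow(d))
  expect_lt(abs(mean(d$CR) - analytic_mean), 3 * se)
})

test_that("risk summaries report moments, percentiles and exceedances", {
  specs <- point_specs()
  d <- run_monte_carlo(specs, ingestion_only_tox(), n_iter = 200, seed = 6)
  s <- summarize_risk(d)
  expect_equal(s$cv, c(0, 0))           # constant draws
  expect_equal(s$p95, s$mean)
  expect_equal(s$p_exceed[s$index == "HQ"], 0)  # HQ << 1
  # order-statistic check on 1..100 with interpolation percentiles
  d2 <- d[1:100, ]
  d2$HQ <- 1:100; d2$CR <- (1:100) * 1e-9
  s2 <- summarize_risk(d2)
  p95 <- s2$p95[s2$index == "HQ"]
  expect_gte(p95, 95); expect_lte(p95, 96)
  expect_equal(s2$p_exceed[s2$index == "CR"], 0)  # all below 1e-6
  expect_true(all(diff(unlist(s2[1, c("p05", "p25", "p50", "p75", "p95")]))
                  >= 0))
  expect_error(summarize_risk(d[1:10, ]), "100")
})

test_that("bioaccessibility adjustment scales risks with common draws", {
  specs <- point_specs(make_spec("C", "lognormal", log(2), 0.5))
  tox <- ingestion_only_tox()
  # point-mass BA = 0.2: exactly 5x reduction of mean and P95
  cmp <- compare_adjustment(specs, tox, make_spec("BA", "point", 0.2),
                            n_iter = 1000, seed = 7)
  expect_equal(cmp$report$mean_ratio, c(5, 5), tolerance = 1e-12)
  expect_equal(cmp$report$p95_ratio, c(5, 5), tolerance = 1e-12)
  expect_equal(cmp$report$p95_decrease_pct, c(80, 80), tolerance = 1e-12)
  # BA = 1 is the identity
  cmp1 <- compare_adjustment(specs, tox, make_spec("BA", "point", 1),
                             n_iter = 500, seed = 8)
  expect_equal(cmp1$report$mean_ratio, c(1, 1), tolerance = 1e-12)
  # stochastic BA <= 1 never raises a percentile under common numbers
  cmp2 <- compare_adjustment(
    specs, tox, make_spec("BA", "lognormal", log(0.2), 0.4, upper = 1),
    n_iter = 2000, seed = 9)
  for (ix in c("HQ", "CR")) {
    u <- cmp2$unadjusted[[ix]]; a <- cmp2$adjusted[[ix]]
    qs <- seq(0.05, 0.95, by = 0.05)
    expect_true(all(quantile(a, qs) <= quantile(u, qs) + 1e-15))
  }
  expect_error(compare_adjustment(specs, tox,
                                  make_spec("BA", "point", 1.2), 500, 1),
               "support")
  expect_error(compare_adjustment(specs, tox,
                                  make_spec("BA", "lognormal", log(0.2), 0.3),
                                  500, 1),
               "support")
})

test_that("variance contributions normalize squared rank correlations", {
  specs <- point_specs(make_spec("C", "lognormal", 0, 0.5))
  d <- run_monte_carlo(specs, ingestion_only_tox(), n_iter = 500, seed = 10)
  expect_warning(
    sv <- variance_contributions(d[, c("C", "IngR", "BW")], d$CR),
    "constant")
  expect_equal(sv$contribution[sv$parameter == "C"], 100)
  expect_equal(sum(sv$contribution), 100, tolerance = 0.1)
  # two iid additive inputs split the contribution evenly
  set.seed(11)
  x1 <- rnorm(10000); x2 <- rnorm(10000)
  sv2 <- variance_contributions(data.frame(x1 = x1, x2 = x2), x1 + x2)
  expect_equal(sv2$contribution, c(50, 50), tolerance = 3)
  expect_equal(sum(sv2$contribution), 100, tolerance = 0.1)
  # signs follow the direction of the monotone relation
  sv3 <- variance_contributions(data.frame(u = x1, v = -x1 + 0.1 * x2),
                                x1)
  expect_equal(sv3$sign[sv3$parameter == "u"], "+")
  expect_equal(sv3$sign[sv3$parameter == "v"], "-")
  expect_error(variance_contributions(data.frame(x = 1:5), 1:4), "same run")
})

test_that("child exposure profiles yield higher risk than adult ones", {
  c_spec <- make_spec("C", "lognormal", log(0.5), 0.8)
  tox <- default_toxicity_values()
  risks <- lapply(c("adult", "child"), function(pop) {
    specs <- rbind(generate_exposure_distributions(pop), c_spec)
    run_monte_carlo(specs, tox, n_iter = 3000, seed = 12)
  })
  expect_gt(median(risks[[2]]$HQ), median(risks[[1]]$HQ))
  expect_gt(median(risks[[2]]$CR), median(risks[[1]]$CR))
})
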