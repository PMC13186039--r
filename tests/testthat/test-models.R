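test_that("train/test split is disjoint, exhaustive and reproducible", {
  soil <- generate_soil_dataset(126, seed = 1)
  frame <- prepare_model_frame(soil)
  sp <- split_data(frame, 0.2, seed = 2)
  expect_equal(nrow(sp$test), 25)   # round(0.2 * 126)
  expect_equal(nrow(sp$train), 101)
  expect_equal(nrow(sp$train) + nrow(sp$test), 126)
  sp2 <- split_data(frame, 0.2, seed = 2)
  expect_identical(sp, sp2)
  expect_error(split_data(frame, 0), "test_fraction")
  expect_error(split_data(frame, 1), "test_fraction")
  expect_error(split_data(frame[1:5, ], 0.2), "n >= 10")
})

test_that("stepwise regression recovers an exact predictor and prunes", {
  set.seed(3)
  d <- data.frame(x = rnorm(50), z = rnorm(50))
  d$y <- 2 * d$x  # single perfect predictor
  sw <- suppressWarnings(  # lm flags the deliberately perfect fit
    stepwise_fit(d, response = "y", candidates = c("x", "z")))
  expect_identical(sw$selected, "x")
  expect_equal(evaluate_model(sw, d, "y")$r2, 1, tolerance = 1e-12)
  # every retained predictor is significant at alpha_remove
  soil <- generate_soil_dataset(126, default_ground_truth(), seed = 4)
  sw2 <- stepwise_fit(prepare_model_frame(soil))
  expect_true(all(sw2$p_values < 0.05))
  # intercept-only fallback warns
  d$noise <- rnorm(50)
  expect_warning(
    sw3 <- stepwise_fit(data.frame(y = rnorm(50), u = rnorm(50)),
                        response = "y", candidates = "u"),
    "intercept-only")
  expect_length(sw3$selected, 0)
})

test_that("stepwise selection is invariant to candidate ordering", {
  soil <- generate_soil_dataset(126, default_ground_truth(
    interaction_strength = 0), seed = 5)
  frame <- prepare_model_frame(soil)
  a <- stepwise_fit(frame, candidates = c("log_cd", "ph", "som", "clay",
                                          "sand"))
  b <- stepwise_fit(frame, candidates = c("sand", "clay", "som", "ph",
                                          "log_cd"))
  expect_setequal(a$selected, b$selected)
})

test_that("forest grid search carries hyperparameters and honors ties", {
  soil <- generate_soil_dataset(150, seed = 6)
  frame <- prepare_model_frame(soil)
  rf <- rf_grid_fit(frame, seed = 7)
  expect_equal(rf$hyperparameters$n_estimators, 100)
  expect_equal(rf$hyperparameters$max_features, 7)
  expect_equal(rf$hyperparameters$min_samples_leaf, 2)
  expect_equal(rf$hyperparameters$min_samples_split, 6)
  expect_true(is.na(rf$hyperparameters$max_depth))
  expect_true(rf$cv_r2 <= 1)
  rf2 <- rf_grid_fit(frame, seed = 7)
  expect_identical(rf2$hyperparameters, rf$hyperparameters)
  expect_identical(predict(rf2, frame), predict(rf, frame))
  expect_error(rf_grid_fit(frame, k_folds = 1000), "k_folds")
  expect_error(rf_grid_fit(frame, grid = data.frame()), "nonempty")
})

test_that("deep unconstrained trees can memorize a deterministic response", {
  set.seed(8)
  d <- data.frame(x = rnorm(200))
  d$y <- sin(3 * d$x)
  grid <- data.frame(n_estimators = 200, max_features = 1,
                     min_samples_leaf = 1, min_samples_split = 2,
                     max_depth = NA_real_)
  rf <- rf_grid_fit(d, response = "y", predictors = "x", grid = grid,
                    seed = 9)
  expect_gte(evaluate_model(rf, d, "y")$r2, 0.99)
})

test_that("R2 and RMSE match the closed-form definitions", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$r2, 0.5)
  expect_equal(regression_metrics(1:10, 1:10)$r2, 1)
  expect_equal(regression_metrics(1:10, 1:10)$rmse, 0)
  expect_equal(regression_metrics(1:10, rep(mean(1:10), 10))$r2, 0)
})

test_that("impurity importances are normalized and identify the driver", {
  set.seed(10)
  d <- data.frame(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  d$y <- 3 * d$a
  grid <- data.frame(n_estimators = 100, max_features = 3,
                     min_samples_leaf = 2, min_samples_split = 6,
                     max_depth = NA_real_)
  rf <- rf_grid_fit(d, response = "y", predictors = c("a", "b", "c"),
                    grid = grid, seed = 11)
  imp <- feature_importances(rf)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_gt(imp[["a"]], 0.9)
  expect_error(feature_importances(list()), "invalid-state")
})

test_that("back-transformed bioaccessibility lies in (0, 100]", {
  # model predicting exactly ln(0.5 * cd_total) -> 50% everywhere
  d <- data.frame(log_cd = log(c(0.1, 1, 5, 20, 100, 0.4, 3, 9, 55, 2)))
  d$log_ba_ip <- log(0.5) + d$log_cd
  sw <- suppressWarnings(stepwise_fit(d, candidates = "log_cd"))
  pb <- predict_bioaccessibility(sw, data.frame(cd_total = c(0.2, 7, 300)))
  expect_equal(pb$ba_percent, rep(50, 3), tolerance = 1e-8)
  # cap at the physical bound
  d2 <- d; d2$log_ba_ip <- d2$log_cd  # content == cd_total
  sw2 <- suppressWarnings(stepwise_fit(d2, candidates = "log_cd"))
  pb2 <- predict_bioaccessibility(sw2, data.frame(cd_total = 4))
  expect_equal(pb2$ba_percent, 100, tolerance = 1e-8)
  expect_error(predict_bioaccessibility(sw, data.frame(cd_total = -1)),
               "cd_total")
  # round trip through log scale is lossless
  x <- c(1e-6, 0.3, 42, 1e5)
  expect_equal(exp(log(x)), x, tolerance = 1e-12)
})

test_that("national synthetic predictions stay within percent bounds", {
  soil <- generate_soil_dataset(200, seed = 12)
  frame <- prepare_model_frame(soil)
  rf <- rf_grid_fit(frame, seed = 13)
  pb <- predict_bioaccessibility(rf, frame)
  expect_true(all(pb$ba_percent > 0 & pb$ba_percent <= 100))
  mm <- model_metrics(rf, frame, frame)
  expect_equal(mm$delta_r2, 0)
})
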