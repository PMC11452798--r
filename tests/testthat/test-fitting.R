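test_that("fit grid defaults match the estimation procedure", {
  g <- fit_grid()
  expect_length(g$c_values, 101)
  expect_equal(g$c_values[2] - g$c_values[1], 0.01)
  expect_equal(range(g$T_values), c(10, 1000))
  expect_length(g$T_values, 100)
  expect_equal(g$delta_values, c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.99))
  expect_error(fit_grid(c_values = numeric(0)), "nonempty")
})

test_that("setting-I predictions ignore c and c = 0 collapses to the direct model", {
  laps <- study_laps()
  u0 <- as.numeric(initialize_session(study_net(), 4, seed = 3))
  p1 <- predict_curve(laps, NULL, 0, 0.7, 60, 15, u0)
  p2 <- predict_curve(laps, NULL, 0.9, 0.7, 60, 15, u0)
  expect_identical(p1, p2)
  p3 <- predict_curve(laps, 2, 0, 0.7, 60, 15, u0)
  expect_equal(p3$proportion, p1$proportion)
  expect_true(all(diff(p3$proportion) >= 0))
})

test_that("grid search recovers in-grid generating parameters with zero error", {
  laps <- study_laps()
  u0 <- as.numeric(initialize_session(study_net(), 4, seed = 3))
  obs <- predict_curve(laps, 2, 0.37, 0.6, 60, 15, u0)
  fit <- suppressMessages(grid_search(obs, laps, 2, u0))
  expect_identical(fit$mse, 0)
  expect_identical(fit$predicted, obs$proportion)
  expect_s3_class(fit, "innovation_fit")
  g <- glance(fit)
  expect_true(g$c %in% fit_grid()$c_values)
  expect_true(g$T %in% fit_grid()$T_values)
  expect_true(g$delta %in% fit_grid()$delta_values)
})

test_that("a setting-I curve refit with a free coefficient lands on c = 0 by tie-break", {
  laps <- study_laps()
  u0 <- as.numeric(initialize_session(study_net(), 4, seed = 4))
  obs <- predict_curve(laps, NULL, 0, 0.7, 60, 15, u0)
  fit <- suppressMessages(grid_search(obs, laps, 2, u0))
  expect_identical(fit$mse, 0)
  expect_equal(fit$c, 0)
})

test_that("grid search is exhaustive: no random grid point beats the optimum", {
  laps <- study_laps()
  net <- study_net()
  u0 <- as.numeric(initialize_session(net, 4, seed = 6))
  rec <- simulate_setting(net, "II", initialize_session(net, 4, seed = 6), seed = 6)
  obs <- observed_curve(rec, pad_to = 15)$proportion
  fit <- suppressMessages(grid_search(obs, laps, 2, u0))
  grid <- fit_grid()
  set.seed(31)
  for (i in 1:100) {
    cand <- predict_curve(
      laps, 2, sample(grid$c_values, 1), sample(grid$delta_values, 1),
      sample(grid$T_values, 1), length(obs), u0
    )
    expect_gte(mean((cand$proportion - obs)^2), fit$mse)
  }
})

test_that("broom methods expose the fitted triplet and per-round curves", {
  laps <- study_laps()
  u0 <- as.numeric(initialize_session(study_net(), 4, seed = 3))
  obs <- predict_curve(laps, 2, 0.5, 0.7, 60, 15, u0)
  fit <- suppressMessages(grid_search(obs, laps, 2, u0))
  td <- tidy(fit)
  expect_equal(td$term, c("c_2", "delta", "T"))
  aug <- augment(fit)
  expect_equal(nrow(aug), 15)
  expect_equal(aug$observed - aug$predicted, aug$residual)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("constant observed curves fit by MSE with missing Pearson", {
  laps <- study_laps()
  u0 <- as.numeric(initialize_session(study_net(), 4, seed = 3))
  fit <- suppressMessages(suppressWarnings(
    grid_search(rep(4 / 31, 15), laps, 2, u0)
  ))
  expect_true(is.na(fit$pearson))
  expect_gte(fit$mse, 0)
})

test_that("fit_sessions fits every session-setting with the right free coefficient", {
  net <- study_net()
  laps <- study_laps()
  rec <- simulate_session(net, seed = 21, settings = c("I", "II"))
  fits <- suppressMessages(fit_sessions(rec, laps, pad_to = 15))
  expect_equal(nrow(fits), 2)
  expect_true(is.na(fits$d[fits$setting == "I"]))
  expect_true(is.na(fits$c[fits$setting == "I"]))
  expect_equal(fits$d[fits$setting == "II"], 2)
  expect_true(all(fits$mse >= 0))
  expect_true(all(fits$pearson >= -1 & fits$pearson <= 1, na.rm = TRUE))
})

test_that("joint multi-coefficient search reproduces a two-term generating model", {
  laps <- study_laps()
  u0 <- as.numeric(initialize_session(study_net(), 4, seed = 8))
  M <- build_generator(laps, c(`2` = 0.6, `3` = 0.2))
  st <- evolve(M, u0, discretize_rounds(60, 15))
  obs <- adopter_curve(st, u0, 0.6)$proportion
  fit <- grid_search_joint(obs, laps, ds = c(2, 3), u0,
                           c_values = seq(0, 1, by = 0.2),
                           T_values = seq(20, 100, by = 20),
                           delta_values = c(0.6, 0.8))
  expect_lt(fit$mse, 1e-3)
})

test_that("mean fitted c2 responds monotonically to the generator's distant influence", {
  net <- study_net()
  laps <- study_laps()
  fitted_c2 <- function(beta, s) {
    init <- initialize_session(net, 4, seed = s)
    rec <- simulate_setting(net, "II", init, seed = s + 1000,
                            behavior = behavior_spec(beta = beta))
    obs <- observed_curve(rec, pad_to = 15)
    u0 <- as.integer(init[order(as.integer(names(init)))])
    suppressMessages(glance(grid_search(obs$proportion, laps, 2, u0))$c)
  }
  means <- vapply(c(0, 1.5, 4), function(beta) {
    mean(vapply(1:30, function(s) fitted_c2(beta, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})
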