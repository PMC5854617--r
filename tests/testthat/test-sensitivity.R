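# Hand-built networks with known structure drive most of these checks.

test_that("connection-weight contributions are exact hand products", {
  # 2 inputs, 1 hidden: input weights (2, -1), output weight 3
  w <- cascadeSDM:::network_weights(matrix(c(2, -1, 0), 3, 1), c(3, 0))
  ol <- olden_weights(w)
  expect_equal(ol$contribution, c(6, -3))
  expect_equal(ol$rank, c(1L, 2L))

  # zero hidden-to-output weights null every contribution
  w0 <- cascadeSDM:::network_weights(matrix(runif(6), 3, 2), c(0, 0, 4))
  expect_equal(olden_weights(w0)$contribution, c(0, 0))

  # cancelling paths: w_i1 v_1 = -w_i2 v_2
  wc <- cascadeSDM:::network_weights(
    matrix(c(1, 0.5, 0, 2, 1, 0), 3, 2), c(2, -1, 0))
  expect_equal(olden_weights(wc)$contribution, c(0, 0))
})

test_that("connection-weight importance is linear in the output weights", {
  set.seed(6)
  w1 <- matrix(runif(12, -1, 1), 4, 3)
  va <- runif(4, -1, 1)
  vb <- runif(4, -1, 1)
  net <- function(v) cascadeSDM:::network_weights(w1, v)
  expect_equal(olden_weights(net(va + vb))$contribution,
               olden_weights(net(va))$contribution +
                 olden_weights(net(vb))$contribution)
})

test_that("Lek profiles sweep one variable and expose inert inputs", {
  data <- normalize_environment(toy_survey())
  # input 'shade' has zero outgoing weights -> five flat curves
  w <- cascadeSDM:::network_weights(
    matrix(c(3, 0, 0.5, 2, 0, -0.25), 3, 2), c(1.5, -1, 0.2))
  ms <- cascadeSDM:::model_spec("spA", data$env_names, character(0),
                                "observed", w, 0.5, NULL, train_config())
  prof <- lek_profile(ms, data, sensitivity_config(profile_scale = 20))
  expect_setequal(unique(prof$variable), c("depth", "shade"))
  expect_setequal(unique(prof$level),
                  c("min", "Q1", "median", "Q3", "max"))
  shade <- prof[prof$variable == "shade", ]
  for (lev in unique(shade$level)) {
    expect_equal(diff(range(shade$response[shade$level == lev])), 0)
  }
  # all-positive weights: every profile curve is non-decreasing
  wp <- cascadeSDM:::network_weights(
    matrix(abs(rnorm(6)), 3, 2), abs(rnorm(3)))
  msp <- cascadeSDM:::model_spec("spA", data$env_names, character(0),
                                 "observed", wp, 0.5, NULL, train_config())
  pp <- lek_profile(msp, data, sensitivity_config(profile_scale = 25))
  for (v in unique(pp$variable)) {
    for (lev in unique(pp$level)) {
      cur <- pp$response[pp$variable == v & pp$level == lev]
      expect_true(all(diff(cur) >= -1e-12))
    }
  }
})

test_that("single-input profiles equal the network's 1-D response", {
  occ <- matrix(rep(c(1, 0), 5), ncol = 1, dimnames = list(NULL, "sp"))
  env <- matrix(seq(0, 1, length.out = 10), ncol = 1,
                dimnames = list(NULL, "e1"))
  data <- survey_dataset(occ, env, normalized = TRUE)
  w <- init_network(1, 3, init_range = 1, seed = 2)
  ms <- cascadeSDM:::model_spec("sp", "e1", character(0), "observed", w,
                                0.5, NULL, train_config())
  prof <- lek_profile(ms, data, sensitivity_config(profile_scale = 50))
  one_level <- prof[prof$level == "median", ]
  expect_equal(nrow(one_level), 50)
  expect_equal(one_level$response, nn_forward(w, matrix(one_level$x)))
})

test_that("fixed-grid profile levels are the five grid values", {
  data <- normalize_environment(toy_survey())
  w <- init_network(2, 2, init_range = 0.5, seed = 3)
  ms <- cascadeSDM:::model_spec("spA", data$env_names, character(0),
                                "observed", w, 0.5, NULL, train_config())
  prof <- lek_profile(ms, data,
                      sensitivity_config(profile_scale = 10,
                                         profile_levels = "fixed_grid"))
  expect_setequal(unique(prof$level),
                  c("0.00", "0.25", "0.50", "0.75", "1.00"))
})

test_that("perturbation importance isolates influential inputs", {
  data <- normalize_environment(toy_survey())
  # input 'depth' dominates the output; 'shade' has zero outgoing weights
  w <- cascadeSDM:::network_weights(
    matrix(c(4, 0, 0, 1, 0, 0), 3, 2), c(2, 1, -1))
  ms <- cascadeSDM:::model_spec("spA", data$env_names, character(0),
                                "observed", w, 0.5, NULL, train_config())
  cfg <- sensitivity_config(noise_reps = 50, seed = 5)
  # against observations: an inert input changes nothing, exactly
  imp_obs <- perturbation_importance(ms, data, cfg)
  expect_equal(imp_obs$mse_increase_pct[imp_obs$variable == "shade"], 0)
  # against unperturbed predictions: output-difference dominance
  imp <- perturbation_importance(ms, data, cfg, against = "predictions")
  expect_equal(imp$mse_increase_pct[imp$variable == "shade"], 0)
  expect_gt(imp$mse_increase_pct[imp$variable == "depth"], 0)
  expect_equal(imp$rank[imp$variable == "depth"], 1L)

  none <- perturbation_importance(ms, data,
                                  sensitivity_config(noise_range = 0,
                                                     noise_reps = 3))
  expect_equal(none$mse_increase_pct, c(0, 0))

  expect_error(perturbation_importance(ms, data,
                                       sensitivity_config(noise_reps = 0)),
               "noise_reps")
})

test_that("cascade importance treats sub-model probabilities as inputs", {
  data <- normalize_environment(hidden_factor_survey(n = 150, seed = 23))
  cfg <- quick_config()
  sub <- list(good = train_submodel(data, "good", config = cfg, seed = 81))
  casc <- assemble_cascade(data, "tgt", "good", sub, config = cfg,
                           seed = 82, cv = FALSE)
  ol <- olden_weights(casc)
  expect_true("good" %in% ol$variable)
  prof <- lek_profile(casc, data, sensitivity_config(profile_scale = 5))
  expect_true("good" %in% unique(prof$variable))
  imp <- perturbation_importance(casc, data,
                                 sensitivity_config(noise_reps = 5))
  expect_equal(nrow(imp), length(data$env_names) + 1)
})
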