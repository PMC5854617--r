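test_that("baseline model learns an environment-driven species", {
  data <- normalize_environment(env_driven_survey(n = 200))
  base <- train_baseline(data, "tgt", config = quick_config(), seed = 3)
  expect_s3_class(base, "model_spec")
  expect_gt(base$cv$median_k, 0.2)
  expect_length(attr(base, "baseline_ci"), 2)

  raw <- env_driven_survey(n = 100)
  expect_error(train_baseline(raw, "tgt", config = quick_config()),
               "normalized")
})

test_that("baseline kappa is near zero for an environment-independent species", {
  data <- normalize_environment(env_driven_survey(n = 200))
  # leakage-free cutoff mode: choosing the cutoff on the held-out fold
  # (the reproduction default) inflates null-model kappa noticeably
  base <- train_baseline(data, "indep", config = quick_config(), seed = 3,
                         cutoff_mode = "train")
  expect_lt(abs(base$cv$median_k), 0.25)
})

test_that("screening selects informative co-predictors and rejects noise", {
  data <- normalize_environment(hidden_factor_survey(n = 250, seed = 11))
  cfg <- quick_config()
  base <- train_baseline(data, "tgt", config = cfg, seed = 21)
  scr <- screen_copredictors(data, "tgt", base,
                             candidates = c("good", "junk"),
                             config = cfg, seed = 21)
  cand <- scr$candidates
  expect_setequal(cand$species, c("good", "junk"))
  expect_gt(cand$median_kappa[cand$species == "good"],
            cand$median_kappa[cand$species == "junk"])
  expect_true(cand$selected[cand$species == "good"])
  expect_false(cand$selected[cand$species == "junk"])
  # selection flag is exactly the CI-exceedance rule
  expect_identical(cand$selected,
                   cand$median_kappa > scr$baseline$ci_high)
  expect_gt(cand$r[cand$species == "good"], 0.5)

  empty <- screen_copredictors(data, "tgt", base,
                               candidates = character(0), config = cfg)
  expect_equal(nrow(empty$candidates), 0)
  expect_equal(empty$baseline$k, scr$baseline$k)

  expect_error(screen_copredictors(data, "tgt", base,
                                   candidates = c("tgt", "good"),
                                   config = cfg),
               "must not include the target")
})

test_that("sub-models are reproducible and validate the species name", {
  data <- normalize_environment(env_driven_survey(n = 150))
  s1 <- train_submodel(data, "tgt", config = quick_config(), seed = 4)
  s2 <- train_submodel(data, "tgt", config = quick_config(), seed = 4)
  expect_identical(s1$weights, s2$weights)
  expect_identical(s1$cutoff, s2$cutoff)
  expect_error(train_submodel(data, "ghost", config = quick_config()),
               "unknown target species")
})

test_that("cascade assembly wires sub-models into the target network", {
  data <- normalize_environment(hidden_factor_survey(n = 250, seed = 13))
  cfg <- quick_config()
  subs <- list(
    good = train_submodel(data, "good", config = cfg, seed = 31),
    junk = train_submodel(data, "junk", config = cfg, seed = 32))

  casc <- assemble_cascade(data, "tgt", c("good", "junk"), subs,
                           config = cfg, seed = 33, cv = FALSE)
  expect_equal(casc$target_model$weights$n_inputs,
               length(data$env_names) + 2)
  expect_equal(casc$target_model$input_mode, "predicted_probability")

  # empty selection degenerates to the environment-only model
  degen <- assemble_cascade(data, "tgt", character(0), list(),
                            config = cfg, seed = 33, cv = FALSE)
  expect_length(degen$sub_models, 0)
  expect_equal(degen$target_model$weights$n_inputs,
               length(data$env_names))

  expect_error(assemble_cascade(data, "tgt", c("good", "junk"),
                                subs["good"], config = cfg, cv = FALSE),
               "missing sub-model")
  expect_error(assemble_cascade(data, "tgt", "good", subs,
                                config = cfg, cv = FALSE),
               "non-selected")
})

test_that("cascade predictions consume environmental columns only", {
  data <- normalize_environment(hidden_factor_survey(n = 250, seed = 17))
  cfg <- quick_config()
  subs <- list(good = train_submodel(data, "good", config = cfg, seed = 41))
  casc <- assemble_cascade(data, "tgt", "good", subs, config = cfg,
                           seed = 42, cv = FALSE)

  full <- predict_cascade(casc, data)
  # delete every species column: predictions must be bitwise identical
  stripped <- survey_dataset(
    occurrence = data$occurrence[, character(0), drop = FALSE],
    environment = data$environment,
    site_ids = data$site_ids, normalized = TRUE)
  expect_identical(predict_cascade(casc, stripped), full)

  # column order is irrelevant: inputs are matched by name
  perm <- data$environment[, rev(data$env_names), drop = FALSE]
  expect_identical(predict_cascade(casc, perm), full)

  one <- predict_cascade(casc, data$environment[1, , drop = FALSE])
  expect_equal(nrow(one), 1)
  expect_true(one$probability > 0 && one$probability < 1)
  expect_true(all(c("good_probability", "good_prediction") %in%
                    names(one)))

  expect_error(
    predict_cascade(casc, data$environment[, -1, drop = FALSE]),
    data$env_names[1])
})

test_that("retrain and reuse compositions coincide for a perfect sub-model", {
  # co-predictor occurrence is a deterministic threshold of one variable,
  # so its sub-model binarizes to exactly the observed occurrence and the
  # retrained network sees the same inputs as the screening-stage network
  n <- 150
  set.seed(55)
  env <- matrix(runif(n * 3), n, 3,
                dimnames = list(NULL, c("e1", "e2", "e3")))
  # keep a margin around the threshold so the sub-model separates exactly
  env[, "e1"] <- ifelse(env[, "e1"] > 0.5, 0.6 + 0.4 * (env[, "e1"] - 0.5) / 0.5,
                        0.4 * env[, "e1"] / 0.5)
  cop <- as.integer(env[, "e1"] > 0.5)
  tgt <- rbinom(n, 1, plogis(3 * (cop - 0.5) + env[, "e2"] - 0.5))
  data <- survey_dataset(cbind(tgt = tgt, cop = cop), env,
                         normalized = TRUE)
  cfg <- quick_config()
  sub <- train_submodel(data, "cop", config = cfg, seed = 61)
  sub_bin <- binarize(nn_forward(sub$weights, data$environment),
                      sub$cutoff)
  expect_identical(sub_bin, as.integer(data$occurrence[, "cop"]))

  seed <- 62
  casc <- assemble_cascade(data, "tgt", "cop", list(cop = sub),
                           config = cfg, seed = seed, composition = "retrain",
                           oof = FALSE, binarize_inputs = TRUE, cv = FALSE)
  step2 <- cascadeSDM:::fit_final_model(
    data, "tgt", "cop", cfg, seed = cascadeSDM:::derive_seed(seed, 0))
  reuse <- assemble_cascade(data, "tgt", "cop", list(cop = sub),
                            config = cfg, seed = seed,
                            composition = "reuse", oof = FALSE,
                            binarize_inputs = TRUE, step2_model = step2,
                            cv = FALSE)
  expect_identical(predict_cascade(casc, data)$probability,
                   predict_cascade(reuse, data)$probability)
})

test_that("cascade bundles survive a JSON round trip", {
  data <- normalize_environment(env_driven_survey(n = 120))
  cfg <- quick_config()
  sub <- list(indep = train_submodel(data, "indep", config = cfg,
                                     seed = 71))
  casc <- assemble_cascade(data, "tgt", "indep", sub, config = cfg,
                           seed = 72, cv = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  save_cascade(casc, path)
  back <- load_cascade(path)
  expect_identical(predict_cascade(back, data), predict_cascade(casc, data))
})
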