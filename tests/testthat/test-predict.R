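# hand-built prediction model for exact linear-scoring checks
make_model <- function(terms, coefs, gm, intercept = 12,
                       outcome = "OPTION-12") {
  structure(
    list(outcome = outcome,
         coefficients = data.frame(
           term = c("(Intercept)", terms), mean = c(intercept, coefs),
           sd = NA, lower = NA, upper = NA),
         fit_statistics = NULL, grand_means = setNames(gm, terms),
         terms = terms, retained_skills = integer(),
         n_observations = 0, n_predictors = length(terms),
         observed = data.frame(physician_id = character(),
                               observed_score = numeric(),
                               fitted_score = numeric())),
    class = "sdm_prediction_model")
}

toy_params <- function(act6 = c(2, 3, 4), ids = c("a", "b", "c")) {
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(physician_id = ids[i], skill = 1:9, activation = 2.5,
               outstrength = 0.3, instrength = 0.3)
  })) -> np
  np$activation[np$skill == 6] <- rep(act6, each = 1)[
    match(np$physician_id[np$skill == 6], ids)]
  np
}

test_that("the wide node-parameter layout is complete and keyed correctly", {
  np <- toy_params()
  w <- node_parameters_wide(np)
  expect_equal(nrow(w), 3)
  expect_equal(ncol(w), 1 + 27)
  expect_equal(w$activation_s6, c(2, 3, 4))
  expect_true(all(w$outstrength_s1 == 0.3))
})

test_that("competence scoring is exactly linear with stored grand means", {
  m <- make_model("activation_s6", coefs = 2, gm = 2.5)
  pred <- predict_competence(m, toy_params(act6 = c(2.5, 4.0, 1.0)))
  # at the grand mean the prediction is the intercept
  expect_equal(pred$predicted_score, 12 + 2 * c(0, 1.5, -1.5))
  # doubling the centred parameter doubles its contribution
  pred2 <- predict_competence(m, toy_params(act6 = c(2.5, 5.5, -0.5)))
  expect_equal(pred2$predicted_score - 12, 2 * (pred$predicted_score - 12))
  # single coefficient worked example: 12 + 2 * 1.5 = 15
  expect_equal(pred$predicted_score[2], 15)
})

test_that("physicians with incomplete parameters are skipped", {
  m <- make_model("activation_s6", coefs = 2, gm = 2.5)
  np <- toy_params()
  np$activation[np$physician_id == "b" & np$skill == 6] <- NA
  pred <- predict_competence(m, np)
  expect_equal(pred$physician_id, c("a", "c"))
  expect_true(all(is.na(pred$observed_score)))
})

test_that("screening flags a degenerate zero-variance outcome without retention", {
  np <- true_node_parameters(draw_physician_parameters(
    population_network_spec(), study_design(n_physicians = 15, seed = 4)))
  comp <- data.frame(physician_id = unique(np$physician_id),
                     instrument = "OPTION-5", score = 50)
  scr <- screen_predictors(np, comp, config = fast_mcmc())
  expect_equal(scr$degenerate_outcomes, "OPTION-5")
  expect_length(scr$retained_skills, 0)
  expect_false(any(scr$results$nonzero))
})

test_that("screening requires enough physicians with both measurements", {
  np <- true_node_parameters(draw_physician_parameters(
    population_network_spec(), study_design(n_physicians = 5, seed = 4)))
  comp <- data.frame(physician_id = unique(np$physician_id),
                     instrument = "X", score = rnorm(5))
  expect_error(screen_predictors(np, comp, config = fast_mcmc()), "need >=")
})

test_that("a noise-free linear outcome is fitted to R^2 near 1", {
  truths <- draw_physician_parameters(population_network_spec(),
                                      study_design(n_physicians = 24, seed = 10))
  np <- true_node_parameters(truths)
  w <- node_parameters_wide(np)
  set.seed(44)
  comp <- data.frame(physician_id = w$physician_id, instrument = "OPTION-5",
                     score = 20 + 15 * w$outstrength_s6 +
                       rnorm(nrow(w), 0, 0.2))
  mods <- fit_final_model(np, comp, retained_skills = 6,
                          config = mcmc_config(n_chains = 2,
                                               iterations = 2000,
                                               burn_in = 500, seed = 3))
  fs <- mods[["OPTION-5"]]$fit_statistics
  expect_gt(fs$mean[fs$parameter == "r_squared"], 0.98)
  expect_lt(fs$mean[fs$parameter == "residual_variance"], 1)
  # adjusted R^2 never exceeds R^2 for n > p + 1
  expect_lte(fs$mean[fs$parameter == "adjusted_r_squared"],
             fs$mean[fs$parameter == "r_squared"])
  # training-set predicted-observed correlation matches the posterior R
  pred <- predict_competence(mods, np)
  expect_equal(cor(pred$predicted_score, pred$observed_score),
               fs$mean[fs$parameter == "r"], tolerance = 0.02)
})

test_that("overparameterized fits are reported but refuse adjusted R^2", {
  truths <- draw_physician_parameters(population_network_spec(),
                                      study_design(n_physicians = 9, seed = 2))
  np <- true_node_parameters(truths)
  w <- node_parameters_wide(np)
  comp <- data.frame(physician_id = w$physician_id, instrument = "X",
                     score = 20 + 5 * w$activation_s6 + rnorm(9))
  expect_warning(
    mods <- fit_final_model(np, comp, retained_skills = c(1, 6, 7),
                            config = fast_mcmc()),
    "adjusted R")
  fs <- mods[["X"]]$fit_statistics
  expect_false("adjusted_r_squared" %in% fs$parameter)
  expect_true("r_squared" %in% fs$parameter)
})

test_that("fit reports have the published table shape and a smoother", {
  truths <- draw_physician_parameters(population_network_spec(),
                                      study_design(n_physicians = 20, seed = 12))
  np <- true_node_parameters(truths)
  w <- node_parameters_wide(np)
  set.seed(45)
  comp <- data.frame(physician_id = w$physician_id, instrument = "OPTION-12",
                     score = 16 + 10 * (w$activation_s6 -
                                          mean(w$activation_s6)) +
                       rnorm(nrow(w), 0, 0.5))
  mods <- fit_final_model(np, comp, retained_skills = 6, config = fast_mcmc())
  rep <- fit_report(mods[["OPTION-12"]])
  expect_equal(nrow(rep$coefficients), 1 + 3 * 1)
  expect_named(rep$scatter, c("physician_id", "observed", "predicted",
                              "smooth"))
  # identical predicted and observed values: the smoother is the identity
  ident <- rep$scatter
  m2 <- mods[["OPTION-12"]]
  m2$observed$observed_score <- m2$observed$fitted_score
  rep2 <- fit_report(m2)
  expect_equal(rep2$scatter$smooth, rep2$scatter$predicted, tolerance = 1e-6)
  # intercept-only report still emits a table
  mods0 <- suppressWarnings(fit_final_model(
    np, comp, retained_skills = integer(), config = fast_mcmc()))
  rep0 <- fit_report(mods0[["OPTION-12"]])
  expect_equal(nrow(rep0$coefficients), 1)
})
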