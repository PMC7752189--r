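test_that("zero-variance populations yield the population parameters exactly", {
  spec <- homogeneous_spec()
  truths <- draw_physician_parameters(spec, study_design(n_physicians = 5,
                                                         seed = 3))
  for (tr in truths) {
    expect_equal(tr$intercepts_p, spec$intercept_means)
    expect_equal(tr$edges_p, spec$fixed_edges)
  }
  # and the whole table is identical whatever the seed
  d1 <- simulate_patient_ratings(truths, homogeneous_spec(residual_sd = 1e-9),
                                 study_design(n_physicians = 5, seed = 1))
  d2 <- simulate_patient_ratings(truths, homogeneous_spec(residual_sd = 1e-9),
                                 study_design(n_physicians = 5, seed = 999))
  expect_identical(d1, d2)
})

test_that("physician draws are reproducible under the design seed", {
  spec <- population_network_spec()
  des <- study_design(n_physicians = 30, seed = 11)
  t1 <- draw_physician_parameters(spec, des)
  t2 <- draw_physician_parameters(spec, des)
  expect_identical(t1, t2)
  t3 <- draw_physician_parameters(spec, study_design(n_physicians = 30,
                                                     seed = 12))
  expect_false(identical(t1, t3))
})

test_that("edge deviations follow the stated sampling distribution", {
  # Monte-Carlo check: across-physician SD of an edge ~ random_sd_slope
  spec <- population_network_spec(random_sd_slope = 0.06)
  truths <- draw_physician_parameters(
    spec, study_design(n_physicians = 500, seed = 17))
  e67 <- vapply(truths, function(tr) tr$edges_p[6, 7], numeric(1))
  e31 <- vapply(truths, function(tr) tr$edges_p[3, 1], numeric(1))
  expect_equal(sd(e67), 0.06, tolerance = 0.10)
  expect_equal(sd(e31), 0.06, tolerance = 0.10)
  expect_equal(mean(e67), spec$fixed_edges[6, 7], tolerance = 0.1)
})

test_that("an unstable population spec is rejected with a clear error", {
  B <- matrix(0.9, 9, 9); diag(B) <- 0 # spectral radius ~ 7
  spec <- population_network_spec(fixed_edges = B, random_sd_slope = 0)
  expect_error(
    draw_physician_parameters(spec, study_design(n_physicians = 1, seed = 1)),
    "unstable")
})

test_that("noise-free fixed point of the rating generator is the documented round", {
  # B = 0, alpha = 2.5: latent items are exactly 2.5, which rounds to 3
  # under round-half-away-from-zero
  spec <- population_network_spec(
    fixed_edges = matrix(0, 9, 9),
    intercept_means = rep(2.5, 9),
    random_sd_intercept = 0, random_sd_slope = 0, residual_sd = 0)
  truths <- draw_physician_parameters(spec, study_design(n_physicians = 2,
                                                         seed = 1))
  tab <- simulate_patient_ratings(truths, spec,
                                  study_design(n_physicians = 2, seed = 1))
  expect_true(all(as.matrix(tab[sdmnet:::item_cols(9)]) == 3L))
})

test_that("latent moments match the structural model closed forms", {
  # B = 0: latent covariance is diagonal with entries residual_sd^2
  spec <- population_network_spec(
    fixed_edges = matrix(0, 9, 9), intercept_means = rep(2.5, 9),
    random_sd_intercept = 0, random_sd_slope = 0, residual_sd = 0.8)
  truths <- draw_physician_parameters(spec, study_design(1, seed = 2))
  lat <- simulate_patient_ratings(
    truths, spec, study_design(1, patients_per_physician = 10000, seed = 2),
    discretize = FALSE)
  S <- cov(as.matrix(lat[sdmnet:::item_cols(9)]))
  expect_equal(unname(diag(S)), rep(0.64, 9), tolerance = 0.05)
  expect_lt(max(abs(S[upper.tri(S)])), 0.03)

  # single edge 1 -> 2 of weight 0.5: OLS of latent item 2 on item 1
  # recovers the structural coefficient
  B <- matrix(0, 9, 9); B[1, 2] <- 0.5
  spec2 <- population_network_spec(
    fixed_edges = B, intercept_means = rep(2.5, 9),
    random_sd_intercept = 0, random_sd_slope = 0, residual_sd = 0.8)
  truths2 <- draw_physician_parameters(spec2, study_design(1, seed = 4))
  lat2 <- simulate_patient_ratings(
    truths2, spec2, study_design(1, patients_per_physician = 10000, seed = 4),
    discretize = FALSE)
  b <- coef(lm(item_2 ~ item_1, data = lat2))[["item_1"]]
  expect_equal(b, 0.5, tolerance = 0.05)
})

test_that("generated scores are integers within the declared ranges", {
  sim <- simulate_study(design = study_design(n_physicians = 8, seed = 5))
  pr <- as.matrix(sim$patient_ratings[sdmnet:::item_cols(9)])
  expect_true(all(pr == floor(pr)))
  expect_true(all(pr >= 0 & pr <= 5))
  for (inst in sim$instruments) {
    sub <- sim$observer_ratings[sim$observer_ratings$instrument == inst$name,
                                sdmnet:::item_cols(inst$n_items)]
    m <- as.matrix(sub)
    expect_true(all(m >= inst$item_min & m <= inst$item_max))
  }
})

test_that("degenerate observer noise makes raters agree exactly", {
  truths <- constant_competence_truths(4)
  des <- study_design(n_physicians = 4, seed = 9)
  tab <- simulate_observer_ratings(truths, observer_noise_spec(1e-12, 0, 0, 0),
                                   des, instruments = calibration_instrument())
  # zero rater/consultation/residual variance: both raters identical per
  # consultation
  sc <- physician_competence(tab, instruments = calibration_instrument())
  wide <- split(tab, tab$rater_id)
  expect_equal(unname(as.matrix(wide$r1[sdmnet:::item_cols(4)])),
               unname(as.matrix(wide$r2[sdmnet:::item_cols(4)])))
  expect_true(all(abs(sc$score - 50) < 1)) # location of competence 50
})

test_that("true node parameters follow the definitions and balance", {
  # B = 0: strengths vanish, activation equals the intercepts
  tr0 <- make_truth(alpha = 1:9 / 2, B = matrix(0, 9, 9))
  np0 <- true_node_parameters(list(tr0))
  expect_equal(np0$activation, 1:9 / 2)
  expect_true(all(np0$outstrength == 0) && all(np0$instrength == 0))

  # single edge 1 -> 2 weight 0.4
  B <- matrix(0, 9, 9); B[1, 2] <- 0.4
  np1 <- true_node_parameters(list(make_truth(B = B)))
  expect_equal(np1$outstrength, c(0.4, rep(0, 8)))
  expect_equal(np1$instrength, c(0, 0.4, rep(0, 7)))

  # random networks: total outstrength equals total instrength
  set.seed(31)
  for (i in 1:20) {
    B <- matrix(rnorm(81, 0, 0.1), 9, 9); diag(B) <- 0
    np <- true_node_parameters(list(make_truth(B = B)))
    expect_equal(sum(np$outstrength), sum(np$instrength), tolerance = 1e-12)
  }
})

test_that("observer noise calibration solves its targets", {
  ns <- calibrate_observer_noise(icc = 0.4, irr = 0.72, total_var = 90,
                                 n_consultations = 3, n_raters = 2)
  expect_equal(ns$icc, 0.4, tolerance = 1e-12)
  vp <- ns$var_physician
  irr <- vp / (vp + ns$var_consultation / 3 +
                 (ns$var_rater + ns$var_residual) / 6)
  expect_equal(irr, 0.72, tolerance = 1e-12)
  expect_error(calibrate_observer_noise(icc = 0.4, irr = 0.99),
               "not attainable")
})
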