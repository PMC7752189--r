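test_that("grand-mean centring zeroes every column mean and keeps the means", {
  tab <- data.frame(physician_id = "p", patient_id = letters[1:2],
                    item_1 = c(3L, 3L), item_2 = c(1L, 5L))
  cp <- center_predictors(tab)
  expect_equal(cp$grand_means, c(item_1 = 3, item_2 = 3))
  expect_equal(cp$table$item_1, c(0, 0))
  expect_equal(cp$table$item_2, c(-2, 2))
  sim <- simulate_study(design = study_design(n_physicians = 5, seed = 2))
  cc <- center_predictors(sim$patient_ratings)
  expect_true(all(abs(colMeans(as.matrix(
    cc$table[sdmnet:::item_cols(9)]))) < 1e-12))
  expect_error(center_predictors(data.frame(x = 1)), "item")
})

test_that("DIC selection applies the three-point relevance rule", {
  sel <- compare_models(fake_fit(100), fake_fit(96, random = TRUE))
  expect_equal(sel$choice, "random")
  expect_equal(sel$dic_difference, 4)
  sel2 <- compare_models(fake_fit(100), fake_fit(98.5, random = TRUE))
  expect_equal(sel2$choice, "fixed")
  # exactly at the margin the random model is selected
  sel3 <- compare_models(fake_fit(100), fake_fit(97, random = TRUE))
  expect_equal(sel3$choice, "random")
  expect_error(compare_models(fake_fit(100, outcome = 1),
                              fake_fit(97, outcome = 2)))
})

test_that("purging masks by the credible-interval rule and is idempotent", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- 0.25; W[1, 3] <- 0.1; W[2, 3] <- -0.25
  lo <- matrix(0, 3, 3); hi <- matrix(0, 3, 3)
  lo[1, 2] <- 0.10; hi[1, 2] <- 0.40   # credibly positive -> retained
  lo[1, 3] <- -0.05; hi[1, 3] <- 0.30  # straddles zero -> removed
  lo[2, 3] <- -0.40; hi[2, 3] <- -0.10 # credibly negative
  net <- make_network(W, lo, hi)
  pos <- purge_network(net, "positive")
  expect_true(pos$retained[1, 2])
  expect_false(pos$retained[1, 3])
  expect_false(pos$retained[2, 3]) # not credibly ABOVE zero
  two <- purge_network(net, "two_sided")
  expect_true(two$retained[2, 3])  # excluded zero on the negative side
  expect_false(two$retained[1, 3])
  # weights preserved; idempotent; purged set within estimated set
  expect_equal(pos$weights, W)
  expect_identical(purge_network(pos, "positive")$retained, pos$retained)
  expect_true(all(which(pos$retained) %in% which(net$ci_low != 0 |
                                                   net$ci_high != 0)))
  expect_false(any(diag(pos$retained)))
})

test_that("strength sums equal the brute-force adjacency double loop", {
  brute <- function(net) {
    n <- nrow(net$weights)
    out <- numeric(n); inn <- numeric(n)
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (net$retained[j, k]) {
        out[j] <- out[j] + net$weights[j, k]
        inn[k] <- inn[k] + net$weights[j, k]
      }
    }
    list(outstrength = out, instrength = inn)
  }
  set.seed(99)
  for (i in 1:25) {
    W <- matrix(rnorm(81, 0, 0.3), 9, 9); diag(W) <- 0
    lo <- W - runif(81, 0, 0.3); hi <- W + runif(81, 0, 0.3)
    net <- purge_network(make_network(W, lo, hi),
                         sample(c("positive", "two_sided"), 1))
    s <- sdmnet:::network_strengths(net)
    # rowSums accumulates in long double: agreement to the last few ulps
    expect_equal(s, brute(net), tolerance = 1e-12)
    expect_equal(sum(s$outstrength), sum(s$instrength), tolerance = 1e-12)
  }
})

test_that("igraph agrees with the package's strength computation", {
  skip_if_not_installed("igraph")
  set.seed(7)
  W <- matrix(rnorm(81, 0.2, 0.1), 9, 9); diag(W) <- 0
  net <- make_network(W, lo = W - 0.01, hi = W + 0.01) # all retained
  net <- purge_network(net, "two_sided")
  g <- igraph::graph_from_adjacency_matrix(W * net$retained,
                                           mode = "directed", weighted = TRUE)
  s <- sdmnet:::network_strengths(net)
  expect_equal(unname(igraph::strength(g, mode = "out")), s$outstrength)
  expect_equal(unname(igraph::strength(g, mode = "in")), s$instrength)
})

test_that("single-physician fixed-effects fit matches ordinary least squares", {
  spec <- homogeneous_spec()
  truths <- draw_physician_parameters(spec, study_design(1, seed = 6))
  tab <- simulate_patient_ratings(truths, spec,
                                  study_design(1, patients_per_physician = 150,
                                               seed = 6))
  fit <- fit_node_model(tab, outcome_skill = 6, random_effects = FALSE,
                        config = mcmc_config(n_chains = 2, iterations = 3000,
                                             burn_in = 500, seed = 1))
  cc <- center_predictors(tab)
  ols <- lm(tab$item_6 ~ as.matrix(cc$table[sdmnet:::item_cols(9)[-6]]))
  expect_equal(unname(fit$population$mean), unname(coef(ols)),
               tolerance = 0.02)
})

test_that("zero heterogeneity shrinks physician slopes onto the population", {
  spec <- homogeneous_spec()
  des <- study_design(n_physicians = 10, patients_per_physician = 20, seed = 8)
  tab <- simulate_patient_ratings(draw_physician_parameters(spec, des),
                                  spec, des)
  fit <- suppressWarnings(
    fit_node_model(tab, outcome_skill = 7, random_effects = TRUE,
                   config = mcmc_config(n_chains = 2, iterations = 2500,
                                        burn_in = 500, seed = 2)))
  pop <- fit$population$mean[-1]
  spread <- apply(fit$physician_coef$mean, 2, sd) # across physicians
  # partial pooling: physician estimates shrink hard toward the population
  # values relative to unpooled per-physician least squares
  cc <- center_predictors(tab)
  ols_spread <- apply(vapply(
    split(seq_len(nrow(tab)), tab$physician_id),
    function(ix) coef(lm(tab$item_7[ix] ~
                           as.matrix(cc$table[ix, sdmnet:::item_cols(9)[-7]])))[-1],
    numeric(8)), 1, sd)
  expect_true(all(spread < 0.5 * ols_spread))
  expect_true(mean(spread) < 0.25 * mean(ols_spread))
  expect_equal(unname(colMeans(fit$physician_coef$mean)), unname(pop),
               tolerance = 0.02)
})

test_that("node parameters assemble intercepts and purged strengths", {
  spec <- population_network_spec()
  des <- study_design(n_physicians = 8, patients_per_physician = 12, seed = 3)
  tab <- simulate_patient_ratings(draw_physician_parameters(spec, des),
                                  spec, des)
  fit <- suppressWarnings(
    fit_skills_network(tab, config = fast_mcmc(seed = 5), compare = FALSE))
  np <- node_parameters(fit)
  expect_equal(nrow(np), 8 * 9)
  # strengths re-derivable from the edge list
  edges <- network_edges(fit)
  for (pid in fit$physician_ids[1:3]) {
    e <- edges[edges$physician_id == pid & edges$retained, ]
    for (s in c(1, 6, 9)) {
      expect_equal(np$outstrength[np$physician_id == pid & np$skill == s],
                   sum(e$weight[e$source_skill == s]))
      expect_equal(np$instrength[np$physician_id == pid & np$skill == s],
                   sum(e$weight[e$target_skill == s]))
    }
  }
  # activation from intercepts tracks raw item means even at this small
  # scale (the >= 0.9 reference-scale bound is asserted in the acceptance
  # suite)
  raw <- node_parameters(fit, activation = "raw_mean", table = tab)
  expect_gt(cor(np$activation, raw$activation), 0.6)
  # raw-mean activation equals the per-physician item mean by definition
  p1 <- fit$physician_ids[1]
  expect_equal(raw$activation[raw$physician_id == p1 & raw$skill == 2],
               mean(tab$item_2[tab$physician_id == p1]))
})

test_that("a homogeneous skill keeps the fixed model while heterogeneous skills go random", {
  # skill 1 is isolated (no edges in or out) with a non-random intercept;
  # all other skills vary across physicians
  B <- sdmnet:::default_fixed_edges()
  B[1, ] <- 0; B[, 1] <- 0
  sd_slope <- matrix(0.06, 9, 9)
  sd_slope[1, ] <- 0; sd_slope[, 1] <- 0
  spec <- population_network_spec(
    fixed_edges = B, random_sd_intercept = c(0, rep(0.35, 8)),
    random_sd_slope = sd_slope)
  des <- study_design(n_physicians = 20, patients_per_physician = 15,
                      seed = 881)
  tab <- simulate_patient_ratings(draw_physician_parameters(spec, des),
                                  spec, des)
  fit <- suppressWarnings(
    fit_skills_network(tab, config = mcmc_preset("desk", seed = 88),
                       compare = TRUE))
  sel <- fit$selection
  expect_equal(sel$choice[sel$outcome_skill == 1], "fixed")
  expect_gte(sum(sel$choice[sel$outcome_skill != 1] == "random"), 6)
})
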