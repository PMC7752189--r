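# short-chain MCMC budget for unit tests; experiments that need stable
# posterior summaries use mcmc_preset("desk") instead
fast_mcmc <- function(seed = 1) mcmc_preset("fast", seed = seed)

# population spec with no physician heterogeneity (all physicians identical)
homogeneous_spec <- function(...) {
  population_network_spec(random_sd_intercept = 0, random_sd_slope = 0, ...)
}

# hand-built physician truth record
make_truth <- function(id = "p1", alpha = rep(2.5, 9),
                       B = matrix(0, 9, 9),
                       competence = c("OPTION-12" = 16, "OPTION-5" = 12,
                                      "4HCS-InvestInTheEnd" = 33)) {
  structure(list(physician_id = id, intercepts_p = alpha, edges_p = B,
                 competence_true = competence),
            class = "physician_truth")
}

# hand-built network with given weight and interval matrices
make_network <- function(W, lo = W - 0.05, hi = W + 0.05, id = "p1") {
  diag(lo) <- diag(hi) <- 0
  structure(list(physician_id = id, weights = W, ci_low = lo, ci_high = hi,
                 retained = matrix(TRUE, nrow(W), ncol(W))),
            class = "sdm_network")
}

# wide-range single instrument for closed-form ICC/IRR recovery: item range
# 0-100 makes discretization noise negligible against unit-scale components
calibration_instrument <- function() {
  list(instrument_spec("CAL", n_items = 4, item_min = 0, item_max = 100))
}

# truths with constant competence for the calibration instrument, so all
# physician-level variance comes from the noise spec alone
constant_competence_truths <- function(n, competence = 50) {
  lapply(seq_len(n), function(p) {
    make_truth(sprintf("phys_%03d", p),
               competence = c("CAL" = competence))
  })
}

# minimal stand-in for a node_model_fit, for testing the DIC selection rule
fake_fit <- function(dic, outcome = 1, n_obs = 100, random = FALSE) {
  structure(list(outcome_skill = outcome, n_obs = n_obs,
                 random_effects = random, dic = list(dic = dic)),
            class = "node_model_fit")
}
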