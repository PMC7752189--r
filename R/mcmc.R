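#' MCMC configuration
#'
#' Settings shared by every Bayesian fit in the package. The default "desk"
#' preset is sized for interactive use and simulation studies; the "paper"
#' preset reproduces the long-run schedule typical of WinBUGS/JAGS era
#' multilevel analyses (three chains, 90 000 retained iterations after
#' 60 000 burn-in, thinning 30).
#'
#' @param n_chains number of independent chains with distinct seeded starting
#'   values (default 3).
#' @param iterations total post-adaptation iterations per chain, burn-in
#'   included.
#' @param burn_in iterations discarded from the start of each chain; must be
#'   `< iterations`.
#' @param thinning keep every `thinning`-th draw (>= 1).
#' @param n_adapt JAGS adaptation steps before burn-in.
#' @param seed integer master seed; each chain receives a derived seed.
#' @param rhat_threshold pass threshold for the split-chain potential scale
#'   reduction factor (default 1.1).
#' @return an object of class `mcmc_config`.
#' @export
#' @examples
#' mcmc_config(iterations = 2000, burn_in = 500)
#' mcmc_preset("paper")
mcmc_config <- function(n_chains = 3, iterations = 1500, burn_in = 500,
                        thinning = 1, n_adapt = 300, seed = 1,
                        rhat_threshold = 1.1) {
  assert_scalar_count(n_chains, "n_chains")
  assert_scalar_count(iterations, "iterations")
  assert_scalar_count(thinning, "thinning")
  if (burn_in < 0 || burn_in >= iterations) {
    stop("`burn_in` must satisfy 0 <= burn_in < iterations", call. = FALSE)
  }
  structure(
    list(n_chains = as.integer(n_chains), iterations = as.integer(iterations),
         burn_in = as.integer(burn_in), thinning = as.integer(thinning),
         n_adapt = as.integer(n_adapt), seed = as.integer(seed),
         rhat_threshold = rhat_threshold),
    class = "mcmc_config"
  )
}

#' @rdname mcmc_config
#' @param preset `"desk"` (default simulation-study budget), `"paper"`
#'   (long-run schedule) or `"fast"` (short chains for smoke runs and
#'   triage; too short for publication-grade summaries).
#' @param ... overrides passed on to [mcmc_config()].
#' @export
mcmc_preset <- function(preset = c("desk", "paper", "fast"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    desk  = list(n_chains = 3, iterations = 1500, burn_in = 500,
                 thinning = 1, n_adapt = 300),
    paper = list(n_chains = 3, iterations = 150000, burn_in = 60000,
                 thinning = 30, n_adapt = 1000),
    fast  = list(n_chains = 2, iterations = 600, burn_in = 250,
                 thinning = 1, n_adapt = 150)
  )
  do.call(mcmc_config, utils::modifyList(base, list(...)))
}

#' Draw posterior samples for a JAGS model specification
#'
#' Thin seeded wrapper around [rjags::jags.model()] and
#' [rjags::coda.samples()]. A model specification is a list with elements
#' `code` (JAGS model string), `data` (named list), `monitors` (character
#' vector of nodes to record) and optionally `inits` (a function of the chain
#' index returning an inits list; RNG seeds are always added by this
#' wrapper so results are deterministic given `config$seed`).
#'
#' @param model model specification list (see Details).
#' @param config an [mcmc_config()].
#' @return an object of class `sdm_posterior`: a list with the
#'   [coda::mcmc.list] `samples`, the flat draw matrix `draws`
#'   (chains stacked), and the `config` used.
#' @export
run_mcmc <- function(model, config = mcmc_config()) {
  stopifnot(is.list(model), !is.null(model$code), !is.null(model$monitors))
  inits <- lapply(seq_len(config$n_chains), function(ch) {
    ini <- if (is.function(model$inits)) model$inits(ch) else list()
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- derive_seed(config$seed, paste0("chain_", ch))
    ini
  })
  jm <- tryCatch(
    rjags::jags.model(textConnection(model$code), data = model$data,
                      inits = inits, n.chains = config$n_chains,
                      n.adapt = config$n_adapt, quiet = TRUE),
    error = function(e) stop("JAGS model setup failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (config$burn_in > 0) update(jm, config$burn_in, progress.bar = "none")
  samples <- rjags::coda.samples(
    jm, variable.names = model$monitors,
    n.iter = config$iterations - config$burn_in,
    thin = config$thinning, progress.bar = "none"
  )
  structure(
    list(samples = samples,
         draws = do.call(rbind, lapply(samples, as.matrix)),
         config = config),
    class = "sdm_posterior"
  )
}

#' @export
print.sdm_posterior <- function(x, ...) {
  cat(sprintf("<sdm_posterior> %d parameters, %d draws (%d chains)\n",
              ncol(x$draws), nrow(x$draws), length(x$samples)))
  invisible(x)
}

#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Computes the potential scale reduction factor for every monitored
#' parameter after splitting each chain in half (so within-chain trends are
#' detected even with few chains). A parameter with zero total variance
#' (e.g. a structurally constant node) is reported as `NA` and flagged
#' degenerate rather than failing the fit.
#'
#' @param posterior an `sdm_posterior` from [run_mcmc()], or a
#'   [coda::mcmc.list].
#' @param threshold pass threshold; defaults to the configuration's
#'   `rhat_threshold` (or 1.1).
#' @return an object of class `convergence_report`: a data frame with
#'   columns `parameter`, `rhat`, `degenerate`, plus attributes `pass` and
#'   `threshold`.
#' @export
gelman_rubin <- function(posterior, threshold = NULL) {
  chains <- if (inherits(posterior, "sdm_posterior")) posterior$samples
            else posterior
  if (!inherits(chains, "mcmc.list")) chains <- coda::as.mcmc.list(chains)
  if (length(chains) < 2) {
    stop("Gelman-Rubin diagnostic requires at least 2 chains", call. = FALSE)
  }
  threshold <- threshold %||%
    (if (inherits(posterior, "sdm_posterior"))
       posterior$config$rhat_threshold else 1.1)
  mats <- lapply(chains, as.matrix)
  n <- min(vapply(mats, nrow, 1L))
  half <- n %/% 2
  # split each chain into halves -> 2 * n_chains sequences of equal length
  seqs <- unlist(lapply(mats, function(m) {
    list(m[seq_len(half), , drop = FALSE],
         m[(n - half + 1):n, , drop = FALSE])
  }), recursive = FALSE)
  params <- colnames(mats[[1]])
  rhat <- vapply(params, function(p) {
    x <- vapply(seqs, function(s) s[, p], numeric(half)) # half x m
    m <- ncol(x)
    means <- colMeans(x)
    vars <- apply(x, 2, var)
    W <- mean(vars)
    B <- half * var(means)
    if (!is.finite(W) || W <= 0) return(NA_real_)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  out <- data.frame(parameter = params, rhat = unname(rhat),
                    degenerate = !is.finite(rhat), row.names = NULL)
  structure(out, class = c("convergence_report", "data.frame"),
            pass = all(rhat[is.finite(rhat)] < threshold),
            threshold = threshold)
}

#' Deviance information criterion from posterior draws
#'
#' `DIC = Dbar + pD`, where `Dbar` is the posterior mean deviance and the
#' effective number of parameters is `pD = Dbar - D(theta_bar)`, the mean
#' deviance minus the deviance at the posterior mean.
#'
#' @param posterior an `sdm_posterior` (or draw matrix with named columns).
#' @param log_lik function taking one named parameter vector (a draw) and
#'   returning the log-likelihood contributions (vector or scalar sum).
#' @return list with elements `dic`, `dbar`, `pd` and `dhat`.
#' @export
dic <- function(posterior, log_lik) {
  draws <- if (inherits(posterior, "sdm_posterior")) posterior$draws
           else as.matrix(posterior)
  dev <- apply(draws, 1, function(th) -2 * sum(log_lik(th)))
  if (any(!is.finite(dev))) {
    stop("non-finite deviance encountered in DIC computation", call. = FALSE)
  }
  dbar <- mean(dev)
  dhat <- -2 * sum(log_lik(colMeans(draws)))
  list(dic = dbar + (dbar - dhat), dbar = dbar, pd = dbar - dhat, dhat = dhat)
}

#' Equal-tailed credible interval
#'
#' @param posterior an `sdm_posterior`, draw matrix, or numeric draw vector.
#' @param parameter column name when `posterior` holds several parameters.
#' @param level interval mass (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(posterior, parameter = NULL, level = 0.95) {
  draws <- if (inherits(posterior, "sdm_posterior")) posterior$draws
           else posterior
  x <- if (is.null(dim(draws))) draws else {
    if (is.null(parameter)) stop("`parameter` required for a draw matrix")
    if (!parameter %in% colnames(draws)) {
      stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
    }
    draws[, parameter]
  }
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a), names = FALSE, type = 7))
}

# posterior summary (mean, sd, equal-tailed interval) for a set of columns
summarise_draws <- function(draws, cols = colnames(draws), level = 0.95) {
  a <- (1 - level) / 2
  data.frame(
    parameter = cols,
    mean = colMeans(draws[, cols, drop = FALSE]),
    sd = apply(draws[, cols, drop = FALSE], 2, sd),
    lower = apply(draws[, cols, drop = FALSE], 2, quantile, probs = a),
    upper = apply(draws[, cols, drop = FALSE], 2, quantile, probs = 1 - a),
    row.names = NULL
  )
}
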