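#' Grand-mean centre the SDM-Q-9 items
#'
#' Subtracts each item's grand mean over all consultations of all physicians.
#' Centred items are used as predictors in every regression; outcomes stay on
#' the raw 0-5 scale so intercepts are interpretable as adjusted item means.
#'
#' @param table patient-rating table with `item_*` columns.
#' @return list of class `sdm_centred` with elements `table` (centred items,
#'   identifiers untouched) and `grand_means` (named vector, kept for later
#'   prediction and reporting).
#' @export
#' @examples
#' tab <- data.frame(physician_id = "p1", patient_id = c("a", "b"),
#'                   item_1 = c(1L, 5L), item_2 = c(3L, 3L))
#' center_predictors(tab)$grand_means
center_predictors <- function(table) {
  cols <- grep("^item_", names(table), value = TRUE)
  if (length(cols) == 0 || nrow(table) == 0) {
    stop("`table` must be a nonempty patient-rating table with item_* columns")
  }
  gm <- vapply(table[cols], mean, numeric(1))
  centred <- table
  centred[cols] <- sweep(as.matrix(table[cols]), 2, gm)
  structure(list(table = centred, grand_means = gm), class = "sdm_centred")
}

# JAGS code for the node-wise models; coefficient priors Normal(0, sd 100),
# scale priors half-Cauchy(5)
node_model_code <- function(random_effects) {
  if (random_effects) "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], tau.res)
    mu[i] <- alpha[phys[i]] + inprod(X[i,], beta[phys[i],])
  }
  for (p in 1:P) {
    alpha[p] ~ dnorm(alpha0, tau.alpha)
    for (j in 1:K) { beta[p,j] ~ dnorm(beta0[j], tau.beta[j]) }
  }
  alpha0 ~ dnorm(0, 1.0E-4)
  for (j in 1:K) {
    beta0[j] ~ dnorm(0, 1.0E-4)
    sigma.beta[j] ~ dt(0, 0.04, 1) T(0,)
    tau.beta[j] <- pow(sigma.beta[j], -2)
  }
  sigma.alpha ~ dt(0, 0.04, 1) T(0,)
  tau.alpha <- pow(sigma.alpha, -2)
  sigma.res ~ dt(0, 0.04, 1) T(0,)
  tau.res <- pow(sigma.res, -2)
}" else "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], tau.res)
    mu[i] <- alpha0 + inprod(X[i,], beta0[])
  }
  alpha0 ~ dnorm(0, 1.0E-4)
  for (j in 1:K) { beta0[j] ~ dnorm(0, 1.0E-4) }
  sigma.res ~ dt(0, 0.04, 1) T(0,)
  tau.res <- pow(sigma.res, -2)
}"
}

# Marginal (integrated) log-likelihood of the random-effects node model:
# random intercept and slope deviations are integrated out analytically, so
# the likelihood depends only on the population coefficients and the scale
# parameters. DIC computed on this likelihood compares the fixed- and
# random-effects structures at the population focus; DIC on the conditional
# likelihood is known to be unstable for this comparison because weakly
# shrunk random effects absorb residual noise. Uses the Woodbury identity
# with per-physician sufficient statistics: with Z = [1, X] and
# D = diag(sd_alpha^2, sd_beta^2), Sigma_p = sigma^2 I + Z_p D Z_p'.
marginal_node_loglik <- function(y, X, pidx, P, K) {
  q <- K + 1
  stats <- lapply(seq_len(P), function(p) {
    sel <- pidx == p
    Z <- cbind(1, X[sel, , drop = FALSE])
    list(n = sum(sel), yy = sum(y[sel]^2),
         Zty = crossprod(Z, y[sel]), ZtZ = crossprod(Z))
  })
  beta_nm <- paste0("beta0[", seq_len(K), "]")
  sbeta_nm <- paste0("sigma.beta[", seq_len(K), "]")
  cache <- new.env(parent = emptyenv())
  function(th) {
    if (is.null(cache$ix)) {
      cache$ix <- list(a = match("alpha0", names(th)),
                       b = match(beta_nm, names(th)),
                       s = match("sigma.res", names(th)),
                       sa = match("sigma.alpha", names(th)),
                       sb = match(sbeta_nm, names(th)))
    }
    ix <- cache$ix
    cvec <- c(th[ix$a], th[ix$b])
    dhalf <- c(th[ix$sa], th[ix$sb])
    s2 <- th[ix$s]^2
    tot <- 0
    for (st in stats) {
      rr <- st$yy - 2 * sum(cvec * st$Zty) +
        drop(crossprod(cvec, st$ZtZ %*% cvec))
      Ztr <- st$Zty - st$ZtZ %*% cvec
      A <- diag(q) + (dhalf %o% dhalf) * st$ZtZ / s2
      ch <- chol(A)
      u <- dhalf * Ztr
      quad <- (rr - sum(backsolve(ch, u, transpose = TRUE)^2) / s2) / s2
      logdet <- st$n * log(s2) + 2 * sum(log(diag(ch)))
      tot <- tot - 0.5 * (st$n * log(2 * pi) + logdet + quad)
    }
    tot
  }
}

# log-likelihood factory for the fixed-effects node model (its marginal and
# conditional likelihoods coincide); caches column positions of the draw
# vector between calls (names are constant across draws)
fixed_node_loglik <- function(y, X, K) {
  cache <- new.env(parent = emptyenv())
  beta_nm <- paste0("beta0[", seq_len(K), "]")
  function(th) {
    if (is.null(cache$bi)) {
      cache$ai <- match("alpha0", names(th))
      cache$bi <- match(beta_nm, names(th))
      cache$si <- match("sigma.res", names(th))
    }
    mu <- th[cache$ai] + as.vector(X %*% th[cache$bi])
    dnorm(y, mu, th[cache$si], log = TRUE)
  }
}

#' Fit one node-wise multilevel regression
#'
#' Regresses one SDM-Q-9 item on the grand-mean-centred remaining eight
#' items. With `random_effects = TRUE` the intercept and every slope receive
#' physician-level Normal deviations around the population values (partial
#' pooling: each physician's estimates borrow strength from all other
#' physicians' data and shrink toward the population values); otherwise a
#' single set of coefficients is shared by all physicians. Non-convergence
#' by the split-chain Gelman-Rubin diagnostic raises a warning carrying the
#' diagnostics.
#'
#' The DIC of a random-effects fit is computed on the marginal likelihood
#' (random deviations integrated out analytically), which makes the fixed-
#' versus-random comparison a population-focused one; DIC on the conditional
#' likelihood is unstable for this comparison because weakly shrunk random
#' effects can absorb residual noise.
#'
#' @param table raw patient-rating table (`physician_id`, `item_*`).
#' @param outcome_skill index of the outcome item.
#' @param random_effects logical.
#' @param config an [mcmc_config()].
#' @param centred optional precomputed [center_predictors()] result for
#'   `table` (avoids recentring in loops).
#' @return object of class `node_model_fit`: population coefficient
#'   summaries, per-physician coefficient and intercept summaries, DIC,
#'   convergence report.
#' @export
fit_node_model <- function(table, outcome_skill, random_effects = TRUE,
                           config = mcmc_config(), centred = NULL) {
  cols <- grep("^item_", names(table), value = TRUE)
  n_skills <- length(cols)
  stopifnot(outcome_skill >= 1, outcome_skill <= n_skills)
  centred <- centred %||% center_predictors(table)
  phys <- factor(table$physician_id)
  P <- nlevels(phys)
  if (random_effects && P < 2) {
    stop("random-effects node models need >= 2 physicians", call. = FALSE)
  }
  pred_skills <- setdiff(seq_len(n_skills), outcome_skill)
  y <- as.numeric(table[[cols[outcome_skill]]])
  X <- as.matrix(centred$table[cols[pred_skills]])
  K <- length(pred_skills)
  N <- length(y)
  pidx <- as.integer(phys)
  data <- list(y = y, X = X, N = N, K = K)
  monitors <- c("alpha0", "beta0", "sigma.res")
  if (random_effects) {
    data$phys <- pidx
    data$P <- P
    monitors <- c(monitors, "alpha", "beta", "sigma.alpha", "sigma.beta")
  }
  cfg <- config
  cfg$seed <- derive_seed(config$seed,
                          sprintf("node_%d_%s", outcome_skill,
                                  if (random_effects) "random" else "fixed"))
  post <- run_mcmc(list(code = node_model_code(random_effects), data = data,
                        monitors = monitors), cfg)
  draws <- post$draws
  pop_cols <- c("alpha0", paste0("beta0[", seq_len(K), "]"))
  pop <- summarise_draws(draws, pop_cols)
  pop$term <- c("(Intercept)", paste0("skill_", pred_skills))
  if (random_effects) {
    coef_mean <- coef_lo <- coef_hi <- matrix(
      NA_real_, P, K, dimnames = list(levels(phys), paste0("skill_", pred_skills)))
    for (j in seq_len(K)) {
      nm <- sprintf("beta[%d,%d]", seq_len(P), j)
      s <- summarise_draws(draws, nm)
      coef_mean[, j] <- s$mean; coef_lo[, j] <- s$lower; coef_hi[, j] <- s$upper
    }
    anm <- sprintf("alpha[%d]", seq_len(P))
    ai <- summarise_draws(draws, anm)
    int_mean <- setNames(ai$mean, levels(phys))
    int_lo <- setNames(ai$lower, levels(phys))
    int_hi <- setNames(ai$upper, levels(phys))
  } else {
    rep_row <- function(v) matrix(v, P, K, byrow = TRUE,
                                  dimnames = list(levels(phys),
                                                  paste0("skill_", pred_skills)))
    coef_mean <- rep_row(pop$mean[-1]); coef_lo <- rep_row(pop$lower[-1])
    coef_hi <- rep_row(pop$upper[-1])
    int_mean <- setNames(rep(pop$mean[1], P), levels(phys))
    int_lo <- setNames(rep(pop$lower[1], P), levels(phys))
    int_hi <- setNames(rep(pop$upper[1], P), levels(phys))
  }
  ll <- if (random_effects) marginal_node_loglik(y, X, pidx, P, K)
        else fixed_node_loglik(y, X, K)
  dic_info <- dic(post, ll)
  conv <- gelman_rubin(post)
  if (!isTRUE(attr(conv, "pass"))) {
    w <- simpleWarning(sprintf(
      "node model for skill %d (%s effects): Gelman-Rubin above %.2f for %d parameter(s)",
      outcome_skill, if (random_effects) "random" else "fixed",
      attr(conv, "threshold"),
      sum(conv$rhat >= attr(conv, "threshold"), na.rm = TRUE)))
    class(w) <- c("sdmnet_convergence", class(w))
    attr(w, "diagnostics") <- conv
    warning(w)
  }
  structure(
    list(outcome_skill = outcome_skill, predictor_skills = pred_skills,
         random_effects = random_effects,
         population = pop[c("term", "mean", "sd", "lower", "upper")],
         physician_coef = list(mean = coef_mean, lower = coef_lo,
                               upper = coef_hi),
         physician_intercept = list(mean = int_mean, lower = int_lo,
                                    upper = int_hi),
         dic = dic_info, convergence = conv,
         grand_means = centred$grand_means,
         physician_ids = levels(phys), n_obs = N),
    class = "node_model_fit"
  )
}

#' Select between fixed- and random-effects node models by DIC
#'
#' The random-effects model is selected only if its DIC undercuts the
#' fixed-effects DIC by at least `threshold` points (default 3, the
#' conventional relevance margin); otherwise the simpler fixed model is
#' retained.
#'
#' @param fit_fixed,fit_random `node_model_fit`s on identical data and
#'   outcome.
#' @param threshold DIC difference deemed relevant.
#' @return list with `selected` (the chosen fit), `choice`
#'   (`"fixed"`/`"random"`), `dic_fixed`, `dic_random` and `dic_difference`
#'   (`dic_fixed - dic_random`; positive favours the random model).
#' @export
compare_models <- function(fit_fixed, fit_random, threshold = 3) {
  stopifnot(fit_fixed$outcome_skill == fit_random$outcome_skill,
            fit_fixed$n_obs == fit_random$n_obs)
  diff <- fit_fixed$dic$dic - fit_random$dic$dic
  choice <- if (diff >= threshold) "random" else "fixed"
  list(selected = if (choice == "random") fit_random else fit_fixed,
       choice = choice, dic_fixed = fit_fixed$dic$dic,
       dic_random = fit_random$dic$dic, dic_difference = diff)
}

#' Estimate all physician-specific skills networks
#'
#' Runs the node-wise multilevel regression for every skill (each item
#' regressed on the centred remaining items), optionally fits both fixed-
#' and random-effects variants and selects by DIC, assembles one directed
#' weighted network per physician and purges edges by the credible-interval
#' rule.
#'
#' @param table raw patient-rating table.
#' @param config an [mcmc_config()].
#' @param compare fit both variants and select by DIC (default). With
#'   `compare = FALSE` only the random-effects models are fitted.
#' @param purge_rule `"positive"` (retain an edge only when its 95% interval
#'   lies entirely above zero) or `"two_sided"` (retain when the interval
#'   excludes zero on either side).
#' @param verbose log per-skill progress.
#' @return object of class `sdm_network_fit`: `fits` (selected
#'   `node_model_fit` per outcome), `selection` (DIC table), `networks`
#'   (list of purged per-physician `sdm_network`s), `grand_means`,
#'   `physician_ids`, `purge_rule`.
#' @export
fit_skills_network <- function(table, config = mcmc_config(), compare = TRUE,
                               purge_rule = c("positive", "two_sided"),
                               verbose = FALSE) {
  purge_rule <- match.arg(purge_rule)
  cols <- grep("^item_", names(table), value = TRUE)
  n_skills <- length(cols)
  centred <- center_predictors(table)
  fits <- vector("list", n_skills)
  sel_rows <- vector("list", n_skills)
  for (k in seq_len(n_skills)) {
    msg("fitting node model for skill %d/%d", k, n_skills, verbose = verbose)
    fr <- fit_node_model(table, k, random_effects = TRUE, config = config,
                         centred = centred)
    if (compare) {
      ff <- fit_node_model(table, k, random_effects = FALSE, config = config,
                           centred = centred)
      cmp <- compare_models(ff, fr)
      fits[[k]] <- cmp$selected
      sel_rows[[k]] <- data.frame(outcome_skill = k,
                                  dic_fixed = cmp$dic_fixed,
                                  dic_random = cmp$dic_random,
                                  dic_difference = cmp$dic_difference,
                                  choice = cmp$choice)
    } else {
      fits[[k]] <- fr
      sel_rows[[k]] <- data.frame(outcome_skill = k, dic_fixed = NA_real_,
                                  dic_random = fr$dic$dic,
                                  dic_difference = NA_real_,
                                  choice = "random")
    }
  }
  phys_ids <- fits[[1]]$physician_ids
  networks <- lapply(phys_ids, function(pid) {
    W <- lo <- hi <- matrix(0, n_skills, n_skills)
    for (k in seq_len(n_skills)) {
      f <- fits[[k]]
      W[f$predictor_skills, k] <- f$physician_coef$mean[pid, ]
      lo[f$predictor_skills, k] <- f$physician_coef$lower[pid, ]
      hi[f$predictor_skills, k] <- f$physician_coef$upper[pid, ]
    }
    purge_network(
      structure(list(physician_id = pid, weights = W, ci_low = lo,
                     ci_high = hi,
                     retained = matrix(TRUE, n_skills, n_skills)),
                class = "sdm_network"),
      rule = purge_rule)
  })
  names(networks) <- phys_ids
  structure(
    list(fits = fits, selection = do.call(rbind, sel_rows),
         networks = networks, grand_means = centred$grand_means,
         physician_ids = phys_ids, purge_rule = purge_rule,
         n_skills = n_skills),
    class = "sdm_network_fit"
  )
}

#' Purge non-credible edges from a skills network
#'
#' Removes (masks) edges whose physician-specific 95% credible interval does
#' not support a real association. Under the default `"positive"` rule an
#' edge is retained only when its interval lies entirely above zero; under
#' `"two_sided"` it is retained whenever the interval excludes zero
#' (credibly negative edges survive). Weights are preserved; purging only
#' updates the `retained` mask, so the operation is idempotent.
#'
#' @param network an `sdm_network` (weights plus interval matrices).
#' @param rule `"positive"` or `"two_sided"`.
#' @return the network with an updated `retained` mask.
#' @export
purge_network <- function(network, rule = c("positive", "two_sided")) {
  rule <- match.arg(rule)
  retained <- if (rule == "positive") network$ci_low > 0
              else network$ci_low > 0 | network$ci_high < 0
  diag(retained) <- FALSE
  network$retained <- retained
  network$purge_rule <- rule
  network
}

# strength sums of one purged network
network_strengths <- function(network) {
  W <- network$weights * network$retained
  list(outstrength = rowSums(W), instrength = colSums(W))
}

#' Node parameters of estimated skills networks
#'
#' Per physician and skill: activation (the physician-specific model
#' intercept of that skill's node model; with grand-mean-centred predictors
#' this is the physician's adjusted item mean on the 0-5 scale -- set
#' `activation = "raw_mean"` to use the raw per-physician item mean
#' instead), outstrength (sum of retained outgoing edge weights) and
#' instrength (sum of retained incoming edge weights).
#'
#' @param fit an `sdm_network_fit` from [fit_skills_network()].
#' @param activation `"intercept"` (default) or `"raw_mean"`.
#' @param table raw patient-rating table; required for
#'   `activation = "raw_mean"`.
#' @return long `data.frame`: `physician_id`, `skill`, `activation`,
#'   `outstrength`, `instrength`.
#' @export
node_parameters <- function(fit, activation = c("intercept", "raw_mean"),
                            table = NULL) {
  activation <- match.arg(activation)
  stopifnot(inherits(fit, "sdm_network_fit"))
  if (activation == "raw_mean" && is.null(table)) {
    stop("`table` is required for activation = \"raw_mean\"")
  }
  out <- do.call(rbind, lapply(fit$physician_ids, function(pid) {
    net <- fit$networks[[pid]]
    if (is.null(net)) stop("physician ", pid, " absent from fits")
    s <- network_strengths(net)
    act <- if (activation == "intercept") {
      vapply(fit$fits, function(f) f$physician_intercept$mean[[pid]],
             numeric(1))
    } else {
      sub <- table[table$physician_id == pid, , drop = FALSE]
      vapply(item_cols(fit$n_skills), function(cl) mean(sub[[cl]]),
             numeric(1))
    }
    data.frame(physician_id = pid, skill = seq_len(fit$n_skills),
               activation = unname(act), outstrength = s$outstrength,
               instrength = s$instrength)
  }))
  rownames(out) <- NULL
  out
}

#' Edge list of an estimated network fit
#'
#' @param fit an `sdm_network_fit`.
#' @return `data.frame`: `physician_id`, `source_skill`, `target_skill`,
#'   `weight`, `ci_low`, `ci_high`, `retained`.
#' @export
network_edges <- function(fit) {
  n <- fit$n_skills
  idx <- which(diag(n) == 0, arr.ind = TRUE) # off-diagonal entries
  out <- do.call(rbind, lapply(fit$networks, function(net) {
    data.frame(physician_id = net$physician_id,
               source_skill = idx[, 1], target_skill = idx[, 2],
               weight = net$weights[idx], ci_low = net$ci_low[idx],
               ci_high = net$ci_high[idx], retained = net$retained[idx])
  }))
  rownames(out) <- NULL
  out[order(out$physician_id, out$source_skill, out$target_skill), ]
}
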