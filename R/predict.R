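#' Wide layout of a node-parameter table
#'
#' One row per physician; columns `activation_s<k>`, `outstrength_s<k>`,
#' `instrength_s<k>` for each skill.
#'
#' @param node_params long node-parameter table ([node_parameters()] or
#'   [true_node_parameters()]).
#' @return wide `data.frame` keyed by `physician_id`.
#' @export
node_parameters_wide <- function(node_params) {
  skills <- sort(unique(node_params$skill))
  ids <- unique(node_params$physician_id)
  out <- data.frame(physician_id = ids)
  for (type in c("activation", "outstrength", "instrength")) {
    for (s in skills) {
      col <- sprintf("%s_s%d", type, s)
      sub <- node_params[node_params$skill == s, ]
      out[[col]] <- sub[[type]][match(ids, sub$physician_id)]
    }
  }
  out
}

# Bayesian linear regression on the 0-100 competence scale; returns draws of
# b0, b[], sigma. Coefficient priors Normal(0, sd 1000), scale half-Cauchy(25).
bayes_lm_code <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], tau)
    mu[i] <- b0 + inprod(X[i,], b[])
  }
  b0 ~ dnorm(0, 1.0E-6)
  for (j in 1:K) { b[j] ~ dnorm(0, 1.0E-6) }
  sigma ~ dt(0, 0.0016, 1) T(0,)
  tau <- pow(sigma, -2)
}"

bayes_lm_intercept_code <- "
model {
  for (i in 1:N) { y[i] ~ dnorm(b0, tau) }
  b0 ~ dnorm(0, 1.0E-6)
  sigma ~ dt(0, 0.0016, 1) T(0,)
  tau <- pow(sigma, -2)
}"

fit_bayes_lm <- function(X, y, config, stream) {
  cfg <- config
  cfg$seed <- derive_seed(config$seed, stream)
  if (is.null(X) || ncol(X) == 0) {
    post <- run_mcmc(list(code = bayes_lm_intercept_code,
                          data = list(y = y, N = length(y)),
                          monitors = c("b0", "sigma")), cfg)
  } else {
    post <- run_mcmc(list(code = bayes_lm_code,
                          data = list(y = y, X = X, N = length(y),
                                      K = ncol(X)),
                          monitors = c("b0", "b", "sigma")), cfg)
  }
  post
}

#' Screen node parameters as predictors of observer-rated competence
#'
#' For every observer-rated outcome, three Bayesian linear regressions are
#' fitted -- one per parameter type (activation, outstrength, instrength) --
#' each using all skills' grand-mean-centred values of that type as
#' predictors of the physician-level competence score. A coefficient is
#' flagged when its 95% credible interval excludes zero; a skill is retained
#' when at least one of its parameters is flagged for at least one outcome.
#'
#' @param node_params long node-parameter table.
#' @param competence `data.frame` with `physician_id`, `instrument`, `score`.
#' @param config an [mcmc_config()].
#' @param level credible level for the non-zero flag (default 0.95).
#' @return object of class `sdm_screening`: `results` (one row per outcome x
#'   type x skill with interval and flag), `retained_skills` (integer
#'   vector), `degenerate_outcomes`.
#' @export
screen_predictors <- function(node_params, competence,
                              config = mcmc_config(), level = 0.95) {
  wide <- node_parameters_wide(node_params)
  skills <- sort(unique(node_params$skill))
  outcomes <- unique(competence$instrument)
  results <- list()
  degenerate <- character()
  for (oc in outcomes) {
    comp <- competence[competence$instrument == oc, ]
    d <- merge(wide, comp[c("physician_id", "score")], by = "physician_id")
    if (nrow(d) < length(skills) + 2) {
      stop(sprintf(
        "outcome %s: only %d physicians have both node parameters and a competence score (need >= %d)",
        oc, nrow(d), length(skills) + 2), call. = FALSE)
    }
    if (var(d$score) < .Machine$double.eps) {
      degenerate <- c(degenerate, oc)
      for (type in c("activation", "outstrength", "instrength")) {
        results[[length(results) + 1L]] <- data.frame(
          outcome = oc, parameter_type = type, skill = skills,
          estimate = NA_real_, lower = NA_real_, upper = NA_real_,
          nonzero = FALSE)
      }
      next
    }
    for (type in c("activation", "outstrength", "instrength")) {
      X <- as.matrix(d[sprintf("%s_s%d", type, skills)])
      X <- sweep(X, 2, colMeans(X))
      post <- fit_bayes_lm(X, d$score, config,
                           stream = sprintf("screen_%s_%s", oc, type))
      b_cols <- paste0("b[", seq_along(skills), "]")
      s <- summarise_draws(post$draws, b_cols, level = level)
      results[[length(results) + 1L]] <- data.frame(
        outcome = oc, parameter_type = type, skill = skills,
        estimate = s$mean, lower = s$lower, upper = s$upper,
        nonzero = s$lower > 0 | s$upper < 0)
    }
  }
  results <- do.call(rbind, results)
  retained <- sort(unique(results$skill[results$nonzero]))
  structure(list(results = results, retained_skills = retained,
                 degenerate_outcomes = degenerate, level = level),
            class = "sdm_screening")
}

#' @export
print.sdm_screening <- function(x, ...) {
  cat("<sdm_screening>\n  retained skills:",
      if (length(x$retained_skills)) paste(x$retained_skills, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Fit the final competence-prediction model
#'
#' One Bayesian linear regression per observer-rated outcome, with an
#' intercept and the activation, outstrength and instrength of every
#' retained skill as grand-mean-centred predictors. Fit statistics are
#' computed per posterior draw and then summarised: model variance is the
#' variance of the linear predictor across physicians, `R^2 =
#' model / (model + residual)`, `R = sqrt(R^2)` and adjusted `R^2` applies
#' the usual `(n - 1) / (n - p - 1)` correction. With `p >= n - 1` the model
#' is reported but the adjusted `R^2` is refused (set to `NA` with a
#' warning).
#'
#' @inheritParams screen_predictors
#' @param retained_skills integer vector of retained skills (may be empty:
#'   intercept-only model).
#' @return object of class `sdm_prediction_models`: a named list of per-
#'   outcome models, each with `coefficients` (posterior mean and 95%
#'   interval per term), `fit_statistics`, `grand_means`, `terms`,
#'   `observed` and sizes.
#' @export
fit_final_model <- function(node_params, competence, retained_skills,
                            config = mcmc_config()) {
  wide <- node_parameters_wide(node_params)
  retained_skills <- sort(unique(as.integer(retained_skills)))
  term_cols <- if (length(retained_skills) == 0) character() else
    as.vector(t(outer(c("activation", "outstrength", "instrength"),
                      retained_skills, function(t, s) sprintf("%s_s%d", t, s))))
  term_cols <- sort(term_cols)
  outcomes <- unique(competence$instrument)
  models <- lapply(outcomes, function(oc) {
    comp <- competence[competence$instrument == oc, ]
    d <- merge(wide, comp[c("physician_id", "score")], by = "physician_id")
    n <- nrow(d)
    p <- length(term_cols)
    if (n < p + 2) {
      warning(sprintf(
        "outcome %s: p = %d predictors for n = %d observations; model reported but adjusted R^2 refused",
        oc, p, n), call. = FALSE)
    }
    X <- if (p > 0) as.matrix(d[term_cols]) else NULL
    gm <- if (p > 0) colMeans(X) else numeric()
    Xc <- if (p > 0) sweep(X, 2, gm) else NULL
    post <- fit_bayes_lm(Xc, d$score, config,
                         stream = paste0("final_", oc))
    draws <- post$draws
    b_cols <- if (p > 0) paste0("b[", seq_len(p), "]") else character()
    coefs <- summarise_draws(draws, c("b0", b_cols))
    coefs$term <- c("(Intercept)", term_cols)
    # per-draw fit statistics
    rv <- draws[, "sigma"]^2
    mv <- if (p > 0) {
      lin <- draws[, b_cols, drop = FALSE] %*% t(Xc)
      apply(lin, 1, var)
    } else rep(0, nrow(draws))
    r2 <- mv / (mv + rv)
    stat_draws <- cbind(residual_variance = rv, model_variance = mv,
                        r = sqrt(r2), r_squared = r2)
    if (n > p + 1) {
      stat_draws <- cbind(stat_draws,
                          adjusted_r_squared = adjusted_r_squared(r2, n, p))
    }
    stats <- summarise_draws(stat_draws)
    fitted <- coefs$mean[1] +
      if (p > 0) as.vector(Xc %*% coefs$mean[-1]) else 0
    structure(
      list(outcome = oc,
           coefficients = coefs[c("term", "mean", "sd", "lower", "upper")],
           fit_statistics = stats, grand_means = gm, terms = term_cols,
           retained_skills = retained_skills,
           n_observations = n, n_predictors = p,
           observed = data.frame(physician_id = d$physician_id,
                                 observed_score = d$score,
                                 fitted_score = fitted)),
      class = "sdm_prediction_model"
    )
  })
  names(models) <- outcomes
  structure(models, class = "sdm_prediction_models")
}

#' @export
print.sdm_prediction_model <- function(x, ...) {
  cat(sprintf("<sdm_prediction_model> outcome %s: n = %d, p = %d\n",
              x$outcome, x$n_observations, x$n_predictors))
  print(x$fit_statistics, row.names = FALSE)
  invisible(x)
}

#' Predict physician competence from node parameters
#'
#' Deterministic linear scoring: `intercept + sum(coefficient * (parameter -
#' stored grand mean))` using the posterior-mean coefficients. Predictions
#' are produced for every physician with complete node parameters, whether
#' or not observer data exist for them -- this is the intended use case of
#' measuring competence from patient-reported data alone. Physicians with
#' missing parameters are skipped with a message.
#'
#' @param model an `sdm_prediction_model` or `sdm_prediction_models`.
#' @param node_params long node-parameter table for the physicians to score.
#' @param verbose log skipped physicians.
#' @return `data.frame`: `physician_id`, `outcome`, `predicted_score`,
#'   `observed_score` (`NA` when no observer data were available).
#' @export
predict_competence <- function(model, node_params, verbose = FALSE) {
  if (inherits(model, "sdm_prediction_models")) {
    out <- do.call(rbind, lapply(model, predict_competence,
                                 node_params = node_params,
                                 verbose = verbose))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(model, "sdm_prediction_model"))
  wide <- node_parameters_wide(node_params)
  complete <- if (length(model$terms) > 0) {
    stats::complete.cases(wide[model$terms])
  } else rep(TRUE, nrow(wide))
  if (any(!complete)) {
    msg("skipping %d physician(s) with incomplete node parameters",
        sum(!complete), verbose = verbose)
  }
  wide <- wide[complete, , drop = FALSE]
  b <- model$coefficients$mean
  pred <- if (length(model$terms) > 0) {
    Xc <- sweep(as.matrix(wide[model$terms]), 2, model$grand_means)
    b[1] + as.vector(Xc %*% b[-1])
  } else rep(b[1], nrow(wide))
  out <- data.frame(physician_id = wide$physician_id, outcome = model$outcome,
                    predicted_score = pred)
  out$observed_score <- model$observed$observed_score[
    match(out$physician_id, model$observed$physician_id)]
  out
}

#' Tabular and graphical report of a fitted prediction model
#'
#' Emits the coefficient table in the conventional layout (posterior mean
#' with 95% credible interval per row, fit statistics below) and the
#' observed-versus-predicted scatter data with a loess smoothing curve.
#'
#' @param model an `sdm_prediction_model`.
#' @param predictions output of [predict_competence()] for this model
#'   (defaults to the training-set predictions).
#' @return list with `coefficients`, `fit_statistics` and `scatter`
#'   (`observed`, `predicted`, `smooth`).
#' @export
fit_report <- function(model, predictions = NULL) {
  stopifnot(inherits(model, "sdm_prediction_model"))
  if (is.null(predictions)) {
    predictions <- data.frame(
      physician_id = model$observed$physician_id,
      outcome = model$outcome,
      predicted_score = model$observed$fitted_score,
      observed_score = model$observed$observed_score)
  }
  sc <- predictions[!is.na(predictions$observed_score), ]
  sc <- sc[order(sc$predicted_score), ]
  smooth <- tryCatch(
    suppressWarnings(predict(loess(observed_score ~ predicted_score,
                                   data = sc, degree = 1, span = 1))),
    error = function(e) NULL)
  if (is.null(smooth) || any(!is.finite(smooth))) {
    # degenerate spread (e.g. intercept-only model): linear fallback
    fit <- lm(observed_score ~ predicted_score, data = sc)
    smooth <- as.vector(predict(fit))
  }
  list(coefficients = model$coefficients,
       fit_statistics = model$fit_statistics,
       scatter = data.frame(physician_id = sc$physician_id,
                            observed = sc$observed_score,
                            predicted = sc$predicted_score,
                            smooth = smooth))
}
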