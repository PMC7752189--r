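#' Population-level specification of the skills network generator
#'
#' Defines the population from which physician-specific skills networks are
#' drawn. The generative model is a simultaneous linear system on the latent
#' item scale: for physician `p` with intercepts `alpha_p` and edge matrix
#' `B_p` (entry `[j, k]` = weight of skill `j` predicting skill `k`), each
#' consultation draws independent residuals `eps` per skill and sets
#' `y = (I - t(B_p))^-1 (alpha_p + eps)`, after which scores are discretized
#' by rounding half away from zero and clipping to the Likert range. This is
#' the joint model whose node-wise conditional regressions correspond to the
#' estimation equations used downstream, so recovery of the generating
#' parameters is a meaningful check of the whole pipeline.
#'
#' The default population network mirrors the qualitative structure reported
#' for SDM consultations: a sparse set of positive directed associations in
#' which eliciting preferences (skill 6) is the most central node, with the
#' focusing/sharing pair (skills 1-2) forming a strongly interrelated block
#' that is only moderately tied to the core.
#'
#' @param n_skills number of skills / items (default 9).
#' @param fixed_edges `n_skills x n_skills` matrix of population edge
#'   weights, zero diagonal. Defaults to the built-in sparse positive
#'   structure when `n_skills == 9`.
#' @param intercept_means per-skill population structural intercepts on the
#'   item scale. The default is derived so that the population reduced-form
#'   item means sit mid-scale (2.8 to 3.4 on the 0-5 scale): the reduced
#'   form `(I - t(B))^-1 alpha` amplifies intercepts, so structural
#'   intercepts are back-transformed from the target means.
#' @param random_sd_intercept SD of physician intercept deviations; scalar or
#'   per-skill vector.
#' @param random_sd_slope SD of physician edge deviations; scalar or
#'   per-edge matrix (entries on the diagonal are ignored).
#' @param residual_sd consultation-level residual SD; scalar or per-skill.
#' @param likert_min,likert_max integer bounds of the rating scale.
#' @return an object of class `population_network_spec`.
#' @export
#' @examples
#' spec <- population_network_spec()
#' round(spec$fixed_edges[6, ], 2) # outgoing edges of 'eliciting preferences'
population_network_spec <- function(n_skills = 9,
                                    fixed_edges = NULL,
                                    intercept_means = NULL,
                                    random_sd_intercept = 0.20,
                                    random_sd_slope = 0.06,
                                    residual_sd = 0.75,
                                    likert_min = 0, likert_max = 5) {
  assert_scalar_count(n_skills, "n_skills")
  if (likert_min >= likert_max) stop("likert_min must be < likert_max")
  if (is.null(fixed_edges)) {
    if (n_skills != 9) {
      stop("`fixed_edges` must be supplied when n_skills != 9")
    }
    fixed_edges <- default_fixed_edges()
  }
  fixed_edges <- as.matrix(fixed_edges)
  if (!all(dim(fixed_edges) == n_skills)) {
    stop("`fixed_edges` must be a square n_skills x n_skills matrix")
  }
  if (any(diag(fixed_edges) != 0)) {
    stop("diagonal of `fixed_edges` must be exactly zero")
  }
  intercept_means <- intercept_means %||% as.numeric(
    (diag(n_skills) - t(fixed_edges)) %*%
      seq(2.8, 3.4, length.out = n_skills))
  intercept_means <- rep_len(intercept_means, n_skills)
  if (length(random_sd_intercept) == 1) {
    random_sd_intercept <- rep(random_sd_intercept, n_skills)
  }
  if (length(random_sd_slope) == 1) {
    random_sd_slope <- matrix(random_sd_slope, n_skills, n_skills)
  }
  random_sd_slope <- as.matrix(random_sd_slope)
  diag(random_sd_slope) <- 0
  residual_sd <- rep_len(residual_sd, n_skills)
  if (any(random_sd_intercept < 0) || any(random_sd_slope < 0)) {
    stop("random-effect SDs must be nonnegative")
  }
  if (any(residual_sd < 0)) stop("residual_sd must be nonnegative")
  structure(
    list(n_skills = as.integer(n_skills), fixed_edges = fixed_edges,
         intercept_means = intercept_means,
         random_sd_intercept = random_sd_intercept,
         random_sd_slope = random_sd_slope, residual_sd = residual_sd,
         likert_min = as.integer(likert_min),
         likert_max = as.integer(likert_max)),
    class = "population_network_spec"
  )
}

# sparse positive population network mirroring the qualitative skills-network
# profile of SDM consultations: eliciting preferences (skill 6) is the most
# strongly influenced hub, sharing (2) and deliberating (7) exert the most
# influence on other skills, planning (9) is a sink, and the focusing/sharing
# pair (1-2) forms a strongly interrelated block at the periphery
default_fixed_edges <- function() {
  B <- matrix(0, 9, 9)
  edges <- rbind(
    c(1, 2, 0.25), c(2, 1, 0.35),             # focusing <-> sharing pair
    c(2, 7, 0.25),                            # sharing feeds deliberation
    c(3, 4, 0.25), c(3, 6, 0.20),             # presenting options -> informing, preferences
    c(4, 5, 0.20), c(4, 6, 0.25),             # informing -> comprehension, preferences
    c(5, 9, 0.15),                            # comprehension supports planning
    c(6, 7, 0.30), c(6, 8, 0.25),             # preferences drive deliberation/selection
    c(7, 6, 0.30), c(7, 8, 0.30),             # deliberation feeds back and selects
    c(8, 6, 0.25), c(8, 9, 0.25)              # selection reflects preferences, plans
  )
  B[edges[, 1:2]] <- edges[, 3]
  B
}

#' Study design of a simulated competence-measurement study
#'
#' Default sizes follow the reference design for this kind of study: about
#' thirty physicians, ten patient-reported consultations per physician, three
#' audio-recorded consultations rated by two observers each. The
#' self-reported and recorded consultations are drawn independently; the two
#' subsamples need not coincide.
#'
#' @param n_physicians number of physicians.
#' @param patients_per_physician SDM-Q-9 ratings per physician.
#' @param recorded_consultations_per_physician recorded consultations per
#'   physician available for observer rating.
#' @param raters_per_consultation observers coding each recording.
#' @param seed master integer seed for the whole simulation.
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_physicians = 29, patients_per_physician = 10,
                         recorded_consultations_per_physician = 3,
                         raters_per_consultation = 2, seed = 1) {
  for (nm in c("n_physicians", "patients_per_physician",
               "recorded_consultations_per_physician",
               "raters_per_consultation")) {
    assert_scalar_count(get(nm), nm)
  }
  structure(
    list(n_physicians = as.integer(n_physicians),
         patients_per_physician = as.integer(patients_per_physician),
         recorded_consultations_per_physician =
           as.integer(recorded_consultations_per_physician),
         raters_per_consultation = as.integer(raters_per_consultation),
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Variance components of simulated observer ratings
#'
#' Item scores are generated as the competence location plus independent
#' Gaussian physician, consultation, rater and residual effects. Variances
#' are specified on the 0-100 rescaled composite scale (the scale on which
#' competence is analysed); the generator converts them to the item scale
#' internally, drawing each component independently per item, so the
#' per-rater composite carries exactly the specified variances (up to
#' discretization) and the physician-level intraclass correlation of the
#' generator is exactly `var_physician / (var_physician + var_consultation
#' + var_rater + var_residual)` -- with any true-competence spread across
#' physicians adding to the physician-level share.
#'
#' @param var_physician,var_consultation,var_rater,var_residual nonnegative
#'   variances on the 0-100 composite scale.
#' @return an object of class `observer_noise_spec` with the implied
#'   physician-level `icc` attached (competence spread not included).
#' @export
#' @examples
#' observer_noise_spec(1, 0.5, 0.2, 0.3)$icc # 0.5
observer_noise_spec <- function(var_physician, var_consultation,
                                var_rater, var_residual) {
  v <- c(var_physician, var_consultation, var_rater, var_residual)
  if (any(v < 0) || sum(v) <= 0) {
    stop("variances must be nonnegative with positive total")
  }
  structure(
    list(var_physician = var_physician, var_consultation = var_consultation,
         var_rater = var_rater, var_residual = var_residual,
         icc = var_physician / sum(v)),
    class = "observer_noise_spec"
  )
}

#' Calibrate observer noise to target ICC and inter-rater reliability
#'
#' Solves for the four variance components that yield a given physician-level
#' intraclass correlation and a given physician-level inter-rater reliability
#' of the mean of `n_consultations` consultations rated by `n_raters` random
#' raters, at a given total variance. The split between rater and residual
#' variance is controlled by `rater_share` (rater main-effect share of the
#' rater + residual variance).
#'
#' @param icc target physician-level intraclass correlation (default 0.40).
#' @param irr target random-rater reliability of the physician mean
#'   (default 0.72).
#' @param total_var total variance on the 0-100 composite scale; ignored
#'   when `var_physician` is given.
#' @param var_physician optional physician-level variance; when given, the
#'   total is derived as `var_physician / icc` (useful when the physician
#'   share is produced by a known true-competence spread).
#' @param n_consultations,n_raters design the reliability refers to.
#' @param rater_share share of rater main-effect variance within the
#'   rater + residual block (default 0.25).
#' @return an [observer_noise_spec()].
#' @export
#' @examples
#' ns <- calibrate_observer_noise(icc = 0.4, irr = 0.72)
#' ns$icc
calibrate_observer_noise <- function(icc = 0.40, irr = 0.72, total_var = 1,
                                     var_physician = NULL,
                                     n_consultations = 3, n_raters = 2,
                                     rater_share = 0.25) {
  stopifnot(icc > 0, icc < 1, irr > icc, irr < 1)
  if (!is.null(var_physician)) total_var <- var_physician / icc
  vp <- icc * total_var
  rest <- total_var - vp
  cc <- n_consultations; kk <- n_raters
  # irr = vp / (vp + vc/c + s/(c k)) with vc + s = rest, s = vr + ve
  target <- vp / irr - vp
  s <- (rest / cc - target) / (1 / cc - 1 / (cc * kk))
  vc <- rest - s
  if (s < 0 || vc < 0) {
    stop("targets are not attainable: need 0 <= rater+residual <= total - ",
         "physician variance at this design", call. = FALSE)
  }
  observer_noise_spec(vp, vc, rater_share * s, (1 - rater_share) * s)
}

#' Draw physician-specific network parameters from the population
#'
#' Each physician's intercept vector is drawn `Normal(intercept_means,
#' random_sd_intercept)` and each off-diagonal edge
#' `Normal(fixed_edges[j, k], random_sd_slope[j, k])`. Draws whose edge
#' matrix has spectral radius >= 1 (an unstable simultaneous system) are
#' rejected and redrawn, up to 1000 attempts per physician.
#'
#' True competence per observer instrument is a documented deterministic
#' linear combination of the physician's true node parameters, loading on the
#' parameters of skill 6 (eliciting preferences):
#' `competence = base + scale * (d_activation + d_outstrength + d_instrength)`
#' where the `d` terms are the deviations of the skill-6 activation,
#' outstrength and instrength from their population values.
#'
#' @param spec a [population_network_spec()].
#' @param design a [study_design()]; its `seed` drives the draws.
#' @param competence_rule list with `base` (named per-instrument intercepts
#'   on the 0-100 scale), `scale` (per-instrument slope on the combined
#'   skill deviation) and `skill` (the loading skill index).
#' @return list of `physician_truth` records, each with `physician_id`,
#'   `intercepts_p`, `edges_p` and `competence_true`.
#' @export
draw_physician_parameters <- function(spec, design,
                                      competence_rule = default_competence_rule()) {
  stopifnot(inherits(spec, "population_network_spec"),
            inherits(design, "study_design"))
  k <- spec$n_skills
  set.seed(derive_seed(design$seed, "physician_parameters"))
  pop <- truth_node_summary(spec$intercept_means, spec$fixed_edges)
  lapply(seq_len(design$n_physicians), function(p) {
    for (attempt in seq_len(1000)) {
      alpha <- rnorm(k, spec$intercept_means, spec$random_sd_intercept)
      B <- matrix(rnorm(k * k, spec$fixed_edges, spec$random_sd_slope), k, k)
      diag(B) <- 0
      if (max(Mod(eigen(B, only.values = TRUE)$values)) < 1) break
      if (attempt == 1000) {
        stop("rejection cap exceeded: the population spec implies an ",
             "unstable simultaneous system (spectral radius >= 1)",
             call. = FALSE)
      }
    }
    own <- truth_node_summary(alpha, B)
    s6 <- competence_rule$skill
    g <- (own$activation[s6] - pop$activation[s6]) +
      (own$outstrength[s6] - pop$outstrength[s6]) +
      (own$instrength[s6] - pop$instrength[s6])
    structure(
      list(physician_id = sprintf("phys_%02d", p),
           intercepts_p = alpha, edges_p = B,
           competence_true = competence_rule$base + competence_rule$scale * g),
      class = "physician_truth"
    )
  })
}

# Monte-Carlo-calibrated SD of the combined skill-6 deviation g under the
# default population spec (4000 physicians); fixed calibration constant so
# the default competence spread hits the target physician-level SDs below.
.g_sd <- 0.99

#' @rdname draw_physician_parameters
#' @details `default_competence_rule()` sets per-instrument baselines of 16,
#'   12 and 33 competence points (typical sample means of the three
#'   instruments in routine primary/specialty care) and scales the combined
#'   skill-6 deviation so the physician-level competence SD is about 6.4,
#'   8.3 and 4.5 points for OPTION-12, OPTION-5 and the 4HCS subscale
#'   respectively -- the outcome spreads a prediction model at this study
#'   scale has to work with.
#' @export
default_competence_rule <- function() {
  target_sd <- c("OPTION-12" = 6.4, "OPTION-5" = 8.3,
                 "4HCS-InvestInTheEnd" = 4.5)
  list(base = c("OPTION-12" = 16, "OPTION-5" = 12, "4HCS-InvestInTheEnd" = 33),
       scale = target_sd / .g_sd,
       target_sd = target_sd,
       skill = 6L)
}

#' Default observer noise per instrument
#'
#' Calibrated so that, combined with the true-competence spread implied by
#' [default_competence_rule()], the generator's physician-level intraclass
#' correlation is about `icc` and the reliability of the physician mean is
#' about `irr` at the given design: the physician-level variance share is
#' supplied entirely by the competence spread (`var_physician = 0` in the
#' noise spec) and the consultation, rater and residual components are
#' solved from the targets.
#'
#' @inheritParams calibrate_observer_noise
#' @param competence_rule the competence rule supplying per-instrument
#'   spread.
#' @param instruments instrument specs; used to discount the known
#'   variance added by integer discretization (rounding adds about 1/12 on
#'   the item scale, i.e. `(1/12) / n_items * (100 / range)^2` composite
#'   points) from the solved residual component, so the targets refer to the
#'   observable discretized scores.
#' @return named list of [observer_noise_spec()]s.
#' @export
default_observer_noise <- function(icc = 0.40, irr = 0.72,
                                   n_consultations = 3, n_raters = 2,
                                   competence_rule = default_competence_rule(),
                                   instruments = sdm_instruments()) {
  inames <- vapply(instruments, `[[`, "", "name")
  out <- lapply(names(competence_rule$target_sd), function(inst) {
    v_comp <- competence_rule$target_sd[[inst]]^2
    ns <- calibrate_observer_noise(icc = icc, irr = irr,
                                   var_physician = v_comp,
                                   n_consultations = n_consultations,
                                   n_raters = n_raters)
    spec <- instruments[[match(inst, inames)]]
    v_disc <- (1 / 12) / spec$n_items *
      (100 / (spec$item_max - spec$item_min))^2
    observer_noise_spec(0, ns$var_consultation, ns$var_rater,
                        max(ns$var_residual - v_disc, 0))
  })
  setNames(out, names(competence_rule$target_sd))
}

# reduced-form mean and strength sums for one parameter set
truth_node_summary <- function(alpha, B) {
  k <- length(alpha)
  activation <- solve(diag(k) - t(B), alpha)
  list(activation = as.numeric(activation),
       outstrength = rowSums(B), instrength = colSums(B))
}

#' Simulate patient-reported SDM-Q-9 ratings
#'
#' One consultation draws independent residuals per skill, solves the
#' physician's simultaneous system for the latent item vector and
#' discretizes (round half away from zero, clip to the Likert range).
#'
#' @param truths list of `physician_truth` records from
#'   [draw_physician_parameters()].
#' @param spec the [population_network_spec()] used to draw `truths`.
#' @param design a [study_design()].
#' @param discretize round half away from zero and clip to the Likert range
#'   (default). `FALSE` returns the continuous latent item values, useful
#'   for checking the generator against closed-form moments.
#' @return `data.frame` with `physician_id`, `patient_id` and
#'   `item_1..item_k` columns (integer when discretized).
#' @export
simulate_patient_ratings <- function(truths, spec, design, discretize = TRUE) {
  stopifnot(length(truths) > 0)
  k <- spec$n_skills
  set.seed(derive_seed(design$seed, "patient_ratings"))
  rows <- lapply(truths, function(tr) {
    IB <- diag(k) - t(tr$edges_p)
    if (abs(det(IB)) < 1e-12) {
      stop("singular (I - B) for ", tr$physician_id, call. = FALSE)
    }
    n <- design$patients_per_physician
    eps <- matrix(rnorm(n * k, 0, rep(spec$residual_sd, each = n)), n, k)
    latent <- t(solve(IB, t(eps + matrix(tr$intercepts_p, n, k, byrow = TRUE))))
    scores <- if (discretize) {
      clip(round_half_away(latent), spec$likert_min, spec$likert_max)
    } else latent
    out <- data.frame(physician_id = tr$physician_id,
                      patient_id = sprintf("%s_pat_%03d", tr$physician_id,
                                           seq_len(n)))
    out[item_cols(k)] <- as.data.frame(scores)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (discretize) out[item_cols(k)] <- lapply(out[item_cols(k)], as.integer)
  out
}

#' Simulate observer ratings of recorded consultations
#'
#' Item scores are the instrument-scale location of the physician's true
#' competence plus independent physician, consultation, rater and residual
#' Gaussian effects (see [observer_noise_spec()]), discretized to the
#' instrument's integer item range. Physician effects are shared across all
#' of a physician's consultations; rater effects are main effects of the
#' globally identified raters (rater `r1` is the same person everywhere).
#'
#' @param truths list of `physician_truth` records.
#' @param noise an [observer_noise_spec()], or a named list of one spec per
#'   instrument.
#' @param design a [study_design()].
#' @param instruments list of [instrument_spec()]s (default
#'   [sdm_instruments()]).
#' @return `data.frame` with `physician_id`, `consultation_id`, `rater_id`,
#'   `instrument` and `item_1..item_m` columns (`NA` beyond an instrument's
#'   item count).
#' @export
simulate_observer_ratings <- function(truths, noise, design,
                                      instruments = sdm_instruments()) {
  stopifnot(length(truths) > 0)
  if (inherits(noise, "observer_noise_spec")) {
    noise <- setNames(rep(list(noise), length(instruments)),
                      vapply(instruments, `[[`, "", "name"))
  }
  set.seed(derive_seed(design$seed, "observer_ratings"))
  n_items_max <- max(vapply(instruments, `[[`, 1L, "n_items"))
  nc <- design$recorded_consultations_per_physician
  nr <- design$raters_per_consultation
  np <- length(truths)
  ids <- vapply(truths, `[[`, "", "physician_id")
  blocks <- lapply(instruments, function(inst) {
    ns <- noise[[inst$name]]
    if (is.null(ns)) stop("no noise spec for instrument ", inst$name)
    m <- inst$n_items
    comp <- vapply(truths, function(tr) {
      v <- tr$competence_true[[inst$name]]
      if (is.null(v)) stop("truth record lacks competence for ", inst$name)
      v
    }, numeric(1))
    loc <- inst$item_min + comp / 100 * (inst$item_max - inst$item_min)
    # composite-scale variances -> per-item variances: the composite is the
    # rescaled mean of m independent item effects, so v_item = v * m * (R/100)^2
    f <- m * ((inst$item_max - inst$item_min) / 100)^2
    # one row per (physician, consultation, rater); effects drawn per item
    p_ix <- rep(seq_len(np), each = nc * nr)
    c_ix <- rep(rep(seq_len(nc), each = nr), np)
    pc_ix <- (p_ix - 1L) * nc + c_ix
    r_ix <- rep_len(seq_len(nr), np * nc * nr)
    n <- length(p_ix)
    phys_eff <- matrix(rnorm(np * m, 0, sqrt(f * ns$var_physician)), np, m)
    cons_eff <- matrix(rnorm(np * nc * m, 0, sqrt(f * ns$var_consultation)),
                       np * nc, m)
    rater_eff <- matrix(rnorm(nr * m, 0, sqrt(f * ns$var_rater)), nr, m)
    resid <- matrix(rnorm(n * m, 0, sqrt(f * ns$var_residual)), n, m)
    raw <- loc[p_ix] + phys_eff[p_ix, , drop = FALSE] +
      cons_eff[pc_ix, , drop = FALSE] + rater_eff[r_ix, , drop = FALSE] +
      resid
    scores <- clip(round_half_away(raw), inst$item_min, inst$item_max)
    out <- data.frame(
      physician_id = ids[p_ix],
      consultation_id = sprintf("%s_cons_%02d", ids[p_ix], c_ix),
      rater_id = sprintf("r%d", r_ix),
      instrument = inst$name
    )
    out[item_cols(m)] <- as.data.frame(matrix(as.integer(scores), n, m))
    if (m < n_items_max) {
      out[paste0("item_", (m + 1):n_items_max)] <- NA_integer_
    }
    out
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Ground-truth node parameters of simulated physicians
#'
#' Activation is the reduced-form mean of the simultaneous system,
#' `(I - t(B_p))^-1 alpha_p`; outstrength and instrength are row and column
#' sums of the physician's edge matrix with every nonzero edge retained
#' (truth is treated as certain, so the downstream retention rule keeps all
#' true edges).
#'
#' @param truths list of `physician_truth` records.
#' @return long `data.frame`: `physician_id`, `skill`, `activation`,
#'   `outstrength`, `instrength`.
#' @export
true_node_parameters <- function(truths) {
  stopifnot(length(truths) > 0)
  out <- do.call(rbind, lapply(truths, function(tr) {
    s <- truth_node_summary(tr$intercepts_p, tr$edges_p)
    data.frame(physician_id = tr$physician_id,
               skill = seq_along(tr$intercepts_p),
               activation = s$activation, outstrength = s$outstrength,
               instrength = s$instrength)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a complete competence-measurement study
#'
#' Convenience wrapper drawing physician truths, patient ratings and
#' observer ratings under one master seed.
#'
#' @inheritParams draw_physician_parameters
#' @inheritParams simulate_observer_ratings
#' @return list with `truths`, `patient_ratings`, `observer_ratings`,
#'   `true_parameters`, and the specs used.
#' @export
#' @examples
#' sim <- simulate_study(design = study_design(n_physicians = 4, seed = 7))
#' head(sim$patient_ratings)
simulate_study <- function(spec = population_network_spec(),
                           design = study_design(),
                           noise = default_observer_noise(
                             n_consultations =
                               design$recorded_consultations_per_physician,
                             n_raters = design$raters_per_consultation,
                             competence_rule = competence_rule),
                           instruments = sdm_instruments(),
                           competence_rule = default_competence_rule()) {
  truths <- draw_physician_parameters(spec, design, competence_rule)
  list(truths = truths,
       patient_ratings = simulate_patient_ratings(truths, spec, design),
       observer_ratings = simulate_observer_ratings(truths, noise, design,
                                                    instruments),
       true_parameters = true_node_parameters(truths),
       spec = spec, design = design, noise = noise,
       instruments = instruments)
}
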