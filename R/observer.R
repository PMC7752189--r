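#' Observer instrument specification
#'
#' Item count and item range of an observer-rated SDM coding instrument.
#' Defaults for the three instruments used throughout the package ship via
#' [sdm_instruments()]; counts and ranges are configurable because published
#' versions of the instruments vary.
#'
#' @param name instrument label.
#' @param n_items number of items.
#' @param item_min,item_max integer item range.
#' @return object of class `instrument_spec`.
#' @export
#' @examples
#' instrument_spec("OPTION-12", 12, 0, 4)
instrument_spec <- function(name, n_items, item_min, item_max) {
  assert_scalar_count(n_items, "n_items")
  if (item_min >= item_max) stop("item_min must be < item_max")
  structure(list(name = name, n_items = as.integer(n_items),
                 item_min = as.integer(item_min),
                 item_max = as.integer(item_max)),
            class = "instrument_spec")
}

#' @rdname instrument_spec
#' @details `sdm_instruments()` returns the default battery: OPTION-12
#'   (12 items, 0-4), OPTION-5 (5 items, 0-4) and the 'Invest in the End'
#'   subscale of the Four Habits Coding Scheme (6 items, 1-5).
#' @export
sdm_instruments <- function() {
  list(instrument_spec("OPTION-12", 12, 0, 4),
       instrument_spec("OPTION-5", 5, 0, 4),
       instrument_spec("4HCS-InvestInTheEnd", 6, 1, 5))
}

#' Unweighted composite score of one rating record
#'
#' Competence instruments are scored under a formative model: the composite
#' is the unweighted arithmetic mean of the items.
#'
#' @param items integer item vector (length `spec$n_items`).
#' @param spec an [instrument_spec()].
#' @return the mean item score on the instrument's item scale.
#' @export
composite_score <- function(items, spec) {
  items <- items[seq_len(spec$n_items)]
  if (anyNA(items)) {
    stop("incomplete rating record: missing item score", call. = FALSE)
  }
  if (any(items < spec$item_min | items > spec$item_max)) {
    stop("item score outside the instrument range", call. = FALSE)
  }
  mean(items)
}

#' Rescale a composite to the 0-100 competence scale
#'
#' @param raw composite on the item scale.
#' @param spec an [instrument_spec()].
#' @return `100 * (raw - item_min) / (item_max - item_min)`.
#' @export
#' @examples
#' rescale_to_0_100(2, instrument_spec("x", 5, 0, 4)) # 50
rescale_to_0_100 <- function(raw, spec) {
  if (any(raw < spec$item_min | raw > spec$item_max)) {
    stop("raw score outside the instrument range", call. = FALSE)
  }
  100 * (raw - spec$item_min) / (spec$item_max - spec$item_min)
}

# per-rater rescaled composite scores: one row per (physician, consultation,
# rater) and instrument; incomplete records are dropped listwise with a log
rater_composites <- function(table, instruments, verbose = FALSE) {
  out <- list()
  for (inst in instruments) {
    sub <- table[table$instrument == inst$name, , drop = FALSE]
    if (nrow(sub) == 0) next
    it <- as.matrix(sub[item_cols(inst$n_items)])
    complete <- stats::complete.cases(it)
    if (any(!complete)) {
      msg("%s: dropped %d incomplete rating record(s)", inst$name,
          sum(!complete), verbose = verbose)
    }
    sub <- sub[complete, , drop = FALSE]
    it <- it[complete, , drop = FALSE]
    if (nrow(sub) == 0) next
    if (any(it < inst$item_min | it > inst$item_max)) {
      stop("item scores outside range for instrument ", inst$name,
           call. = FALSE)
    }
    out[[inst$name]] <- data.frame(
      physician_id = sub$physician_id,
      consultation_id = sub$consultation_id,
      rater_id = sub$rater_id,
      instrument = inst$name,
      score = rescale_to_0_100(rowMeans(it), inst)
    )
  }
  if (length(out) == 0) return(NULL)
  out <- do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Physician-level competence scores from observer ratings
#'
#' Per consultation the rescaled rater composites are averaged; per
#' physician the consultation means are averaged. Physicians without any
#' complete observer record are omitted, not imputed. The result is
#' invariant to row order and rater relabelling.
#'
#' @param table observer-rating table: `physician_id`, `consultation_id`,
#'   `rater_id`, `instrument`, `item_1..item_m`.
#' @param instruments list of [instrument_spec()]s (default
#'   [sdm_instruments()]).
#' @param verbose log dropped-record counts.
#' @return `data.frame`: `physician_id`, `instrument`, `score` (0-100),
#'   `n_consultations`, `n_raters`.
#' @export
physician_competence <- function(table, instruments = sdm_instruments(),
                                 verbose = FALSE) {
  rc <- rater_composites(table, instruments, verbose = verbose)
  if (is.null(rc) || nrow(rc) == 0) {
    return(data.frame(physician_id = character(), instrument = character(),
                      score = numeric(), n_consultations = integer(),
                      n_raters = integer()))
  }
  cons <- aggregate(score ~ instrument + physician_id + consultation_id,
                    data = rc, FUN = mean)
  phys <- aggregate(score ~ instrument + physician_id, data = cons,
                    FUN = mean)
  ncons <- aggregate(consultation_id ~ instrument + physician_id, data = cons,
                     FUN = length)
  nrat <- aggregate(rater_id ~ instrument + physician_id, data = rc,
                    FUN = function(x) length(unique(x)))
  out <- merge(merge(phys, ncons, by = c("instrument", "physician_id")),
               nrat, by = c("instrument", "physician_id"))
  names(out)[names(out) == "consultation_id"] <- "n_consultations"
  names(out)[names(out) == "rater_id"] <- "n_raters"
  out <- out[c("physician_id", "instrument", "score", "n_consultations",
               "n_raters")]
  out <- out[order(out$instrument, out$physician_id), ]
  rownames(out) <- NULL
  out
}

#' Multilevel variance decomposition of observer composites
#'
#' REML fit of the nested Gaussian model
#' `score ~ 1 + (1 | physician) + (1 | physician:consultation)` on per-rater
#' rescaled composites, per instrument. The physician-level intraclass
#' correlation is the physician variance share of the total. Zero-variance
#' data (all composites identical) is flagged rather than estimated.
#'
#' @inheritParams physician_competence
#' @return `data.frame`: `instrument`, `var_physician`, `var_consultation`,
#'   `var_residual`, `icc`, `zero_variance`.
#' @export
variance_decomposition <- function(table, instruments = sdm_instruments(),
                                   verbose = FALSE) {
  rc <- rater_composites(table, instruments, verbose = verbose)
  if (is.null(rc) || nrow(rc) == 0) stop("no complete observer records")
  out <- lapply(split(rc, rc$instrument), function(d) {
    if (length(unique(d$physician_id)) < 2) {
      stop("variance decomposition needs >= 2 physicians", call. = FALSE)
    }
    if (var(d$score) < .Machine$double.eps) {
      return(data.frame(instrument = d$instrument[1], var_physician = 0,
                        var_consultation = 0, var_residual = 0,
                        icc = NA_real_, zero_variance = TRUE))
    }
    fit <- suppressMessages(lme4::lmer(
      score ~ 1 + (1 | physician_id) + (1 | physician_id:consultation_id),
      data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- setNames(pmax(vc$vcov, 0), vc$grp)
    vp <- unname(v["physician_id"])
    vcons <- unname(v["physician_id:consultation_id"])
    ve <- unname(v["Residual"])
    data.frame(instrument = d$instrument[1], var_physician = vp,
               var_consultation = vcons, var_residual = ve,
               icc = vp / (vp + vcons + ve), zero_variance = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Physician-level inter-rater reliability
#'
#' Variance components are estimated by REML from the three-level crossed
#' model `score ~ 1 + (1 | physician) + (1 | physician:consultation) +
#' (1 | rater)` on per-rater rescaled composites. The reliability of the
#' physician-level mean of `c` consultations each rated by `k` raters is the
#' Spearman-Brown-style composite
#' `var_p / (var_p + var_c / c + (var_r * random + var_e) / (c k))`,
#' reported in both a random-rater variant (`random = 1`: raters are a sample
#' from a rater population) and a fixed-rater variant (`random = 0`: the same
#' raters are used throughout, so rater main effects do not add error).
#'
#' @inheritParams physician_competence
#' @param n_consultations,n_raters the design the reliability refers to;
#'   default to the observed mean number of consultations per physician and
#'   raters per consultation.
#' @return `data.frame`: `instrument`, the four variance components,
#'   `n_consultations`, `n_raters`, `reliability_random`,
#'   `reliability_fixed`.
#' @export
interrater_reliability <- function(table, instruments = sdm_instruments(),
                                   n_consultations = NULL, n_raters = NULL,
                                   verbose = FALSE) {
  rc <- rater_composites(table, instruments, verbose = verbose)
  if (is.null(rc) || nrow(rc) == 0) stop("no complete observer records")
  out <- lapply(split(rc, rc$instrument), function(d) {
    per_cons <- tapply(d$rater_id, d$consultation_id,
                       function(x) length(unique(x)))
    if (max(per_cons) < 2) {
      stop("inter-rater reliability needs >= 2 raters for some ",
           "consultations", call. = FALSE)
    }
    cc <- n_consultations %||%
      mean(tapply(d$consultation_id, d$physician_id,
                  function(x) length(unique(x))))
    kk <- n_raters %||% mean(per_cons)
    within_var <- tapply(d$score, d$physician_id, var)
    if (max(within_var, na.rm = TRUE) < 1e-8) {
      # perfect within-physician agreement: all variance is physician-level,
      # reliability 1 by construction (REML would be degenerate here)
      return(data.frame(instrument = d$instrument[1],
                        var_physician = var(tapply(d$score, d$physician_id,
                                                   mean)),
                        var_consultation = 0, var_rater = 0, var_residual = 0,
                        n_consultations = cc, n_raters = kk,
                        reliability_random = 1, reliability_fixed = 1))
    }
    fit <- suppressMessages(lme4::lmer(
      score ~ 1 + (1 | physician_id) + (1 | physician_id:consultation_id) +
        (1 | rater_id),
      data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- setNames(pmax(vc$vcov, 0), vc$grp)
    vp <- unname(v["physician_id"])
    vcons <- unname(v["physician_id:consultation_id"])
    vr <- unname(v["rater_id"])
    ve <- unname(v["Residual"])
    rel <- function(random) {
      denom <- vp + vcons / cc + (vr * random + ve) / (cc * kk)
      if (denom <= 0) return(NA_real_)
      vp / denom
    }
    data.frame(instrument = d$instrument[1], var_physician = vp,
               var_consultation = vcons, var_rater = vr, var_residual = ve,
               n_consultations = cc, n_raters = kk,
               reliability_random = rel(1), reliability_fixed = rel(0))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
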