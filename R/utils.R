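#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from one integer seed. Independent
#' stages (physician draws, patient ratings, observer ratings, MCMC chains,
#' layout) derive their own seed deterministically from the master seed and a
#' stream label, so that adding draws to one stage never perturbs another.
#'
#' The derivation is a fixed integer hash of the label mixed with the seed by
#' a Lehmer-style step modulo 2^31 - 1; it is reproducible across platforms
#' and keeps every derived seed in the 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param stream character label of the consuming stage.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "patient_ratings")
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% m
  s <- (abs(as.numeric(seed)) %% m)
  out <- (48271 * ((s + h) %% 44488)) %% m # Lehmer step keeps products < 2^53
  out <- (out + 7 * h + s) %% m
  as.integer(out %% (m - 2) + 1)
}

#' Adjusted coefficient of determination
#'
#' The small-sample correction `1 - (1 - R^2) (n - 1) / (n - p - 1)` applied
#' to a coefficient of determination from a regression with `p` predictors
#' fitted to `n` observations. Used per posterior draw when summarising
#' prediction models, and directly as a worked-example check against
#' published fit statistics.
#'
#' @param r_squared coefficient of determination in `[0, 1]` (vectorised).
#' @param n number of observations.
#' @param p number of predictors (excluding the intercept).
#' @return adjusted R-squared (can be negative).
#' @export
#' @examples
#' adjusted_r_squared(0.510, n = 22, p = 9) # 0.143 to 3 dp
adjusted_r_squared <- function(r_squared, n, p) {
  stopifnot(n > p + 1)
  1 - (1 - r_squared) * (n - 1) / (n - p - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}

#' @noRd
assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a single count >= 1", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

# item column names for a k-item instrument / questionnaire
item_cols <- function(k) paste0("item_", seq_len(k))

# round half away from zero, the discretization used for all simulated
# Likert scores (base round() rounds half to even, which would make the
# documented noise-free fixed points depend on parity)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
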