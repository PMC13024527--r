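# Sample-size calculators for planning the clinical evaluation of a
# diagnostic AI: the single-arm target-value design (observed accuracy vs a
# pre-specified minimum acceptable threshold) and the diagnostic-accuracy
# design (precision of a sensitivity or specificity estimate), plus the
# dropout adjustment.

round_half_up <- function(x) floor(x + 0.5)

z_quantile <- function(p, use_text_constants = FALSE) {
  if (!use_text_constants) return(stats::qnorm(p))
  # the 2-3 digit constants conventionally printed in protocol documents
  if (isTRUE(all.equal(p, 0.975))) return(1.96)
  if (isTRUE(all.equal(p, 0.8))) return(0.842)
  stats::qnorm(p)
}

#' Single-arm target-value sample size
#'
#' Per-group size for testing an expected accuracy `PT` against a minimum
#' acceptable accuracy `P0`:
#' `n = [z_{1-a/2} sqrt(P0(1-P0)) + z_{1-b} sqrt(PT(1-PT))]^2 / (PT-P0)^2`,
#' rounded half-up to an integer (use `ceil = TRUE` for the conservative
#' ceiling convention).
#'
#' @param PT expected accuracy, in (0, 1).
#' @param P0 minimum acceptable accuracy, in (0, 1); must differ from `PT`.
#' @param alpha two-sided type-I error rate.
#' @param beta type-II error rate (power = 1 - beta).
#' @param use_text_constants use the rounded normal quantiles 1.96 / 0.842
#'   instead of exact ones (the results agree on typical inputs).
#' @param ceil round up instead of half-up.
#' @return integer per-group sample size.
#' @export
single_arm_n <- function(PT, P0, alpha = 0.05, beta = 0.2,
                         use_text_constants = FALSE, ceil = FALSE) {
  stopifnot(PT > 0, PT < 1, P0 > 0, P0 < 1,
            alpha > 0, alpha < 0.5, beta > 0, beta < 0.5)
  if (PT == P0) stop("single_arm_n: PT and P0 must differ")
  za <- z_quantile(1 - alpha / 2, use_text_constants)
  zb <- z_quantile(1 - beta, use_text_constants)
  n <- (za * sqrt(P0 * (1 - P0)) + zb * sqrt(PT * (1 - PT)))^2 / (PT - P0)^2
  as.integer(if (ceil) ceiling(n) else round_half_up(n))
}

#' Diagnostic-accuracy sample size
#'
#' Per-group size needed to estimate a sensitivity (positive group) or
#' specificity (negative group) `P` to within a half-confidence-interval
#' width `delta`: `n = P(1-P) z_{1-a/2}^2 / delta^2`, rounded half-up.
#' `delta` is conventionally chosen in 0.05-0.10.
#'
#' @param P expected sensitivity or specificity, in (0, 1).
#' @param delta allowable margin of error (half CI width), > 0.
#' @inheritParams single_arm_n
#' @return integer per-group sample size.
#' @export
diagnostic_n <- function(P, delta = 0.05, alpha = 0.05,
                         use_text_constants = FALSE, ceil = FALSE) {
  stopifnot(P > 0, P < 1, alpha > 0, alpha < 0.5)
  if (delta <= 0) stop("diagnostic_n: delta must be positive")
  za <- z_quantile(1 - alpha / 2, use_text_constants)
  n <- P * (1 - P) * za^2 / delta^2
  as.integer(if (ceil) ceiling(n) else round_half_up(n))
}

#' Dropout adjustment
#'
#' Inflates a computed sample size for an anticipated dropout fraction:
#' `round(n / (1 - dropout))`, half-up.
#'
#' @param n unadjusted per-group size.
#' @param dropout anticipated dropout fraction in `[0, 1)`.
#' @inheritParams single_arm_n
#' @return adjusted integer sample size.
#' @export
adjust_for_dropout <- function(n, dropout, ceil = FALSE) {
  if (dropout < 0 || dropout >= 1)
    stop("adjust_for_dropout: dropout must lie in [0, 1)")
  x <- n / (1 - dropout)
  as.integer(if (ceil) ceiling(x) else round_half_up(x))
}
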