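#' Glycemic reward functions
#'
#' Four per-sample scores of a CGM reading (mg/dL), used as reinforcement
#' signals for the insulin controller. All are bounded and finite for any
#' finite input; all are vectorised.
#'
#' * `bump_score()`: the smooth bump `exp(-1 / (1 - x^2))` with
#'   `x = (CGM - 90)/45 - 1`, supported on 90 < CGM < 180 and 0 elsewhere
#'   (including both endpoints, where the exponent diverges); peak value
#'   `exp(-1)` at 135 mg/dL.
#' * `piecewise_score()`: -1 below 70, +1 in `[70, 180]`, 0 above 180.
#' * `cosine_score()`: `-cos(CGM / 45)` for 0 < CGM < 300, -1 elsewhere
#'   (continuous at 0, where `-cos(0) = -1`).
#' * `mexican_hat_score()`: the Ricker wavelet
#'   `(2/sqrt(3)) * pi^(-1/4) * (1 - z^2) * exp(-z^2/2)` with
#'   `z = (CGM - 140)/140`; peak `(2/sqrt(3)) * pi^(-1/4)` at 140 mg/dL,
#'   zero-crossings at 0 and 280.
#'
#' @param cgm CGM reading(s), mg/dL; must be finite.
#' @return numeric score(s).
#' @name reward_functions
NULL

check_finite_cgm <- function(cgm) {
  if (!all(is.finite(cgm))) stop("CGM values must be finite")
  cgm
}

#' @rdname reward_functions
#' @export
bump_score <- function(cgm) {
  check_finite_cgm(cgm)
  x <- (cgm - 90) / 45 - 1
  out <- numeric(length(cgm))
  inside <- cgm > 90 & cgm < 180
  out[inside] <- exp(-1 / (1 - x[inside]^2))
  out
}

#' @rdname reward_functions
#' @export
piecewise_score <- function(cgm) {
  check_finite_cgm(cgm)
  ifelse(cgm < 70, -1, ifelse(cgm <= 180, 1, 0))
}

#' @rdname reward_functions
#' @export
cosine_score <- function(cgm) {
  check_finite_cgm(cgm)
  ifelse(cgm > 0 & cgm < 300, -cos(cgm / 45), -1)
}

#' @rdname reward_functions
#' @export
mexican_hat_score <- function(cgm) {
  check_finite_cgm(cgm)
  z <- (cgm - 140) / 140
  (2 / sqrt(3)) * pi^(-1 / 4) * (1 - z^2) * exp(-z^2 / 2)
}

#' Look up a reward function by name
#'
#' @param kind one of `"bump"`, `"piecewise"`, `"cosine"`, `"mexican_hat"`.
#' @return the scoring function.
#' @export
reward_function <- function(kind = c("bump", "piecewise", "cosine", "mexican_hat")) {
  switch(match.arg(kind),
         bump = bump_score,
         piecewise = piecewise_score,
         cosine = cosine_score,
         mexican_hat = mexican_hat_score)
}

#' Episode-level reward
#'
#' The arithmetic mean of the per-sample scores over a simulation,
#' `R = (1/n) * sum(score_i)`.
#'
#' @param scores per-sample scores; must be non-empty.
#' @export
episode_reward <- function(scores) {
  if (length(scores) == 0L) stop("scores must be non-empty")
  mean(scores)
}

#' Legacy one-hour feature extraction
#'
#' The earlier observation design: from 12 CGM samples and 12 insulin values
#' spanning one hour at 5-min spacing, compute the 11 glucose first
#' differences, the same divided by the 5-min sample interval, the 11
#' insulin first differences, and the insulin span `u[12] - u[1]`
#' (34 features in total). The final controller uses the compact
#' two-element observation instead; this extractor is retained for
#' experiments with the richer feature vector.
#'
#' @param cgm12 numeric vector of exactly 12 CGM samples, mg/dL.
#' @param u12 numeric vector of exactly 12 insulin values.
#' @return list with `dG` (11), `dG_dt` (11), `du` (11), `du_span` (1).
#' @export
legacy_features <- function(cgm12, u12) {
  if (length(cgm12) != 12L || length(u12) != 12L) {
    stop("legacy features require exactly 12 CGM and 12 insulin samples")
  }
  dG <- diff(cgm12)
  du <- diff(u12)
  list(dG = dG, dG_dt = dG / 5, du = du, du_span = u12[12] - u12[1])
}
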