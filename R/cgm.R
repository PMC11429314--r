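#' CGM sensor configuration
#'
#' The continuous glucose monitor layer adds (i) an interstitial glucose
#' compartment `IG` relaxing to blood glucose with time constant `tau_ig`
#' (the physiological sensing lag) and (ii) additive AR(2) sensor noise
#' \deqn{v(t) = \alpha_1 v(t - T_s) + \alpha_2 v(t - 2T_s) + w(t), \quad
#'   w \sim N(0, \sigma^2),}
#' sampled on the `ts_min` grid. The reported value is
#' `CGM(t) = max(IG(t) + v(t), 0)`. Sensor drift is deliberately not
#' modelled. Defaults place the AR(2) well inside its stationary region.
#'
#' @param tau_ig interstitial lag time constant, min (> 0).
#' @param alpha1,alpha2 AR(2) coefficients; stationarity
#'   (`|alpha2| < 1`, `alpha2 < 1 - |alpha1|`... i.e. `alpha2 + alpha1 < 1`,
#'   `alpha2 - alpha1 < 1`) is enforced at construction.
#' @param sigma white-noise SD, mg/dL (>= 0; 0 gives a noiseless sensor).
#' @param ts_min sample interval, min.
#' @param enabled if `FALSE` the environment reads true blood glucose.
#' @export
cgm_config <- function(tau_ig = 10, alpha1 = 1.23, alpha2 = -0.3995,
                       sigma = 1.0, ts_min = 5, enabled = TRUE) {
  if (ts_min <= 0) stop("ts_min must be > 0")
  if (tau_ig <= 0) stop("tau_ig must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (!(abs(alpha2) < 1 && alpha1 + alpha2 < 1 && alpha2 - alpha1 < 1)) {
    stop("AR(2) coefficients outside the stationary region")
  }
  structure(list(tau_ig = tau_ig, alpha1 = alpha1, alpha2 = alpha2,
                 sigma = sigma, ts_min = ts_min, enabled = isTRUE(enabled)),
            class = "cgm_config")
}

#' Interstitial glucose lag step
#'
#' Integrates `dIG/dt = (G - IG) / tau_ig` over `dt` minutes holding `G`
#' constant, i.e. the exact first-order response
#' `IG' = G + (IG - G) exp(-dt/tau_ig)`. Inside the closed-loop environment
#' the IG compartment is instead integrated jointly with the patient ODE by
#' the same RK4 scheme (where G varies within the step); this standalone
#' step is the constant-G special case.
#'
#' @param IG current interstitial glucose, mg/dL.
#' @param G blood glucose over the step, mg/dL.
#' @param tau_ig lag time constant, min.
#' @param dt step, min.
#' @export
ig_step <- function(IG, G, tau_ig, dt) {
  if (dt <= 0) stop("dt must be > 0")
  G + (IG - G) * exp(-dt / tau_ig)
}

#' CGM noise state
#'
#' Holds the last two AR(2) noise values.
#'
#' @param v_prev,v_prev2 noise at the previous one/two sample instants, mg/dL.
#' @export
cgm_noise_state <- function(v_prev = 0, v_prev2 = 0) {
  structure(list(v_prev = v_prev, v_prev2 = v_prev2), class = "cgm_noise_state")
}

#' One AR(2) noise draw
#'
#' Advances the sensor noise process by one sample interval using R's global
#' RNG.
#'
#' @param state a [cgm_noise_state()].
#' @param cfg a [cgm_config()].
#' @return list with the new noise value `v` and the updated `state`.
#' @export
ar2_noise_step <- function(state, cfg) {
  w <- if (cfg$sigma > 0) stats::rnorm(1, 0, cfg$sigma) else 0
  v <- cfg$alpha1 * state$v_prev + cfg$alpha2 * state$v_prev2 + w
  list(v = v, state = cgm_noise_state(v_prev = v, v_prev2 = state$v_prev))
}

#' Sensor reading
#'
#' `CGM = IG + v`, floored at 0 mg/dL (a sensor cannot report a negative
#' concentration).
#'
#' @param IG interstitial glucose, mg/dL.
#' @param v additive sensor noise, mg/dL.
#' @export
cgm_reading <- function(IG, v) pmax(IG + v, 0)

#' Stationary moments of the AR(2) sensor noise
#'
#' Closed-form stationary variance and lag-1 autocorrelation,
#' \deqn{Var[v] = \frac{\sigma^2 (1-\alpha_2)}
#'   {(1+\alpha_2)\left((1-\alpha_2)^2 - \alpha_1^2\right)}, \qquad
#'   \rho_1 = \frac{\alpha_1}{1-\alpha_2}.}
#' Used as the analytic reference for the simulated noise process.
#'
#' @param cfg a [cgm_config()].
#' @return named numeric `(variance, rho1)`.
#' @export
ar2_stationary_moments <- function(cfg) {
  a1 <- cfg$alpha1; a2 <- cfg$alpha2
  v <- cfg$sigma^2 * (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
  c(variance = v, rho1 = a1 / (1 - a2))
}
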