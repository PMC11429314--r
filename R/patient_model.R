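#' IVP model state
#'
#' The continuous state of the identifiable virtual patient model: blood
#' glucose `G` (mg/dL), insulin effectiveness `IEFF` (1/min), plasma insulin
#' `IP` (uU/mL), subcutaneous insulin `ISC` (uU/mL), and the simulation clock
#' `t` (min).
#'
#' @param G,IEFF,IP,ISC,t initial values; concentrations must be >= 0.
#' @return a named numeric vector of class `patient_state`.
#' @export
patient_state <- function(G = 120, IEFF = 0, IP = 0, ISC = 0, t = 0) {
  s <- c(G = G, IEFF = IEFF, IP = IP, ISC = ISC, t = t)
  if (!all(is.finite(s))) stop("patient state must be finite")
  if (any(s[c("G", "IEFF", "IP", "ISC")] < 0)) {
    stop("G, IEFF, IP, ISC must be non-negative")
  }
  structure(s, class = c("patient_state", "numeric"))
}

#' Time derivative of the IVP model
#'
#' Right-hand side of the four-compartment glucose-insulin system:
#' \deqn{\dot G = -(GEZI + I_{EFF}) G + EGP + RA(t)}
#' \deqn{\dot I_{EFF} = -p_2 I_{EFF} + p_2 S_I I_P}
#' \deqn{\dot I_P = -(I_P - I_{SC})/\tau_2}
#' \deqn{\dot I_{SC} = -I_{SC}/\tau_1 + u/(\tau_1 C_I)}
#' where `u` is the exogenous insulin infusion in uU/min (see
#' [insulin_Uh_to_uUmin()]) and `RA` the meal glucose appearance in
#' mg/dL/min.
#'
#' @param state a [patient_state()] (only `G`, `IEFF`, `IP`, `ISC` are used).
#' @param p an [ivp_patient()].
#' @param u insulin delivery rate, uU/min; must be >= 0.
#' @param ra glucose appearance, mg/dL/min; must be >= 0.
#' @return named numeric `(dG, dIEFF, dIP, dISC)` in per-minute units.
#' @export
ivp_derivatives <- function(state, p, u = 0, ra = 0) {
  if (!all(is.finite(c(state[1:4], u, ra)))) {
    stop("invalid simulation state: non-finite state or inputs")
  }
  if (u < 0 || ra < 0) stop("u and ra must be non-negative")
  G <- state[["G"]]; IEFF <- state[["IEFF"]]
  IP <- state[["IP"]]; ISC <- state[["ISC"]]
  c(dG    = -(p$GEZI + IEFF) * G + p$EGP + ra,
    dIEFF = -p$p2 * IEFF + p$p2 * p$SI * IP,
    dIP   = -(IP - ISC) / p$tau2,
    dISC  = -ISC / p$tau1 + u / (p$tau1 * p$CI))
}

#' Convert an insulin infusion rate from U/h to uU/min
#'
#' 1 U = 1e6 uU, so `u` U/h equals `u * 1e6 / 60` uU/min. The pump/agent
#' interface speaks U/h; the model equations consume uU/min.
#'
#' @param u_Uh rate in U/h.
#' @export
insulin_Uh_to_uUmin <- function(u_Uh) u_Uh * 1e6 / 60

#' Meal glucose appearance
#'
#' Rate of glucose appearance from a carbohydrate schedule, the sum of gamma
#' kernels
#' \deqn{RA(t) = \sum_k \frac{1000\, d_k}{V_G \tau_D^2} (t - \zeta_k)
#'   e^{-(t-\zeta_k)/\tau_D} \quad (t \ge \zeta_k),}
#' with meal size \eqn{d_k} in grams (converted to mg) so that RA carries
#' mg/dL/min. Each kernel integrates to \eqn{1000 d_k / V_G}: the full meal
#' mass eventually appears in the glucose space. Future meals contribute 0.
#'
#' @param t time(s) in minutes from schedule start; vectorised.
#' @param meals a [meal_schedule()] (data.frame with `t_min`, `grams` and
#'   optionally a per-meal `tauD` column).
#' @param VG glucose distribution volume, dL.
#' @param tauD default absorption time constant, min, for meals without one.
#' @return numeric vector of RA values, mg/dL/min.
#' @export
meal_ra <- function(t, meals, VG, tauD = 40) {
  if (any(t < 0)) stop("t must be >= 0")
  ra <- numeric(length(t))
  if (is.null(meals) || nrow(meals) == 0L) return(ra)
  tD <- if ("tauD" %in% names(meals)) meals$tauD else rep(tauD, nrow(meals))
  for (k in seq_len(nrow(meals))) {
    s <- t - meals$t_min[k]
    on <- s > 0
    ra[on] <- ra[on] +
      (1000 * meals$grams[k] / (VG * tD[k]^2)) * s[on] * exp(-s[on] / tD[k])
  }
  ra
}

# RK4 core over the joint (G, IEFF, IP, ISC, IG) state. `ra_half` holds RA
# sampled on the dt/2 grid starting at t0, length 2*n_steps+1, so substep i
# reads RA at indices 2i-1, 2i, 2i+1. IG relaxes to G with time constant
# tau_ig (Inf disables the sensor compartment). Negative concentrations are
# clamped to 0 after each substep.
rk4_core <- function(G, IEFF, IP, ISC, IG, p, u, ra_half, n_steps, dt, tau_ig = Inf) {
  GEZI <- p$GEZI; EGP <- p$EGP; p2 <- p$p2; SI <- p$SI
  tau1 <- p$tau1; tau2 <- p$tau2
  uin <- u / (tau1 * p$CI)
  kig <- if (is.finite(tau_ig)) 1 / tau_ig else 0
  h <- dt
  for (i in seq_len(n_steps)) {
    ra1 <- ra_half[2L * i - 1L]; ra2 <- ra_half[2L * i]; ra3 <- ra_half[2L * i + 1L]

    dG1 <- -(GEZI + IEFF) * G + EGP + ra1
    dE1 <- p2 * (SI * IP - IEFF)
    dP1 <- (ISC - IP) / tau2
    dS1 <- -ISC / tau1 + uin
    dI1 <- kig * (G - IG)

    G2 <- G + 0.5 * h * dG1; E2 <- IEFF + 0.5 * h * dE1
    P2 <- IP + 0.5 * h * dP1; S2 <- ISC + 0.5 * h * dS1
    I2 <- IG + 0.5 * h * dI1
    dG2 <- -(GEZI + E2) * G2 + EGP + ra2
    dE2 <- p2 * (SI * P2 - E2)
    dP2 <- (S2 - P2) / tau2
    dS2 <- -S2 / tau1 + uin
    dI2 <- kig * (G2 - I2)

    G3 <- G + 0.5 * h * dG2; E3 <- IEFF + 0.5 * h * dE2
    P3 <- IP + 0.5 * h * dP2; S3 <- ISC + 0.5 * h * dS2
    I3 <- IG + 0.5 * h * dI2
    dG3 <- -(GEZI + E3) * G3 + EGP + ra2
    dE3 <- p2 * (SI * P3 - E3)
    dP3 <- (S3 - P3) / tau2
    dS3 <- -S3 / tau1 + uin
    dI3 <- kig * (G3 - I3)

    G4 <- G + h * dG3; E4 <- IEFF + h * dE3
    P4 <- IP + h * dP3; S4 <- ISC + h * dS3
    I4 <- IG + h * dI3
    dG4 <- -(GEZI + E4) * G4 + EGP + ra3
    dE4 <- p2 * (SI * P4 - E4)
    dP4 <- (S4 - P4) / tau2
    dS4 <- -S4 / tau1 + uin
    dI4 <- kig * (G4 - I4)

    G <- G + h / 6 * (dG1 + 2 * dG2 + 2 * dG3 + dG4)
    IEFF <- IEFF + h / 6 * (dE1 + 2 * dE2 + 2 * dE3 + dE4)
    IP <- IP + h / 6 * (dP1 + 2 * dP2 + 2 * dP3 + dP4)
    ISC <- ISC + h / 6 * (dS1 + 2 * dS2 + 2 * dS3 + dS4)
    IG <- IG + h / 6 * (dI1 + 2 * dI2 + 2 * dI3 + dI4)
    if (G < 0) G <- 0
    if (IEFF < 0) IEFF <- 0
    if (IP < 0) IP <- 0
    if (ISC < 0) ISC <- 0
    if (IG < 0) IG <- 0
  }
  c(G, IEFF, IP, ISC, IG)
}

#' Advance the virtual patient by one interval
#'
#' Integrates the IVP system with a fixed-step fourth-order Runge-Kutta
#' scheme at step `dt` (default 1 min), holding the insulin rate `u`
#' constant over the interval (zero-order hold, as an insulin pump does).
#' Negative concentrations are clamped to 0 after each substep.
#'
#' @inheritParams ivp_derivatives
#' @param u insulin delivery rate, uU/min, held constant over the interval.
#' @param meals a [meal_schedule()] or `NULL` for no carbohydrate input.
#' @param duration interval length in minutes; must be a positive multiple
#'   of `dt`.
#' @param dt integration step, min.
#' @return the advanced [patient_state()] (with `t` increased by `duration`).
#' @export
step_patient <- function(state, p, u = 0, meals = NULL, duration = 5, dt = 1) {
  if (dt <= 0) stop("dt must be > 0")
  n <- duration / dt
  if (abs(n - round(n)) > 1e-9 || n < 1) {
    stop("duration must be a positive multiple of dt")
  }
  n <- as.integer(round(n))
  t0 <- state[["t"]]
  t_half <- t0 + seq(0, by = dt / 2, length.out = 2L * n + 1L)
  ra_half <- meal_ra(t_half, meals, VG = p$VG, tauD = p$tauD)
  out <- rk4_core(state[["G"]], state[["IEFF"]], state[["IP"]], state[["ISC"]],
                  0, p, u, ra_half, n, dt, tau_ig = Inf)
  if (!all(is.finite(out))) {
    stop(sprintf("integrator divergence for patient %s at t = %g min",
                 ifelse(is.na(p$id), "<unnamed>", p$id), t0))
  }
  patient_state(G = out[1], IEFF = out[2], IP = out[3], ISC = out[4],
                t = t0 + n * dt)
}

#' Insulin steady state for a constant basal rate
#'
#' For a constant infusion `u_Uh` the linear insulin cascade settles at
#' `ISC = IP = u / CI` (uU/mL, with `u` in uU/min) and `IEFF = SI * IP`.
#' Useful for initialising simulations at a basal equilibrium.
#'
#' @inheritParams ivp_derivatives
#' @param u_Uh basal rate, U/h.
#' @return named numeric `(IEFF, IP, ISC)`.
#' @export
ivp_basal_steady_state <- function(p, u_Uh = 0) {
  isc <- insulin_Uh_to_uUmin(u_Uh) / p$CI
  c(IEFF = p$SI * isc, IP = isc, ISC = isc)
}
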