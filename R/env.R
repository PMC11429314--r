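#' Observation encoding
#'
#' The controller observes two numbers in `[0, 1]`: the previous CGM reading
#' divided by 1000 (clipped to `[0, 1]`) and the previous action mapped from
#' `[-1, 1]` to `[0, 1]` via `(a + 1)/2`.
#'
#' @param cgm_prev previous CGM reading, mg/dL (>= 0).
#' @param a_prev previous action in `[-1, 1]`.
#' @return numeric length-2 vector in `[0, 1]^2`.
#' @export
make_observation <- function(cgm_prev, a_prev) {
  if (cgm_prev < 0) stop("cgm_prev must be >= 0")
  c(min(max(cgm_prev / 1000, 0), 1), (a_prev + 1) / 2)
}

#' Action to insulin infusion rate
#'
#' Maps an action in `[-1, 1]` (clipped if outside) to an infusion rate in
#' `[0, action_max_Uh]` U/h: `u = (a + 1) * action_max_Uh / 2`. The rate is
#' held constant over the following 5-min control interval.
#'
#' @param a action value.
#' @param action_max_Uh top of the pump range, U/h (default 25).
#' @export
action_to_insulin <- function(a, action_max_Uh = 25) {
  a <- min(max(a, -1), 1)
  (a + 1) * action_max_Uh / 2
}

#' Closed-loop glycemic control environment
#'
#' Couples the virtual patient, the CGM sensor layer, the meal generator and
#' a reward function into a seeded reset/step environment with a 5-minute
#' control interval. Observations live in `[0, 1]^2`
#' (see [make_observation()]), actions in `[-1, 1]`
#' (see [action_to_insulin()]).
#'
#' @param patient an [ivp_patient()].
#' @param cgm a [cgm_config()]; set `enabled = FALSE` to observe true blood
#'   glucose directly.
#' @param reward reward kind, see [reward_function()].
#' @param episode_days episode length in days (288 control steps per day).
#' @param meal_cfg a [meal_gen_config()] used when no schedule is installed
#'   at reset.
#' @param control_interval control step, min.
#' @param action_max_Uh top of the pump range, U/h.
#' @param dt integration step for the patient + IG ODE, min; must divide the
#'   control interval.
#' @param terminate_on_bounds if `TRUE`, terminate the episode when the CGM
#'   reading leaves `(bounds[1], bounds[2])`; the final configuration
#'   simulates the whole horizon regardless.
#' @param bounds termination bounds, mg/dL.
#' @param G0 initial blood glucose, mg/dL.
#' @param basal_Uh basal rate whose steady state initialises the insulin
#'   compartments (default 0: all insulin states start at 0).
#' @param reward_signal score the `"cgm"` reading (the controller-facing
#'   signal, default) or the `"true"` blood glucose.
#' @return an object of class `glyco_env` (a mutable environment).
#' @export
glyco_env <- function(patient,
                      cgm = cgm_config(),
                      reward = "bump",
                      episode_days = 10,
                      meal_cfg = meal_gen_config(),
                      control_interval = 5,
                      action_max_Uh = 25,
                      dt = 1,
                      terminate_on_bounds = FALSE,
                      bounds = c(50, 400),
                      G0 = 120,
                      basal_Uh = 0,
                      reward_signal = c("cgm", "true")) {
  stopifnot(inherits(patient, "ivp_patient"), inherits(cgm, "cgm_config"))
  if (action_max_Uh <= 0) stop("action_max_Uh must be > 0")
  if (episode_days < 1) stop("episode_days must be >= 1")
  nsub <- control_interval / dt
  if (abs(nsub - round(nsub)) > 1e-9 || nsub < 1) {
    stop("dt must divide the control interval")
  }
  e <- new.env(parent = emptyenv())
  e$patient <- patient
  e$cgm <- cgm
  e$reward_kind <- reward
  e$score_fn <- reward_function(reward)
  e$episode_days <- episode_days
  e$meal_cfg <- meal_cfg
  e$ci_min <- control_interval
  e$action_max <- action_max_Uh
  e$dt <- dt
  e$nsub <- as.integer(round(nsub))
  e$terminate_on_bounds <- isTRUE(terminate_on_bounds)
  e$bounds <- bounds
  e$G0 <- G0
  e$basal_Uh <- basal_Uh
  e$reward_signal <- match.arg(reward_signal)
  e$n_steps <- as.integer(episode_days * 1440 / control_interval)
  e$active <- FALSE
  class(e) <- "glyco_env"
  e
}

#' Reset the environment
#'
#' Initialises the patient at `G0` with insulin compartments at the basal
#' steady state, the IG compartment at `G0`, and zero sensor noise history;
#' installs `schedule` or draws a fresh multi-day schedule from the meal
#' generator. The previous action starts at -1 (zero insulin).
#'
#' @param env a [glyco_env()].
#' @param seed optional integer passed to [set.seed()] before sampling.
#' @param schedule optional [meal_schedule()]; `NULL` draws one.
#' @return the initial observation (length-2 numeric in `[0, 1]^2`).
#' @export
env_reset <- function(env, seed = NULL, schedule = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) {
    schedule <- concatenate_days(env$episode_days, env$patient$BW, env$meal_cfg)
  }
  horizon <- env$episode_days * 1440
  if (nrow(schedule) && any(schedule$t_min >= horizon)) {
    stop("meal schedule extends beyond the episode horizon")
  }
  env$schedule <- schedule
  # meal RA precomputed on the dt/2 half grid for the whole episode
  n_half <- 2L * as.integer(horizon / env$dt) + 1L
  t_half <- seq(0, horizon, by = env$dt / 2)
  env$ra_half <- meal_ra(t_half, schedule, VG = env$patient$VG,
                         tauD = env$patient$tauD)
  # grams delivered within each control interval, for the episode log
  env$carbs_step <- numeric(env$n_steps)
  if (nrow(schedule)) {
    bin <- pmin(floor(schedule$t_min / env$ci_min) + 1L, env$n_steps)
    for (i in seq_along(bin)) {
      env$carbs_step[bin[i]] <- env$carbs_step[bin[i]] + schedule$grams[i]
    }
  }
  ss <- ivp_basal_steady_state(env$patient, env$basal_Uh)
  env$G <- env$G0; env$IEFF <- ss[["IEFF"]]
  env$IP <- ss[["IP"]]; env$ISC <- ss[["ISC"]]
  env$IG <- env$G0
  env$noise <- cgm_noise_state()
  env$cgm_prev <- if (env$cgm$enabled) env$IG else env$G
  env$a_prev <- -1
  env$step_i <- 0L
  env$active <- TRUE
  # per-step log, filled in env_step
  n <- env$n_steps
  env$log <- list(t_min = numeric(n), cgm = numeric(n), G = numeric(n),
                  action = numeric(n), insulin_Uh = numeric(n),
                  carbs = numeric(n), score = numeric(n))
  make_observation(env$cgm_prev, env$a_prev)
}

#' Advance the closed loop by one control interval
#'
#' Converts the action to an infusion rate, integrates the patient and IG
#' ODEs over the control interval with the meal appearance input, draws one
#' AR(2) noise sample, forms the CGM reading and scores it.
#'
#' @param env a [glyco_env()] that has been reset.
#' @param a action in `[-1, 1]` (values outside are clipped).
#' @return list `(observation, reward, terminated, truncated, info)`; `info`
#'   carries the true blood glucose `G`, the CGM reading and the insulin
#'   rate in U/h.
#' @export
env_step <- function(env, a) {
  if (!isTRUE(env$active)) stop("env_step called on an inactive episode; call env_reset first")
  a <- min(max(a, -1), 1)
  u_Uh <- (a + 1) * env$action_max / 2
  u <- insulin_Uh_to_uUmin(u_Uh)
  i <- env$step_i
  off <- 2L * i * env$nsub  # half-grid offset of this interval's start
  ra_half <- env$ra_half[(off + 1L):(off + 2L * env$nsub + 1L)]
  tau_ig <- if (env$cgm$enabled) env$cgm$tau_ig else Inf
  out <- rk4_core(env$G, env$IEFF, env$IP, env$ISC, env$IG,
                  env$patient, u, ra_half, env$nsub, env$dt, tau_ig)
  if (!all(is.finite(out))) {
    stop(sprintf("integrator divergence for patient %s at t = %g min",
                 ifelse(is.na(env$patient$id), "<unnamed>", env$patient$id),
                 i * env$ci_min))
  }
  env$G <- out[1]; env$IEFF <- out[2]; env$IP <- out[3]; env$ISC <- out[4]
  env$IG <- out[5]
  if (env$cgm$enabled) {
    ns <- ar2_noise_step(env$noise, env$cgm)
    env$noise <- ns$state
    cgm_val <- cgm_reading(env$IG, ns$v)
  } else {
    cgm_val <- env$G
  }
  score <- if (env$reward_signal == "cgm") env$score_fn(cgm_val) else env$score_fn(env$G)

  i <- i + 1L
  env$step_i <- i
  env$log$t_min[i] <- i * env$ci_min
  env$log$cgm[i] <- cgm_val
  env$log$G[i] <- env$G
  env$log$action[i] <- a
  env$log$insulin_Uh[i] <- u_Uh
  env$log$carbs[i] <- env$carbs_step[i]
  env$log$score[i] <- score

  terminated <- env$terminate_on_bounds &&
    (cgm_val <= env$bounds[1] || cgm_val >= env$bounds[2])
  truncated <- i >= env$n_steps
  if (terminated || truncated) env$active <- FALSE
  env$cgm_prev <- cgm_val
  env$a_prev <- a
  list(observation = make_observation(cgm_val, a),
       reward = score,
       terminated = terminated,
       truncated = truncated,
       info = list(G = env$G, cgm = cgm_val, insulin_Uh = u_Uh))
}

#' Episode log
#'
#' The aligned per-step time series of the last (possibly ongoing) episode:
#' time (min), CGM reading, true blood glucose, action, insulin rate (U/h),
#' carbohydrates delivered in the interval (g) and the per-step score.
#'
#' @param env a [glyco_env()].
#' @return a data.frame with one row per completed control step.
#' @export
episode_log <- function(env) {
  i <- env$step_i
  if (is.null(i) || i == 0L) stop("no steps have been simulated")
  as.data.frame(lapply(env$log, function(v) v[seq_len(i)]))
}

#' Write an episode log to CSV
#'
#' @param log a data.frame from [episode_log()].
#' @param path file path.
#' @export
write_episode_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.glyco_env <- function(x, ...) {
  cat("closed-loop glycemic control environment\n")
  cat(sprintf("  patient #%s (BW %g kg), %d-day episodes (%d steps), reward '%s'\n",
              ifelse(is.na(x$patient$id), "?", x$patient$id), x$patient$BW,
              x$episode_days, x$n_steps, x$reward_kind))
  cat(sprintf("  CGM %s (tau_ig %g min, sigma %g mg/dL), action range 0-%g U/h\n",
              if (x$cgm$enabled) "enabled" else "disabled",
              x$cgm$tau_ig, x$cgm$sigma, x$action_max))
  invisible(x)
}
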