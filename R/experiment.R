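#' Baseline policies
#'
#' `zero_insulin_policy()` always outputs action -1 (no insulin);
#' `random_policy()` samples actions uniformly on `[-1, 1]`;
#' `constant_policy(a)` holds a fixed action. Used as reference controllers
#' when judging a trained agent.
#'
#' @return a policy function `obs -> action`.
#' @export
zero_insulin_policy <- function() function(obs) -1

#' @rdname zero_insulin_policy
#' @export
random_policy <- function() function(obs) stats::runif(1, -1, 1)

#' @rdname zero_insulin_policy
#' @param a the constant action in `[-1, 1]`.
#' @export
constant_policy <- function(a) function(obs) a

as_policy_fn <- function(policy, use_best = TRUE) {
  if (is.function(policy)) return(policy)
  nets <- agent_nets(policy, use_best)
  sigma <- exp(nets$log_sigma)
  function(obs) squashed_mean_action(mlp_forward1(nets$policy, obs), sigma)
}

#' Run one closed-loop episode under a policy
#'
#' Resets the environment (optionally seeding and/or installing a meal
#' schedule) and steps it to the end of the horizon or until termination.
#'
#' @param env a [glyco_env()].
#' @param policy a policy function, `ppo_agent` or `nets` list; agents act
#'   deterministically (distribution mean).
#' @param seed,schedule passed to [env_reset()].
#' @return the [episode_log()] data.frame.
#' @export
run_episode <- function(env, policy, seed = NULL, schedule = NULL) {
  fn <- as_policy_fn(policy)
  obs <- env_reset(env, seed = seed, schedule = schedule)
  repeat {
    res <- env_step(env, fn(obs))
    if (res$terminated || res$truncated) break
    obs <- res$observation
  }
  episode_log(env)
}

#' Build the 13-scenario test protocol for one patient
#'
#' Ten scenarios carry generator-sampled random days; three are predefined:
#' `no_meal` (0 g), `hourly_12g` (12 g at every hour mark, 24 meals = 288 g)
#' and `spike_at_12h` (a generated day plus an extra 5 g bolus at minute
#' 720).
#'
#' @param patient an [ivp_patient()] (body weight drives the generator).
#' @param seed base seed; scenario `i` uses `seed + i`.
#' @param meal_cfg a [meal_gen_config()].
#' @return list of 13 scenarios, each a list
#'   `(id, kind, schedule, seed)`.
#' @export
build_test_scenarios <- function(patient, seed = 1L, meal_cfg = meal_gen_config()) {
  scen <- vector("list", 13L)
  for (i in 1:10) {
    set.seed(seed + i)
    scen[[i]] <- list(id = sprintf("random_%02d", i), kind = "random",
                      schedule = generate_daily_meals(patient$BW, meal_cfg),
                      seed = seed + i)
  }
  scen[[11]] <- list(id = "no_meal", kind = "no_meal",
                     schedule = meal_schedule(), seed = seed + 11L)
  scen[[12]] <- list(id = "hourly_12g", kind = "hourly_12g",
                     schedule = meal_schedule(t_min = 60 * (0:23),
                                              grams = rep(12, 24)),
                     seed = seed + 12L)
  set.seed(seed + 13L)
  base_day <- generate_daily_meals(patient$BW, meal_cfg)
  scen[[13]] <- list(id = "spike_at_12h", kind = "spike_at_12h",
                     schedule = meal_schedule(c(base_day$t_min, 720),
                                              c(base_day$grams, 5)),
                     seed = seed + 13L)
  scen
}

#' Evaluate a policy over a scenario set
#'
#' One 1-day episode per scenario, deterministic actions, no termination.
#'
#' @param policy policy function, `ppo_agent` or `nets`.
#' @param patient an [ivp_patient()].
#' @param scenarios from [build_test_scenarios()].
#' @param cgm a [cgm_config()].
#' @param reward reward kind used for the per-step scores in the logs.
#' @param ... further arguments to [glyco_env()].
#' @return named list of [episode_log()] data.frames, one per scenario.
#' @export
evaluate_scenarios <- function(policy, patient, scenarios,
                               cgm = cgm_config(), reward = "bump", ...) {
  env <- glyco_env(patient, cgm = cgm, reward = reward, episode_days = 1,
                   terminate_on_bounds = FALSE, ...)
  logs <- lapply(scenarios, function(sc) {
    run_episode(env, policy, seed = sc$seed, schedule = sc$schedule)
  })
  names(logs) <- vapply(scenarios, `[[`, character(1), "id")
  logs
}

#' Full test-protocol evaluation
#'
#' Evaluates one policy per virtual patient over the 13-scenario protocol
#' (17 x 13 = 221 test days for the full cohort), computes a [day_summary()]
#' per day, the aggregate summary table, CVGA zone percentages and the
#' cohort blood-glucose curve data (median with 10th-90th percentile band,
#' and mean +/- 2 SD).
#'
#' @param policies a single policy (function/`ppo_agent`/`nets`) used for
#'   every patient, or a list indexed by patient id with one policy each.
#' @param patients data.frame from [ivp_patients()] (or a subset of rows).
#' @param seed base seed; patient `id` uses `seed + 1000 * id` for its
#'   scenario set.
#' @param cgm a [cgm_config()].
#' @param metrics_signal compute day summaries from the `"cgm"` reading (the
#'   controller-facing signal, default) or the `"true"` blood glucose.
#' @param curves_signal signal used for the cohort curves (default
#'   `"true"`).
#' @param ... further arguments to [glyco_env()].
#' @return list with `days` (one summary row per test day), `aggregate`
#'   (the 7-column x 7-statistic table), `cvga` (zone percentages),
#'   `curves` (per-time-of-day cohort statistics) and `n_days`.
#' @export
run_full_evaluation <- function(policies, patients = ivp_patients(),
                                seed = 1L, cgm = cgm_config(),
                                metrics_signal = c("cgm", "true"),
                                curves_signal = c("true", "cgm"), ...) {
  metrics_signal <- match.arg(metrics_signal)
  curves_signal <- match.arg(curves_signal)
  one_policy <- is.function(policies) || inherits(policies, "ppo_agent") ||
    (is.list(policies) && !is.null(policies$policy))
  rows <- list(); curves <- list(); carbs <- list()
  for (r in seq_len(nrow(patients))) {
    pt <- ivp_patient(x = patients[r, ])
    pol <- if (one_policy) policies else {
      pol <- policies[[as.character(pt$id)]]
      if (is.null(pol)) stop("missing policy for patient ", pt$id)
      pol
    }
    scen <- build_test_scenarios(pt, seed = seed + 1000L * pt$id)
    logs <- evaluate_scenarios(pol, pt, scen, cgm = cgm, ...)
    for (i in seq_along(logs)) {
      log <- logs[[i]]
      trace <- if (metrics_signal == "cgm") log$cgm else log$G
      ds <- day_summary(trace)
      ds$patient <- pt$id
      ds$scenario <- names(logs)[i]
      rows[[length(rows) + 1L]] <- ds
      curves[[length(curves) + 1L]] <- if (curves_signal == "cgm") log$cgm else log$G
      carbs[[length(carbs) + 1L]] <- log$carbs
    }
  }
  days <- do.call(rbind, rows)
  rownames(days) <- NULL
  cm <- do.call(rbind, curves)
  carbm <- do.call(rbind, carbs)
  t_min <- seq(5, by = 5, length.out = ncol(cm))
  curve_stats <- data.frame(
    t_min = t_min,
    median = apply(cm, 2, stats::median),
    q10 = apply(cm, 2, stats::quantile, 0.10),
    q90 = apply(cm, 2, stats::quantile, 0.90),
    mean = colMeans(cm),
    sd = apply(cm, 2, stats::sd),
    carbs_mean = colMeans(carbm))
  list(days = days,
       aggregate = aggregate_summary(days),
       cvga = cvga_zone_percentages(days$cvga_zone),
       curves = curve_stats,
       n_days = nrow(days))
}

#' Write evaluation outputs
#'
#' Emits `table3.csv` (the aggregate summary), `summaries.csv` (per-day
#' rows) and `cvga.csv` (zone percentages) under `dir`.
#'
#' @param result output of [run_full_evaluation()].
#' @param dir output directory (created if needed).
#' @export
write_evaluation <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cbind(stat = rownames(result$aggregate), result$aggregate),
                   file.path(dir, "table3.csv"), row.names = FALSE)
  utils::write.csv(result$days, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(zone = names(result$cvga), pct = result$cvga),
                   file.path(dir, "cvga.csv"), row.names = FALSE)
  invisible(dir)
}

#' CVGA scatter plot
#'
#' Per-day (min, max) glucose points on the control variability grid, with
#' the reversed minimum axis and the nine zone cells.
#'
#' @param days the `days` data.frame from [run_full_evaluation()].
#' @return a ggplot object.
#' @export
plot_cvga <- function(days) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_cvga requires the ggplot2 package")
  }
  cells <- expand.grid(xi = 1:3, yi = 1:3)
  xb <- rbind(c(90, 110), c(70, 90), c(50, 70))
  yb <- rbind(c(90, 180), c(180, 300), c(300, 400))
  cells$xmin <- xb[cells$xi, 1]; cells$xmax <- xb[cells$xi, 2]
  cells$ymin <- yb[cells$yi, 1]; cells$ymax <- yb[cells$yi, 2]
  cells$zone <- mapply(function(xi, yi) {
    cvga_zone(c(mean(xb[xi, ]), mean(yb[yi, ])))
  }, cells$xi, cells$yi)
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = cells,
                       ggplot2::aes(xmin = xmin, xmax = xmax,
                                    ymin = ymin, ymax = ymax,
                                    fill = zone),
                       colour = "grey40", alpha = 0.25) +
    ggplot2::geom_point(data = days,
                        ggplot2::aes(x = cvga_min, y = cvga_max)) +
    ggplot2::scale_x_reverse(breaks = c(110, 90, 70, 50)) +
    ggplot2::scale_y_continuous(breaks = c(90, 180, 300, 400)) +
    ggplot2::labs(x = "minimum BG (mg/dL)", y = "maximum BG (mg/dL)",
                  title = "Control variability grid") +
    ggplot2::theme_minimal()
}

#' Cohort blood-glucose curves
#'
#' Either the median curve with the 10th-90th percentile band, or the mean
#' curve with a +/- 2 SD band, over all evaluated days, with the average
#' carbohydrate intake underneath.
#'
#' @param result output of [run_full_evaluation()].
#' @param type `"median"` or `"mean"`.
#' @return a ggplot object.
#' @export
plot_bg_curves <- function(result, type = c("median", "mean")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bg_curves requires the ggplot2 package")
  }
  type <- match.arg(type)
  cv <- result$curves
  if (type == "median") {
    cv$lo <- cv$q10; cv$hi <- cv$q90; cv$center <- cv$median
    lab <- "median BG with 10th-90th percentile band"
  } else {
    cv$lo <- cv$mean - 2 * cv$sd; cv$hi <- cv$mean + 2 * cv$sd
    cv$center <- cv$mean
    lab <- "mean BG with +/- 2 SD band"
  }
  ggplot2::ggplot(cv, ggplot2::aes(x = t_min / 60)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = center), colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(70, 180), linetype = "dashed") +
    ggplot2::geom_col(ggplot2::aes(y = carbs_mean), width = 0.05,
                      fill = "grey30") +
    ggplot2::labs(x = "time of day (h)", y = "blood glucose (mg/dL)",
                  title = lab) +
    ggplot2::theme_minimal()
}
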