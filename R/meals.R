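#' Meal schedules
#'
#' A meal schedule is a data.frame of carbohydrate events with integer
#' minute-of-episode times `t_min` and integer gram amounts `grams`
#' (non-negative), ordered by time.
#'
#' @param t_min event times, minutes from episode start.
#' @param grams carbohydrate amounts, g.
#' @return a data.frame of class `meal_schedule`.
#' @export
meal_schedule <- function(t_min = numeric(0), grams = numeric(0)) {
  if (length(t_min) != length(grams)) stop("t_min and grams must have equal length")
  if (any(t_min < 0)) stop("meal times must be non-negative")
  if (any(grams < 0)) stop("meal amounts must be non-negative")
  o <- order(t_min)
  structure(data.frame(t_min = t_min[o], grams = grams[o]),
            class = c("meal_schedule", "data.frame"))
}

#' Daily meal generator configuration
#'
#' Six candidate meals per day: three main meals (breakfast, lunch, dinner)
#' that appear with probability 0.95 and three snacks with probability 0.3.
#' Meal times are truncated-normal draws within slot bounds; amounts are
#' normal draws scaled by body weight, floored at 0 and rounded to whole
#' grams.
#'
#' Defaults (times in minutes from midnight):
#' `p = c(0.95, 0.3, 0.95, 0.3, 0.95, 0.3)`;
#' `up = c(9, 10, 14, 16, 20, 23) * 60`; `lo = c(5, 9, 10, 14, 16, 20) * 60`;
#' `mu_t = c(7, 9.5, 12, 15, 18, 21.5) * 60`; `sigma_t = c(60, 30, 60, 30, 60, 30)`;
#' `mu_a_coeff = c(0.7, 0.15, 1.1, 0.15, 1.25, 0.15)` g per kg body weight;
#' amount SD = 0.15 of the mean.
#'
#' @param p per-slot appearance probabilities.
#' @param lo,up truncation bounds on meal time, min.
#' @param mu_t,sigma_t meal-time mean and SD, min.
#' @param mu_a_coeff amount mean coefficients, g/kg.
#' @param sigma_a_frac amount SD as a fraction of the mean.
#' @export
meal_gen_config <- function(p = c(0.95, 0.3, 0.95, 0.3, 0.95, 0.3),
                            up = c(9, 10, 14, 16, 20, 23) * 60,
                            lo = c(5, 9, 10, 14, 16, 20) * 60,
                            mu_t = c(7, 9.5, 12, 15, 18, 21.5) * 60,
                            sigma_t = c(60, 30, 60, 30, 60, 30),
                            mu_a_coeff = c(0.7, 0.15, 1.1, 0.15, 1.25, 0.15),
                            sigma_a_frac = 0.15) {
  n <- length(p)
  stopifnot(length(up) == n, length(lo) == n, length(mu_t) == n,
            length(sigma_t) == n, length(mu_a_coeff) == n)
  if (any(p < 0 | p > 1)) stop("appearance probabilities must lie in [0, 1]")
  if (any(lo > mu_t | mu_t > up)) stop("need lo[k] <= mu_t[k] <= up[k] for all slots")
  if (any(sigma_t <= 0) || sigma_a_frac <= 0) stop("spread parameters must be > 0")
  structure(list(p = p, up = up, lo = lo, mu_t = mu_t, sigma_t = sigma_t,
                 mu_a_coeff = mu_a_coeff, sigma_a_frac = sigma_a_frac),
            class = "meal_gen_config")
}

# truncated-normal draw by rejection from the parent normal; the default
# bounds are wide relative to sigma so rejection is cheap and exact
rtruncnorm1 <- function(mu, sigma, lo, up) {
  repeat {
    x <- stats::rnorm(1, mu, sigma)
    if (x >= lo && x <= up) return(x)
  }
}

#' Generate one day of meals
#'
#' For each of the six candidate slots, a meal is included with the slot's
#' appearance probability; its amount is `round(max(0, N(mu_a, sigma_a)))`
#' grams with `mu_a = mu_a_coeff * BW`, and its time is a rounded
#' truncated-normal draw within the slot bounds. Uses R's global RNG; seed
#' with [set.seed()] for reproducibility.
#'
#' @param BW body weight, kg.
#' @param cfg a [meal_gen_config()].
#' @return a [meal_schedule()] covering one day (times < 1440 min).
#' @export
generate_daily_meals <- function(BW, cfg = meal_gen_config()) {
  if (BW <= 0) stop("BW must be > 0")
  t_min <- numeric(0); grams <- numeric(0)
  for (k in seq_along(cfg$p)) {
    if (stats::runif(1) <= cfg$p[k]) {
      mu_a <- cfg$mu_a_coeff[k] * BW
      e <- round(max(0, stats::rnorm(1, mu_a, cfg$sigma_a_frac * mu_a)))
      z <- round(rtruncnorm1(cfg$mu_t[k], cfg$sigma_t[k], cfg$lo[k], cfg$up[k]))
      t_min <- c(t_min, z); grams <- c(grams, e)
    }
  }
  meal_schedule(t_min, grams)
}

#' Concatenate independent daily schedules into a multi-day schedule
#'
#' Draws `n_days` independent days and offsets day `d` (0-based) by
#' `1440 * d` minutes, merging events in time order.
#'
#' @inheritParams generate_daily_meals
#' @param n_days number of days, >= 1.
#' @export
concatenate_days <- function(n_days, BW, cfg = meal_gen_config()) {
  if (n_days < 1) stop("n_days must be >= 1")
  days <- lapply(seq_len(n_days) - 1L, function(d) {
    m <- generate_daily_meals(BW, cfg)
    m$t_min <- m$t_min + 1440 * d
    m
  })
  all <- do.call(rbind, days)
  meal_schedule(all$t_min, all$grams)
}

#' Read/write meal schedules
#'
#' Schedules round-trip through a two-column CSV (`t_min,grams`).
#'
#' @param meals a [meal_schedule()].
#' @param path file path.
#' @export
write_meal_schedule <- function(meals, path) {
  utils::write.csv(as.data.frame(meals), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meal_schedule
#' @export
read_meal_schedule <- function(path) {
  m <- utils::read.csv(path)
  meal_schedule(m$t_min, m$grams)
}
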