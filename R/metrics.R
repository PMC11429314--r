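#' Time-in-range zone occupancy
#'
#' Percentage of samples in the five clinical glucose zones: `< 50`,
#' `[50, 70)`, `[70, 180]` (the time-in-range target), `(180, 250]` and
#' `> 250` mg/dL. The boundary convention keeps 70 and 180 inside the
#' in-range zone. The five percentages sum to 100.
#'
#' @param trace blood glucose samples, mg/dL; non-empty.
#' @return named numeric of length 5:
#'   `(pct_lt50, pct_50_70, pct_70_180, pct_180_250, pct_gt250)`.
#' @export
tir_fractions <- function(trace) {
  if (length(trace) == 0L) stop("trace must be non-empty")
  n <- length(trace)
  c(pct_lt50    = 100 * sum(trace < 50) / n,
    pct_50_70   = 100 * sum(trace >= 50 & trace < 70) / n,
    pct_70_180  = 100 * sum(trace >= 70 & trace <= 180) / n,
    pct_180_250 = 100 * sum(trace > 180 & trace <= 250) / n,
    pct_gt250   = 100 * sum(trace > 250) / n)
}

#' Root-mean-square error from a reference glucose level
#'
#' `sqrt(mean((trace - ref)^2))`, reported against 90 and 150 mg/dL in the
#' summary tables.
#'
#' @param trace blood glucose samples, mg/dL; non-empty.
#' @param ref reference level, mg/dL.
#' @export
rmse_from <- function(trace, ref) {
  if (length(trace) == 0L) stop("trace must be non-empty")
  sqrt(mean((trace - ref)^2))
}

#' Control variability grid point for one day
#'
#' The per-day (minimum, maximum) glucose pair, clipped to the CVGA axes:
#' the minimum axis spans `[50, 110]` and the maximum axis `[90, 400]`
#' mg/dL.
#'
#' @param day_trace one day of glucose samples, mg/dL.
#' @return named numeric `(cvga_min, cvga_max)` after clipping.
#' @export
cvga_point <- function(day_trace) {
  if (length(day_trace) == 0L) stop("day_trace must be non-empty")
  c(cvga_min = min(max(min(day_trace), 50), 110),
    cvga_max = min(max(max(day_trace), 90), 400))
}

#' CVGA zone classification
#'
#' Classifies a clipped (min, max) point on the standard 3x3 control
#' variability grid. The (reversed) minimum axis is segmented at 110/90/70/50
#' and the maximum axis at 90/180/300/400; segment membership is closed on
#' the side adjacent to zone A (x = 90 counts as the best minimum segment,
#' y = 180 as the best maximum segment):
#'
#' | min \\ max    | `[90,180]` | `(180,300]` | `(300,400]` |
#' |---------------|------------|-------------|-------------|
#' | `[90,110]`    | A          | Upper B     | Upper C     |
#' | `[70,90)`     | Lower B    | B           | Upper D     |
#' | `[50,70)`     | Lower C    | Lower D     | E           |
#'
#' @param point output of [cvga_point()] (or any length-2 `(min, max)` pair
#'   within the axes).
#' @return a single zone label, one of `A`, `UpperB`, `B`, `LowerB`,
#'   `UpperC`, `LowerC`, `UpperD`, `LowerD`, `E`.
#' @export
cvga_zone <- function(point) {
  x <- point[[1]]; y <- point[[2]]
  xi <- if (x >= 90) 1L else if (x >= 70) 2L else 3L
  yi <- if (y <= 180) 1L else if (y <= 300) 2L else 3L
  grid <- matrix(c("A",      "UpperB", "UpperC",
                   "LowerB", "B",      "UpperD",
                   "LowerC", "LowerD", "E"),
                 nrow = 3, byrow = TRUE)
  grid[xi, yi]
}

cvga_zone_levels <- c("A", "UpperB", "B", "LowerB", "UpperC", "LowerC",
                      "UpperD", "LowerD", "E")

#' Per-day glycemic summary
#'
#' Computes the five TIR-zone percentages, RMSE from 90 and 150 mg/dL, and
#' the CVGA point and zone for one day of glucose samples.
#'
#' @param day_trace one day of glucose samples, mg/dL.
#' @return a one-row data.frame of class `day_summary`.
#' @export
day_summary <- function(day_trace) {
  tir <- tir_fractions(day_trace)
  pt <- cvga_point(day_trace)
  out <- data.frame(t(tir),
                    rmse90 = rmse_from(day_trace, 90),
                    rmse150 = rmse_from(day_trace, 150),
                    cvga_min = pt[["cvga_min"]], cvga_max = pt[["cvga_max"]],
                    cvga_zone = cvga_zone(pt))
  class(out) <- c("day_summary", "data.frame")
  out
}

#' Aggregate per-day summaries
#'
#' Builds the cohort summary table: for each of the five TIR-zone columns
#' and the two RMSE columns, the mean, standard deviation, minimum,
#' quartiles (linear interpolation) and maximum over days.
#'
#' @param days a data.frame of row-bound [day_summary()] rows.
#' @return a data.frame with rows `mean, std, min, 25%, 50%, 75%, max` and
#'   columns `<50, 50-70, 70-180, 180-250, >250, RMSE90, RMSE150`.
#' @export
aggregate_summary <- function(days) {
  if (NROW(days) == 0L) stop("days must be non-empty")
  cols <- c(pct_lt50 = "<50", pct_50_70 = "50-70", pct_70_180 = "70-180",
            pct_180_250 = "180-250", pct_gt250 = ">250",
            rmse90 = "RMSE90", rmse150 = "RMSE150")
  stats_of <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(mean = mean(x), std = stats::sd(x), min = min(x),
      `25%` = q[1], `50%` = q[2], `75%` = q[3], max = max(x))
  }
  out <- as.data.frame(lapply(days[names(cols)], stats_of))
  names(out) <- unname(cols)
  if (NROW(days) == 1L) out["std", ] <- 0
  out
}

#' CVGA zone occupancy percentages
#'
#' Fraction of days falling in each CVGA zone, in percent; the nine zones
#' partition the grid, so the percentages sum to 100.
#'
#' @param zones character vector of zone labels (from [cvga_zone()]).
#' @return named numeric over the nine zones plus `A+B` (the combined
#'   A, Upper B, B, Lower B occupancy).
#' @export
cvga_zone_percentages <- function(zones) {
  if (length(zones) == 0L) stop("zones must be non-empty")
  tab <- table(factor(zones, levels = cvga_zone_levels))
  pct <- 100 * as.numeric(tab) / length(zones)
  names(pct) <- cvga_zone_levels
  c(pct, `A+B` = sum(pct[c("A", "UpperB", "B", "LowerB")]))
}
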