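#' Virtual patient parameter sets
#'
#' The identifiable virtual patient (IVP) model is parameterised per subject.
#' The package ships 17 parameter sets covering 10 subjects (some subjects
#' have separate daytime and night-time rows, distinguishable by shared
#' `BW`/`VG`). `ivp_patients()` loads the full cohort; `ivp_patient()`
#' selects and validates a single row.
#'
#' Columns and units:
#' \describe{
#'   \item{BW}{body weight, kg}
#'   \item{GEZI}{glucose effectiveness at zero insulin, 1/min}
#'   \item{EGP}{endogenous glucose production, mg/dL/min}
#'   \item{CI}{insulin clearance, mL/min}
#'   \item{SI}{insulin sensitivity, mL/uU/min}
#'   \item{tau1, tau2}{subcutaneous/plasma insulin time constants, min}
#'   \item{p2}{insulin-action rate constant, 1/min}
#'   \item{VG}{glucose distribution volume, dL}
#'   \item{tauD}{meal absorption time constant, min (global default, not part
#'     of the identified cohort; see [meal_ra()])}
#' }
#'
#' @return `ivp_patients()`: a data.frame with one row per parameter set and
#'   an `id` column; `ivp_patient()`: a single-row object of class
#'   `ivp_patient` (a named list).
#' @export
ivp_patients <- function() {
  path <- system.file("extdata", "patients.csv", package = "glyco", mustWork = TRUE)
  pts <- utils::read.csv(path)
  pts$id <- seq_len(nrow(pts))
  pts[, c("id", setdiff(names(pts), "id"))]
}

#' @rdname ivp_patients
#' @param id row index of the parameter set (1-17), used when `x` is missing.
#' @param x optionally, a one-row data.frame or named list carrying the
#'   parameter fields directly.
#' @param tauD meal absorption time constant in minutes.
#' @export
ivp_patient <- function(id = 1L, x = NULL, tauD = 40) {
  if (is.null(x)) {
    pts <- ivp_patients()
    if (!(id %in% pts$id)) {
      stop("unknown patient id ", id, "; available ids are 1..", nrow(pts))
    }
    x <- pts[pts$id == id, ]
  }
  p <- as.list(x)[c("BW", "GEZI", "EGP", "CI", "SI", "tau1", "tau2", "p2", "VG")]
  p <- lapply(p, as.numeric)
  p$tauD <- as.numeric(tauD)
  p$id <- if (!is.null(x$id)) as.integer(x$id) else NA_integer_
  validate_ivp_patient(p)
  structure(p, class = "ivp_patient")
}

validate_ivp_patient <- function(p) {
  num <- vapply(p[c("BW", "GEZI", "EGP", "CI", "SI", "tau1", "tau2", "p2", "VG", "tauD")],
                function(v) is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))
  if (!all(num)) stop("patient parameters must be finite scalars: ",
                      paste(names(num)[!num], collapse = ", "))
  if (p$GEZI < 0) stop("GEZI must be >= 0")
  strict <- c("BW", "EGP", "CI", "SI", "tau1", "tau2", "p2", "VG", "tauD")
  bad <- strict[vapply(p[strict], function(v) v <= 0, logical(1))]
  if (length(bad)) stop("patient parameters must be strictly positive: ",
                        paste(bad, collapse = ", "))
  invisible(p)
}

#' @export
print.ivp_patient <- function(x, ...) {
  cat("IVP virtual patient", if (!is.na(x$id)) paste0("#", x$id) else "", "\n")
  cat(sprintf("  BW %g kg, VG %g dL, EGP %g mg/dL/min, GEZI %g 1/min\n",
              x$BW, x$VG, x$EGP, x$GEZI))
  cat(sprintf("  CI %g mL/min, SI %g mL/uU/min, tau1 %g min, tau2 %g min, p2 %g 1/min\n",
              x$CI, x$SI, x$tau1, x$tau2, x$p2))
  invisible(x)
}
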