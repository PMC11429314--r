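#' Read a YAML run configuration
#'
#' Builds a [glyco_env()] from a YAML file of the form:
#'
#' ```yaml
#' patient: 10            # Table row id (1-17)
#' episode_days: 10
#' action_max_Uh: 25
#' reward:
#'   kind: bump           # bump | piecewise | cosine | mexican_hat
#'   signal: cgm          # cgm | true
#' cgm:
#'   tau_ig: 10
#'   alpha1: 1.23
#'   alpha2: -0.3995
#'   sigma: 1.0
#'   ts_min: 5
#'   enabled: true
#' ```
#'
#' Missing keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return a [glyco_env()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  patient <- ivp_patient(id = cfg$patient %||% 1L)
  cgm_args <- cfg$cgm %||% list()
  cgm <- do.call(cgm_config, cgm_args[names(cgm_args) %in%
                   c("tau_ig", "alpha1", "alpha2", "sigma", "ts_min", "enabled")])
  rw <- cfg$reward %||% list()
  sig <- rw$signal %||% "cgm"
  if (is.logical(sig)) sig <- tolower(as.character(sig))  # YAML bare `true`
  glyco_env(patient,
            cgm = cgm,
            reward = rw$kind %||% "bump",
            reward_signal = sig,
            episode_days = cfg$episode_days %||% 10,
            action_max_Uh = cfg$action_max_Uh %||% 25,
            terminate_on_bounds = isTRUE(cfg$terminate_on_bounds),
            bounds = unlist(cfg$bounds %||% c(50, 400)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
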