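#' Default run configuration
#'
#' The full configuration of a reproducible run: plant block (Droop
#' parameters), observer block (gains and initial observer state), solver
#' block, and experiment block. The defaults reproduce the uptake-rate
#' reference example exactly; a user configuration file overrides fields
#' selectively.
#'
#' @return A nested list of class `runConfig`.
#' @export
defaultRunConfig <- function() {
  structure(list(
    plant = list(rho_m = 0.03, K_s = 0.001, mu_m = 0.5, Q0 = 0.045,
                 s_in_bar = 0.05, tau_D = 8, tau_si = 3,
                 D_switch_time = 6, D_amplitude = 0.25,
                 feed_uncertainty_fraction = 0.1,
                 continuous_phase = "before_switch",
                 x0 = 0.1, s0 = 0.01, q0 = 0.06),
    observer = list(omega = 8.56, epsilon = 0.0015, k = 40, gamma = 100,
                    x1_hat0 = 0.1, x2_hat0 = 0, theta_hat0 = 0),
    solver = list(method = "rk45", rtol = 1e-8, atol = 1e-10,
                  grid_step = 0.001),
    experiment = list(example = "uptake", t_end = 20)),
    class = "runConfig")
}

mergeConfig <- function(base, user, path = character()) {
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base)) {
      stop(sprintf("unknown configuration field '%s'", here))
    }
    if (is.list(base[[nm]])) {
      if (!is.list(user[[nm]])) {
        stop(sprintf("configuration field '%s' must be a block", here))
      }
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]], c(path, nm))
    } else {
      v <- user[[nm]]
      if (length(v) != 1) {
        stop(sprintf("configuration field '%s' must be a scalar", here))
      }
      base[[nm]] <- v
    }
  }
  base
}

validateRunConfig <- function(cfg) {
  ob <- cfg$observer
  for (nm in c("omega", "epsilon", "k", "gamma")) {
    if (!is.numeric(ob[[nm]]) || ob[[nm]] <= 0) {
      stop(sprintf("configuration field 'observer.%s' must be positive", nm))
    }
  }
  sv <- cfg$solver
  if (!identical(sv$method, "rk45")) {
    stop("configuration field 'solver.method' must be \"rk45\"")
  }
  for (nm in c("rtol", "atol", "grid_step")) {
    if (!is.numeric(sv[[nm]]) || sv[[nm]] <= 0) {
      stop(sprintf("configuration field 'solver.%s' must be positive", nm))
    }
  }
  if (!cfg$experiment$example %in% c("uptake", "growth")) {
    stop("configuration field 'experiment.example' must be \"uptake\" or \"growth\"")
  }
  if (!is.numeric(cfg$experiment$t_end) || cfg$experiment$t_end <= 0) {
    stop("configuration field 'experiment.t_end' must be positive")
  }
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration file, overlays it on [defaultRunConfig()] and
#' validates the result. Unknown fields are errors (fail fast, with the
#' offending field named); an empty file or `NULL` path yields the full
#' defaults.
#'
#' @param path path to a JSON configuration file, or `NULL` for defaults.
#' @return A validated `runConfig`.
#' @export
loadRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (nzchar(trimws(txt))) {
      user <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
      cfg <- mergeConfig(unclass(cfg), user)
      class(cfg) <- "runConfig"
    }
  }
  validateRunConfig(cfg)
}

#' Extract typed objects from a run configuration
#'
#' @param cfg a `runConfig`.
#' @return list with `params` ([droopParameters()]), `gains`
#'   ([observerGains()]), `initialObserver` ([observerState()]), and the
#'   `solver` and `experiment` blocks.
#' @export
configObjects <- function(cfg) {
  stopifnot(inherits(cfg, "runConfig"))
  p <- cfg$plant
  list(params = do.call(droopParameters, p),
       gains = observerGains(cfg$observer$omega, cfg$observer$epsilon,
                             cfg$observer$k, cfg$observer$gamma),
       initialObserver = observerState(cfg$observer$x1_hat0,
                                       cfg$observer$x2_hat0,
                                       cfg$observer$theta_hat0),
       solver = cfg$solver,
       experiment = cfg$experiment)
}

roundReport <- function(x, digits) {
  if (is.numeric(x)) return(round(x, digits))
  if (is.list(x)) return(lapply(x, roundReport, digits = digits))
  x
}

#' Write a report as JSON
#'
#' Serializes a tuning report, disturbance bounds or verification report to
#' JSON with stable key order: a `full` block at double precision and a
#' `rounded` block at reporting precision. Data-frame members (e.g. the
#' half-width curve) are dropped from the JSON — they belong in CSV.
#'
#' @param report a list-like report object.
#' @param path output path.
#' @param digits decimals for the `rounded` block.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, digits = 4) {
  plain <- function(x) {
    if (is.data.frame(x) || is.function(x)) return(NULL)
    if (is.list(x)) {
      x <- lapply(unclass(x), plain)
      return(x[!vapply(x, is.null, logical(1))])
    }
    x
  }
  keep <- plain(report)
  out <- list(full = keep, rounded = roundReport(keep, digits))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write / read a trajectory CSV
#'
#' Plain-CSV persistence for trajectories. Truth columns that are absent
#' (data-driven runs) simply do not appear. `readTrajectoryCSV` restores the
#' `observerTrajectory` class when the observer columns are present; gains
#' are not persisted in the CSV and must be re-attached via `gains` to rerun
#' verification.
#'
#' @param traj a trajectory data.frame.
#' @param path CSV path.
#' @param gains optional [observerGains()] to attach on read.
#' @return `writeTrajectoryCSV`: `path`, invisibly. `readTrajectoryCSV`: the
#'   trajectory data.frame.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path, gains = NULL) {
  d <- utils::read.csv(path)
  if (all(c("x1_err", "x2_err", "z", "b") %in% names(d))) {
    class(d) <- c("observerTrajectory", class(d))
    if (!is.null(gains)) attr(d, "gains") <- gains
    if ("b" %in% names(d)) attr(d, "sigma") <- as.integer(sign(d$b[1]))
  }
  d
}
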