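#' Controlled cortical impact scenario
#'
#' A rigid flat-tipped cylindrical impactor is driven into the top surface of
#' the tissue block at constant velocity to a set depth, dwells, and
#' optionally retracts. Only the 2 mm (2000 um) impact depth is an emulated
#' experimental setting; the impactor radius, velocity and dwell are
#' package assumptions, exposed as configuration.
#'
#' @param impact_depth impactor travel into the tissue, um (default 2000).
#' @param impact_velocity impactor speed, um/ms (default 4000, i.e. 4 m/s).
#' @param impactor_radius flat tip radius, um.
#' @param dwell_time hold at peak depth, ms.
#' @param retract withdraw at `impact_velocity` after the dwell?
#' @param total_sim_time simulated time, ms; defaults to the full
#'   descend + dwell (+ retract) schedule.
#' @return object of class `cci_scenario`.
#' @export
cci_scenario <- function(impact_depth = 2000,
                         impact_velocity = 4000,
                         impactor_radius = 2500,
                         dwell_time = 0.1,
                         retract = TRUE,
                         total_sim_time = NULL) {
  stopifnot_scalar(impact_depth)
  stopifnot_scalar(impact_velocity)
  stopifnot_scalar(impactor_radius)
  if (impact_depth < 0) stop("impact_depth must be >= 0")
  if (impact_velocity <= 0) stop("impact_velocity must be > 0")
  t_desc <- impact_depth / impact_velocity
  if (is.null(total_sim_time)) {
    total_sim_time <- t_desc + dwell_time + if (retract) t_desc else 0
  }
  if (total_sim_time < t_desc) {
    stop("total_sim_time must cover at least the descend phase (",
         signif(t_desc, 4), " ms)")
  }
  structure(list(impact_depth = impact_depth,
                 impact_velocity = impact_velocity,
                 impactor_radius = impactor_radius,
                 dwell_time = dwell_time,
                 retract = retract,
                 total_sim_time = total_sim_time,
                 time_to_peak = t_desc),
            class = "cci_scenario")
}

#' Build a CCI scenario from a flat configuration list
#'
#' Validates required fields (`impact_depth`, `impact_velocity`,
#' `impactor_radius`) and applies documented defaults for the rest; missing
#' required fields are reported together.
#' @param config named list.
#' @return a [cci_scenario()].
#' @export
make_cci_scenario <- function(config = list()) {
  defaults <- list(impact_depth = 2000, impact_velocity = 4000,
                   impactor_radius = 2500, dwell_time = 0.1,
                   retract = TRUE, total_sim_time = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  }
  merged <- utils::modifyList(defaults, config, keep.null = TRUE)
  required <- c("impact_depth", "impact_velocity", "impactor_radius")
  missing <- required[vapply(merged[required],
                             function(x) is.null(x) || !is.finite(x),
                             logical(1))]
  if (length(missing) > 0) {
    stop("scenario config validation failed; missing/invalid field(s): ",
         paste(missing, collapse = ", "))
  }
  do.call(cci_scenario, merged)
}

#' @export
print.cci_scenario <- function(x, ...) {
  cat(sprintf(paste0("<cci_scenario> depth %g um at %g um/ms ",
                     "(tip radius %g um), dwell %g ms, retract: %s, ",
                     "%g ms total\n"),
              x$impact_depth, x$impact_velocity, x$impactor_radius,
              x$dwell_time, x$retract, x$total_sim_time))
  invisible(x)
}
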