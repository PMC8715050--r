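#' Task geometry for the speeded multi-target saccade task
#'
#' Defines the spatial and temporal layout of the eye-movement task: a ring of
#' candidate target locations around a central fixation cross, the subset size
#' shown per trial, hit radii, and trial timing.  Defaults reproduce the
#' published task: 18 of 42 candidate locations on an 11.5 degree eccentricity
#' ring, 0.75 degree target radius, a 1.2 degree online (2.4 degree offline)
#' hit radius, a 2.5 degree refixation zone, and 8 s trials sampled at
#' 1000 Hz.
#'
#' @param n_candidates Number of equally spaced candidate locations on the
#'   ring.
#' @param eccentricity Ring eccentricity in degrees of visual angle.
#' @param target_radius Target disc radius in degrees.
#' @param n_targets Number of targets drawn (without replacement) per trial.
#' @param hit_radius_online Radius (degrees) within which a gaze sample marks
#'   a target during the task.
#' @param hit_radius_offline Radius used by the offline hit analysis (twice
#'   the online radius in the original task).
#' @param fixation_radius Radius (degrees) of the central refixation zone.
#' @param trial_duration Trial length in ms.
#' @param sampling_rate Nominal sampling rate in Hz.
#' @return An object of class `task_geometry` (a validated list).
#' @examples
#' geom <- task_geometry()
#' geom$n_targets
#' @export
task_geometry <- function(n_candidates = 42,
                          eccentricity = 11.5,
                          target_radius = 0.75,
                          n_targets = 18,
                          hit_radius_online = 1.2,
                          hit_radius_offline = 2.4,
                          fixation_radius = 2.5,
                          trial_duration = 8000,
                          sampling_rate = 1000) {
  geom <- list(
    n_candidates = as.integer(n_candidates),
    eccentricity = eccentricity,
    target_radius = target_radius,
    n_targets = as.integer(n_targets),
    hit_radius_online = hit_radius_online,
    hit_radius_offline = hit_radius_offline,
    fixation_radius = fixation_radius,
    trial_duration = trial_duration,
    sampling_rate = sampling_rate
  )
  abort_if(geom$n_targets > geom$n_candidates,
           "`n_targets` must not exceed `n_candidates`.",
           class = "ocuvigor_geometry_error")
  abort_if(geom$trial_duration <= 0, "`trial_duration` must be positive.",
           class = "ocuvigor_geometry_error")
  abort_if(geom$eccentricity <= 0, "`eccentricity` must be positive.",
           class = "ocuvigor_geometry_error")
  abort_if(geom$sampling_rate <= 0, "`sampling_rate` must be positive.",
           class = "ocuvigor_geometry_error")
  structure(geom, class = "task_geometry")
}

#' Draw a trial's target layout
#'
#' Samples `n_targets` distinct locations, without replacement, from the
#' `n_candidates` equally spaced positions on the eccentricity ring.  Every
#' returned position lies exactly at the ring eccentricity.
#'
#' @param geometry A [task_geometry()].
#' @param seed Optional integer seed; the same seed always yields the same
#'   layout and the caller's RNG state is left untouched.
#' @return A tibble with one row per target: `target` (index into the
#'   candidate ring), `angle_deg`, `x_deg`, `y_deg`.
#' @examples
#' layout <- make_layout(task_geometry(), seed = 1)
#' sqrt(layout$x_deg^2 + layout$y_deg^2) # all 11.5
#' @export
make_layout <- function(geometry = task_geometry(), seed = NULL) {
  stopifnot(inherits(geometry, "task_geometry"))
  idx <- with_seed(seed, sample.int(geometry$n_candidates, geometry$n_targets))
  angle <- 2 * pi * (idx - 1) / geometry$n_candidates
  tibble::tibble(
    target = idx,
    angle_deg = angle * 180 / pi,
    x_deg = geometry$eccentricity * cos(angle),
    y_deg = geometry$eccentricity * sin(angle)
  )
}
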