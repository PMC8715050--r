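# Effort metrics: per-trial saccade frequency, target hits, destination
# classification, and the condition summary table.

#' Per-trial saccade frequency
#'
#' Counts detected saccades per trial — all saccades within the task window,
#' irrespective of landing position.  Trials present in `trials` but absent
#' from `events` are counted as zero.
#'
#' @param events Event tibble keyed by `subject`, `block`, `trial` (or a
#'   single trial's events, in which case the bare count is returned).
#' @param trials Optional trial metadata used to restore zero-event trials.
#' @return A tibble `subject`, `block`, `trial`, `frequency`, or a scalar
#'   count for unkeyed input.
#' @export
saccade_frequency <- function(events, trials = NULL) {
  keyed <- all(c("subject", "block", "trial") %in% names(events))
  if (!keyed) return(nrow(events))
  counts <- dplyr::count(events, .data$subject, .data$block, .data$trial,
                         name = "frequency")
  if (!is.null(trials)) {
    counts <- dplyr::left_join(
      dplyr::select(trials, "subject", "block", "trial"),
      counts, by = c("subject", "block", "trial"))
    counts$frequency[is.na(counts$frequency)] <- 0L
  }
  tibble::as_tibble(counts)
}

#' Classify saccade destinations
#'
#' Labels each event as target-directed or fixation-directed by the
#' nearest-destination rule: an event is target-directed when its end point
#' is closer to some peripheral target than to the fixation point.  The
#' landing error is the distance from the end point to the chosen
#' destination's centre.
#'
#' @param events Event tibble with `x_offset`, `y_offset`.
#' @param layout Target layout (`x_deg`, `y_deg`, `target`) for the trial.
#' @param fixation Fixation-point coordinates, degrees.
#' @return `events` with added `destination_class` (`"target"` /
#'   `"fixation"`), `dest_target` (layout target index or `NA`), and
#'   `landing_error_deg`.
#' @export
classify_destination <- function(events, layout, fixation = c(0, 0)) {
  if (nrow(events) == 0) {
    return(dplyr::mutate(events, destination_class = character(),
                         dest_target = integer(),
                         landing_error_deg = numeric()))
  }
  d_t <- sqrt(outer(events$x_offset, layout$x_deg, "-")^2 +
                outer(events$y_offset, layout$y_deg, "-")^2)
  nearest <- max.col(-d_t)
  d_near <- d_t[cbind(seq_len(nrow(events)), nearest)]
  d_fix <- sqrt((events$x_offset - fixation[1])^2 +
                  (events$y_offset - fixation[2])^2)
  is_target <- d_near < d_fix
  dplyr::mutate(
    events,
    destination_class = ifelse(is_target, "target", "fixation"),
    dest_target = ifelse(is_target, layout$target[nearest], NA_integer_),
    landing_error_deg = ifelse(is_target, d_near, d_fix))
}

#' Count target hits in a trial
#'
#' A target is hit when a valid gaze sample falls within the hit radius of
#' its centre (online 1.2 degrees, offline 2.4 degrees by default).  Each
#' target can be hit at most once, and — mirroring the task's alternation
#' rule — a re-entry into the central fixation zone is required between
#' successive hits (switch off with `require_refixation = FALSE`).
#'
#' @param trace One trial's gaze tibble.
#' @param layout The trial's target layout.
#' @param mode `"online"` or `"offline"` (chooses the hit radius).
#' @param geometry A [task_geometry()].
#' @param require_refixation Enforce the fixation-return rule.
#' @return A tibble of hits in gaze order: `order`, `target`, `t_ms`.
#' @export
count_hits <- function(trace, layout, mode = c("offline", "online"),
                       geometry = task_geometry(),
                       require_refixation = TRUE) {
  mode <- match.arg(mode)
  radius <- if (mode == "online") geometry$hit_radius_online
  else geometry$hit_radius_offline
  ok <- trace$valid & is.finite(trace$x_deg) & is.finite(trace$y_deg)
  x <- trace$x_deg; y <- trace$y_deg
  within <- (outer(x, layout$x_deg, "-")^2 +
               outer(y, layout$y_deg, "-")^2) <= radius^2
  within[!ok, ] <- FALSE
  in_fix <- ok & (x^2 + y^2 <= geometry$fixation_radius^2)
  k <- nrow(layout)
  unhit <- rep(TRUE, k)
  armed <- TRUE
  hit_target <- integer(); hit_t <- numeric()
  any_within <- which(rowSums(within) > 0)
  relevant <- sort(unique(c(any_within, which(in_fix))))
  for (i in relevant) {
    if (armed) {
      j <- which(within[i, ] & unhit)
      if (length(j)) {
        if (length(j) > 1) {
          # overlapping hit zones (adjacent ring positions): take nearest
          dd <- (x[i] - layout$x_deg[j])^2 + (y[i] - layout$y_deg[j])^2
          j <- j[which.min(dd)]
        } else j <- j[1]
        unhit[j] <- FALSE
        hit_target <- c(hit_target, layout$target[j])
        hit_t <- c(hit_t, trace$t_ms[i])
        if (require_refixation) armed <- FALSE
      }
    } else if (in_fix[i]) {
      armed <- TRUE
    }
  }
  tibble::tibble(order = seq_along(hit_target), target = hit_target,
                 t_ms = hit_t)
}

#' Summarise effort measures per subject and condition
#'
#' Builds the condition summary: one row per subject x reward x duration
#' cell with the six performance measures — mean hits per trial, mean
#' saccade frequency, mean peak velocity, vigor, mean amplitude, and mean
#' end-point error.  Excluded trials (logical `excluded` column in `trials`)
#' are omitted from all means; subjects with an empty condition cell are
#' reported with a warning.
#'
#' @param events Detected events keyed by `subject`, `block`, `trial`.
#' @param trials Trial metadata (`subject`, `block`, `trial`,
#'   `reward_cents`, `duration_condition`, optional `excluded`).
#' @param gaze Optional gaze dataset (needed for hit counting).
#' @param layouts Optional per-trial layouts (`subject`, `block`, `trial`,
#'   `target`, `x_deg`, `y_deg`; needed for hit counting and landing
#'   errors).
#' @param geometry A [task_geometry()].
#' @param fits Optional named list of per-subject [fit_main_sequence()]
#'   objects; fitted from `events` when `NULL`.
#' @param hit_mode `"offline"` or `"online"` hit radius.
#' @param require_refixation Offline alternation rule switch.
#' @return A tibble `subject`, `reward_cents`, `duration_condition`,
#'   `n_hits`, `frequency`, `peak_vel`, `vigor`, `amplitude`,
#'   `endpoint_error`.
#' @export
summarize_conditions <- function(events, trials, gaze = NULL,
                                 layouts = NULL,
                                 geometry = task_geometry(),
                                 fits = NULL,
                                 hit_mode = "offline",
                                 require_refixation = TRUE) {
  keys <- c("subject", "block", "trial")
  if (!("excluded" %in% names(trials))) trials$excluded <- FALSE
  kept <- dplyr::filter(trials, !.data$excluded)
  ev <- dplyr::inner_join(events, dplyr::select(kept, dplyr::all_of(keys),
                                                "reward_cents",
                                                "duration_condition"),
                          by = keys)

  if (is.null(fits)) {
    fits <- purrr::map(split(ev, ev$subject), fit_main_sequence)
  }

  # landing error via per-trial nearest-destination classification
  if (!is.null(layouts)) {
    ev <- purrr::list_rbind(purrr::map(
      split(ev, interaction(ev$subject, ev$block, ev$trial, drop = TRUE)),
      function(e) {
        lay <- dplyr::semi_join(layouts, e[1, keys], by = keys)
        classify_destination(e, lay)
      }))
  } else {
    ev$landing_error_deg <- NA_real_
  }

  # per-trial frequency including zero-event trials
  freq <- saccade_frequency(ev, kept)
  freq <- dplyr::left_join(freq,
                           dplyr::select(kept, dplyr::all_of(keys),
                                         "reward_cents",
                                         "duration_condition"),
                           by = keys)

  # per-trial hits
  if (!is.null(gaze) && !is.null(layouts)) {
    hit_tbl <- dplyr::group_modify(
      dplyr::group_by(dplyr::semi_join(gaze, kept, by = keys),
                      .data$subject, .data$block, .data$trial),
      function(.x, .y) {
        lay <- dplyr::semi_join(layouts, .y, by = keys)
        tibble::tibble(n_hits = nrow(count_hits(
          .x, lay, mode = hit_mode, geometry = geometry,
          require_refixation = require_refixation)))
      })
    hit_tbl <- dplyr::left_join(dplyr::ungroup(hit_tbl),
                                dplyr::select(kept, dplyr::all_of(keys),
                                              "reward_cents",
                                              "duration_condition"),
                                by = keys)
    hits_cell <- dplyr::summarise(
      dplyr::group_by(hit_tbl, .data$subject, .data$reward_cents,
                      .data$duration_condition),
      n_hits = mean(.data$n_hits), .groups = "drop")
  } else {
    hits_cell <- NULL
  }

  cells <- dplyr::summarise(
    dplyr::group_by(ev, .data$subject, .data$reward_cents,
                    .data$duration_condition),
    peak_vel = mean(.data$peak_vel_deg_s),
    amplitude = mean(.data$amplitude_deg),
    endpoint_error = mean(.data$landing_error_deg),
    vigor = vigor_ratio(dplyr::pick("amplitude_deg", "peak_vel_deg_s"),
                        fits[[as.character(.data$subject[1])]]),
    .groups = "drop")

  freq_cell <- dplyr::summarise(
    dplyr::group_by(freq, .data$subject, .data$reward_cents,
                    .data$duration_condition),
    frequency = mean(.data$frequency), .groups = "drop")

  out <- dplyr::full_join(freq_cell, cells,
                          by = c("subject", "reward_cents",
                                 "duration_condition"))
  if (!is.null(hits_cell)) {
    out <- dplyr::left_join(out, hits_cell,
                            by = c("subject", "reward_cents",
                                   "duration_condition"))
  } else {
    out$n_hits <- NA_real_
  }
  n_cells <- length(unique(out$reward_cents)) *
    length(unique(out$duration_condition))
  per_subj <- dplyr::count(out, .data$subject)
  if (any(per_subj$n < n_cells) || anyNA(out$peak_vel)) {
    rlang::warn("Some subjects have empty condition cells.")
  }
  dplyr::select(out, "subject", "reward_cents", "duration_condition",
                "n_hits", "frequency", "peak_vel", "vigor", "amplitude",
                "endpoint_error")
}
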