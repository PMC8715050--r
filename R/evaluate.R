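# Detector evaluation against ground truth.

#' Match detected events to ground truth
#'
#' Greedy one-to-one matching of detected saccades to ground-truth events:
#' a detected event matches a true event when their time intervals overlap
#' (among several overlap candidates, the one with the nearest onset is
#' taken).  Sensitivity is the matched fraction of true events, precision
#' the matched fraction of detected events, and the signed onset errors of
#' the matches quantify onset timing accuracy separately.
#'
#' @param truth Ground-truth events with `onset_ms`, `offset_ms`.
#' @param detected Detected events with `onset_ms`, `offset_ms`.
#' @return A list: `n_truth`, `n_detected`, `n_matched`, `sensitivity`,
#'   `precision`, `onset_errors_ms` (signed, one per match).
#' @export
match_events <- function(truth, detected) {
  nt <- nrow(truth); nd <- nrow(detected)
  if (nt == 0 || nd == 0) {
    return(list(n_truth = nt, n_detected = nd, n_matched = 0L,
                sensitivity = if (nt == 0) NA_real_ else 0,
                precision = if (nd == 0) NA_real_ else 0,
                onset_errors_ms = numeric()))
  }
  used <- rep(FALSE, nd)
  errs <- numeric()
  for (i in order(truth$onset_ms)) {
    overlap <- !used & detected$onset_ms < truth$offset_ms[i] &
      detected$offset_ms > truth$onset_ms[i]
    if (!any(overlap)) next
    cand <- which(overlap)
    j <- cand[which.min(abs(detected$onset_ms[cand] - truth$onset_ms[i]))]
    used[j] <- TRUE
    errs <- c(errs, detected$onset_ms[j] - truth$onset_ms[i])
  }
  m <- sum(used)
  list(n_truth = nt, n_detected = nd, n_matched = m,
       sensitivity = m / nt, precision = m / nd,
       onset_errors_ms = errs)
}

#' Detector recovery experiment on synthetic trials
#'
#' Synthesises `n_trials` single-subject trials at a given measurement-noise
#' level, runs a detector on each, and accumulates event-level sensitivity
#' and precision against the generator's ground truth.
#'
#' @param n_trials Number of trials.
#' @param algorithms Detectors to evaluate on the same trials
#'   (`"fixed"`, `"adaptive"`, or both).
#' @param noise_sd Measurement noise, degrees.
#' @param agent Optional [agent_profile()] override (noise is set from
#'   `noise_sd`).
#' @param geometry A [task_geometry()].
#' @param seed Master seed.
#' @return One row per algorithm: `algorithm`, `noise_sd`, `n_trials`,
#'   `n_truth`, `n_detected`, `sensitivity`, `precision`,
#'   `mean_abs_onset_err_ms`, `frac_onset_within_4ms`,
#'   `max_abs_onset_err_ms`.
#' @export
detector_recovery <- function(n_trials,
                              algorithms = c("fixed", "adaptive"),
                              noise_sd = 0, agent = NULL,
                              geometry = task_geometry(), seed = 1) {
  base <- agent %||% agent_profile()
  base$noise_sd <- noise_sd
  acc <- lapply(algorithms, function(a) {
    list(t = 0L, d = 0L, m = 0L, errs = numeric())
  })
  names(acc) <- algorithms
  for (i in seq_len(n_trials)) {
    lay <- make_layout(geometry, seed = derive_seed(seed, i, 1))
    tr <- synth_trial(lay, base, geometry = geometry,
                      seed = derive_seed(seed, i, 2))
    for (a in algorithms) {
      ev <- detect_saccades(tr$trace, algorithm = a)
      m <- match_events(tr$events, ev)
      acc[[a]]$t <- acc[[a]]$t + m$n_truth
      acc[[a]]$d <- acc[[a]]$d + m$n_detected
      acc[[a]]$m <- acc[[a]]$m + m$n_matched
      acc[[a]]$errs <- c(acc[[a]]$errs, m$onset_errors_ms)
    }
  }
  purrr::list_rbind(purrr::map(algorithms, function(a) {
    z <- acc[[a]]
    tibble::tibble(algorithm = a, noise_sd = noise_sd,
                   n_trials = n_trials, n_truth = z$t, n_detected = z$d,
                   sensitivity = z$m / z$t, precision = z$m / z$d,
                   mean_abs_onset_err_ms = mean(abs(z$errs)),
                   frac_onset_within_4ms = mean(abs(z$errs) <= 4),
                   max_abs_onset_err_ms = max(abs(z$errs)))
  }))
}
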