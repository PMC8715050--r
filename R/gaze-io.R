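# Plain-text I/O for gaze samples, trial metadata, events and 4AFC tables,
# plus resampling and the missing-data trial exclusion rule.

gaze_cols <- c("subject", "block", "trial", "t_ms", "x_deg", "y_deg", "valid")

#' Write / read a gaze sample table
#'
#' The on-disk dialect is delimiter-separated UTF-8 text with header
#' `subject,block,trial,t_ms,x_deg,y_deg,valid` and '.' decimals; one file
#' holds a whole dataset.  `read_gaze()` validates the header and checks that
#' time is strictly increasing with a constant step within every
#' (subject, block, trial) cell, naming the offending trial otherwise.
#' A write -> read round trip reproduces all samples.
#'
#' @param gaze A tibble with the columns above ([synth_experiment()]'s
#'   `$gaze` component has this shape).
#' @param path File path.
#' @return `read_gaze()` returns the validated tibble (with a
#'   `sampling_rate` attribute inferred from the time step);
#'   `write_gaze()` returns `path` invisibly.
#' @export
write_gaze <- function(gaze, path) {
  abort_if(!all(gaze_cols %in% names(gaze)),
           paste("Gaze table must have columns:",
                 paste(gaze_cols, collapse = ", ")),
           class = "ocuvigor_format_error")
  readr::write_csv(gaze[gaze_cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  gaze <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            subject = readr::col_integer(),
                            block = readr::col_integer(),
                            trial = readr::col_integer(),
                            t_ms = readr::col_double(),
                            x_deg = readr::col_double(),
                            y_deg = readr::col_double(),
                            valid = readr::col_logical()))
  abort_if(!all(gaze_cols %in% names(gaze)),
           paste("Gaze file must have columns:",
                 paste(gaze_cols, collapse = ", ")),
           class = "ocuvigor_format_error")
  steps <- dplyr::summarise(
    dplyr::group_by(gaze, .data$subject, .data$block, .data$trial),
    ok = all(diff(.data$t_ms) > 0) &&
      (dplyr::n() < 3 || max(abs(diff(diff(.data$t_ms)))) < 1e-9),
    step = if (dplyr::n() > 1) .data$t_ms[2] - .data$t_ms[1] else NA_real_,
    .groups = "drop")
  bad <- steps[!steps$ok, ]
  abort_if(nrow(bad) > 0,
           sprintf("Non-monotone or irregular time in trial subject=%d block=%d trial=%d.",
                   bad$subject[1], bad$block[1], bad$trial[1]),
           class = "ocuvigor_format_error")
  rate <- 1000 / stats::median(steps$step, na.rm = TRUE)
  attr(gaze, "sampling_rate") <- rate
  gaze
}

#' Write / read trial metadata, event and 4AFC tables
#'
#' Thin CSV wrappers for the remaining dataset tables.  Trial metadata uses
#' columns `subject,block,trial,reward_cents,duration_condition`; event
#' tables use the detector output columns; 4AFC tables use
#' `subject,phase,duration_condition,coin,response,correct,seen`.
#'
#' @param x The table to write.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# Linear interpolation within one trial, propagating invalid gaps: inserted
# samples between an invalid neighbour and anything else stay invalid.
resample_trial <- function(trace, to = 1000) {
  step_in <- trace$t_ms[2] - trace$t_ms[1]
  rate_in <- 1000 / step_in
  if (abs(rate_in - to) < 1e-9) return(trace)
  abort_if(to %% rate_in != 0,
           sprintf("Input rate %g Hz does not divide %g Hz.", rate_in, to),
           class = "ocuvigor_format_error")
  t_out <- seq(trace$t_ms[1], trace$t_ms[nrow(trace)], by = 1000 / to)
  x <- trace$x_deg; y <- trace$y_deg
  ok <- trace$valid & is.finite(x) & is.finite(y)
  interp <- function(v) {
    if (sum(ok) < 2) return(rep(NA_real_, length(t_out)))
    stats::approx(trace$t_ms[ok], v[ok], xout = t_out, rule = 1)$y
  }
  xo <- interp(x); yo <- interp(y)
  # a new sample is valid only if both bracketing original samples are valid
  idx_lo <- findInterval(t_out, trace$t_ms)
  idx_hi <- pmin(idx_lo + 1L, nrow(trace))
  on_grid <- abs(t_out - trace$t_ms[idx_lo]) < 1e-9
  valid_out <- ifelse(on_grid, ok[idx_lo], ok[idx_lo] & ok[idx_hi])
  xo[on_grid] <- x[idx_lo[on_grid]]
  yo[on_grid] <- y[idx_lo[on_grid]]
  xo[!valid_out] <- NA_real_; yo[!valid_out] <- NA_real_
  tibble::tibble(t_ms = t_out, x_deg = xo, y_deg = yo, valid = valid_out)
}

#' Resample gaze recordings to a target rate
#'
#' Upsamples lower-rate recordings (e.g. 250 Hz) to the analysis rate by
#' linear interpolation.  Original samples are preserved bit-for-bit at
#' coincident timestamps; inserted samples adjacent to an invalid original
#' sample are themselves invalid (no interpolation across dropouts).
#' Input already at the target rate is returned unchanged.
#'
#' @param gaze A gaze tibble, either a single trial (`t_ms,x_deg,y_deg,valid`)
#'   or a dataset with `subject,block,trial` key columns.
#' @param to Target sampling rate, Hz (must be an integer multiple of the
#'   input rate).
#' @return A tibble of the same shape at the target rate.
#' @export
resample_gaze <- function(gaze, to = 1000) {
  if (all(c("subject", "block", "trial") %in% names(gaze))) {
    out <- dplyr::group_modify(
      dplyr::group_by(gaze, .data$subject, .data$block, .data$trial),
      ~ resample_trial(.x, to = to))
    dplyr::ungroup(out)
  } else {
    resample_trial(gaze, to = to)
  }
}

#' Missing-data fraction and trial exclusion
#'
#' A sample is missing when it is flagged invalid or has a non-finite
#' coordinate.  A trial is excluded when more than `max_missing` (default
#' 25%) of its samples in the task window are missing — strictly greater, so
#' a trial at exactly 25% is retained.
#'
#' @param trace One trial's gaze tibble.
#' @param max_missing Exclusion threshold as a fraction.
#' @return `missing_fraction()`: scalar in \\[0, 1\\]; `exclude_trial()`:
#'   logical.
#' @export
missing_fraction <- function(trace) {
  abort_if(nrow(trace) == 0, "Empty trace.",
           class = "ocuvigor_degenerate_error")
  bad <- !trace$valid | !is.finite(trace$x_deg) | !is.finite(trace$y_deg)
  mean(bad)
}

#' @rdname missing_fraction
#' @export
exclude_trial <- function(trace, max_missing = 0.25) {
  missing_fraction(trace) > max_missing
}
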