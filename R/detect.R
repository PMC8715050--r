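# Saccade detection: Savitzky-Golay smoothing, 2-D velocity, and the two
# detection algorithms (fixed 35 deg/s threshold; noise-adaptive thresholds).

#' Detector configurations
#'
#' `detector_config()` parameterises the fixed-threshold algorithm: positions
#' are smoothed with a Savitzky-Golay filter (order 2, 20 ms window), a
#' saccade onset is the first sample whose 2-D velocity exceeds
#' `velocity_threshold`, the offset is the first post-peak sample where
#' velocity drops below the threshold and |acceleration| drops below
#' `accel_threshold`, events shorter than `min_duration` are discarded, and
#' when the interval between an offset and the next onset is below `min_isi`
#' the later event is discarded.
#'
#' A 20 ms window at 1000 Hz is 20 samples; the filter needs odd support, so
#' the nearest odd width (21 samples) is used.
#'
#' `adaptive_config()` parameterises the noise-adaptive algorithm: the peak
#' threshold is mean + `peak_k` SD and the onset/offset threshold mean +
#' `onset_k` SD of the trial's velocity samples.  With `iterate = TRUE`
#' (default) the thresholds are recomputed from the samples below the current
#' peak threshold until convergence, so they track the fixation/noise
#' velocity distribution rather than being inflated by the saccades
#' themselves; `iterate = FALSE` uses the whole-trial moments once.
#' `min_onset_threshold` / `min_peak_threshold` are numerical floors that
#' only bind on essentially noise-free signals, where the converged
#' thresholds would collapse towards zero.  Events with a preceding fixation
#' shorter than `min_fixation` are discarded.
#'
#' @param velocity_threshold 2-D velocity threshold, degrees/s.
#' @param accel_threshold Offset acceleration criterion, degrees/s^2.
#' @param min_duration Minimum event duration, ms.
#' @param min_isi Minimum offset-to-next-onset interval, ms.
#' @param sg_order,sg_window_ms Savitzky-Golay polynomial order and window.
#' @return A list of class `detector_config` / `adaptive_config`.
#' @export
detector_config <- function(velocity_threshold = 35,
                            accel_threshold = 1000,
                            min_duration = 10,
                            min_isi = 40,
                            sg_order = 2,
                            sg_window_ms = 20) {
  abort_if(velocity_threshold <= 0 || min_duration <= 0,
           "Thresholds must be positive.", class = "ocuvigor_config_error")
  structure(list(velocity_threshold = velocity_threshold,
                 accel_threshold = accel_threshold,
                 min_duration = min_duration, min_isi = min_isi,
                 sg_order = sg_order, sg_window_ms = sg_window_ms),
            class = "detector_config")
}

#' @rdname detector_config
#' @param peak_k,onset_k SD multipliers for the peak and onset thresholds.
#' @param min_fixation Minimum preceding fixation duration, ms.
#' @param iterate Recompute thresholds from below-threshold samples until
#'   convergence.
#' @param init_threshold Starting peak threshold (degrees/s) for the
#'   iteration; must sit below typical saccade peaks so the first
#'   below-threshold set is dominated by fixation samples.
#' @param max_iter,tol Iteration cap and convergence tolerance (degrees/s).
#' @param min_onset_threshold,min_peak_threshold Numerical floors, degrees/s.
#' @export
adaptive_config <- function(peak_k = 4,
                            onset_k = 2.5,
                            min_duration = 10,
                            min_fixation = 40,
                            iterate = TRUE,
                            init_threshold = 100,
                            max_iter = 20,
                            tol = 1,
                            min_onset_threshold = 10,
                            min_peak_threshold = 10,
                            sg_order = 2,
                            sg_window_ms = 20) {
  abort_if(!(peak_k > onset_k && onset_k > 0),
           "Need peak_k > onset_k > 0.", class = "ocuvigor_config_error")
  structure(list(peak_k = peak_k, onset_k = onset_k,
                 min_duration = min_duration, min_fixation = min_fixation,
                 iterate = iterate, init_threshold = init_threshold,
                 max_iter = max_iter, tol = tol,
                 min_onset_threshold = min_onset_threshold,
                 min_peak_threshold = min_peak_threshold,
                 sg_order = sg_order, sg_window_ms = sg_window_ms),
            class = "adaptive_config")
}

sg_window_samples <- function(window_ms, rate) {
  w <- round(window_ms * rate / 1000)
  if (w %% 2 == 0) w <- w + 1L
  as.integer(w)
}

#' Savitzky-Golay smoothing of gaze positions
#'
#' Filters x and y with a least-squares polynomial filter.  The filter is
#' polynomial-preserving: inputs that are exact polynomials of degree <=
#' `order` pass through unchanged in the interior.  Valid segments shorter
#' than the window are left unfiltered and counted in the
#' `unfiltered_segments` attribute.
#'
#' @param trace One trial's gaze tibble (`t_ms`, `x_deg`, `y_deg`, `valid`).
#' @param order Polynomial order.
#' @param window_ms Window length in ms (rounded to the nearest odd number
#'   of samples).
#' @return The trace with filtered `x_deg`, `y_deg`.
#' @export
smooth_gaze <- function(trace, order = 2, window_ms = 20) {
  rate <- 1000 / (trace$t_ms[2] - trace$t_ms[1])
  w <- sg_window_samples(window_ms, rate)
  abort_if(w <= order, "Window must exceed the polynomial order.",
           class = "ocuvigor_config_error")
  ok <- trace$valid & is.finite(trace$x_deg) & is.finite(trace$y_deg)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  x <- trace$x_deg; y <- trace$y_deg
  skipped <- 0L
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    idx <- starts[r]:ends[r]
    if (length(idx) < w) { skipped <- skipped + 1L; next }
    x[idx] <- signal::sgolayfilt(trace$x_deg[idx], p = order, n = w)
    y[idx] <- signal::sgolayfilt(trace$y_deg[idx], p = order, n = w)
  }
  out <- dplyr::mutate(trace, x_deg = x, y_deg = y)
  attr(out, "unfiltered_segments") <- skipped
  out
}

#' Two-dimensional velocity and acceleration series
#'
#' Velocity components are central differences of the (already filtered)
#' positions; speed is their Euclidean norm; acceleration is the central
#' difference of speed.  Endpoints use one-sided differences.
#'
#' @param trace A (filtered) gaze tibble for one contiguous valid segment.
#' @return The trace with added `speed_deg_s` and `accel_deg_s2` columns.
#' @export
speed_series <- function(trace) {
  n <- nrow(trace)
  abort_if(n < 3, "Need at least 3 samples for central differences.",
           class = "ocuvigor_degenerate_error")
  dt <- (trace$t_ms[2] - trace$t_ms[1]) / 1000
  cdiff <- function(v) {
    d <- numeric(n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
    d[1] <- (v[2] - v[1]) / dt
    d[n] <- (v[n] - v[n - 1]) / dt
    d
  }
  vx <- cdiff(trace$x_deg)
  vy <- cdiff(trace$y_deg)
  speed <- sqrt(vx^2 + vy^2)
  dplyr::mutate(trace, speed_deg_s = speed, accel_deg_s2 = cdiff(speed))
}

empty_events <- function() {
  tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                 duration_ms = numeric(), amplitude_deg = numeric(),
                 peak_vel_deg_s = numeric(),
                 x_onset = numeric(), y_onset = numeric(),
                 x_offset = numeric(), y_offset = numeric())
}

make_events <- function(seg, onsets, offsets) {
  if (length(onsets) == 0) return(empty_events())
  peak <- purrr::map2_dbl(onsets, offsets,
                          ~ max(seg$speed_deg_s[.x:.y]))
  tibble::tibble(
    onset_ms = seg$t_ms[onsets],
    offset_ms = seg$t_ms[offsets],
    duration_ms = seg$t_ms[offsets] - seg$t_ms[onsets],
    amplitude_deg = sqrt((seg$x_deg[offsets] - seg$x_deg[onsets])^2 +
                           (seg$y_deg[offsets] - seg$y_deg[onsets])^2),
    peak_vel_deg_s = peak,
    x_onset = seg$x_deg[onsets], y_onset = seg$y_deg[onsets],
    x_offset = seg$x_deg[offsets], y_offset = seg$y_deg[offsets]
  )
}

detect_fixed_segment <- function(seg, cfg) {
  v <- seg$speed_deg_s; a <- seg$accel_deg_s2
  n <- length(v)
  vt <- cfg$velocity_threshold
  above <- v > vt
  if (!any(above)) return(empty_events())
  runs <- rle(above)
  run_ends <- cumsum(runs$lengths)
  run_starts <- run_ends - runs$lengths + 1L
  onsets <- integer(); offsets <- integer()
  prev_off <- 0L
  for (r in which(runs$values)) {
    onset <- run_starts[r]
    if (onset <= prev_off) next  # swallowed by the previous offset search
    peak <- onset - 1L + which.max(v[onset:run_ends[r]])
    k <- peak
    while (k < n && !(v[k] < vt && abs(a[k]) < cfg$accel_threshold)) {
      k <- k + 1L
    }
    onsets <- c(onsets, onset); offsets <- c(offsets, k)
    prev_off <- k
  }
  make_events(seg, onsets, offsets)
}

iterate_thresholds <- function(v, cfg) {
  mu <- mean(v); s <- stats::sd(v)
  if (is.na(s) || s == 0) return(NULL)
  pt <- mu + cfg$peak_k * s
  ot <- mu + cfg$onset_k * s
  if (cfg$iterate) {
    pt <- cfg$init_threshold
    for (it in seq_len(cfg$max_iter)) {
      below <- v < pt
      if (!any(below)) break
      mu_b <- mean(v[below]); s_b <- stats::sd(v[below])
      if (is.na(s_b)) break
      pt_new <- mu_b + cfg$peak_k * s_b
      ot <- mu_b + cfg$onset_k * s_b
      if (abs(pt_new - pt) < cfg$tol) { pt <- pt_new; break }
      pt <- pt_new
    }
  }
  ot <- max(ot, cfg$min_onset_threshold)
  pt <- max(pt, cfg$min_peak_threshold, ot * 1.01)
  list(peak = pt, onset = ot)
}

detect_adaptive_segment <- function(seg, cfg) {
  v <- seg$speed_deg_s
  n <- length(v)
  th <- iterate_thresholds(v, cfg)
  if (is.null(th)) return(empty_events())
  above <- v > th$peak
  if (!any(above)) return(empty_events())
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  onsets <- integer(); offsets <- integer()
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    i <- starts[r]
    while (i > 1 && v[i - 1] >= th$onset) i <- i - 1L
    j <- ends[r]
    while (j < n && v[j + 1] >= th$onset) j <- j + 1L
    if (length(offsets) && i <= offsets[length(offsets)]) {
      offsets[length(offsets)] <- max(offsets[length(offsets)], j)
    } else {
      onsets <- c(onsets, i); offsets <- c(offsets, j)
    }
  }
  ev <- make_events(seg, onsets, offsets)
  attr(ev, "thresholds") <- th
  ev
}

# Split a trial into contiguous valid segments long enough to filter.
valid_segments <- function(trace, min_len) {
  ok <- trace$valid & is.finite(trace$x_deg) & is.finite(trace$y_deg)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= min_len)
  purrr::map(keep, ~ trace[starts[.x]:ends[.x], ])
}

detect_trial <- function(trace, algorithm, cfg) {
  rate <- 1000 / (trace$t_ms[2] - trace$t_ms[1])
  w <- sg_window_samples(cfg$sg_window_ms, rate)
  segs <- valid_segments(trace, min_len = max(w, 3L))
  ev <- purrr::map(segs, function(s) {
    s <- smooth_gaze(s, order = cfg$sg_order, window_ms = cfg$sg_window_ms)
    s <- speed_series(s)
    if (algorithm == "fixed") detect_fixed_segment(s, cfg)
    else {
      out <- detect_adaptive_segment(s, cfg)
      attr(out, "seg_start") <- s$t_ms[1]
      out
    }
  })
  if (algorithm == "adaptive") {
    # preceding-fixation rule, applied within each segment
    ev <- purrr::map(ev, function(e) {
      if (nrow(e) == 0) return(e)
      seg_start <- attr(e, "seg_start")
      e <- e[e$duration_ms >= cfg$min_duration, ]
      keep <- logical(nrow(e))
      prev_off <- seg_start
      for (i in seq_len(nrow(e))) {
        keep[i] <- (e$onset_ms[i] - prev_off) >= cfg$min_fixation
        if (keep[i]) prev_off <- e$offset_ms[i]
      }
      e[keep, ]
    })
    events <- dplyr::arrange(purrr::list_rbind(ev), .data$onset_ms)
  } else {
    events <- dplyr::arrange(purrr::list_rbind(ev), .data$onset_ms)
    if (nrow(events)) {
      events <- events[events$duration_ms >= cfg$min_duration, ]
      # ISI rule: when offset-to-next-onset < min_isi, drop the later event
      keep <- logical(nrow(events))
      prev_off <- -Inf
      for (i in seq_len(nrow(events))) {
        keep[i] <- (events$onset_ms[i] - prev_off) >= cfg$min_isi
        if (keep[i]) prev_off <- events$offset_ms[i]
      }
      events <- events[keep, ]
    }
  }
  if (nrow(events) == 0) empty_events() else events
}

#' Detect saccades in gaze recordings
#'
#' Applies one of the two detection algorithms to each trial of a gaze
#' dataset.  Invalid-sample gaps split a trial into segments; no event spans
#' a gap.  Both algorithms are deterministic.
#'
#' @param gaze A gaze tibble: either a single trial (`t_ms`, `x_deg`,
#'   `y_deg`, `valid`) or a dataset keyed by `subject`, `block`, `trial`.
#' @param algorithm `"fixed"` (35 deg/s threshold) or `"adaptive"`
#'   (noise-scaled thresholds).
#' @param config A [detector_config()] or [adaptive_config()]; defaults are
#'   chosen to match `algorithm`.
#' @return An event tibble (keys if present, plus `algorithm`, `onset_ms`,
#'   `offset_ms`, `duration_ms`, `amplitude_deg`, `peak_vel_deg_s`, and
#'   onset/offset positions).  Amplitude is the Euclidean distance between
#'   the filtered positions at onset and offset; peak velocity is the
#'   maximum filtered 2-D velocity between them.
#' @examples
#' tr <- synth_trial(make_layout(seed = 1), agent_profile(noise_sd = 0),
#'                   seed = 1)
#' ev <- detect_saccades(tr$trace, "fixed")
#' nrow(ev) == nrow(tr$events)
#' @export
detect_saccades <- function(gaze,
                            algorithm = c("fixed", "adaptive"),
                            config = NULL) {
  algorithm <- match.arg(algorithm)
  cfg <- config %||% if (algorithm == "fixed") detector_config()
  else adaptive_config()
  if (algorithm == "fixed") stopifnot(inherits(cfg, "detector_config"))
  else stopifnot(inherits(cfg, "adaptive_config"))
  keyed <- all(c("subject", "block", "trial") %in% names(gaze))
  if (keyed) {
    out <- dplyr::group_modify(
      dplyr::group_by(gaze, .data$subject, .data$block, .data$trial),
      ~ detect_trial(.x, algorithm, cfg))
    out <- dplyr::ungroup(out)
  } else {
    out <- detect_trial(gaze, algorithm, cfg)
  }
  dplyr::mutate(out, algorithm = algorithm,
                .before = "onset_ms")
}
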