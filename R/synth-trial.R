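# Trial-level gaze synthesis: alternating fixation -> target -> fixation
# saccades with raised-cosine kinematics on the agent's main sequence.

# Truncated-normal draw (lower truncation only) via inverse CDF.
rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd <= 0) return(pmax(rep(mean, n), lower))
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, 1), mean, sd)
}

#' Synthesise one trial of the speeded saccade task
#'
#' Simulates an 8-second trial in which the observer alternates between the
#' central fixation cross and peripheral targets.  Each leg is a single
#' primary saccade (see [synth_saccade()] for the waveform) whose peak
#' velocity follows the agent's main sequence (scaled by `vel_gain`); intersaccadic pauses are
#' truncated-normal with mean `isi_mean / freq_gain`, so the frequency gain
#' scales the number of target visits.  When a target-directed saccade lands
#' outside the online hit radius, a small corrective saccade is issued with
#' probability `agent$p_corrective`.  Gaussian measurement noise of
#' `agent$noise_sd` degrees is added per sample and axis; optional invalid
#' gaps emulate tracker dropouts.
#'
#' @param layout Target layout tibble from [make_layout()].
#' @param agent An [agent_profile()].
#' @param freq_gain,vel_gain Condition multipliers for this trial.
#' @param geometry A [task_geometry()].
#' @param seed Optional integer seed (caller RNG untouched).
#' @param n_gaps Number of invalid (tracker-dropout) gaps to inject.
#' @param gap_ms Length of each injected gap, ms.
#' @return A list with `trace` (tibble `t_ms`, `x_deg`, `y_deg`, `valid`) and
#'   `events`, the chronological ground truth (`onset_ms`, `offset_ms`,
#'   `amplitude_deg`, `peak_vel_deg_s`, `destination`, `target`,
#'   `corrective`, `x_land`, `y_land`).  Onsets are real-valued times; the
#'   trace is sampled on the regular grid.
#' @export
synth_trial <- function(layout, agent,
                        freq_gain = 1, vel_gain = 1,
                        geometry = task_geometry(),
                        seed = NULL, n_gaps = 0, gap_ms = 100) {
  with_seed(seed, {
    dt <- 1000 / geometry$sampling_rate
    dur_tot <- geometry$trial_duration
    n <- round(dur_tot / dt)
    t_grid <- (seq_len(n) - 1) * dt

    target_order <- sample.int(nrow(layout))
    next_target <- 1L
    events <- list()
    cur <- c(0, 0)
    now <- rtrunc_norm(1, agent$isi_mean / freq_gain, agent$isi_sd,
                       agent$isi_min)
    at_fixation <- TRUE
    pending_corrective <- NULL  # target row index needing correction

    add_event <- function(from, to, dest, target_idx, corrective, now) {
      amp <- sqrt(sum((to - from)^2))
      vp <- vel_gain * main_sequence_velocity(amp, agent$alpha, agent$beta)
      dur <- amp / (vp * .sacc_gain) * 1000
      if (dur < 2 * dt) return(NULL)  # degenerate leg: no saccade emitted
      # place the speed peak on the sample grid so the sampled maximum equals
      # the analytic peak exactly
      tp <- saccade_peak_time(dur)
      t0 <- round((now + tp) / dt) * dt - tp
      if (t0 < now - dt / 2) t0 <- t0 + dt
      if (t0 + dur > dur_tot) return("stop")
      list(onset_ms = t0, offset_ms = t0 + dur, amplitude_deg = amp,
           peak_vel_deg_s = vp, destination = dest,
           target = target_idx, corrective = corrective,
           from_x = from[1], from_y = from[2],
           x_land = to[1], y_land = to[2])
    }

    repeat {
      if (!is.null(pending_corrective)) {
        k <- pending_corrective
        pending_corrective <- NULL
        aim <- c(layout$x_deg[k], layout$y_deg[k])
        land <- aim + stats::rnorm(2, 0, agent$landing_sd / 3)
        ev <- add_event(cur, land, "target", layout$target[k], TRUE, now)
      } else if (at_fixation) {
        k <- target_order[next_target]
        next_target <- if (next_target == length(target_order)) 1L else next_target + 1L
        aim <- c(layout$x_deg[k], layout$y_deg[k])
        land <- aim + stats::rnorm(2, 0, agent$landing_sd)
        ev <- add_event(cur, land, "target", layout$target[k], FALSE, now)
        if (is.list(ev)) {
          err <- sqrt(sum((land - aim)^2))
          if (err > geometry$hit_radius_online &&
              stats::runif(1) < agent$p_corrective) {
            pending_corrective <- k
          }
        }
      } else {
        land <- stats::rnorm(2, 0, agent$landing_sd / 2)
        ev <- add_event(cur, land, "fixation", NA_integer_, FALSE, now)
      }
      if (identical(ev, "stop")) break
      if (is.list(ev)) {
        events[[length(events) + 1L]] <- ev
        cur <- c(ev$x_land, ev$y_land)
        now <- ev$offset_ms +
          rtrunc_norm(1, agent$isi_mean / freq_gain, agent$isi_sd,
                      agent$isi_min)
        if (is.null(pending_corrective)) at_fixation <- !at_fixation
      } else {
        # degenerate (near-zero) leg: treat as completed without a saccade
        cur <- land
        if (is.null(pending_corrective)) at_fixation <- !at_fixation
      }
    }

    events <- dplyr::bind_rows(events)
    x <- rep(0, n); y <- rep(0, n)
    if (nrow(events) > 0) {
      for (i in seq_len(nrow(events))) {
        e <- events[i, ]
        seg <- t_grid >= e$onset_ms
        x[seg] <- e$x_land; y[seg] <- e$y_land
        inside <- which(t_grid >= e$onset_ms & t_grid < e$offset_ms)
        if (length(inside)) {
          disp <- saccade_pos_profile(t_grid[inside] - e$onset_ms,
                                      e$peak_vel_deg_s,
                                      e$offset_ms - e$onset_ms)
          dvec <- c(e$x_land - e$from_x, e$y_land - e$from_y)
          dvec <- dvec / sqrt(sum(dvec^2))
          x[inside] <- e$from_x + dvec[1] * disp
          y[inside] <- e$from_y + dvec[2] * disp
        }
      }
    }
    if (agent$noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, agent$noise_sd)
      y <- y + stats::rnorm(n, 0, agent$noise_sd)
    }
    valid <- rep(TRUE, n)
    if (n_gaps > 0) {
      gap_len <- max(1L, round(gap_ms / dt))
      starts <- sample.int(max(1L, n - gap_len), n_gaps)
      for (s in starts) valid[s:min(n, s + gap_len - 1L)] <- FALSE
    }
    x[!valid] <- NA_real_; y[!valid] <- NA_real_

    if (nrow(events) > 0) {
      events <- dplyr::select(events, -"from_x", -"from_y")
    } else {
      events <- tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                               amplitude_deg = numeric(),
                               peak_vel_deg_s = numeric(),
                               destination = character(),
                               target = integer(), corrective = logical(),
                               x_land = numeric(), y_land = numeric())
    }
    list(
      trace = tibble::tibble(t_ms = t_grid, x_deg = x, y_deg = y,
                             valid = valid),
      events = events
    )
  })
}
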