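#' Kinematic profile of a simulated observer
#'
#' Bundles the parameters of the generating model for one simulated
#' participant: the hyperbolic main sequence linking saccade amplitude to
#' peak velocity, the intersaccadic pause distribution, end-point scatter,
#' measurement noise, and condition-wise frequency/velocity gain multipliers.
#'
#' The main sequence is `v(x) = alpha * (1 - 1 / (1 + beta * x))`, with `x`
#' the amplitude in degrees and `v` the peak velocity in degrees/s; `alpha`
#' is the asymptotic velocity and `beta` the curvature.  Defaults (alpha =
#' 560 deg/s, beta = 0.25 /deg) give realistic human kinematics, e.g. a peak
#' velocity of 400 deg/s for a 10 degree saccade.
#'
#' @param alpha Main-sequence asymptote, degrees/s (> 0).
#' @param beta Main-sequence curvature, 1/degrees (> 0).
#' @param isi_mean,isi_sd Mean and SD (ms) of the truncated-normal
#'   intersaccadic pause distribution.
#' @param isi_min Lower truncation bound of the pause distribution, ms.
#' @param landing_sd Per-axis end-point scatter, degrees.
#' @param noise_sd Per-sample, per-axis Gaussian measurement noise, degrees.
#' @param p_corrective Probability of issuing a small corrective saccade when
#'   a primary saccade lands outside the online hit radius.
#' @param freq_gain,vel_gain Named numeric vectors of per-condition
#'   multipliers (names are condition labels); a gain of 1 is the baseline.
#'   Frequency gain shortens intersaccadic pauses; velocity gain scales peak
#'   velocity relative to the main sequence.
#' @return An object of class `agent_profile`.
#' @export
agent_profile <- function(alpha = 560,
                          beta = 0.25,
                          isi_mean = 180,
                          isi_sd = 40,
                          isi_min = 60,
                          landing_sd = 0.8,
                          noise_sd = 0.02,
                          p_corrective = 0.5,
                          freq_gain = c(baseline = 1),
                          vel_gain = c(baseline = 1)) {
  abort_if(alpha <= 0 || beta <= 0, "`alpha` and `beta` must be positive.",
           class = "ocuvigor_agent_error")
  abort_if(noise_sd < 0, "`noise_sd` must be non-negative.",
           class = "ocuvigor_agent_error")
  abort_if(any(freq_gain <= 0) || any(vel_gain <= 0),
           "Condition gains must be positive.",
           class = "ocuvigor_agent_error")
  structure(list(alpha = alpha, beta = beta,
                 isi_mean = isi_mean, isi_sd = isi_sd, isi_min = isi_min,
                 landing_sd = landing_sd, noise_sd = noise_sd,
                 p_corrective = p_corrective,
                 freq_gain = freq_gain, vel_gain = vel_gain),
            class = "agent_profile")
}

#' Main-sequence peak velocity
#'
#' Evaluates the hyperbolic main sequence
#' `v(x) = alpha * (1 - 1 / (1 + beta * x))`.
#'
#' @param amplitude Saccade amplitude(s), degrees.
#' @param alpha Asymptotic peak velocity, degrees/s.
#' @param beta Curvature, 1/degrees.
#' @return Peak velocity, degrees/s (vectorised over `amplitude`).
#' @export
main_sequence_velocity <- function(amplitude, alpha, beta) {
  alpha * (1 - 1 / (1 + beta * amplitude))
}

# Saccadic speed profile: a positively skewed beta-family pulse
#   v(u) = vp * u^2 (1-u)^3 / N,  u = t/D,  N = 2^2 3^3 / 5^5,
# unimodal with its peak at u = 0.4 (time-to-peak ~40% of duration, the skew
# seen in real saccades), zero speed and acceleration at both ends, and
# analytically integrable: the path length is vp * D * B(3,4)/N, so
# D = A / (vp * B(3,4)/N) yields amplitude A exactly.
.sacc_norm <- (2^2 * 3^3) / 5^5           # profile peak normaliser
.sacc_gain <- (1 / 60) / .sacc_norm       # B(3,4)/N: path length / (vp * D)

saccade_pos_profile <- function(t_ms, vp, dur_ms) {
  u <- pmin(pmax(t_ms / dur_ms, 0), 1)
  vp * (dur_ms / 1000) / .sacc_norm *
    (u^3 / 3 - 3 * u^4 / 4 + 3 * u^5 / 5 - u^6 / 6)
}

saccade_speed_profile <- function(t_ms, vp, dur_ms) {
  u <- t_ms / dur_ms
  out <- numeric(length(t_ms))
  inside <- u >= 0 & u <= 1
  out[inside] <- vp * u[inside]^2 * (1 - u[inside])^3 / .sacc_norm
  out
}

# Time of peak speed relative to onset, ms.
saccade_peak_time <- function(dur_ms) 0.4 * dur_ms

#' Synthesise a single saccade waveform
#'
#' Generates the displacement time course of one saccade.  The speed profile
#' is a positively skewed unimodal pulse (rise proportional to t^2, decay to
#' (D - t)^3, peak at 40% of the movement duration — the asymmetry seen in
#' real saccades), zero at both ends, whose peak follows the agent's main
#' sequence (optionally scaled by a condition velocity gain).  The duration
#' is proportional to amplitude / peak velocity (factor ~2.07), and the
#' profile integrates exactly to the requested amplitude.
#'
#' @param amplitude Saccade amplitude, degrees (> 0).
#' @param direction Length-2 unit vector giving movement direction.
#' @param agent An [agent_profile()].
#' @param vel_gain Multiplier on the main-sequence peak velocity.
#' @param dt Sampling step, ms.
#' @return A list with `waveform`, a tibble (`t_ms` relative to saccade
#'   onset, `dx_deg`, `dy_deg` cumulative displacement, `speed_deg_s`), and
#'   `event`, a one-row ground-truth tibble (`onset_ms` = 0, `offset_ms`,
#'   `amplitude_deg`, `peak_vel_deg_s`).
#' @examples
#' s <- synth_saccade(10, c(1, 0), agent_profile())
#' s$event$peak_vel_deg_s # 400 for alpha = 560, beta = 0.25
#' @export
synth_saccade <- function(amplitude, direction, agent, vel_gain = 1, dt = 1) {
  abort_if(amplitude <= 0, "`amplitude` must be positive.",
           class = "ocuvigor_waveform_error")
  abort_if(dt <= 0, "`dt` must be positive.",
           class = "ocuvigor_waveform_error")
  direction <- direction / sqrt(sum(direction^2))
  vp <- vel_gain * main_sequence_velocity(amplitude, agent$alpha, agent$beta)
  dur <- amplitude / (vp * .sacc_gain) * 1000  # ms
  abort_if(dur < 2 * dt,
           sprintf("Amplitude %.3g deg gives duration %.3g ms < 2 dt.",
                   amplitude, dur),
           class = "ocuvigor_waveform_error")
  t_ms <- seq(0, dur + dt, by = dt)
  disp <- saccade_pos_profile(t_ms, vp, dur)
  speed <- saccade_speed_profile(t_ms, vp, dur)
  list(
    waveform = tibble::tibble(
      t_ms = t_ms,
      dx_deg = direction[1] * disp,
      dy_deg = direction[2] * disp,
      speed_deg_s = speed
    ),
    event = tibble::tibble(
      onset_ms = 0,
      offset_ms = dur,
      amplitude_deg = amplitude,
      peak_vel_deg_s = vp
    )
  )
}
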