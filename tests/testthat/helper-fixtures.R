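# Shared fixtures built in code.

# A short trace with a single step-ramp "spike" of the given velocity
# (deg/s) lasting `dur_ms`, surrounded by fixation.
spike_trace <- function(velocity, dur_ms = 8, n = 600, at = 300) {
  x <- rep(0, n)
  ramp <- at + seq_len(dur_ms) - 1L
  x[ramp] <- seq_len(dur_ms) * velocity / 1000
  x[(at + dur_ms):n] <- dur_ms * velocity / 1000
  tibble::tibble(t_ms = 0:(n - 1), x_deg = x, y_deg = 0, valid = TRUE)
}

# Law-exact saccade samples for main-sequence tests.
law_events <- function(n, alpha = 560, beta = 0.25, gain = 1,
                       amin = 2, amax = 20) {
  x <- stats::runif(n, amin, amax)
  tibble::tibble(amplitude_deg = x,
                 peak_vel_deg_s = gain * main_sequence_velocity(x, alpha,
                                                                beta))
}

# Independent brute-force two-way repeated-measures ANOVA decomposition
# (balanced, no between terms), used as the oracle for rm_anova.
brute_rm_anova <- function(d, dv, f1, f2, subject) {
  y <- d[[dv]]
  A <- factor(d[[f1]]); B <- factor(d[[f2]]); S <- factor(d[[subject]])
  g <- mean(y)
  a <- tapply(y, A, mean); b <- tapply(y, B, mean); s <- tapply(y, S, mean)
  ab <- tapply(y, list(A, B), mean)
  as_ <- tapply(y, list(A, S), mean)
  bs <- tapply(y, list(B, S), mean)
  nA <- nlevels(A); nB <- nlevels(B); nS <- nlevels(S)
  ss_a <- nB * nS * sum((a - g)^2)
  ss_b <- nA * nS * sum((b - g)^2)
  ss_ab <- nS * sum((sweep(sweep(ab, 1, a), 2, b) + g)^2)
  ss_as <- nB * sum((sweep(sweep(as_, 1, a), 2, s) + g)^2)
  ss_bs <- nA * sum((sweep(sweep(bs, 1, b), 2, s) + g)^2)
  ss_tot <- sum((y - g)^2)
  ss_s <- nA * nB * sum((s - g)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs
  f_a <- (ss_a / (nA - 1)) / (ss_as / ((nA - 1) * (nS - 1)))
  f_b <- (ss_b / (nB - 1)) / (ss_bs / ((nB - 1) * (nS - 1)))
  f_ab <- (ss_ab / ((nA - 1) * (nB - 1))) /
    (ss_abs / ((nA - 1) * (nB - 1) * (nS - 1)))
  list(
    F = c(f_a, f_b, f_ab),
    p = c(stats::pf(f_a, nA - 1, (nA - 1) * (nS - 1), lower.tail = FALSE),
          stats::pf(f_b, nB - 1, (nB - 1) * (nS - 1), lower.tail = FALSE),
          stats::pf(f_ab, (nA - 1) * (nB - 1),
                    (nA - 1) * (nB - 1) * (nS - 1), lower.tail = FALSE)),
    eta_p2 = c(ss_a / (ss_a + ss_as), ss_b / (ss_b + ss_bs),
               ss_ab / (ss_ab + ss_abs)))
}
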