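test_that("Savitzky-Golay smoothing preserves low-order polynomials", {
  t <- 0:199
  const <- tibble::tibble(t_ms = t, x_deg = 3, y_deg = -1, valid = TRUE)
  out <- smooth_gaze(const)
  expect_equal(out$x_deg, const$x_deg, tolerance = 1e-12)

  quad <- tibble::tibble(t_ms = t, x_deg = 1e-4 * t^2 - 0.01 * t + 2,
                         y_deg = -2e-5 * t^2, valid = TRUE)
  sm <- smooth_gaze(quad)
  interior <- 11:189
  expect_equal(sm$x_deg[interior], quad$x_deg[interior], tolerance = 1e-9)
  expect_equal(sm$y_deg[interior], quad$y_deg[interior], tolerance = 1e-9)
})

test_that("smoothing reduces noise variance on a constant signal", {
  less <- vapply(1:50, function(i) {
    set.seed(i)
    tr <- tibble::tibble(t_ms = 0:499, x_deg = rnorm(500, 0, 0.05),
                         y_deg = 0, valid = TRUE)
    var(smooth_gaze(tr)$x_deg) < var(tr$x_deg)
  }, logical(1))
  expect_true(all(less))
})

test_that("speed series is exact for linear motion and zero at rest", {
  t <- 0:199
  lin <- tibble::tibble(t_ms = t, x_deg = 0.1 * t, y_deg = 0, valid = TRUE)
  sp <- speed_series(smooth_gaze(lin))
  expect_equal(sp$speed_deg_s[20:180], rep(100, 161), tolerance = 1e-9)

  still <- tibble::tibble(t_ms = t, x_deg = 2, y_deg = 2, valid = TRUE)
  sp0 <- speed_series(smooth_gaze(still))
  expect_lt(max(abs(sp0$speed_deg_s)), 1e-9)
  expect_lt(max(abs(sp0$accel_deg_s2)), 1e-6)

  expect_error(speed_series(lin[1:2, ]),
               class = "ocuvigor_degenerate_error")
})

test_that("filtered peak speed matches the generator within 1%", {
  s <- synth_saccade(10, c(1, 0), agent_profile())
  w <- s$waveform
  pad <- 150
  tr <- tibble::tibble(
    t_ms = seq_len(nrow(w) + 2 * pad) - 1,
    x_deg = c(rep(0, pad), w$dx_deg, rep(w$dx_deg[nrow(w)], pad)),
    y_deg = 0, valid = TRUE)
  sp <- speed_series(smooth_gaze(tr))
  expect_equal(max(sp$speed_deg_s), s$event$peak_vel_deg_s,
               tolerance = 0.01)
})

test_that("both detectors recover noiseless trials event for event", {
  lay <- make_layout(seed = 21)
  tr <- synth_trial(lay, agent_profile(noise_sd = 0), seed = 21)
  fx <- detect_saccades(tr$trace, "fixed")
  ad <- detect_saccades(tr$trace, "adaptive")
  expect_equal(nrow(fx), nrow(tr$events))
  expect_equal(nrow(ad), nrow(fx))   # cross-algorithm agreement, clean data
  m <- match_events(tr$events, fx)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$precision, 1)
  expect_lt(mean(abs(m$onset_errors_ms)), 4)
  ma <- match_events(tr$events, ad)
  expect_equal(ma$sensitivity, 1)
  expect_lt(max(abs(ma$onset_errors_ms)), 4)
  # amplitudes track the ground truth
  expect_equal(sort(fx$amplitude_deg), sort(tr$events$amplitude_deg),
               tolerance = 0.05)
})

test_that("fixation-level noise and constant traces yield no events", {
  set.seed(8)
  noisy_fix <- tibble::tibble(t_ms = 0:2999,
                              x_deg = rnorm(3000, 0, 0.02),
                              y_deg = rnorm(3000, 0, 0.02), valid = TRUE)
  expect_equal(nrow(detect_saccades(noisy_fix, "fixed")), 0)

  flat <- tibble::tibble(t_ms = 0:999, x_deg = 1, y_deg = 1, valid = TRUE)
  expect_equal(nrow(detect_saccades(flat, "fixed")), 0)
  expect_equal(nrow(detect_saccades(flat, "adaptive")), 0)
})

test_that("the minimum-duration rule discards brief events", {
  tr <- spike_trace(50, dur_ms = 8)   # detected duration ~12 ms
  ev <- detect_saccades(tr, "fixed")
  expect_equal(nrow(ev), 1)
  expect_lt(ev$duration_ms, 15)
  stricter <- detector_config(min_duration = 15)
  expect_equal(nrow(detect_saccades(tr, "fixed", stricter)), 0)
})

test_that("the ISI rule drops the later of two close events", {
  tr <- spike_trace(150, dur_ms = 12, n = 800, at = 300)
  # add a second movement 30 ms after the first ends
  tr$x_deg[345:356] <- tr$x_deg[344] + (1:12) * 0.15
  tr$x_deg[357:800] <- tr$x_deg[356]
  both <- detect_saccades(tr, "fixed", detector_config(min_isi = 0))
  expect_equal(nrow(both), 2)
  one <- detect_saccades(tr, "fixed")   # min_isi = 40
  expect_equal(nrow(one), 1)
  expect_equal(one$onset_ms, both$onset_ms[1])
})

test_that("adaptive thresholds scale with trial noise", {
  lay <- make_layout(seed = 31)
  same <- vapply(1:30, function(i) {
    tr1 <- synth_trial(lay, agent_profile(noise_sd = 0.05), seed = i)
    tr2 <- synth_trial(lay, agent_profile(noise_sd = 0.10), seed = i)
    nrow(detect_saccades(tr1$trace, "adaptive")) ==
      nrow(detect_saccades(tr2$trace, "adaptive"))
  }, logical(1))
  expect_gte(mean(same), 0.9)
})

test_that("event lists are ordered, disjoint, and respect the threshold", {
  for (i in 1:5) {
    tr <- synth_trial(make_layout(seed = i),
                      agent_profile(noise_sd = 0.05), seed = i)
    for (algo in c("fixed", "adaptive")) {
      ev <- detect_saccades(tr$trace, algo)
      expect_true(all(diff(ev$onset_ms) > 0))
      expect_true(all(ev$offset_ms[-nrow(ev)] < ev$onset_ms[-1]))
      if (algo == "fixed") {
        expect_true(all(ev$peak_vel_deg_s >= 35))
      }
      # determinism
      expect_identical(ev, detect_saccades(tr$trace, algo))
    }
  }
})

test_that("invalid gaps split trials and block cross-gap events", {
  lay <- make_layout(seed = 41)
  tr <- synth_trial(lay, agent_profile(noise_sd = 0), seed = 41,
                    n_gaps = 3, gap_ms = 300)
  ev <- detect_saccades(tr$trace, "fixed")
  bad <- which(!tr$trace$valid)
  for (i in seq_len(nrow(ev))) {
    inside <- tr$trace$t_ms >= ev$onset_ms[i] &
      tr$trace$t_ms <= ev$offset_ms[i]
    expect_true(all(tr$trace$valid[inside]))
  }
})
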