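test_that("frequency counts events per trial, restoring zero-event trials", {
  expect_equal(saccade_frequency(empty <- tibble::tibble(
    amplitude_deg = numeric())), 0)
  ds <- synth_experiment(n_subjects = 2, n_blocks = 1, trials_per_block = 6,
                         seed = 13)
  ev <- detect_saccades(ds$gaze, "fixed")
  fr <- saccade_frequency(ev, ds$trials)
  expect_equal(nrow(fr), nrow(ds$trials))
  truth_counts <- dplyr::count(ds$truth, subject, block, trial)
  j <- dplyr::inner_join(fr, truth_counts,
                         by = c("subject", "block", "trial"))
  expect_equal(j$frequency, j$n)
})

test_that("destinations follow the nearest-destination rule", {
  lay <- tibble::tibble(target = 1:2, x_deg = c(11.5, -11.5),
                        y_deg = c(0, 0))
  ev <- tibble::tibble(x_offset = c(11.5, 0, 6.5), y_offset = c(0, 0, 0))
  out <- classify_destination(ev, lay)
  # exactly on a target centre
  expect_equal(out$destination_class[1], "target")
  expect_equal(out$landing_error_deg[1], 0)
  # at screen centre
  expect_equal(out$destination_class[2], "fixation")
  expect_equal(out$landing_error_deg[2], 0)
  # 5.0 deg from the nearest target, 6.5 deg from fixation -> target, 5.0
  expect_equal(out$destination_class[3], "target")
  expect_equal(out$landing_error_deg[3], 5.0)
})

test_that("hit counting respects radius, uniqueness and alternation", {
  geom <- task_geometry()
  lay <- make_layout(geom, seed = 6)
  # a dwell 2.0 deg outside a target centre: offline hit, online miss
  near <- tibble::tibble(
    t_ms = 0:199, x_deg = c(rep(0, 100), rep(lay$x_deg[1] + 2.0, 100)),
    y_deg = c(rep(0, 100), rep(lay$y_deg[1], 100)), valid = TRUE)
  expect_equal(nrow(count_hits(near, lay, "offline", geom)), 1)
  expect_equal(nrow(count_hits(near, lay, "online", geom)), 0)

  # perfect agent: all 18 targets with refixation in between -> 18 hits
  per_leg <- 20
  xs <- c(); ys <- c()
  for (i in seq_len(nrow(lay))) {
    xs <- c(xs, rep(0, per_leg), rep(lay$x_deg[i], per_leg))
    ys <- c(ys, rep(0, per_leg), rep(lay$y_deg[i], per_leg))
  }
  perfect <- tibble::tibble(t_ms = seq_along(xs) - 1, x_deg = xs,
                            y_deg = ys, valid = TRUE)
  hits <- count_hits(perfect, lay, "online", geom)
  expect_equal(nrow(hits), 18)
  expect_equal(hits$target, lay$target)   # gaze order preserved

  # two consecutive target entries without refixation -> only the first
  two <- tibble::tibble(
    t_ms = 0:59,
    x_deg = c(rep(0, 20), rep(lay$x_deg[1], 20), rep(lay$x_deg[2], 20)),
    y_deg = c(rep(0, 20), rep(lay$y_deg[1], 20), rep(lay$y_deg[2], 20)),
    valid = TRUE)
  expect_equal(nrow(count_hits(two, lay, "online", geom)), 1)
  expect_equal(nrow(count_hits(two, lay, "online", geom,
                               require_refixation = FALSE)), 2)
})

test_that("offline hits are a superset of online hits", {
  geom <- task_geometry()
  for (i in 1:6) {
    lay <- make_layout(geom, seed = i)
    tr <- synth_trial(lay, agent_profile(), seed = i)
    # pure radius monotonicity (no alternation interplay)
    on <- count_hits(tr$trace, lay, "online", geom,
                     require_refixation = FALSE)
    off <- count_hits(tr$trace, lay, "offline", geom,
                      require_refixation = FALSE)
    expect_true(all(on$target %in% off$target))
    expect_gte(nrow(off), nrow(on))
  }
})

test_that("the main-sequence fit recovers generating parameters", {
  set.seed(10)
  clean <- law_events(2000)
  f <- fit_main_sequence(clean)
  expect_equal(f$alpha, 560, tolerance = 0.001)
  expect_equal(f$beta, 0.25, tolerance = 0.001)

  # 5% multiplicative velocity noise: recovery within 3% (several seeds)
  errs <- vapply(1:8, function(i) {
    set.seed(i)
    noisy <- law_events(2000)
    noisy$peak_vel_deg_s <- noisy$peak_vel_deg_s * rnorm(2000, 1, 0.05)
    fi <- fit_main_sequence(noisy)
    max(abs(fi$alpha - 560) / 560, abs(fi$beta - 0.25) / 0.25)
  }, numeric(1))
  expect_lt(max(errs), 0.03)

  # amplitude-degenerate input is unidentifiable
  flatx <- tibble::tibble(amplitude_deg = rep(8, 50),
                          peak_vel_deg_s = rep(370, 50))
  expect_error(fit_main_sequence(flatx), class = "ocuvigor_fit_error")

  # broom-style accessors
  expect_equal(tidy(f)$estimate, c(f$alpha, f$beta))
  expect_equal(glance(f)$n_saccades, 2000)
})

test_that("vigor ratios are self-consistent and recover injected gains", {
  set.seed(11)
  base <- law_events(2000)
  f <- fit_main_sequence(base)
  expect_equal(vigor_ratio(base, f), 1, tolerance = 1e-6)

  high <- law_events(1000, gain = 1.05)
  low <- law_events(1000, gain = 0.95)
  f2 <- fit_main_sequence(dplyr::bind_rows(high, low))
  expect_equal(vigor_ratio(high, f2), 1.05, tolerance = 0.01)
  expect_equal(vigor_ratio(low, f2), 0.95, tolerance = 0.01)

  expect_warning(v <- vigor_ratio(base[0, ], f))
  expect_true(is.na(v))
})

test_that("condition summaries have one complete row per cell", {
  ds <- synth_experiment(n_subjects = 3, n_blocks = 1, trials_per_block = 6,
                         seed = 17)
  ev <- detect_saccades(ds$gaze, "fixed")
  sm <- summarize_conditions(ev, ds$trials, gaze = ds$gaze,
                             layouts = ds$layouts)
  expect_equal(nrow(sm), 3 * 6)
  expect_true(all(!is.na(sm$frequency) & !is.na(sm$vigor) &
                    !is.na(sm$n_hits)))
  expect_true(all(sm$n_hits <= 18))

  # single-trial cells equal that trial's values
  one <- dplyr::filter(sm, subject == 1, reward_cents == 1,
                       duration_condition == "17")
  tr1 <- dplyr::filter(ds$trials, subject == 1, reward_cents == 1,
                       duration_condition == "17")
  ev1 <- dplyr::semi_join(ev, tr1, by = c("subject", "block", "trial"))
  expect_equal(one$frequency, nrow(ev1))
  expect_equal(one$peak_vel, mean(ev1$peak_vel_deg_s))
})
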