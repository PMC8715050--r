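test_that("gaze files round-trip exactly and reject malformed time", {
  ds <- synth_experiment(n_subjects = 2, n_blocks = 1, trials_per_block = 6,
                         seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze(ds$gaze, path)
  back <- read_gaze(path)
  expect_equal(as.data.frame(back), as.data.frame(ds$gaze),
               ignore_attr = TRUE)
  expect_equal(attr(back, "sampling_rate"), 1000)

  # detection is identical on the written-then-read dataset
  expect_equal(detect_saccades(back, "fixed"),
               detect_saccades(ds$gaze, "fixed"))

  shuffled <- ds$gaze[sample.int(nrow(ds$gaze)), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_gaze(shuffled, path2)
  expect_error(read_gaze(path2), class = "ocuvigor_format_error")

  expect_error(write_gaze(ds$gaze[, 1:3], path),
               class = "ocuvigor_format_error")
})

test_that("resampling interpolates linearly and preserves originals", {
  # linear motion: inserted samples lie exactly on the line
  tr <- tibble::tibble(t_ms = seq(0, 96, by = 4),
                       x_deg = seq(0, 96, by = 4) * 0.01,
                       y_deg = -seq(0, 96, by = 4) * 0.02,
                       valid = TRUE)
  up <- resample_gaze(tr, to = 1000)
  expect_equal(diff(up$t_ms[1:2]), 1)
  expect_equal(up$x_deg, up$t_ms * 0.01, tolerance = 1e-12)
  expect_equal(up$y_deg, -up$t_ms * 0.02, tolerance = 1e-12)
  # originals bit-for-bit at coincident timestamps
  expect_identical(up$x_deg[up$t_ms %in% tr$t_ms], tr$x_deg)

  # identity at the target rate
  tr1000 <- tibble::tibble(t_ms = 0:50, x_deg = rnorm(51), y_deg = 0,
                           valid = TRUE)
  expect_identical(resample_gaze(tr1000, to = 1000), tr1000)

  # invalid gaps propagate instead of being interpolated across
  tr$valid[10] <- FALSE
  up2 <- resample_gaze(tr, to = 1000)
  gap <- up2$t_ms > tr$t_ms[9] & up2$t_ms < tr$t_ms[11]
  expect_true(all(!up2$valid[gap]))
  expect_true(all(is.na(up2$x_deg[gap])))
})

test_that("downsampled-then-upsampled traces yield matching saccade counts", {
  agree <- vapply(1:40, function(i) {
    tr <- synth_trial(make_layout(seed = i), agent_profile(), seed = i)
    tr250 <- tr$trace[seq(1, nrow(tr$trace), by = 4), ]
    up <- resample_gaze(tr250, to = 1000)
    nrow(detect_saccades(up, "fixed")) ==
      nrow(detect_saccades(tr$trace, "fixed"))
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("the missing-data rule discards trials strictly above 25%", {
  n <- 1000
  mk <- function(n_bad) {
    tibble::tibble(t_ms = 0:(n - 1), x_deg = 0, y_deg = 0,
                   valid = rep(c(FALSE, TRUE), c(n_bad, n - n_bad)))
  }
  expect_equal(missing_fraction(mk(260)), 0.26)
  expect_true(exclude_trial(mk(260)))
  expect_false(exclude_trial(mk(250)))   # exactly 25%: retained
  expect_equal(missing_fraction(mk(0)), 0)
  expect_false(exclude_trial(mk(0)))
  # non-finite coordinates count as missing even when flagged valid
  tr <- mk(0); tr$x_deg[1:300] <- NaN
  expect_true(exclude_trial(tr))
  expect_error(missing_fraction(mk(0)[0, ]),
               class = "ocuvigor_degenerate_error")
})
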