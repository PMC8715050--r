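test_that("cohort generation is reproducible and validates its inputs", {
  a <- synth_experiment(n_subjects = 2, n_blocks = 1, trials_per_block = 6,
                        seed = 5)
  b <- synth_experiment(n_subjects = 2, n_blocks = 1, trials_per_block = 6,
                        seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a$trials), 12)
  expect_setequal(unique(a$gaze$subject), 1:2)
  expect_true(all(c("subject", "block", "trial", "onset_ms") %in%
                    names(a$truth)))
  expect_error(synth_experiment(n_subjects = 1),
               class = "ocuvigor_cohort_error")
  expect_error(synth_cohort_means(n_subjects = 1),
               class = "ocuvigor_cohort_error")
})

test_that("null cohorts reject at the nominal rate, calibrated gains near the target", {
  # type-I calibration of the paired test on cohort means
  p_null <- vapply(1:400, function(i) {
    cm <- synth_cohort_means(n_subjects = 17, seed = i,
                             durations = "Dindiv")
    cm$cell <- paste0("r", cm$reward_cents)
    ph <- posthoc_paired(cm, dv = "frequency", cell = "cell",
                         subject = "subject",
                         pairs = list(c("r50", "r1")), tails = "one")
    ph$p
  }, numeric(1))
  expect_lt(abs(mean(p_null <= 0.05) - 0.05), 0.035)

  # the calibrated high-reward gain exceeds 1 and scales with dz
  g65 <- calibrate_freq_gain(0.65)
  g30 <- calibrate_freq_gain(0.30)
  expect_gt(g65, 1)
  expect_gt(g65, g30)
})

test_that("4AFC simulation matches its Bernoulli/binomial model", {
  all_seen <- synth_afc(1, 1, 40, seed = 1)
  expect_true(all(all_seen$correct))
  expect_true(all(all_seen$seen))
  expect_true(all(startsWith(all_seen$response, "seen_")))

  chance <- vapply(1:300, function(i) {
    mean(synth_afc(0.5, 0, 80, seed = i)$correct)
  }, numeric(1))
  expect_equal(mean(chance), 0.5, tolerance = 0.02)

  # correct-count distribution vs the exact binomial pmf
  counts <- vapply(1:2000, function(i) {
    sum(synth_afc(0.61, 0.1, 80, seed = 10000 + i)$correct)
  }, numeric(1))
  grid <- 0:80
  pmf <- stats::dbinom(grid, 80, 0.61)
  bins <- c(-Inf, 42, 45, 48, 50, 52, 55, Inf)  # merge sparse tails
  obs <- table(cut(counts, bins))
  expp <- tapply(pmf, cut(grid, bins), sum) * 2000
  chi <- sum((as.numeric(obs) - expp)^2 / expp)
  expect_lt(chi, stats::qchisq(0.99, df = length(expp) - 1))
})
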