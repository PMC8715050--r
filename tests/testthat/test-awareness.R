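test_that("4AFC summaries pool phases and compute both proportions", {
  a <- dplyr::bind_rows(
    synth_afc(1, 1, 40, subject = 1, phase = 1, seed = 1),
    synth_afc(1, 1, 40, subject = 1, phase = 2, seed = 2))
  s <- summarize_afc(a)
  expect_equal(s$p_correct, 1)
  expect_equal(s$p_seen, 1)
  expect_equal(s$n_trials, 80)

  guess <- synth_afc(0.5, 0, 80, subject = 2, seed = 3)
  s2 <- summarize_afc(guess)
  expect_equal(s2$p_seen, 0)
  expect_lt(abs(s2$p_correct - 0.5), 0.2)
})

test_that("group tests behave at chance and flag degenerate inputs", {
  at_chance <- tibble::tibble(subject = 1:10, duration_condition = "17",
                              p_correct = 0.5, p_seen = 0,
                              n_trials = 80)
  # constant at the null: direction-only verdict, non-rejection
  g <- awareness_group_tests(at_chance)
  expect_true(g$degenerate)
  expect_equal(g$p_correct_vs_chance, 1)
  expect_equal(g$p_seen_vs_zero, 1)

  set.seed(2)
  varied <- dplyr::mutate(at_chance,
                          p_correct = 0.5 + rnorm(10, 0, 0.04),
                          p_seen = runif(10, 0, 0.1))
  g2 <- awareness_group_tests(varied)
  expect_false(g2$degenerate)
  # matches a direct one-sample t computation
  tt <- t.test(varied$p_correct, mu = 0.5, alternative = "greater")
  expect_equal(g2$p_correct_vs_chance, tt$p.value)
  expect_error(awareness_group_tests(at_chance[1, ]),
               class = "ocuvigor_cohort_error")
})

test_that("the exact binomial test matches tail enumeration", {
  # brute-force tail enumeration oracle over a grid of n
  for (n in c(1, 2, 7, 20, 80, 137, 200)) {
    for (k in unique(c(0, 1, floor(n / 2), n - 1, n))) {
      enum <- sum(choose(n, k:n) * 0.5^n)
      got <- binomial_above_chance(k, n)$p
      expect_equal(got, enum, tolerance = 1e-12)
    }
  }
  # the published cut points at n = 80
  expect_true(binomial_above_chance(48, 80)$above_chance)
  expect_false(binomial_above_chance(47, 80)$above_chance)
  # closed forms
  expect_equal(binomial_above_chance(10, 10)$p, 0.5^10)
  expect_gt(binomial_above_chance(40, 80)$p, 0.5)
  expect_error(binomial_above_chance(1, 0), class = "ocuvigor_afc_error")
})

test_that("awareness splits partition the cohort", {
  flags <- c(FALSE, TRUE, FALSE, TRUE, TRUE)
  g <- split_awareness_groups(1:5, flags)
  expect_equal(g$at_chance, c(1, 3))
  expect_equal(g$above_chance, c(2, 4, 5))
  expect_equal(length(g$at_chance) + length(g$above_chance), 5)
  all_false <- split_awareness_groups(1:3, rep(FALSE, 3))
  expect_equal(all_false$at_chance, 1:3)
  expect_length(all_false$above_chance, 0)
})

test_that("required sample sizes match the noncentral-t power function", {
  expect_equal(required_n_paired_t(0.65), 17)
  expect_equal(required_n_paired_t(0.5), 27)
  # monotonicity: doubled effect needs strictly fewer subjects
  expect_lt(required_n_paired_t(1.3), 17)
  # bracketing: power at n meets the target, at n - 1 it does not
  pw <- function(n, dz) pt(qt(0.95, n - 1), n - 1, ncp = dz * sqrt(n),
                           lower.tail = FALSE)
  for (dz in c(0.4, 0.65, 1)) {
    n <- required_n_paired_t(dz)
    expect_gte(pw(n, dz), 0.8)
    expect_lt(pw(n - 1, dz), 0.8)
  }
  # non-increasing in alpha and non-decreasing in power
  expect_gte(required_n_paired_t(0.65, alpha = 0.01),
             required_n_paired_t(0.65, alpha = 0.05))
  expect_gte(required_n_paired_t(0.65, power = 0.95),
             required_n_paired_t(0.65, power = 0.8))
  expect_gte(required_n_paired_t(0.65, tails = "two"),
             required_n_paired_t(0.65, tails = "one"))
  expect_error(required_n_paired_t(-1), class = "ocuvigor_power_error")
})
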