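test_that("within-subject z-scores standardise each individual", {
  set.seed(5)
  d <- tibble::tibble(subject = rep(1:4, each = 30),
                      y = rnorm(120, rep(c(10, 50, -3, 0), each = 30),
                                rep(c(1, 9, 0.2, 4), each = 30)))
  z <- zscore_within_subject(d, y, subject)
  ms <- tapply(z$z, z$subject, mean)
  ss <- tapply(z$z, z$subject, sd)
  expect_true(all(abs(ms) < 1e-12))
  expect_true(all(abs(ss - 1) < 1e-12))

  # affine invariance
  d2 <- dplyr::mutate(d, y = 3.7 * y - 11)
  z2 <- zscore_within_subject(d2, y, subject)
  expect_equal(z2$z, z$z, tolerance = 1e-12)

  const <- tibble::tibble(subject = rep(1, 5), y = rep(2, 5))
  expect_warning(zc <- zscore_within_subject(const, y, subject))
  expect_true(all(zc$z == 0))
})

test_that("mean-centering sums to zero and is idempotent", {
  x <- c(3, 8, -2, 0.5)
  cx <- mean_center(x)
  expect_lt(abs(sum(cx)), 1e-12)
  expect_equal(mean_center(cx), cx)
  expect_equal(mean_center(rep(4, 6)), rep(0, 6))
})

test_that("rm_anova matches a brute-force two-factor decomposition", {
  set.seed(9)
  d <- tidyr::expand_grid(subject = 1:3, A = c("a1", "a2"),
                          B = c("b1", "b2", "b3"))
  d$y <- rnorm(nrow(d)) + ifelse(d$A == "a2", 0.8, 0)
  fit <- rm_anova(d, "y", c("A", "B"), "subject")
  oracle <- brute_rm_anova(d, "y", "A", "B", "subject")
  expect_equal(fit$table$F, oracle$F, tolerance = 1e-8)
  expect_equal(fit$table$p, oracle$p, tolerance = 1e-8)
  expect_equal(fit$table$eta_p2, oracle$eta_p2, tolerance = 1e-8)
})

test_that("GG epsilon is exactly 1 for two-level factors and never raises p", {
  set.seed(12)
  d <- tidyr::expand_grid(subject = 1:14, reward = c("lo", "hi"),
                          dur = c("a", "b", "c"))
  d$y <- rnorm(nrow(d))
  fit <- rm_anova(d, "y", c("reward", "dur"), "subject")
  tab <- fit$table
  expect_equal(tab$epsilon[tab$effect == "reward"], 1)
  # the correction can only raise p where F exceeds 1; below 1 the scaled
  # reference distribution is not stochastically ordered the same way
  infl <- tab$F >= 1
  expect_true(all(tab$p_gg[infl] >= tab$p[infl] - 1e-12))
  k <- 3
  expect_true(all(tab$epsilon >= 1 / (k - 1) - 1e-9 & tab$epsilon <= 1))
  expect_true(all(tab$eta_p2 >= 0 & tab$eta_p2 <= 1))

  # partial eta^2 invariance under within-subject centering and common
  # affine transforms of the dependent measure
  d$yc <- stats::ave(d$y, d$subject, FUN = function(v) v - mean(v))
  d$ya <- 2.5 * d$y + 3
  expect_equal(rm_anova(d, "yc", c("reward", "dur"), "subject")$table$eta_p2,
               tab$eta_p2, tolerance = 1e-9)
  expect_equal(rm_anova(d, "ya", c("reward", "dur"), "subject")$table$eta_p2,
               tab$eta_p2, tolerance = 1e-9)
})

test_that("rm_anova supports a covariate and rejects broken designs", {
  set.seed(13)
  d <- tidyr::expand_grid(subject = 1:12, reward = c("lo", "hi"),
                          dur = c("a", "b", "c"))
  d$y <- rnorm(nrow(d))
  d$vis <- rep(runif(12), each = 6)
  fit <- rm_anova(d, "y", c("reward", "dur"), "subject",
                  covariate = "vis")
  expect_true(all(c("vis", "reward", "vis:reward", "dur", "vis:dur",
                    "reward:dur", "vis:reward:dur") %in%
                    fit$table$effect))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n_subjects, 12)

  expect_error(rm_anova(d[-1, ], "y", c("reward", "dur"), "subject"),
               class = "ocuvigor_design_error")
  d$one <- "x"
  expect_error(rm_anova(d, "y", "one", "subject"),
               class = "ocuvigor_design_error")
})

test_that("paired post hoc tests handle ties, correction, and direction", {
  d <- tibble::tibble(subject = rep(1:6, 2),
                      cell = rep(c("A", "B"), each = 6),
                      y = c(1:6, 1:6))
  same <- posthoc_paired(d, "y", "cell", "subject")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$dz, 0)
  expect_equal(same$p_bonferroni, same$p)   # m = 1

  set.seed(3)
  d$y[d$cell == "A"] <- d$y[d$cell == "A"] + rnorm(6, 1)
  two <- posthoc_paired(d, "y", "cell", "subject")
  diffs <- d$y[d$cell == "A"] - d$y[d$cell == "B"]
  expect_equal(two$dz, mean(diffs) / sd(diffs))
  expect_equal(two$t, unname(t.test(diffs)$statistic))
  one <- posthoc_paired(d, "y", "cell", "subject", tails = "one")
  expect_equal(one$p, two$p / 2, tolerance = 1e-12)

  # Bonferroni over three cells
  d3 <- tibble::tibble(subject = rep(1:6, 3),
                       cell = rep(c("A", "B", "C"), each = 6),
                       y = rnorm(18))
  ph3 <- posthoc_paired(d3, "y", "cell", "subject")
  expect_equal(nrow(ph3), 3)
  expect_equal(ph3$p_bonferroni, pmin(1, ph3$p * 3))

  expect_error(posthoc_paired(d[c(1, 7), ], "y", "cell", "subject"),
               class = "ocuvigor_cohort_error")
})
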