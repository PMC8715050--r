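# Subliminal-awareness criteria on 4AFC visibility data and the paired-t
# sample-size computation.

#' Summarise 4AFC responses per subject and display duration
#'
#' Pools responses over the task's two assessment phases and computes, per
#' subject x duration cell, the proportion of correct answers (counting both
#' "seen" and "guess" responses that name the shown coin) and the proportion
#' of "seen" responses.
#'
#' @param afc A 4AFC response tibble (`subject`, `phase`,
#'   `duration_condition`, `coin`, `response`, `correct`, `seen`).
#' @return Tibble `subject`, `duration_condition`, `p_correct`, `p_seen`,
#'   `n_trials`.  Cells with zero trials are absent (they have no row to
#'   summarise).
#' @export
summarize_afc <- function(afc) {
  dplyr::summarise(
    dplyr::group_by(afc, .data$subject, .data$duration_condition),
    p_correct = mean(.data$correct),
    p_seen = mean(.data$seen),
    n_trials = dplyr::n(),
    .groups = "drop")
}

#' Group-level awareness tests
#'
#' For each display duration, tests whether the cohort's proportion of
#' correct answers exceeds chance (50%) and whether the proportion of "seen"
#' responses exceeds 0, with one-tailed one-sample t tests on the
#' per-subject proportions (alternative: greater).  Subliminal perception
#' requires both tests to be non-significant.  When a proportion is
#' constant across subjects the t statistic is undefined; the row is flagged
#' degenerate and judged by direction only (p = 1 when the constant equals
#' the null value, p = 0 above it).
#'
#' @param summaries Output of [summarize_afc()].
#' @return Tibble per duration: `duration_condition`, `n`, `mean_correct`,
#'   `t_correct`, `p_correct_vs_chance`, `dz_correct`, `mean_seen`,
#'   `t_seen`, `p_seen_vs_zero`, `dz_seen`, `degenerate`.
#' @export
awareness_group_tests <- function(summaries) {
  one_tail <- function(x, mu) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      d <- mean(x) - mu
      return(list(t = NA_real_, p = if (d > 0) 0 else 1, dz = NA_real_,
                  degenerate = TRUE))
    }
    tt <- stats::t.test(x, mu = mu, alternative = "greater")
    list(t = unname(tt$statistic), p = tt$p.value,
         dz = (mean(x) - mu) / s, degenerate = FALSE)
  }
  dplyr::reframe(
    dplyr::group_by(summaries, .data$duration_condition),
    {
      abort_if(dplyr::n() < 2, "Need >= 2 subjects for group tests.",
               class = "ocuvigor_cohort_error")
      pc <- .data$p_correct
      ps <- .data$p_seen
      a <- one_tail(pc, 0.5)
      b <- one_tail(ps, 0)
      tibble::tibble(
        n = length(pc),
        mean_correct = mean(pc),
        t_correct = a$t, p_correct_vs_chance = a$p, dz_correct = a$dz,
        mean_seen = mean(ps),
        t_seen = b$t, p_seen_vs_zero = b$p, dz_seen = b$dz,
        degenerate = a$degenerate || b$degenerate)
    })
}

#' Per-subject exact binomial test against chance
#'
#' One-sided exact binomial test of `correct` successes in `n` trials
#' against the chance probability: `p = P(X >= correct)` under
#' `Binomial(n, chance)`.  A subject is above chance when `p <= alpha`.
#'
#' @param correct Number of correct responses.
#' @param n Number of trials (> 0).
#' @param chance Chance probability (0.5 for two coin values).
#' @param alpha Significance cut-off.
#' @return Tibble `correct`, `n`, `p`, `above_chance` (vectorised over
#'   `correct`/`n`).
#' @examples
#' binomial_above_chance(48, 80) # just significant
#' @export
binomial_above_chance <- function(correct, n, chance = 0.5, alpha = 0.05) {
  abort_if(any(n <= 0), "`n` must be positive.",
           class = "ocuvigor_afc_error")
  abort_if(any(correct < 0) || any(correct > n),
           "`correct` must lie in [0, n].",
           class = "ocuvigor_afc_error")
  p <- stats::pbinom(correct - 1, n, chance, lower.tail = FALSE)
  tibble::tibble(correct = correct, n = n, p = p,
                 above_chance = p <= alpha)
}

#' Split a cohort by individual awareness
#'
#' Partitions subjects into at-chance and above-chance groups from
#' per-subject booleans (e.g. `binomial_above_chance()$above_chance`).
#'
#' @param subjects Subject identifiers.
#' @param above_chance Logical vector, one per subject.
#' @return A list with `at_chance` and `above_chance` subject vectors.
#' @export
split_awareness_groups <- function(subjects, above_chance) {
  stopifnot(length(subjects) == length(above_chance))
  list(at_chance = subjects[!above_chance],
       above_chance = subjects[above_chance])
}

#' Sample size for a paired t test
#'
#' Smallest `n` such that a paired t test with `n - 1` degrees of freedom
#' and noncentrality `dz * sqrt(n)` reaches the requested power at level
#' `alpha`.  One-tailed tests use the `alpha` critical value, two-tailed the
#' `alpha / 2` value (lower-tail rejection mass is negligible at useful
#' powers).  With dz = 0.65, alpha = 0.05 one-tailed and power 0.8 the
#' answer is 17.
#'
#' @param dz Cohen's dz effect size (> 0).
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails `"one"` or `"two"`.
#' @param n_max Search cap.
#' @return The smallest sufficient integer n.
#' @examples
#' required_n_paired_t(0.65) # 17
#' @export
required_n_paired_t <- function(dz, alpha = 0.05, power = 0.8,
                                tails = c("one", "two"), n_max = 1e5) {
  tails <- match.arg(tails)
  abort_if(dz <= 0, "`dz` must be positive.", class = "ocuvigor_power_error")
  abort_if(alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1,
           "`alpha` and `power` must lie in (0, 1).",
           class = "ocuvigor_power_error")
  a <- if (tails == "one") alpha else alpha / 2
  achieved <- function(n) {
    stats::pt(stats::qt(1 - a, n - 1), n - 1, ncp = dz * sqrt(n),
              lower.tail = FALSE)
  }
  for (n in 2:n_max) {
    if (achieved(n) >= power) return(n)
  }
  rlang::abort("Power not reachable within `n_max` subjects.",
               class = "ocuvigor_power_error")
}
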