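# Cohort-level synthesis: population distributions of agent parameters,
# condition effect specifications, and the closed-form dz calibration.

#' Population distributions for a simulated cohort
#'
#' Describes how per-subject [agent_profile()] parameters are drawn.
#' Between-subject spreads are normal around the stated means (truncated away
#' from non-physical values).  `freq_trial_sd` is the within-subject,
#' per-trial SD of the saccade count used by the fast cohort-means generator.
#'
#' @param alpha_mean,alpha_sd Main-sequence asymptote distribution, deg/s.
#' @param beta_mean,beta_sd Main-sequence curvature distribution, 1/deg.
#' @param isi_mean,isi_bs_sd Between-subject distribution of the mean
#'   intersaccadic pause, ms.
#' @param isi_sd Within-subject pause SD, ms.
#' @param landing_sd,noise_sd,p_corrective Passed to [agent_profile()].
#' @param freq_gain_bs_sd Between-subject SD of a condition frequency gain.
#' @param vel_gain_bs_sd Between-subject SD of a condition velocity gain.
#' @param freq_trial_sd Per-trial SD of saccade counts (cohort-means mode).
#' @param saccade_overhead_ms Effective time consumed per saccadic leg on top
#'   of the pause (movement duration plus amortised corrective legs), ms.
#' @return A list of class `cohort_population`.
#' @export
cohort_population <- function(alpha_mean = 560, alpha_sd = 40,
                              beta_mean = 0.25, beta_sd = 0.03,
                              isi_mean = 180, isi_bs_sd = 20, isi_sd = 40,
                              landing_sd = 0.8, noise_sd = 0.02,
                              p_corrective = 0.5,
                              freq_gain_bs_sd = 0.04,
                              vel_gain_bs_sd = 0.02,
                              freq_trial_sd = 3,
                              saccade_overhead_ms = 70) {
  structure(as.list(environment()), class = "cohort_population")
}

#' Condition effect specification
#'
#' Per-reward-level multipliers applied to the intersaccadic pause (frequency
#' gain) and peak velocity (velocity gain).  Names must match the schedule's
#' reward levels (in cents); a gain of 1 is no effect.
#'
#' @param freq_gain,vel_gain Named numeric vectors, e.g.
#'   `c("1" = 1, "50" = 1.04)`.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(freq_gain = c("1" = 1, "50" = 1),
                        vel_gain = c("1" = 1, "50" = 1)) {
  abort_if(any(freq_gain <= 0) || any(vel_gain <= 0),
           "Gains must be positive.", class = "ocuvigor_effect_error")
  structure(list(freq_gain = freq_gain, vel_gain = vel_gain),
            class = "effect_spec")
}

#' Calibrate a frequency gain to a target within-subject effect size
#'
#' Returns the high-reward frequency gain `g` such that the per-subject
#' difference in mean saccade frequency between the high-gain and baseline
#' conditions has Cohen's dz equal to `dz`.  Uses the linearised closed form
#' for the per-trial count `mu(g) = T / (isi/g + s)` (T trial duration, isi
#' mean pause, s per-saccade overhead): with slope `mu' = T * isi / (isi +
#' s)^2`, between-subject gain SD `sd_g` in both cells, and cell means over
#' `n_trials` trials with per-trial SD `sd_t`,
#' `dz = mu' (g - 1) / sqrt(2 mu'^2 sd_g^2 + 2 sd_t^2 / n_trials)`.
#'
#' @param dz Target Cohen's dz (> 0 gives g > 1).
#' @param population A [cohort_population()].
#' @param n_trials_per_cell Trials per condition cell.
#' @param trial_duration Trial length, ms.
#' @return The calibrated gain (scalar).
#' @export
calibrate_freq_gain <- function(dz, population = cohort_population(),
                                n_trials_per_cell = 35,
                                trial_duration = 8000) {
  p <- population
  denom <- p$isi_mean + p$saccade_overhead_ms
  slope <- trial_duration * p$isi_mean / denom^2
  sd_d <- sqrt(2 * slope^2 * p$freq_gain_bs_sd^2 +
                 2 * p$freq_trial_sd^2 / n_trials_per_cell)
  1 + dz * sd_d / slope
}

# Expected per-trial saccade count at frequency gain g.
expected_frequency <- function(g, isi, overhead, trial_duration = 8000) {
  trial_duration / (isi / g + overhead)
}

#' Fast cohort generator: per-subject condition means
#'
#' Draws a cohort from the population model and returns observed condition
#' cell means of saccade frequency without synthesising gaze traces: each
#' subject's true mean is `T / (isi_i / g_i + s)` with subject-specific pause
#' `isi_i` and condition gain `g_i ~ N(g_cond, freq_gain_bs_sd)`, and the
#' observed cell mean adds sampling noise `N(0, freq_trial_sd /
#' sqrt(n_trials))`.  This is the generator behind power-calibration
#' experiments, where thousands of replicate cohorts are needed.
#'
#' @param n_subjects Cohort size.
#' @param effects An [effect_spec()].
#' @param population A [cohort_population()].
#' @param reward_levels Reward levels (cents), matched against effect names.
#' @param durations Display-duration condition labels.
#' @param n_trials_per_cell Trials per condition cell.
#' @param trial_duration Trial length, ms.
#' @param seed Optional integer seed.
#' @return Tibble `subject`, `reward_cents`, `duration_condition`,
#'   `true_frequency`, `frequency` (observed cell mean).
#' @export
synth_cohort_means <- function(n_subjects = 17,
                               effects = effect_spec(),
                               population = cohort_population(),
                               reward_levels = c(1, 50),
                               durations = c("17", "Dindiv", "100"),
                               n_trials_per_cell = 35,
                               trial_duration = 8000,
                               seed = NULL) {
  abort_if(n_subjects < 2, "Need at least 2 subjects for a cohort.",
           class = "ocuvigor_cohort_error")
  p <- population
  with_seed(seed, {
    grid <- tidyr::expand_grid(subject = seq_len(n_subjects),
                               reward_cents = reward_levels,
                               duration_condition = durations)
    isi_i <- rtrunc_norm(n_subjects, p$isi_mean, p$isi_bs_sd, p$isi_mean / 3)
    g_cond <- effects$freq_gain[as.character(grid$reward_cents)]
    g_i <- stats::rnorm(nrow(grid), g_cond, p$freq_gain_bs_sd)
    g_i <- pmax(g_i, 0.1)
    truef <- expected_frequency(g_i, isi_i[grid$subject],
                                p$saccade_overhead_ms, trial_duration)
    obs <- truef + stats::rnorm(nrow(grid),
                                0, p$freq_trial_sd / sqrt(n_trials_per_cell))
    dplyr::mutate(grid, true_frequency = truef, frequency = obs)
  })
}

#' Synthesise a full multi-subject experiment with ground truth
#'
#' Draws per-subject agents from the population model, builds a
#' counterbalanced schedule per subject, synthesises every trial's gaze trace
#' (with a fresh random target layout per trial), and returns the traces
#' together with the ground-truth event lists and the true per-subject
#' condition means implied by the generating parameters.  Sub-streams are
#' derived from the master seed per subject and trial, so any subset is
#' reproducible.
#'
#' @param n_subjects Number of simulated participants (>= 2).
#' @param effects An [effect_spec()] of condition gains.
#' @param population A [cohort_population()].
#' @param geometry A [task_geometry()].
#' @param n_blocks,trials_per_block Schedule dimensions per subject.
#' @param reward_levels,durations Condition sets (reward in cents).
#' @param seed Master integer seed.
#' @return A list with tibbles `subjects` (drawn agent parameters), `trials`
#'   (schedule with subject ids), `layouts` (per-trial target positions),
#'   `gaze` (long sample table), `truth` (ground-truth events keyed by
#'   subject/block/trial), and `true_means` (per subject x condition
#'   generating frequency and velocity-gain values).
#' @export
synth_experiment <- function(n_subjects = 17,
                             effects = effect_spec(),
                             population = cohort_population(),
                             geometry = task_geometry(),
                             n_blocks = 5, trials_per_block = 42,
                             reward_levels = c(1, 50),
                             durations = c("17", "Dindiv", "100"),
                             seed = 1) {
  abort_if(n_subjects < 2, "Need at least 2 subjects for a cohort.",
           class = "ocuvigor_cohort_error")
  p <- population
  subjects <- with_seed(derive_seed(seed, 0), tibble::tibble(
    subject = seq_len(n_subjects),
    alpha = rtrunc_norm(n_subjects, p$alpha_mean, p$alpha_sd, 100),
    beta = rtrunc_norm(n_subjects, p$beta_mean, p$beta_sd, 0.05),
    isi_mean = rtrunc_norm(n_subjects, p$isi_mean, p$isi_bs_sd,
                           p$isi_mean / 3)
  ))

  res <- purrr::map(seq_len(n_subjects), function(s) {
    sub <- subjects[s, ]
    agent <- agent_profile(alpha = sub$alpha, beta = sub$beta,
                           isi_mean = sub$isi_mean, isi_sd = p$isi_sd,
                           landing_sd = p$landing_sd, noise_sd = p$noise_sd,
                           p_corrective = p$p_corrective)
    sched <- make_schedule(n_blocks, trials_per_block, reward_levels,
                           durations, seed = derive_seed(seed, s, 0))
    # subject-specific realised condition gains
    gains <- with_seed(derive_seed(seed, s, 1), tibble::tibble(
      reward_cents = reward_levels,
      freq_gain = pmax(0.1, stats::rnorm(
        length(reward_levels),
        effects$freq_gain[as.character(reward_levels)],
        p$freq_gain_bs_sd)),
      vel_gain = pmax(0.1, stats::rnorm(
        length(reward_levels),
        effects$vel_gain[as.character(reward_levels)],
        p$vel_gain_bs_sd))
    ))
    sched <- dplyr::left_join(sched, gains, by = "reward_cents")
    per_trial <- purrr::map(seq_len(nrow(sched)), function(i) {
      tr_seed <- derive_seed(seed, s, 100 + i)
      layout <- make_layout(geometry, seed = tr_seed)
      tr <- synth_trial(layout, agent,
                        freq_gain = sched$freq_gain[i],
                        vel_gain = sched$vel_gain[i],
                        geometry = geometry, seed = tr_seed + 1L)
      key <- tibble::tibble(subject = s, block = sched$block[i],
                            trial = sched$trial[i])
      list(
        layout = dplyr::bind_cols(key, layout),
        gaze = dplyr::bind_cols(key[rep(1, nrow(tr$trace)), ], tr$trace),
        truth = if (nrow(tr$events)) {
          dplyr::bind_cols(key[rep(1, nrow(tr$events)), ], tr$events)
        } else NULL
      )
    })
    tm <- dplyr::mutate(
      gains,
      subject = s,
      true_frequency = expected_frequency(
        .data$freq_gain, sub$isi_mean, p$saccade_overhead_ms,
        geometry$trial_duration))
    list(
      trials = dplyr::mutate(sched, subject = s, .before = 1),
      layouts = purrr::list_rbind(purrr::map(per_trial, "layout")),
      gaze = purrr::list_rbind(purrr::map(per_trial, "gaze")),
      truth = purrr::list_rbind(purrr::compact(purrr::map(per_trial, "truth"))),
      true_means = tm
    )
  })

  list(
    subjects = subjects,
    trials = purrr::list_rbind(purrr::map(res, "trials")),
    layouts = purrr::list_rbind(purrr::map(res, "layouts")),
    gaze = purrr::list_rbind(purrr::map(res, "gaze")),
    truth = purrr::list_rbind(purrr::map(res, "truth")),
    true_means = purrr::list_rbind(purrr::map(res, "true_means"))
  )
}

#' Simulate a 4AFC visibility-response table
#'
#' Generates forced-choice responses for one subject x duration cell: each
#' trial shows a coin (counterbalanced), the response is correct with
#' probability `p_correct` and flagged "seen" with probability `p_seen`
#' (independently).
#'
#' @param p_correct Probability a response names the shown coin.
#' @param p_seen Probability a response is a "seen" (vs "guess") answer.
#' @param n_trials Number of trials in the cell.
#' @param subject,phase,duration_condition Identifier columns.
#' @param coins Coin values counterbalanced across trials.
#' @param seed Optional integer seed.
#' @return Tibble in the 4AFC dialect: `subject`, `phase`,
#'   `duration_condition`, `coin`, `response`, `correct`, `seen`.
#' @export
synth_afc <- function(p_correct, p_seen, n_trials,
                      subject = 1L, phase = 1L, duration_condition = "17",
                      coins = c(1, 50), seed = NULL) {
  abort_if(p_correct < 0 || p_correct > 1 || p_seen < 0 || p_seen > 1,
           "Probabilities must lie in [0, 1].",
           class = "ocuvigor_afc_error")
  with_seed(seed, {
    coin <- rep_len(coins, n_trials)
    correct <- stats::runif(n_trials) < p_correct
    seen <- stats::runif(n_trials) < p_seen
    answer <- ifelse(correct, coin, ifelse(coin == coins[1], coins[2],
                                           coins[1]))
    tibble::tibble(
      subject = subject, phase = phase,
      duration_condition = duration_condition,
      coin = coin,
      response = paste0(ifelse(seen, "seen_", "guess_"), answer),
      correct = correct, seen = seen
    )
  })
}
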