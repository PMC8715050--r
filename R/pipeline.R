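# End-to-end orchestration: simulate -> detect -> metrics -> reward ->
# awareness -> stats, from one configuration object.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: synthetic-cohort spec, task
#' geometry, detector choice, visibility (4AFC) generating probabilities per
#' display duration, and statistics options.  The default demo configuration
#' simulates 17 subjects with one trial per condition cell per block, a
#' frequency and velocity reward effect, and partial visibility at the two
#' longer durations.
#'
#' @param n_subjects Simulated cohort size.
#' @param n_blocks,trials_per_block Schedule dimensions.
#' @param reward_levels,durations Condition sets.
#' @param effects An [effect_spec()].
#' @param population A [cohort_population()].
#' @param geometry A [task_geometry()].
#' @param detector `"fixed"`, `"adaptive"`, or `"both"`.
#' @param afc_p_correct,afc_p_seen Named per-duration generating
#'   probabilities for the 4AFC task.
#' @param afc_trials_per_phase 4AFC trials per phase and duration.
#' @param covariate_duration Duration whose visibility enters the ANOVA as
#'   the mean-centered covariate.
#' @param use_covariate Include the covariate in the ANOVAs.
#' @param posthoc_tails Tails for the reward post hoc comparisons.
#' @param offline_requires_refixation Hit-counting alternation rule.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 17,
                            n_blocks = 1,
                            trials_per_block = 6,
                            reward_levels = c(1, 50),
                            durations = c("17", "Dindiv", "100"),
                            effects = effect_spec(
                              freq_gain = c("1" = 0.98, "50" = 1.04),
                              vel_gain = c("1" = 0.97, "50" = 1.03)),
                            population = cohort_population(),
                            geometry = task_geometry(),
                            detector = c("fixed", "adaptive", "both"),
                            afc_p_correct = c("17" = 0.55, "Dindiv" = 0.65,
                                              "100" = 0.95),
                            afc_p_seen = c("17" = 0.02, "Dindiv" = 0.3,
                                           "100" = 0.9),
                            afc_trials_per_phase = 40,
                            covariate_duration = "17",
                            use_covariate = TRUE,
                            posthoc_tails = "two",
                            offline_requires_refixation = TRUE,
                            seed = 1) {
  detector <- match.arg(detector)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, applies the missing-data exclusion rule, detects
#' saccades, summarises the condition metrics, computes payouts, evaluates
#' the awareness criteria, and fits the repeated-measures models.  The run
#' is deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return A result bundle (class `pipeline_result`): `config`, `dataset`
#'   (simulation output), `trials` (with exclusion flags), `events`,
#'   `condition_summary` (per detector), `payouts`, `afc`, `afc_summary`,
#'   `awareness`, `awareness_flags`, `groups`, `anova` (per measure),
#'   `posthoc`, and `log` (one structured line per stage).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) {
    log[[length(log) + 1L]] <<- sprintf(...)
    invisible(NULL)
  }

  ds <- synth_experiment(
    n_subjects = config$n_subjects, effects = config$effects,
    population = config$population, geometry = config$geometry,
    n_blocks = config$n_blocks, trials_per_block = config$trials_per_block,
    reward_levels = config$reward_levels, durations = config$durations,
    seed = config$seed)
  note("simulate: %d subjects, %d trials, %d gaze samples",
       config$n_subjects, nrow(ds$trials), nrow(ds$gaze))

  excl <- dplyr::summarise(
    dplyr::group_by(ds$gaze, .data$subject, .data$block, .data$trial),
    excluded = exclude_trial(dplyr::pick(dplyr::everything())),
    .groups = "drop")
  trials <- dplyr::left_join(ds$trials, excl,
                             by = c("subject", "block", "trial"))
  note("exclude: %d of %d trials discarded (>25%% missing)",
       sum(trials$excluded), nrow(trials))

  algos <- if (config$detector == "both") c("fixed", "adaptive")
  else config$detector
  events <- purrr::list_rbind(purrr::map(algos, function(a) {
    ev <- detect_saccades(ds$gaze, algorithm = a)
    note("detect[%s]: %d events", a, nrow(ev))
    ev
  }))

  summaries <- purrr::map(
    rlang::set_names(algos),
    function(a) summarize_conditions(
      dplyr::filter(events, .data$algorithm == a), trials,
      gaze = ds$gaze, layouts = ds$layouts, geometry = config$geometry,
      hit_mode = "offline",
      require_refixation = config$offline_requires_refixation))
  note("metrics: %d condition rows per detector", nrow(summaries[[1]]))

  # payout ledger from online hits
  hit_counts <- dplyr::group_modify(
    dplyr::group_by(ds$gaze, .data$subject, .data$block, .data$trial),
    function(.x, .y) {
      lay <- dplyr::semi_join(ds$layouts, .y,
                              by = c("subject", "block", "trial"))
      tibble::tibble(landed = nrow(count_hits(
        .x, lay, mode = "online", geometry = config$geometry)))
    })
  payouts <- dplyr::left_join(dplyr::ungroup(hit_counts),
                              dplyr::select(trials, "subject", "block",
                                            "trial", "reward_cents"),
                              by = c("subject", "block", "trial"))
  payouts <- dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(payouts, .data$subject),
    ~ block_account(.x, total = config$geometry$n_targets)))
  note("reward: mean payout %.3f cents/trial", mean(payouts$gained_cents))

  afc <- purrr::list_rbind(purrr::map(seq_len(config$n_subjects), function(s) {
    purrr::list_rbind(purrr::map(config$durations, function(d) {
      purrr::list_rbind(purrr::map(1:2, function(ph) {
        synth_afc(config$afc_p_correct[[d]], config$afc_p_seen[[d]],
                  config$afc_trials_per_phase, subject = s, phase = ph,
                  duration_condition = d,
                  coins = config$reward_levels,
                  seed = derive_seed(config$seed, 7000 + s,
                                     match(d, config$durations), ph))
      }))
    }))
  }))
  afc_summary <- summarize_afc(afc)
  awareness <- awareness_group_tests(afc_summary)
  cov_tbl <- dplyr::filter(afc_summary,
                           .data$duration_condition ==
                             config$covariate_duration)
  flags <- binomial_above_chance(
    round(cov_tbl$p_correct * cov_tbl$n_trials), cov_tbl$n_trials)
  groups <- split_awareness_groups(cov_tbl$subject, flags$above_chance)
  note("awareness: %d at chance, %d above chance at %s ms",
       length(groups$at_chance), length(groups$above_chance),
       config$covariate_duration)

  covariate <- if (config$use_covariate) {
    stats::setNames(cov_tbl$p_correct, cov_tbl$subject)
  } else NULL

  anovas <- purrr::map(summaries, function(sm) {
    if (!is.null(covariate)) sm$visibility <- covariate[as.character(sm$subject)]
    purrr::map(
      rlang::set_names(c("frequency", "peak_vel", "vigor")),
      function(measure) rm_anova(
        sm, dv = measure,
        within = c("reward_cents", "duration_condition"),
        subject = "subject",
        covariate = if (!is.null(covariate)) "visibility" else NULL))
  })
  note("stats: %d ANOVAs fitted", length(anovas) * 3L)

  posthocs <- purrr::map(summaries, function(sm) {
    purrr::list_rbind(purrr::map(unique(sm$duration_condition), function(d) {
      sub <- dplyr::filter(sm, .data$duration_condition == d)
      sub$cell <- paste0("reward", sub$reward_cents)
      ph <- posthoc_paired(sub, dv = "frequency", cell = "cell",
                           subject = "subject",
                           pairs = list(c(paste0("reward",
                                                 max(sub$reward_cents)),
                                          paste0("reward",
                                                 min(sub$reward_cents)))),
                           tails = config$posthoc_tails)
      dplyr::mutate(ph, duration_condition = d, .before = 1)
    }))
  })

  structure(list(config = config, dataset = ds, trials = trials,
                 events = events, condition_summary = summaries,
                 payouts = payouts, afc = afc, afc_summary = afc_summary,
                 awareness = awareness, awareness_flags = flags,
                 groups = groups, anova = anovas, posthoc = posthocs,
                 log = log),
            class = "pipeline_result")
}

#' Render a human-readable pipeline report
#'
#' Formats the condition summary (means +/- SD per measure and condition
#' cell), the GG-corrected ANOVA tables, the awareness tests, and the post
#' hoc comparisons as plain text.  Rendering is pure: the same bundle always
#' yields the identical document, and all numbers come from the bundle.
#'
#' @param bundle A `pipeline_result` from [run_pipeline()].
#' @return A character vector of report lines (one element per line).
#' @export
pipeline_report <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_result"))
  required <- c("condition_summary", "anova", "awareness", "posthoc")
  missing <- required[!purrr::map_lgl(bundle[required],
                                      ~ !is.null(.x) && length(.x) > 0)]
  abort_if(length(missing) > 0,
           paste("Incomplete bundle; missing:",
                 paste(missing, collapse = ", ")),
           class = "ocuvigor_report_error")
  lines <- c("# Oculomotor effort report", "")
  measures <- c("n_hits", "frequency", "peak_vel", "vigor", "amplitude",
                "endpoint_error")
  for (algo in names(bundle$condition_summary)) {
    sm <- bundle$condition_summary[[algo]]
    lines <- c(lines, sprintf("## Condition summary (%s detector)", algo),
               "", "measure | cell | mean +/- SD")
    long <- tidyr::pivot_longer(sm, dplyr::all_of(measures),
                                names_to = "measure")
    cellstats <- dplyr::summarise(
      dplyr::group_by(long, .data$measure, .data$reward_cents,
                      .data$duration_condition),
      m = mean(.data$value), s = stats::sd(.data$value), .groups = "drop")
    cellstats <- dplyr::arrange(cellstats,
                                match(.data$measure, measures),
                                .data$reward_cents,
                                .data$duration_condition)
    lines <- c(lines, sprintf("%s | %s cents @ %s ms | %.3f +/- %.3f",
                              cellstats$measure, cellstats$reward_cents,
                              cellstats$duration_condition, cellstats$m,
                              cellstats$s), "")
    for (measure in names(bundle$anova[[algo]])) {
      tab <- bundle$anova[[algo]][[measure]]$table
      lines <- c(lines, sprintf("### ANOVA: %s (%s)", measure, algo),
                 sprintf("%s: F(%.2f, %.2f) = %.3f, eps = %.3f, pGG = %.4g, etaP2 = %.3f",
                         tab$effect, tab$df1, tab$df2, tab$F, tab$epsilon,
                         tab$p_gg, tab$eta_p2), "")
    }
    ph <- bundle$posthoc[[algo]]
    sig <- ph[ph$p_bonferroni < 0.05, ]
    lines <- c(lines, sprintf("### Post hoc (frequency, %s)", algo),
               sprintf("%s: %s vs %s, diff = %.3f, t(%d) = %.3f, pBonf = %.4g, dz = %.3f",
                       ph$duration_condition, ph$cell_a, ph$cell_b,
                       ph$mean_diff, ph$df, ph$t, ph$p_bonferroni, ph$dz),
               if (nrow(sig) == 0) "No significant post hoc effects." else
                 sprintf("%d significant post hoc effect(s).", nrow(sig)),
               "")
  }
  aw <- bundle$awareness
  lines <- c(lines, "## Awareness (4AFC)",
             sprintf("%s ms: correct %.3f (p vs chance %.4g), seen %.3f (p vs 0 %.4g)%s",
                     aw$duration_condition, aw$mean_correct,
                     aw$p_correct_vs_chance, aw$mean_seen,
                     aw$p_seen_vs_zero,
                     ifelse(aw$degenerate, " [degenerate]", "")))
  lines
}
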