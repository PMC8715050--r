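#' Build a counterbalanced trial schedule
#'
#' Produces the full experiment schedule: every combination of reward level
#' and display-duration condition appears equally often, with trial order
#' randomised within the experiment.  The default layout reproduces the
#' published design of five 42-trial blocks over a 2 (reward: 1 vs 50 cents)
#' by 3 (display duration) factorial, i.e. 35 trials per cell.
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block.
#' @param reward_levels Reward magnitudes in cents.
#' @param durations Display-duration condition labels.
#' @param seed Optional integer seed for the trial-order shuffle.
#' @return A tibble with columns `block`, `trial` (within block),
#'   `reward_cents`, `duration_condition`, one row per trial in presentation
#'   order.
#' @examples
#' sched <- make_schedule(seed = 1)
#' table(sched$reward_cents, sched$duration_condition) # 35 everywhere
#' @export
make_schedule <- function(n_blocks = 5,
                          trials_per_block = 42,
                          reward_levels = c(1, 50),
                          durations = c("17", "Dindiv", "100"),
                          seed = NULL) {
  n_total <- n_blocks * trials_per_block
  n_cells <- length(reward_levels) * length(durations)
  abort_if(n_total %% n_cells != 0,
           sprintf(paste0("Cannot counterbalance: %d trials are not divisible",
                          " by %d condition cells."), n_total, n_cells),
           class = "ocuvigor_counterbalance_error")
  per_cell <- n_total %/% n_cells
  cells <- tidyr::expand_grid(
    reward_cents = reward_levels,
    duration_condition = durations
  )
  trials <- cells[rep(seq_len(nrow(cells)), each = per_cell), ]
  ord <- with_seed(seed, sample.int(n_total))
  trials <- trials[ord, ]
  trials$block <- rep(seq_len(n_blocks), each = trials_per_block)
  trials$trial <- rep(seq_len(trials_per_block), times = n_blocks)
  dplyr::select(tibble::as_tibble(trials),
                "block", "trial", "reward_cents", "duration_condition")
}
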