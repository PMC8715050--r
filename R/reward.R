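# The trial payout rule and block-level reward accounting.

#' Trial payout from landed targets
#'
#' The gained reward is an exponentially accelerating fraction of the coin
#' value:
#' `coin_value * (10^(LT/NT) - (1 - LT/NT)) / 10`,
#' where `LT` is the number of landed targets and `NT` the number of targets
#' shown.  The payout is 0 at `LT = 0`, the full coin value at `LT = NT`,
#' strictly increasing in `LT`, and linear in `coin_value`.  Values are kept
#' as exact real cents (no rounding).
#'
#' @param landed Landed-target count(s), `0 <= landed <= total`.
#' @param coin_value Coin value in cents (1 or 50 in the task).
#' @param total Total number of targets.
#' @return Payout in cents (vectorised).
#' @examples
#' gained_reward(0:18, coin_value = 50)
#' @export
gained_reward <- function(landed, coin_value, total = 18) {
  abort_if(any(total <= 0) || any(coin_value <= 0),
           "`total` and `coin_value` must be positive.",
           class = "ocuvigor_reward_error")
  abort_if(any(landed < 0) || any(landed > total),
           "`landed` must lie in [0, total].",
           class = "ocuvigor_reward_error")
  frac <- landed / total
  coin_value * (10^frac - (1 - frac)) / 10
}

#' Block-level reward accounting
#'
#' Computes per-trial payouts, the running block total, and the reward-bar
#' fraction: cumulative gained reward over the maximum attainable in the
#' block (the sum of the block's coin values).
#'
#' @param trials Tibble with `block`, `trial`, `reward_cents`, and `landed`
#'   (landed-target counts).
#' @param total Targets per trial.
#' @return `trials` with added `gained_cents`, `cumulative_cents`, and
#'   `bar_fraction` (in \\[0, 1\\]), computed within block in trial order.
#' @export
block_account <- function(trials, total = 18) {
  trials <- dplyr::arrange(trials, .data$block, .data$trial)
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(trials, .data$block),
    gained_cents = gained_reward(.data$landed, .data$reward_cents, total),
    cumulative_cents = cumsum(.data$gained_cents),
    bar_fraction = .data$cumulative_cents / sum(.data$reward_cents)))
}
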