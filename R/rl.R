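#' Scale a payout to the block's range
#'
#' Divides the payout by the block's maximum absolute payout (an adjustment
#' for range adaptation across the changing payout variants), mapping all
#' payouts into \[-1, 1\].
#'
#' @param payout Payout(s) in points.
#' @param variant Payout variant 1..4 of the block.
#' @return Scaled payout(s) in \[-1, 1\].
#' @export
scale_payout <- function(payout, variant) {
  events <- urn_events(variant)
  mx <- max(abs(events$payout))
  if (!all(payout %in% events$payout))
    stop("payout not possible under variant ", variant, ": ",
         paste(setdiff(payout, events$payout), collapse = ", "),
         call. = FALSE)
  payout / mx
}

#' Run a Rescorla-Wagner learner over a session
#'
#' Delta-rule value learning on range-scaled payouts: on each trial the
#' reward prediction error is \eqn{\delta_t = p_t - EV_t} and the expected
#' value updates as \eqn{EV_{t+1} = EV_t + \alpha\,\delta_t}. By default one
#' EV is kept per urn (only the chosen urn updates) and EVs reset to 0 at
#' each block boundary, since the payout variant changes between blocks; a
#' single EV shared by both urns is available via `per_urn = FALSE`.
#'
#' @param session An `urn_session`.
#' @param alpha Learning rate in \[0, 1\].
#' @param per_urn One EV per urn (default) or a single shared EV.
#' @param reset_blocks Reset EVs to 0 at block boundaries (default TRUE).
#' @return A data.frame with one row per trial: `block`, `trial`, `urn`,
#'   `p_scaled`, `ev` (value before update), `rpe` and `ev_post` (value
#'   after update).
#' @export
run_rl_trace <- function(session, alpha, per_urn = TRUE, reset_blocks = TRUE) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("`alpha` must be a single value in [0, 1]", call. = FALSE)
  validate_session(session)
  tr <- session$trials
  n <- nrow(tr)
  variants <- vapply(session$blocks, function(b) as.integer(b$variant),
                     integer(1))
  max_pay <- vapply(variants, function(v) max(abs(urn_events(v)$payout)),
                    numeric(1))
  p_scaled <- tr$payout / max_pay[tr$block]

  ev_pre <- rpe <- ev_post <- numeric(n)
  ev <- c(blue = 0, yellow = 0)
  cur_block <- 0L
  for (i in seq_len(n)) {
    if (reset_blocks && tr$block[i] != cur_block) {
      cur_block <- tr$block[i]
      ev <- c(blue = 0, yellow = 0)
    }
    key <- if (per_urn) tr$chosen_urn[i] else "blue"
    ev_pre[i] <- ev[[key]]
    rpe[i] <- p_scaled[i] - ev[[key]]
    ev[[key]] <- ev[[key]] + alpha * rpe[i]
    ev_post[i] <- ev[[key]]
  }
  data.frame(block = tr$block, trial = tr$trial, urn = tr$chosen_urn,
             p_scaled = p_scaled, ev = ev_pre, rpe = rpe, ev_post = ev_post,
             stringsAsFactors = FALSE)
}
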