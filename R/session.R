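#' Construct a session log
#'
#' Bundles a task configuration, the block specifications, the per-trial
#' records and the end-of-block gamble responses into a validated
#' `urn_session` object. Normally produced by [simulate_agent_session()] or
#' [read_session()]; exported so that externally recorded sessions can be
#' brought into the same container.
#'
#' @param config An [task_config()] object.
#' @param blocks Block list from [generate_schedule()].
#' @param trials data.frame with columns `block`, `trial` (1-based within
#'   block), `chosen_urn`, `event_class`, `event`, `payout`, `prompted`,
#'   `belief_prompt` (0-100, `NA` on unprompted trials).
#' @param gambles data.frame with columns `block`, `urn`, `response`
#'   ("good"/"bad"/"abstain") and `truth`.
#' @param discretize Were prompts discretized to steps of 10? Governs the
#'   divisible-by-10 validation of `belief_prompt`.
#' @return An object of class `urn_session` with a `totals` element from
#'   [score_session()].
#' @export
urn_session <- function(config, blocks, trials, gambles, discretize = TRUE) {
  session <- structure(
    list(config = config, blocks = blocks, trials = trials,
         gambles = gambles, discretize = isTRUE(discretize), totals = NULL),
    class = "urn_session")
  validate_session(session)
  session$totals <- score_session(session)
  session
}

#' Validate a session log
#'
#' Checks trial counts, prompt consistency (`belief_prompt` present iff
#' `prompted`), the 0-100 range and, for discretized sessions, divisibility
#' of prompts by 10. Violations are reported with the offending row numbers.
#'
#' @param session An `urn_session` object.
#' @return The session, invisibly.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "urn_session"))
  tr <- session$trials
  cfg <- session$config
  needed <- c("block", "trial", "chosen_urn", "event_class", "event",
              "payout", "prompted", "belief_prompt")
  missing_cols <- setdiff(needed, names(tr))
  if (length(missing_cols))
    stop("session trials missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(tr) != cfg$n_blocks * cfg$trials_per_block)
    stop("trial count ", nrow(tr), " != n_blocks x trials_per_block = ",
         cfg$n_blocks * cfg$trials_per_block, call. = FALSE)
  bad <- which(tr$prompted != !is.na(tr$belief_prompt))
  if (length(bad))
    stop("belief_prompt must be present exactly on prompted trials; rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  pr <- tr$belief_prompt[tr$prompted]
  if (length(pr) && (any(pr < 0) || any(pr > 100)))
    stop("belief prompts outside [0, 100]", call. = FALSE)
  if (session$discretize) {
    bad <- which(tr$prompted & (tr$belief_prompt %% 10 != 0))
    if (length(bad))
      stop("belief_prompt not a multiple of 10; rows: ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  g <- session$gambles
  expect_g <- cfg$n_blocks * 2L
  if (nrow(g) != expect_g) {
    have <- interaction(g$block, g$urn)
    stop("gamble table has ", nrow(g), " rows, expected ", expect_g,
         " (two urns per block)", call. = FALSE)
  }
  if (!all(g$response %in% c("good", "bad", "abstain")))
    stop("gamble responses must be good/bad/abstain", call. = FALSE)
  invisible(session)
}

#' @export
print.urn_session <- function(x, ...) {
  cfg <- x$config
  cat("<urn_session> ", cfg$n_blocks, " blocks x ", cfg$trials_per_block,
      " trials (", cfg$mode, " mode, prompt every ", cfg$prompt_every,
      ")\n", sep = "")
  cat("  total points:", x$totals$points,
      sprintf("(%.2f EUR)", x$totals$euros), "\n")
  n_good <- sum(x$trials$prompted)
  cat("  prompted trials:", n_good, "\n")
  invisible(x)
}

# variant of the block a trial belongs to
block_variant <- function(session, block) session$blocks[[block]]$variant

# truth of the chosen urn on each trial, vectorized over the trial table
chosen_truth <- function(session) {
  vapply(seq_len(nrow(session$trials)), function(i) {
    b <- session$trials$block[i]
    unname(session$blocks[[b]]$truth[session$trials$chosen_urn[i]])
  }, character(1))
}
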