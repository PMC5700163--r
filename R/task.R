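#' Event distribution table for one payout variant
#'
#' Builds the seven-event distribution of the two-urn task for one of the four
#' payout variants. Each row is a payout event with its probability under a
#' good and under a bad urn. Informative events occur with unequal
#' probabilities in the two urn types (likelihood ratio 2.5 or 0.4) and so
#' carry evidence about the urn's long-term valence; non-informative events
#' are equally likely in both and carry only short-term (monetary) valence.
#'
#' The probability columns are identical across variants: (.10, .25, .10,
#' .10, .10, .10, .25) under a good urn and (.25, .10, .10, .10, .10, .25,
#' .10) under a bad urn. Only the payout column changes with the variant, in
#' a way that keeps the per-trial expected value at +1.5 points for good and
#' -1.5 points for bad urns.
#'
#' @param variant Integer in 1..4 selecting the payout column.
#' @return A data.frame with one row per event and columns `event` (row id
#'   1..7), `short_valence` ("negative"/"zero"/"positive"), `long_indication`
#'   ("good"/"bad"/"none": the valence the event is evidence for),
#'   `informative` (logical), `congruent` (logical, `NA` for non-informative
#'   events), `p_good`, `p_bad` and `payout` (points).
#' @examples
#' ev <- urn_events(1)
#' sum(ev$p_good * ev$payout)  # +1.5 points per trial from a good urn
#' @export
urn_events <- function(variant) {
  if (length(variant) != 1L || !variant %in% 1:4)
    stop("`variant` must be a single integer in 1..4", call. = FALSE)
  payouts <- switch(variant,
    `1` = c(-50, -40, -30, 0,  30, 40, 50),
    `2` = c(-50, -40, -60, 0,  60, 40, 50),
    `3` = c(-30, -20, -10, 0,  10, 20, 30),
    `4` = c(-30, -20, -40, 0,  40, 20, 30)
  )
  data.frame(
    event           = 1:7,
    short_valence   = c("negative", "negative", "negative", "zero",
                        "positive", "positive", "positive"),
    long_indication = c("bad", "good", "none", "none", "none", "bad", "good"),
    informative     = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    congruent       = c(TRUE, FALSE, NA, NA, NA, FALSE, TRUE),
    p_good          = c(.10, .25, .10, .10, .10, .10, .25),
    p_bad           = c(.25, .10, .10, .10, .10, .25, .10),
    payout          = payouts,
    stringsAsFactors = FALSE
  )
}

#' Expected payout per trial under one urn valence
#'
#' @param events Event table from [urn_events()].
#' @param valence "good" or "bad": which conditional distribution to use.
#' @return Expected points per trial (+1.5 for good, -1.5 for bad urns in
#'   every variant).
#' @export
expected_value <- function(events, valence = c("good", "bad")) {
  valence <- match.arg(valence)
  p <- if (valence == "good") events$p_good else events$p_bad
  sum(p * events$payout)
}

#' Likelihood ratio of an event between good and bad urns
#'
#' The ratio p(event | good) / p(event | bad). Informative events have ratio
#' 2.5 (evidence for good) or 0.4 (evidence for bad); non-informative events
#' have ratio 1 and leave any Bayesian belief unchanged.
#'
#' @param event One row of the table from [urn_events()] (or any data.frame
#'   slice with `p_good` and `p_bad` columns).
#' @return Numeric likelihood ratio(s).
#' @export
likelihood_ratio <- function(event) {
  if (any(event$p_bad == 0))
    stop("likelihood ratio undefined: p_bad is zero", call. = FALSE)
  event$p_good / event$p_bad
}

# Scheduled event classes, defined relative to the chosen urn's true valence:
# likely-* events have probability .25 under the truth, unlikely-* events .10
# and indicate the opposite valence; congruency is the Table column (payout
# sign vs indicated valence). Counts per 20-trial block follow the event
# probabilities exactly.
EVENT_CLASSES <- c(
  "likely-congruent"    = 5L,
  "likely-incongruent"  = 5L,
  "unlikely-congruent"  = 2L,
  "unlikely-incongruent" = 2L,
  "noninf-negative"     = 2L,
  "noninf-zero"         = 2L,
  "noninf-positive"     = 2L
)

# map a scheduled class to the concrete event row given the chosen urn's truth
class_to_event <- function(class, truth) {
  if (truth == "good") {
    switch(class,
      "likely-congruent"     = 7L,
      "likely-incongruent"   = 2L,
      "unlikely-congruent"   = 1L,
      "unlikely-incongruent" = 6L,
      "noninf-negative" = 3L, "noninf-zero" = 4L, "noninf-positive" = 5L,
      stop("unknown event class: ", class, call. = FALSE))
  } else {
    switch(class,
      "likely-congruent"     = 1L,
      "likely-incongruent"   = 6L,
      "unlikely-congruent"   = 7L,
      "unlikely-incongruent" = 2L,
      "noninf-negative" = 3L, "noninf-zero" = 4L, "noninf-positive" = 5L,
      stop("unknown event class: ", class, call. = FALSE))
  }
}

#' Task configuration
#'
#' Assembles the session-level parameters of the two-urn task. The defaults
#' reproduce the original protocol: 12 blocks of 20 trials (240 trials), a
#' belief prompt after every trial with a persistent marker, 5 bonus points
#' per correct end-of-block gamble, and 3 euro cents per 10 points.
#' `mode = "replication"` switches to a prompt every third trial with the
#' marker reset to the indifference point (50) between prompts.
#'
#' @param n_blocks Number of blocks (default 12).
#' @param trials_per_block Trials per block (default 20; class frequencies
#'   times this must be integer).
#' @param mode "original" or "replication" (presets for `prompt_every` and
#'   `marker_reset`).
#' @param prompt_every Prompt the belief every k-th trial (1 = every trial).
#' @param marker_reset Reset the belief marker to 50 before each prompt?
#' @param bonus_points Points gained/lost per correct/incorrect gamble.
#' @param cents_per_point Conversion to euro cents (3 cents per point, i.e.
#'   10 points = 30 cents).
#' @param both_good_block Index of the block in which both urns are good, or
#'   `NULL` to draw a seeded position >= 4. The both-bad block is always
#'   block 3.
#' @param shared_schedule Should every agent of a cohort see the same
#'   event-class schedule?
#' @param rng_seed Seed used for schedule generation when none is passed
#'   explicitly.
#' @return A list of class `"urn_config"`.
#' @export
task_config <- function(n_blocks = 12L, trials_per_block = 20L,
                        mode = c("original", "replication"),
                        prompt_every = NULL, marker_reset = NULL,
                        bonus_points = 5, cents_per_point = 3,
                        both_good_block = NULL, shared_schedule = TRUE,
                        rng_seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(prompt_every)) prompt_every <- if (mode == "replication") 3L else 1L
  if (is.null(marker_reset)) marker_reset <- mode == "replication"
  if (prompt_every < 1L) stop("`prompt_every` must be >= 1", call. = FALSE)
  counts <- EVENT_CLASSES / 20 * trials_per_block
  if (any(counts != round(counts)))
    stop("`trials_per_block` must keep all event-class counts integer ",
         "(multiples of 20)", call. = FALSE)
  if (!is.null(both_good_block) &&
      (both_good_block == 3L || both_good_block > n_blocks))
    stop("`both_good_block` must differ from 3 and be <= n_blocks",
         call. = FALSE)
  structure(list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    mode = mode,
    prompt_every = as.integer(prompt_every),
    marker_reset = isTRUE(marker_reset),
    bonus_points = bonus_points,
    cents_per_point = cents_per_point,
    both_good_block = both_good_block,
    shared_schedule = isTRUE(shared_schedule),
    rng_seed = as.integer(rng_seed)
  ), class = "urn_config")
}

#' Generate the deterministic block/event schedule of a session
#'
#' Per block, the multiset of event classes (5 likely-congruent, 5
#' likely-incongruent, 2 unlikely-congruent, 2 unlikely-incongruent and 2 of
#' each non-informative valence per 20 trials) is shuffled with the seeded
#' RNG, so each class is observed with a frequency exactly matching its
#' probability. Payout variants rotate round-robin over 1..4 from a seeded
#' starting offset. Ten blocks have one good and one bad urn; block 3 has two
#' bad urns and one seeded block (position >= 4 unless configured) has two
#' good urns.
#'
#' @param config An [task_config()] object.
#' @param seed Integer seed; defaults to `config$rng_seed`.
#' @return A list of block specifications, each a list with `block`,
#'   `variant`, `truth` (named c(blue=, yellow=)) and `classes`
#'   (character vector of length `trials_per_block`).
#' @export
generate_schedule <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "urn_config"))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  nb <- config$n_blocks
  tpb <- config$trials_per_block
  counts <- as.integer(EVENT_CLASSES / 20 * tpb)
  class_pool <- rep(names(EVENT_CLASSES), counts)

  start <- sample.int(4L, 1L)
  variants <- ((start - 1L + seq_len(nb) - 1L) %% 4L) + 1L

  both_good <- config$both_good_block
  if (is.null(both_good)) {
    both_good <- if (nb >= 4L) sample(4:nb, 1L) else NA_integer_
  }
  truths <- vector("list", nb)
  for (b in seq_len(nb)) {
    if (b == 3L && nb >= 3L) {
      truths[[b]] <- c(blue = "bad", yellow = "bad")
    } else if (!is.na(both_good) && b == both_good) {
      truths[[b]] <- c(blue = "good", yellow = "good")
    } else {
      good_urn <- sample(c("blue", "yellow"), 1L)
      truths[[b]] <- if (good_urn == "blue") c(blue = "good", yellow = "bad")
                     else c(blue = "bad", yellow = "good")
    }
  }

  lapply(seq_len(nb), function(b) {
    list(block = b,
         variant = variants[b],
         truth = truths[[b]],
         classes = sample(class_pool, length(class_pool)))
  })
}

#' Realize one scheduled trial for a chosen urn
#'
#' Maps a scheduled event class to a concrete payout event conditional on the
#' chosen urn's true valence: the information conveyed is predetermined, but
#' the payout depends on the choice (a likely-congruent event is +50 from a
#' good urn and -50 from a bad urn in variant 1).
#'
#' @param block One block spec from [generate_schedule()].
#' @param trial Trial index within the block (1-based).
#' @param chosen_urn "blue" or "yellow".
#' @return A list with `event` (row id in [urn_events()]), `payout` (points),
#'   `class`, and `truth` of the chosen urn.
#' @export
realize_trial <- function(block, trial, chosen_urn = c("blue", "yellow")) {
  chosen_urn <- match.arg(chosen_urn)
  cls <- block$classes[trial]
  truth <- unname(block$truth[chosen_urn])
  ev <- class_to_event(cls, truth)
  events <- urn_events(block$variant)
  list(event = ev, payout = events$payout[ev], class = cls, truth = truth)
}

#' Score a session: total points and euros
#'
#' Sums trial payouts and end-of-block gamble bonuses (+/- `bonus_points` per
#' correct/incorrect valence guess, 0 for abstentions) and converts points to
#' euros (3 cents per point).
#'
#' @param session An `urn_session` object.
#' @return A list with `points_payout`, `points_bonus`, `points` and `euros`.
#' @export
score_session <- function(session) {
  stopifnot(inherits(session, "urn_session"))
  trials <- session$trials
  expected_n <- session$config$n_blocks * session$config$trials_per_block
  if (nrow(trials) != expected_n)
    stop("incomplete session log: ", nrow(trials), " trials, expected ",
         expected_n, call. = FALSE)
  g <- session$gambles
  bonus <- ifelse(g$response == "abstain", 0,
                  ifelse(g$response == g$truth,
                         session$config$bonus_points,
                         -session$config$bonus_points))
  points <- sum(trials$payout) + sum(bonus)
  list(points_payout = sum(trials$payout),
       points_bonus = sum(bonus),
       points = points,
       euros = points * session$config$cents_per_point / 100)
}

# Seeded RNG scoped to a function: saves and restores .Random.seed so that
# package internals do not disturb the caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
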