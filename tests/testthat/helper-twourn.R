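# Hand-built sessions with a fully controlled event sequence, bypassing the
# agent simulator, for unit tests of the learners and fitters.
toy_session <- function(events, chosen = "blue", variant = 1,
                        truth = c(blue = "good", yellow = "bad"),
                        prompts = NULL, discretize = TRUE) {
  n <- length(events)
  stopifnot(n %% 20 == 0)
  nb <- n %/% 20L
  cfg <- task_config(n_blocks = nb, trials_per_block = 20L,
                     both_good_block = NULL)
  ev_tab <- urn_events(variant)
  blocks <- lapply(seq_len(nb), function(b)
    list(block = b, variant = variant, truth = truth,
         classes = rep("manual", 20L)))
  chosen <- rep_len(chosen, n)
  if (is.null(prompts)) prompts <- rep(NA_real_, n)
  trials <- data.frame(
    block = rep(seq_len(nb), each = 20L),
    trial = rep(1:20, nb),
    chosen_urn = chosen,
    event_class = "manual",
    event = as.integer(events),
    payout = ev_tab$payout[events],
    prompted = !is.na(prompts),
    belief_prompt = prompts,
    stringsAsFactors = FALSE
  )
  gambles <- data.frame(block = rep(seq_len(nb), each = 2L),
                        urn = rep(c("blue", "yellow"), nb),
                        response = "abstain",
                        truth = rep(unname(truth[c("blue", "yellow")]), nb),
                        stringsAsFactors = FALSE)
  urn_session(cfg, blocks, trials, gambles, discretize = discretize)
}

# Session whose prompts are written by an external rule (e.g. a known RL
# trace plus noise); prompts are continuous, so discretization is off.
with_prompts <- function(session, prompts01) {
  session$trials$belief_prompt <- prompts01 * 100
  session$trials$prompted <- !is.na(prompts01)
  session$discretize <- FALSE
  validate_session(session)
  session
}

fast_config <- function(...) task_config(rng_seed = 99L, ...)
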