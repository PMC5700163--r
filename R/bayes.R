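#' One Bayesian belief update
#'
#' Posterior probability that the chosen urn is good after observing one
#' payout event, given the prior belief and the event's conditional
#' probabilities under good and bad urns:
#' \deqn{B_{t+1} = \frac{p(E|good)\,B_t}{p(E|good)\,B_t + p(E|bad)\,(1-B_t)}}
#' Non-informative events (equal probabilities) leave the belief unchanged;
#' beliefs of exactly 0 or 1 are absorbing.
#'
#' @param prior Prior belief in \[0, 1\] (probability the urn is good).
#' @param event One row of [urn_events()] (anything with `p_good`/`p_bad`).
#' @return Posterior belief in \[0, 1\].
#' @examples
#' ev <- urn_events(1)
#' posterior_update(0.5, ev[7, ])  # congruent event: 5/7
#' @export
posterior_update <- function(prior, event) {
  if (any(prior < 0 | prior > 1)) stop("prior must lie in [0, 1]", call. = FALSE)
  # equal likelihoods carry no evidence: return the prior bit-exactly so the
  # no-update-on-non-informative-events invariant holds without FP noise
  if (all(event$p_good == event$p_bad)) {
    if (any(event$p_good == 0))
      stop("posterior undefined: predictive probability of the event is zero",
           call. = FALSE)
    return(prior)
  }
  num <- event$p_good * prior
  den <- num + event$p_bad * (1 - prior)
  if (any(den == 0))
    stop("posterior undefined: predictive probability of the event is zero",
         call. = FALSE)
  num / den
}

#' Surprise (Shannon information) of an event
#'
#' Negative log predictive probability of the event under the current belief,
#' \eqn{I_t = -\ln(B_t\,p(E|good) + (1-B_t)\,p(E|bad))}, in nats. In this
#' task surprise is deliberately decoupled from belief change: rare
#' non-informative events are surprising but never move the belief.
#'
#' @inheritParams posterior_update
#' @return Surprise in nats; `Inf` when the event has predictive
#'   probability zero.
#' @export
surprise <- function(prior, event) {
  if (any(prior < 0 | prior > 1)) stop("prior must lie in [0, 1]", call. = FALSE)
  p <- prior * event$p_good + (1 - prior) * event$p_bad
  ifelse(p == 0, Inf, -log(p))
}

#' Run a Bayesian learner over a session
#'
#' Chains the one-step Bayes update over every trial of a session, tracking
#' one belief per urn. Beliefs reset to the instructed prior of 0.5 at each
#' block start; the unchosen urn's belief never changes.
#'
#' Two modes:
#' \describe{
#'   \item{normative}{the ideal observer: each trial's prior is the model's
#'     own previous posterior for the chosen urn.}
#'   \item{subjective}{the same Bayes rule re-anchored to the participant:
#'     each trial's prior is the most recent prompted belief for the chosen
#'     urn within the block (scaled /100), falling back to 0.5 (flagged in
#'     `prior_fallback`) when that urn has not been prompted yet.}
#' }
#'
#' @param session An `urn_session`.
#' @param mode "normative" or "subjective".
#' @return A data.frame (one row per trial, chosen urn only) with columns
#'   `block`, `trial`, `urn`, `event`, `prior`, `posterior`, `delta_b`
#'   (signed update, posterior - prior), `d_kl` (its magnitude), `surprise`
#'   (nats) and `prior_fallback`.
#' @export
run_bayesian_trace <- function(session, mode = c("normative", "subjective")) {
  mode <- match.arg(mode)
  validate_session(session)
  tr <- session$trials
  if (mode == "subjective" && !any(tr$prompted))
    stop("subjective mode requires at least one belief prompt", call. = FALSE)

  n <- nrow(tr)
  prior <- posterior <- srp <- numeric(n)
  fallback <- logical(n)

  belief <- c(blue = 0.5, yellow = 0.5)       # normative chained beliefs
  last_prompt <- c(blue = NA_real_, yellow = NA_real_)
  cur_block <- 0L
  for (i in seq_len(n)) {
    if (tr$block[i] != cur_block) {           # block boundary: reset priors
      cur_block <- tr$block[i]
      belief <- c(blue = 0.5, yellow = 0.5)
      last_prompt <- c(blue = NA_real_, yellow = NA_real_)
      events <- urn_events(session$blocks[[cur_block]]$variant)
    }
    urn <- tr$chosen_urn[i]
    ev <- events[tr$event[i], ]
    if (mode == "normative") {
      b0 <- belief[[urn]]
    } else {
      b0 <- last_prompt[[urn]]
      if (is.na(b0)) { b0 <- 0.5; fallback[i] <- TRUE }
    }
    b1 <- posterior_update(b0, ev)
    prior[i] <- b0
    posterior[i] <- b1
    srp[i] <- surprise(b0, ev)
    if (mode == "normative") belief[[urn]] <- b1
    if (tr$prompted[i]) last_prompt[[urn]] <- tr$belief_prompt[i] / 100
  }
  data.frame(block = tr$block, trial = tr$trial, urn = tr$chosen_urn,
             event = tr$event, prior = prior, posterior = posterior,
             delta_b = posterior - prior, d_kl = abs(posterior - prior),
             surprise = srp, prior_fallback = fallback,
             stringsAsFactors = FALSE)
}
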