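#' Generative parameters of a synthetic participant
#'
#' The synthetic agent updates an internal belief per urn with a linear
#' hybrid of the ideal Bayesian update and a reward-prediction-error bias —
#' the generative mirror of the behavioural regression model — and chooses
#' between urns by a softmax over current beliefs with a count-based
#' exploration bonus (exploitative but exploratory behaviour).
#'
#' On each trial the chosen urn's belief changes by
#' \deqn{\Delta = w_{bayes}\,\Delta B_t + w_{rpe}\,\delta_t + \epsilon,\quad
#'   \epsilon \sim N(0, noise\_sd^2)}
#' attenuated multiplicatively by `edge_shrink` when the urn's last confirmed
#' marker sits at a bound (0 or 100), then clipped to \[0, 1\]. The belief is
#' reported on prompted trials, discretized to the nearest 10 on the 0-100
#' scale unless `discretize = FALSE` (the internal belief always stays
#' continuous). At block ends the agent gambles "good" when its belief
#' exceeds 0.5 + `gamble_margin`, "bad" below 0.5 - `gamble_margin`, and
#' abstains in between.
#'
#' @param w_bayes Weight (>= 0) on the Bayesian update (1 = ideal observer).
#' @param w_rpe Weight on the RPE bias (0 = unbiased).
#' @param alpha Learning rate of the agent's internal delta-rule learner.
#' @param edge_shrink Multiplicative attenuation in \[0, 1\] of updates made
#'   while the marker is at a bound (0 = none).
#' @param noise_sd SD of Gaussian update noise on the \[0, 1\] belief scale.
#' @param choice_temperature Softmax temperature (> 0); lower = more
#'   exploitative.
#' @param exploration_bonus Bonus (>= 0) added to the less-sampled urn's
#'   choice value, decaying with its within-block choice count.
#' @param gamble_margin Belief margin around 0.5 inside which the agent
#'   abstains from the end-of-block gamble.
#' @param discretize Report prompts in steps of 10 (default TRUE).
#' @param seed Optional agent-level RNG seed.
#' @return A list of class `urn_agent_params`.
#' @export
agent_params <- function(w_bayes = 1, w_rpe = 0, alpha = 0.06,
                         edge_shrink = 0.3, noise_sd = 0.05,
                         choice_temperature = 0.4, exploration_bonus = 0.3,
                         gamble_margin = 0.1, discretize = TRUE,
                         seed = NULL) {
  stopifnot(w_bayes >= 0, alpha >= 0, alpha <= 1,
            edge_shrink >= 0, edge_shrink <= 1, noise_sd >= 0,
            choice_temperature > 0, exploration_bonus >= 0)
  structure(list(w_bayes = w_bayes, w_rpe = w_rpe, alpha = alpha,
                 edge_shrink = edge_shrink, noise_sd = noise_sd,
                 choice_temperature = choice_temperature,
                 exploration_bonus = exploration_bonus,
                 gamble_margin = gamble_margin,
                 discretize = isTRUE(discretize), seed = seed),
            class = "urn_agent_params")
}

#' Simulate one agent's full session
#'
#' Runs a synthetic agent (see [agent_params()]) through a scheduled session
#' of the two-urn task and returns the complete session log, including
#' end-of-block gambles and totals. With `w_bayes = 1`, `w_rpe = 0`,
#' `noise_sd = 0` and `discretize = FALSE` the prompts reproduce the
#' normative Bayesian trace exactly.
#'
#' @param config A [task_config()].
#' @param params An [agent_params()].
#' @param schedule Optional pre-generated schedule (so cohorts can share one);
#'   defaults to [generate_schedule()] under `config$rng_seed`.
#' @param seed RNG seed for choices and noise; defaults to `params$seed`,
#'   then `config$rng_seed`.
#' @return An `urn_session`.
#' @export
simulate_agent_session <- function(config, params = agent_params(),
                                   schedule = NULL, seed = NULL) {
  stopifnot(inherits(config, "urn_config"),
            inherits(params, "urn_agent_params"))
  if (is.null(schedule)) schedule <- generate_schedule(config)
  if (is.null(seed)) seed <- if (!is.null(params$seed)) params$seed else config$rng_seed
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  nb <- config$n_blocks
  tpb <- config$trials_per_block
  n <- nb * tpb
  rec <- data.frame(block = rep(seq_len(nb), each = tpb),
                    trial = rep(seq_len(tpb), nb),
                    chosen_urn = character(n), event_class = character(n),
                    event = integer(n), payout = numeric(n),
                    prompted = logical(n), belief_prompt = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  gambles <- data.frame(block = rep(seq_len(nb), each = 2),
                        urn = rep(c("blue", "yellow"), nb),
                        response = character(2 * nb),
                        truth = character(2 * nb), stringsAsFactors = FALSE)

  i <- 0L
  for (b in seq_len(nb)) {
    blk <- schedule[[b]]
    events <- urn_events(blk$variant)
    max_pay <- max(abs(events$payout))
    belief <- c(blue = 0.5, yellow = 0.5)
    ev_rl <- c(blue = 0, yellow = 0)
    marker <- c(blue = NA_real_, yellow = NA_real_)
    n_chosen <- c(blue = 0L, yellow = 0L)

    for (t in seq_len(tpb)) {
      i <- i + 1L
      # softmax choice over belief + exploration bonus for less-sampled urn
      val <- belief + params$exploration_bonus / (1 + n_chosen)
      pr_blue <- 1 / (1 + exp((val[["yellow"]] - val[["blue"]]) /
                                params$choice_temperature))
      urn <- if (stats::runif(1) < pr_blue) "blue" else "yellow"
      n_chosen[[urn]] <- n_chosen[[urn]] + 1L

      out <- realize_trial(blk, t, urn)
      ev <- events[out$event, ]

      db <- posterior_update(belief[[urn]], ev) - belief[[urn]]
      p_scaled <- out$payout / max_pay
      rpe <- p_scaled - ev_rl[[urn]]
      ev_rl[[urn]] <- ev_rl[[urn]] + params$alpha * rpe

      upd <- params$w_bayes * db + params$w_rpe * rpe
      if (params$noise_sd > 0) upd <- upd + stats::rnorm(1, 0, params$noise_sd)
      at_edge <- params$discretize && !config$marker_reset &&
        !is.na(marker[[urn]]) && marker[[urn]] %in% c(0, 100)
      if (at_edge) upd <- upd * (1 - params$edge_shrink)
      belief[[urn]] <- min(1, max(0, belief[[urn]] + upd))

      prompted <- t %% config$prompt_every == 0L
      rec$chosen_urn[i] <- urn
      rec$event_class[i] <- out$class
      rec$event[i] <- out$event
      rec$payout[i] <- out$payout
      rec$prompted[i] <- prompted
      if (prompted) {
        prompt <- if (params$discretize) round(belief[[urn]] * 10) * 10
                  else belief[[urn]] * 100
        rec$belief_prompt[i] <- prompt
        marker[[urn]] <- prompt
      }
    }

    for (u in c("blue", "yellow")) {
      resp <- if (belief[[u]] > 0.5 + params$gamble_margin) "good"
              else if (belief[[u]] < 0.5 - params$gamble_margin) "bad"
              else "abstain"
      row <- (b - 1L) * 2L + match(u, c("blue", "yellow"))
      gambles$response[row] <- resp
      gambles$truth[row] <- unname(blk$truth[u])
    }
  }

  urn_session(config, schedule, rec, gambles, discretize = params$discretize)
}

#' Simulate a cohort of synthetic agents
#'
#' Simulates `n` independent agents, each with its own derived seed. With
#' `config$shared_schedule` (the default) every agent sees the same
#' event-class schedule, mirroring the constant-information design across
#' participants; otherwise each agent's schedule is drawn under its own seed.
#'
#' @param n Number of agents (default 24, the study-sized cohort).
#' @param config A [task_config()].
#' @param params A single [agent_params()] shared by all agents, or a list of
#'   `n` of them.
#' @param seed Master seed for the cohort.
#' @return A list of class `urn_cohort`: `sessions` (list of `urn_session`),
#'   `truth` (data.frame agent / parameter / value) and `seed`.
#' @export
simulate_cohort <- function(n = 24, config = task_config(),
                            params = agent_params(), seed = 1L) {
  stopifnot(n >= 1)
  if (inherits(params, "urn_agent_params")) params <- rep(list(params), n)
  if (length(params) != n)
    stop("`params` must be one agent_params or a list of n of them",
         call. = FALSE)
  shared <- if (config$shared_schedule)
    generate_schedule(config, seed = config$rng_seed) else NULL

  sessions <- vector("list", n)
  for (a in seq_len(n)) {
    aseed <- (seed * 1009L + a * 101L) %% .Machine$integer.max
    sched <- if (is.null(shared))
      generate_schedule(config, seed = aseed + 7L) else shared
    sessions[[a]] <- simulate_agent_session(config, params[[a]],
                                            schedule = sched, seed = aseed)
  }
  fields <- c("w_bayes", "w_rpe", "alpha", "edge_shrink", "noise_sd",
              "choice_temperature", "exploration_bonus", "gamble_margin")
  truth <- do.call(rbind, lapply(seq_len(n), function(a)
    data.frame(agent = a, param = fields,
               value = unlist(params[[a]][fields], use.names = FALSE))))
  structure(list(sessions = sessions, truth = truth, seed = seed),
            class = "urn_cohort")
}

#' Simulate-and-refit parameter recovery experiment
#'
#' For each cell of a grid of agent parameters, simulates a cohort, then
#' recovers (i) the learning rate by the log-distance MLE
#' ([fit_learning_rate()]) and (ii) the Bayesian and RPE regression weights
#' by the within-participant update regression (subjective Bayesian trace,
#' delta-rule trace at the fitted learning rate), and tabulates recovered
#' against true values.
#'
#' @param grid A list of [agent_params()] objects (one per cell).
#' @param config A [task_config()].
#' @param n_per Agents per cell.
#' @param seed Master seed.
#' @param predictors Predictor set for the recovery regression.
#' @return A list of class `urn_recovery`: `per_agent` (data.frame with true
#'   and recovered values per agent), `by_cell` (means per grid cell) and
#'   `correlations` (true-vs-recovered Pearson r and mean error for alpha and
#'   w_rpe, where they vary over the grid).
#' @export
recovery_experiment <- function(grid, config = task_config(), n_per = 20,
                                seed = 1L,
                                predictors = c("delta_b", "rpe", "edge")) {
  if (!length(grid)) stop("`grid` must be non-empty", call. = FALSE)
  rows <- vector("list", 0L)
  for (g in seq_along(grid)) {
    cohort <- simulate_cohort(n_per, config, grid[[g]],
                              seed = seed + 131L * g)
    for (a in seq_along(cohort$sessions)) {
      s <- cohort$sessions[[a]]
      afit <- fit_learning_rate(s)
      bt <- run_bayesian_trace(s, mode = "subjective")
      rt <- run_rl_trace(s, alpha = afit$alpha)
      tab <- build_update_table(s, bt, rt)
      rfit <- fit_participant(tab, predictors = predictors)
      rows[[length(rows) + 1L]] <- data.frame(
        cell = g, agent = a,
        true_w_bayes = grid[[g]]$w_bayes, true_w_rpe = grid[[g]]$w_rpe,
        true_alpha = grid[[g]]$alpha, true_noise_sd = grid[[g]]$noise_sd,
        alpha_hat = afit$alpha,
        w_bayes_hat = unname(rfit$coefficients["delta_b"]),
        w_rpe_hat = if ("rpe" %in% names(rfit$coefficients))
          unname(rfit$coefficients["rpe"]) else NA_real_)
    }
  }
  per_agent <- do.call(rbind, rows)
  by_cell <- do.call(rbind, lapply(split(per_agent, per_agent$cell), function(d)
    data.frame(cell = d$cell[1], true_w_rpe = d$true_w_rpe[1],
               true_alpha = d$true_alpha[1],
               mean_alpha_hat = mean(d$alpha_hat),
               mean_w_bayes_hat = mean(d$w_bayes_hat),
               mean_w_rpe_hat = mean(d$w_rpe_hat))))
  correlations <- list()
  if (length(unique(per_agent$true_alpha)) > 1)
    correlations$alpha <- list(
      r = stats::cor(per_agent$true_alpha, per_agent$alpha_hat),
      mean_error = mean(per_agent$alpha_hat - per_agent$true_alpha))
  if (length(unique(per_agent$true_w_rpe)) > 1)
    correlations$w_rpe <- list(
      r = stats::cor(per_agent$true_w_rpe, per_agent$w_rpe_hat),
      mean_error = mean(per_agent$w_rpe_hat - per_agent$true_w_rpe))
  structure(list(per_agent = per_agent, by_cell = by_cell,
                 correlations = correlations),
            class = "urn_recovery")
}
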