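#' Build the per-trial belief-update table of one participant
#'
#' Joins the session's prompted trials with the Bayesian and delta-rule
#' traces into the table the behavioural regressions operate on. The observed
#' update is \eqn{\Delta IBU_t}: prompted posterior belief minus the prior
#' belief (the most recent confirmed prompt for the chosen urn within the
#' block, 50 at block start), on the \[0, 1\] scale. Predictors are the
#' Bayesian signed update \eqn{\Delta B_t}, the reward prediction error
#' \eqn{\delta_t} and the scaled outcome \eqn{p_t}. The edge regressor is
#' the predicted update direction gated by an extreme prior,
#' \eqn{sign(\Delta B_t)\,1\{prior prompt \in \{0, 100\}\}}, so a negative
#' coefficient encodes attenuated updating at the scale's bounds.
#'
#' Updates and predictors are additionally normalized within participant
#' (`*_raw` columns keep the raw values): by the maximum absolute value
#' (default, `normalize = "max"`), by the standard deviation
#' (`"sd"`, for standardized coefficients) or not at all (`"none"`).
#'
#' @param session An `urn_session`.
#' @param bayes_trace Trace from [run_bayesian_trace()].
#' @param rl_trace Trace from [run_rl_trace()].
#' @param normalize "max", "sd" or "none".
#' @return A data.frame of class `urn_update_table`, one row per prompted
#'   trial: identifiers, `prior_prompt`, `post_prompt` (0-100), raw and
#'   normalized `dibu`, `delta_b`, `rpe`, `outcome`, plus `edge`,
#'   `informative`, `congruency` ("congruent"/"incongruent"/
#'   "non-informative") and `info_dir` (+1 evidence for good, -1 for bad, 0
#'   none).
#' @export
build_update_table <- function(session, bayes_trace, rl_trace,
                               normalize = c("max", "sd", "none")) {
  normalize <- match.arg(normalize)
  validate_session(session)
  tr <- session$trials
  n <- nrow(tr)
  if (nrow(bayes_trace) != n || nrow(rl_trace) != n)
    stop("traces are not aligned with the session", call. = FALSE)
  if (!any(tr$prompted))
    stop("session has no prompted trials: update table would be empty",
         call. = FALSE)

  # prior prompt: last confirmed marker for the chosen urn within the block
  prior_prompt <- numeric(n)
  last <- c(blue = NA_real_, yellow = NA_real_)
  cur_block <- 0L
  for (i in seq_len(n)) {
    if (tr$block[i] != cur_block) {
      cur_block <- tr$block[i]
      last <- c(blue = NA_real_, yellow = NA_real_)
    }
    urn <- tr$chosen_urn[i]
    prior_prompt[i] <- if (is.na(last[[urn]])) 50 else last[[urn]]
    if (tr$prompted[i]) last[[urn]] <- tr$belief_prompt[i]
  }

  keep <- which(tr$prompted)
  events <- urn_events(1)   # informativity/congruency columns are variant-free
  ev <- tr$event[keep]
  info_dir <- ifelse(events$long_indication[ev] == "good", 1,
                     ifelse(events$long_indication[ev] == "bad", -1, 0))
  congruency <- ifelse(!events$informative[ev], "non-informative",
                       ifelse(events$congruent[ev], "congruent", "incongruent"))

  out <- data.frame(
    block = tr$block[keep], trial = tr$trial[keep],
    urn = tr$chosen_urn[keep], event = ev,
    prior_prompt = prior_prompt[keep],
    post_prompt = tr$belief_prompt[keep],
    dibu_raw = (tr$belief_prompt[keep] - prior_prompt[keep]) / 100,
    delta_b_raw = bayes_trace$delta_b[keep],
    rpe_raw = rl_trace$rpe[keep],
    outcome_raw = rl_trace$p_scaled[keep],
    edge = sign(bayes_trace$delta_b[keep]) *
      (prior_prompt[keep] %in% c(0, 100)),
    informative = events$informative[ev],
    congruency = congruency,
    info_dir = info_dir,
    stringsAsFactors = FALSE
  )

  norm_const <- function(x) {
    s <- switch(normalize,
                max = max(abs(x)),
                sd = stats::sd(x),
                none = 1)
    if (!is.finite(s) || s == 0) 1 else s
  }
  out$dibu    <- out$dibu_raw    / norm_const(out$dibu_raw)
  out$delta_b <- out$delta_b_raw / norm_const(out$delta_b_raw)
  out$rpe     <- out$rpe_raw     / norm_const(out$rpe_raw)
  out$outcome <- out$outcome_raw / norm_const(out$outcome_raw)
  class(out) <- c("urn_update_table", class(out))
  out
}

#' Within-participant belief-update regression
#'
#' Ordinary least squares of the normalized observed update on a chosen set
#' of normalized predictors plus an intercept. Predictors that are constant
#' in the design (for example an edge regressor of an agent whose prior never
#' reaches the bounds) are dropped with a flag rather than an error; genuine
#' collinearity among non-constant predictors is an error naming the
#' offending columns. The Gaussian negative log-likelihood (with the ML
#' residual variance) is returned so that nested predictor sets can be
#' compared with [likelihood_ratio_compare()].
#'
#' @param table An `urn_update_table`.
#' @param predictors Subset of `c("delta_b", "rpe", "outcome", "edge")`.
#' @return A list of class `urn_reg_fit`: `coefficients` (named, including
#'   intercept), `neg_ll`, `r_squared`, `sigma`, `n`, `dropped` (constant
#'   columns removed) and `degenerate` (TRUE when the response has no
#'   variance).
#' @export
fit_participant <- function(table, predictors = c("delta_b", "rpe", "edge")) {
  allowed <- c("delta_b", "rpe", "outcome", "edge")
  if (!length(predictors) || !all(predictors %in% allowed))
    stop("`predictors` must be a non-empty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  if (nrow(table) < 10)
    stop("need at least 10 prompted trials to fit a participant",
         call. = FALSE)

  X <- table[, predictors, drop = FALSE]
  constant <- vapply(X, function(x) stats::sd(x) == 0, logical(1))
  dropped <- predictors[constant]
  use <- predictors[!constant]
  degenerate <- stats::sd(table$dibu) == 0

  if (!length(use)) {
    fit <- stats::lm(dibu ~ 1, data = table)
  } else {
    fit <- stats::lm(stats::reformulate(use, response = "dibu"), data = table)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("collinear design: could not estimate ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  res <- stats::residuals(fit)
  n <- length(res)
  sigma <- sqrt(mean(res^2))
  neg_ll <- if (sigma == 0) -Inf else
    n / 2 * (log(2 * pi * sigma^2) + 1)
  coefs <- stats::coef(fit)
  # dropped columns are reported with coefficient 0 so cohorts stay aligned
  for (d in dropped) coefs[d] <- 0
  structure(list(coefficients = coefs, neg_ll = neg_ll,
                 r_squared = if (degenerate) NA_real_ else
                   suppressWarnings(summary(fit)$r.squared),
                 sigma = sigma, n = n, dropped = dropped,
                 degenerate = degenerate),
            class = "urn_reg_fit")
}

#' @export
print.urn_reg_fit <- function(x, ...) {
  cat("<urn_reg_fit> n =", x$n, " -LL =", format(x$neg_ll, digits = 4), "\n")
  print(round(x$coefficients, 4))
  if (length(x$dropped))
    cat("  dropped constant predictors:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Group-level test of within-participant regression weights
#'
#' One-sample two-sided t test of a predictor's per-participant coefficients
#' against zero (df = n - 1). When all coefficients are identical and
#' nonzero the t statistic is infinite; this is returned with a flag rather
#' than an error.
#'
#' @param fits A list of `urn_reg_fit` objects (one per participant).
#' @param predictor Name of the coefficient to test.
#' @return A list: `t`, `df`, `p`, `mean`, `n` and `zero_variance` flag.
#' @export
group_test <- function(fits, predictor) {
  w <- vapply(fits, function(f) {
    if (!predictor %in% names(f$coefficients))
      stop("predictor '", predictor, "' absent from a participant fit",
           call. = FALSE)
    unname(f$coefficients[predictor])
  }, numeric(1))
  if (length(w) < 2) stop("need at least 2 participants", call. = FALSE)
  if (stats::sd(w) == 0) {
    m <- mean(w)
    return(list(t = if (m == 0) 0 else sign(m) * Inf, df = length(w) - 1L,
                p = if (m == 0) 1 else 0, mean = m, n = length(w),
                zero_variance = TRUE))
  }
  tt <- stats::t.test(w, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = mean(w), n = length(w), zero_variance = FALSE)
}

#' Congruency contrast of information-direction updates
#'
#' For each participant, informative prompted trials are split by congruency
#' (payout sign matching vs opposing the conveyed long-term valence) and the
#' observed update is projected onto the information direction
#' (`dibu_raw * info_dir`, so positive = update toward the evidence). The
#' per-participant means are compared with a paired t test. An ideal
#' Bayesian updater shows a contrast of ~0 (congruent and incongruent events
#' carry the same likelihood ratio); reward-biased updaters show
#' congruent > incongruent.
#'
#' @param tables List of `urn_update_table`s, one per participant.
#' @return A list: `t`, `df`, `p`, `mean_congruent`, `mean_incongruent`,
#'   `contrast` (congruent - incongruent), `n` (participants used) and
#'   `dropped` (participants missing one of the classes).
#' @export
congruency_contrast <- function(tables) {
  per <- lapply(tables, function(tb) {
    tb <- tb[tb$informative, , drop = FALSE]
    con <- tb$dibu_raw[tb$congruency == "congruent"] *
      tb$info_dir[tb$congruency == "congruent"]
    inc <- tb$dibu_raw[tb$congruency == "incongruent"] *
      tb$info_dir[tb$congruency == "incongruent"]
    if (!length(con) || !length(inc)) return(NULL)
    c(congruent = mean(con), incongruent = mean(inc))
  })
  dropped <- which(vapply(per, is.null, logical(1)))
  if (length(dropped))
    warning("dropping participants without both congruency classes: ",
            paste(dropped, collapse = ", "))
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) < 2)
    stop("need at least 2 participants with both classes", call. = FALSE)
  m <- do.call(rbind, per)
  d <- m[, "congruent"] - m[, "incongruent"]
  if (stats::sd(d) == 0) {
    tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
               parameter = length(d) - 1L,
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(m[, "congruent"], m[, "incongruent"], paired = TRUE)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_congruent = mean(m[, "congruent"]),
       mean_incongruent = mean(m[, "incongruent"]),
       contrast = mean(d), n = length(d), dropped = dropped)
}

#' Per-trial Bayesianness of an observed update
#'
#' Similarity of the reported update to the ideal Bayesian update,
#' \eqn{Bayesianness_t = 1 - |\Delta B_t - \Delta IBU_t|}: 1 means exact
#' Bayesian updating, smaller values increasing deviation. Returned
#' unclipped.
#'
#' @param delta_b Ideal Bayesian signed update(s).
#' @param dibu Observed signed update(s) on the same \[0, 1\] belief scale.
#' @return Numeric score(s).
#' @export
bayesianness <- function(delta_b, dibu) 1 - abs(delta_b - dibu)
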