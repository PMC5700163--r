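#' Log-distance objective between reported beliefs and model expectation
#'
#' The maximum-likelihood objective for the learning-rate fit:
#' \deqn{LD = \sum_t \log(1 - |B_{subj,t} - B_{EV,t}|)}
#' where `B_subj` are the reported beliefs on \[0, 1\] and `B_EV` the
#' learner's expected value mapped onto the belief scale. EV lives on the
#' scaled-payout scale \[-1, 1\]; by default it is mapped through
#' \eqn{(EV+1)/2} so that both series are commensurable and the log argument
#' stays positive (`map_ev = FALSE` gives the raw difference for sensitivity
#' analysis). Each term is \eqn{\le 0}, so larger (closer to zero) LD means a
#' better fit; absolute differences of 1 are clipped at `1 - 1e-12`.
#'
#' @param beliefs Reported beliefs in \[0, 1\], one per prompted trial.
#' @param ev Expected values in \[-1, 1\], aligned with `beliefs`.
#' @param map_ev Map EV onto the belief scale via (EV+1)/2 (default TRUE).
#' @return The summed log distance (a scalar \eqn{\le 0}).
#' @export
log_distance <- function(beliefs, ev, map_ev = TRUE) {
  if (length(beliefs) != length(ev))
    stop("`beliefs` and `ev` must be aligned series of equal length",
         call. = FALSE)
  b_ev <- if (map_ev) (ev + 1) / 2 else ev
  d <- pmin(abs(beliefs - b_ev), 1 - 1e-12)
  sum(log(1 - d))
}

#' Fit the Rescorla-Wagner learning rate to reported beliefs
#'
#' Maximum-likelihood estimation of the single free parameter \eqn{\alpha}:
#' for a candidate learning rate the delta-rule learner is run over the
#' session, its post-outcome expected value for the chosen urn is mapped onto
#' the belief scale, and the [log_distance()] to the prompted beliefs is
#' computed over prompted trials. The optimum is located by a coarse grid
#' (51 points over \[0, 1\], guarding against local optima) followed by
#' bounded scalar refinement around the best grid cell.
#'
#' @param session An `urn_session` with at least one prompted trial.
#' @param map_ev Passed to [log_distance()].
#' @param per_urn,reset_blocks Passed to [run_rl_trace()].
#' @param n_grid Number of coarse grid points (default 51).
#' @return A list of class `urn_alpha_fit`: `alpha` (the estimate), `ld`
#'   (objective at the optimum), `convergence` (logical), `flat` (TRUE when
#'   the objective does not discriminate between learning rates, in which
#'   case `alpha` is reported as 0.5), `n` (number of prompted trials) and
#'   `beliefs` (the B_subj series used).
#' @export
fit_learning_rate <- function(session, map_ev = TRUE, per_urn = TRUE,
                              reset_blocks = TRUE, n_grid = 51L) {
  validate_session(session)
  prompted <- which(session$trials$prompted)
  if (!length(prompted))
    stop("cannot fit: session has no prompted trials", call. = FALSE)
  beliefs <- session$trials$belief_prompt[prompted] / 100

  objective <- function(alpha) {
    trace <- run_rl_trace(session, alpha, per_urn = per_urn,
                          reset_blocks = reset_blocks)
    log_distance(beliefs, trace$ev_post[prompted], map_ev = map_ev)
  }

  grid <- seq(0, 1, length.out = n_grid)
  ld_grid <- vapply(grid, objective, numeric(1))

  if (max(ld_grid) - min(ld_grid) < 1e-10) {
    return(structure(list(alpha = 0.5, ld = ld_grid[1], convergence = TRUE,
                          flat = TRUE, n = length(prompted),
                          beliefs = beliefs),
                     class = "urn_alpha_fit"))
  }

  best <- which.max(ld_grid)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(n_grid, best + 1L)]
  opt <- stats::optimize(objective, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-6)
  # keep whichever of grid-best and refined point scores higher
  if (opt$objective >= ld_grid[best]) {
    alpha <- opt$maximum; ld <- opt$objective
  } else {
    alpha <- grid[best]; ld <- ld_grid[best]
  }
  structure(list(alpha = alpha, ld = ld, convergence = TRUE, flat = FALSE,
                 n = length(prompted), beliefs = beliefs),
            class = "urn_alpha_fit")
}

#' @export
print.urn_alpha_fit <- function(x, ...) {
  cat(sprintf("<urn_alpha_fit> alpha = %.4f, LD = %.3f over %d prompted trials%s\n",
              x$alpha, x$ld, x$n, if (x$flat) " (flat objective)" else ""))
  invisible(x)
}

#' Likelihood-ratio test between two nested models
#'
#' Compares nested models by their summed negative log-likelihoods: the
#' statistic is \eqn{2(−LL_a − (−LL_b))} for a null model `a` nested in an
#' alternative `b`, referred to a chi-squared distribution with `df_diff`
#' degrees of freedom.
#'
#' @param negll_null Summed -LL of the restricted (null) model.
#' @param negll_alt Summed -LL of the richer model.
#' @param df_diff Difference in free parameters (>= 1).
#' @return A list: `statistic`, `df`, `p`, `preferred` ("null"/"alt") and
#'   `negative_statistic` flag (TRUE when the richer model fit worse,
#'   indicating misuse on non-nested models; the statistic is then reported
#'   as is and p set to 1).
#' @export
likelihood_ratio_compare <- function(negll_null, negll_alt, df_diff) {
  if (df_diff < 1) stop("`df_diff` must be >= 1 for nested models", call. = FALSE)
  stat <- 2 * (negll_null - negll_alt)
  neg <- stat < 0
  if (neg) warning("negative LR statistic: models may not be nested")
  p <- if (neg) 1 else stats::pchisq(stat, df = df_diff, lower.tail = FALSE)
  list(statistic = stat, df = df_diff, p = p,
       preferred = if (!neg && p < 0.05) "alt" else "null",
       negative_statistic = neg)
}
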