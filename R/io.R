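#' Write a session log to CSV + JSON sidecar
#'
#' The trial table goes to `<path>.csv` (UTF-8, header
#' `block,trial,chosen_urn,event_class,event,payout,prompted,belief_prompt`,
#' '.' decimal, no index column) and everything nested — configuration,
#' block specifications, gambles, totals and a run manifest (package version,
#' seeds, flags) — to `<path>.json`. The round trip through
#' [read_session()] is lossless.
#'
#' @param session An `urn_session`.
#' @param path Output stem (without extension).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  utils::write.csv(session$trials, paste0(path, ".csv"), row.names = FALSE)
  sidecar <- list(
    config = unclass(session$config),
    blocks = lapply(session$blocks, function(b)
      list(block = b$block, variant = b$variant, truth = as.list(b$truth),
           classes = b$classes)),
    gambles = session$gambles,
    totals = session$totals,
    discretize = session$discretize,
    manifest = list(package = "twourn",
                    version = as.character(utils::packageVersion("twourn")),
                    rng_seed = session$config$rng_seed,
                    mode = session$config$mode)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session log written by [write_session()]
#'
#' Schema violations (missing columns, prompts inconsistent with the
#' `prompted` flag, prompts off the 10-step grid of a discretized session)
#' are reported with row numbers; a sidecar whose gamble table does not
#' cover every block/urn is rejected listing the missing block indices.
#'
#' @param path Stem used in [write_session()].
#' @return An `urn_session`.
#' @export
read_session <- function(path) {
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  if (!file.exists(csv) || !file.exists(json))
    stop("expected both ", csv, " and ", json, call. = FALSE)
  trials <- utils::read.csv(csv, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(json, simplifyVector = TRUE)

  trials$belief_prompt <- as.numeric(trials$belief_prompt)
  trials$prompted <- as.logical(trials$prompted)

  cfg_fields <- side$config
  if (length(cfg_fields$both_good_block) == 0) cfg_fields["both_good_block"] <- list(NULL)
  config <- task_config(
    n_blocks = cfg_fields$n_blocks,
    trials_per_block = cfg_fields$trials_per_block,
    mode = cfg_fields$mode,
    prompt_every = cfg_fields$prompt_every,
    marker_reset = cfg_fields$marker_reset,
    bonus_points = cfg_fields$bonus_points,
    cents_per_point = cfg_fields$cents_per_point,
    both_good_block = cfg_fields$both_good_block,
    shared_schedule = cfg_fields$shared_schedule,
    rng_seed = cfg_fields$rng_seed)

  blocks <- lapply(seq_len(nrow(side$blocks)), function(i) {
    b <- side$blocks[i, ]
    list(block = b$block, variant = b$variant,
         truth = c(blue = b$truth$blue, yellow = b$truth$yellow),
         classes = unlist(b$classes))
  })
  gambles <- side$gambles
  missing_blocks <- setdiff(seq_len(config$n_blocks), unique(gambles$block))
  if (length(missing_blocks))
    stop("sidecar gamble table missing blocks: ",
         paste(missing_blocks, collapse = ", "), call. = FALSE)
  urn_session(config, blocks, trials, gambles,
              discretize = isTRUE(side$discretize))
}

#' Summary figures for simulated or analyzed runs
#'
#' Three report plots in the style of the behavioural figures:
#' mean observed update (in the information direction) by event class,
#' the decorrelation scatter of the Bayesian update against the normalized
#' RPE, and a parameter-recovery scatter.
#'
#' @param tables List of `urn_update_table`s (one per participant).
#' @return A ggplot object.
#' @export
plot_update_by_class <- function(tables) {
  df <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    dir_update <- ifelse(tb$info_dir == 0, tb$dibu_raw,
                         tb$dibu_raw * tb$info_dir)
    cls <- ifelse(tb$informative, tb$congruency,
                  paste0("noninf-", ifelse(tb$outcome_raw > 0, "positive",
                                           ifelse(tb$outcome_raw < 0,
                                                  "negative", "zero"))))
    stats::aggregate(dir_update, by = list(class = cls), FUN = mean) |>
      transform(participant = i)
  }))
  agg <- stats::aggregate(df$x, by = list(class = df$class),
                          FUN = function(v) c(mean = mean(v),
                                              se = stats::sd(v) / sqrt(length(v))))
  agg <- data.frame(class = agg$class, mean = agg$x[, "mean"],
                    se = agg$x[, "se"])
  ggplot2::ggplot(agg, ggplot2::aes(x = class, y = mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - se, ymax = mean + se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean update (information direction)",
                  title = "Belief update by event class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname plot_update_by_class
#' @param table A single `urn_update_table`.
#' @export
plot_predictor_correlation <- function(table) {
  r <- stats::cor(table$delta_b, table$rpe)
  ggplot2::ggplot(table, ggplot2::aes(x = rpe, y = delta_b)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "firebrick") +
    ggplot2::labs(x = "normalized RPE", y = "Bayesian update",
                  title = sprintf("Predictor decorrelation (r = %.2f)", r)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_update_by_class
#' @param recovery An `urn_recovery` from [recovery_experiment()].
#' @param param "alpha" or "w_rpe".
#' @export
plot_recovery <- function(recovery, param = c("alpha", "w_rpe")) {
  param <- match.arg(param)
  df <- recovery$per_agent
  x <- df[[paste0("true_", param)]]
  y <- df[[paste0(param, "_hat")]]
  ggplot2::ggplot(data.frame(true = x, recovered = y),
                  ggplot2::aes(x = true, y = recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_jitter(width = diff(range(x)) / 60, alpha = 0.6) +
    ggplot2::labs(title = sprintf("Recovery of %s", param)) +
    ggplot2::theme_minimal()
}
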