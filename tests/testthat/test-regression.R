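make_traces <- function(session, mode = "normative", alpha = 0.06) {
  list(bayes = run_bayesian_trace(session, mode),
       rl = run_rl_trace(session, alpha))
}

test_that("update table arithmetic, edge coding and row selection", {
  prompts <- rep(NA_real_, 20); prompts[c(1, 2, 5)] <- c(50, 70, 100)
  s <- toy_session(rep(7L, 20), prompts = prompts)
  tr <- make_traces(s)
  tab <- build_update_table(s, tr$bayes, tr$rl)
  expect_equal(nrow(tab), 3)                    # rows only for prompted trials
  # prior prompt 50 -> posterior prompt 70 is a raw update of +0.2
  expect_equal(tab$prior_prompt[2], 50)
  expect_equal(tab$dibu_raw[2], 0.2, tolerance = 1e-12)
  # block start anchors the prior at 50
  expect_equal(tab$prior_prompt[1], 50)
  # edge is the predicted direction gated on an extreme prior prompt
  expect_equal(tab$edge, c(0, 0, 0))
  prompts2 <- rep(NA_real_, 20); prompts2[1:3] <- c(100, 100, 90)
  s2 <- toy_session(rep(7L, 20), prompts = prompts2)
  tr2 <- make_traces(s2)
  tab2 <- build_update_table(s2, tr2$bayes, tr2$rl)
  expect_equal(tab2$edge, c(0, 1, 1))           # prior at 100, positive dB
  # congruency classes follow the event table
  expect_true(all(tab$congruency == "congruent"))
  expect_error(build_update_table(toy_session(rep(4L, 20)), tr$bayes, tr$rl),
               "no prompted")
})

test_that("replication-style prompting yields rows only every third trial", {
  prompts <- rep(NA_real_, 20); prompts[seq(3, 18, by = 3)] <- 60
  s <- toy_session(rep(7L, 20), prompts = prompts)
  tr <- make_traces(s)
  tab <- build_update_table(s, tr$bayes, tr$rl)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$trial, seq(3, 18, by = 3))
})

test_that("noiseless ideal-Bayesian agent regresses onto its own updates", {
  cfg <- fast_config()
  ideal <- agent_params(w_bayes = 1, w_rpe = 0, noise_sd = 0,
                        discretize = FALSE, seed = 21)
  s <- simulate_agent_session(cfg, ideal)
  tr <- make_traces(s)
  tab <- build_update_table(s, tr$bayes, tr$rl)
  fit <- fit_participant(tab, predictors = c("delta_b", "edge"))
  expect_equal(unname(fit$coefficients["delta_b"]), 1, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  expect_true("edge" %in% fit$dropped)          # never at the bounds
  # adding RPE explains nothing extra
  fit2 <- fit_participant(tab, predictors = c("delta_b", "rpe", "edge"))
  expect_equal(unname(fit2$coefficients["rpe"]), 0, tolerance = 1e-8)
  # Bayesianness is exactly 1 on every trial
  expect_equal(bayesianness(tab$delta_b_raw, tab$dibu_raw), rep(1, nrow(tab)),
               tolerance = 1e-12)
})

test_that("degenerate and invalid designs are reported", {
  prompts <- rep(50, 20)
  s <- toy_session(rep(c(7L, 1L), 10), prompts = prompts)
  tr <- make_traces(s)
  tab <- build_update_table(s, tr$bayes, tr$rl)
  fit <- fit_participant(tab, predictors = c("delta_b", "rpe"))
  expect_true(fit$degenerate)                   # constant update column
  expect_error(fit_participant(tab, predictors = "payout"), "subset")
  expect_error(fit_participant(tab[1:5, ], predictors = "delta_b"),
               "at least 10")
  # duplicated predictor column is genuine collinearity
  tab2 <- tab
  tab2$dibu <- tab2$delta_b
  tab2$rpe <- tab2$delta_b
  expect_error(fit_participant(tab2, predictors = c("delta_b", "rpe")),
               "collinear")
})

test_that("group tests behave at the limits and on real cohorts", {
  fake_fit <- function(w) structure(list(coefficients = c(delta_b = w)),
                                    class = "urn_reg_fit")
  res <- group_test(lapply(rep(0.4, 24), fake_fit), "delta_b")
  expect_true(res$zero_variance)
  expect_equal(res$t, Inf)
  expect_equal(res$p, 0)
  sym <- group_test(lapply(c(-0.2, 0.2, -0.1, 0.1), fake_fit), "delta_b")
  expect_equal(sym$t, 0, tolerance = 1e-12)
  expect_error(group_test(list(fake_fit(1)), "delta_b"), "at least 2")
  expect_error(group_test(lapply(1:3, fake_fit), "rpe"), "absent")
})

test_that("congruency contrast separates biased from ideal updaters", {
  cfg <- fast_config()
  tables_for <- function(params, n = 8) {
    cohort <- simulate_cohort(n, cfg, params, seed = 77)
    lapply(cohort$sessions, function(s) {
      tr <- make_traces(s, mode = "subjective", alpha = params$alpha)
      build_update_table(s, tr$bayes, tr$rl)
    })
  }
  ideal <- tables_for(agent_params(w_bayes = 1, w_rpe = 0, noise_sd = 0,
                                   discretize = FALSE))
  res_ideal <- congruency_contrast(ideal)
  # ideal Bayes updates equally on congruent and incongruent information
  expect_lt(abs(res_ideal$contrast), 0.02)
  biased <- tables_for(agent_params(w_rpe = 0.3))
  res_biased <- congruency_contrast(biased)
  expect_gt(res_biased$contrast, res_ideal$contrast)
  expect_gt(res_biased$contrast, 0)
  # non-informative trials never enter the contrast
  one <- ideal[[1]]
  expect_false(any(one$info_dir[!one$informative] != 0))
})

test_that("bayesianness scores reported updates against the ideal", {
  expect_equal(bayesianness(0.3, 0.3), 1)
  expect_equal(bayesianness(0.2143, 0), 0.7857, tolerance = 1e-12)
  expect_equal(bayesianness(0.2, -0.2), 0.6)
  expect_lt(bayesianness(0.9, -0.9), 0)          # unclipped
})
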