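test_that("event tables carry the correct probabilities, payouts and flags", {
  for (v in 1:4) {
    ev <- urn_events(v)
    expect_equal(ev$p_good, c(.10, .25, .10, .10, .10, .10, .25))
    expect_equal(ev$p_bad,  c(.25, .10, .10, .10, .10, .25, .10))
    expect_equal(sum(ev$p_good), 1)
    expect_equal(sum(ev$p_bad), 1)
    # informative iff unequal probabilities; congruent iff payout sign
    # matches the indicated valence
    expect_equal(ev$informative, ev$p_good != ev$p_bad)
    inf <- ev[ev$informative, ]
    expect_equal(inf$congruent,
                 sign(inf$payout) == ifelse(inf$long_indication == "good", 1, -1))
    expect_true(all(ev$p_good[!ev$informative] == ev$p_bad[!ev$informative]))
    # non-informative mass 30%, zero-payout mass 10%
    expect_equal(sum(ev$p_good[!ev$informative]), 0.30)
    expect_equal(sum(ev$p_good[ev$payout == 0]), 0.10)
  }
  expect_equal(urn_events(1)$payout, c(-50, -40, -30, 0, 30, 40, 50))
  expect_equal(urn_events(2)$payout, c(-50, -40, -60, 0, 60, 40, 50))
  expect_error(urn_events(5), "variant")
})

test_that("expected value is +/-1.5 points per trial in every variant", {
  for (v in 1:4) {
    ev <- urn_events(v)
    expect_equal(expected_value(ev, "good"), 1.5)
    expect_equal(expected_value(ev, "bad"), -1.5)
  }
  ev0 <- urn_events(1)
  ev0$payout <- 0
  expect_equal(expected_value(ev0, "good"), 0)
})

test_that("likelihood ratios are 2.5 / 0.4 / 1 and guard against p_bad = 0", {
  ev <- urn_events(3)
  expect_equal(likelihood_ratio(ev[7, ]), 2.5)   # congruent informative
  expect_equal(likelihood_ratio(ev[6, ]), 0.4)   # +40-style incongruent
  expect_equal(likelihood_ratio(ev[4, ]), 1)
  bad <- ev[1, ]; bad$p_bad <- 0
  expect_error(likelihood_ratio(bad), "undefined")
})

test_that("schedules have exact class counts, block structure and determinism", {
  cfg <- fast_config()
  sch <- generate_schedule(cfg, seed = 11)
  expect_length(sch, 12)
  for (b in sch) {
    counts <- table(b$classes)
    expect_equal(as.integer(counts[c("likely-congruent", "likely-incongruent",
                                     "unlikely-congruent",
                                     "unlikely-incongruent",
                                     "noninf-negative", "noninf-zero",
                                     "noninf-positive")]),
                 c(5L, 5L, 2L, 2L, 2L, 2L, 2L))
  }
  truths <- vapply(sch, function(b) paste(sort(b$truth), collapse = "-"),
                   character(1))
  expect_equal(truths[3], "bad-bad")
  expect_equal(sum(truths == "bad-bad"), 1L)
  expect_equal(sum(truths == "good-good"), 1L)
  expect_gte(which(truths == "good-good"), 4L)
  expect_equal(sum(truths == "bad-good"), 10L)
  # variants rotate round-robin over 1..4
  variants <- vapply(sch, `[[`, integer(1), "variant")
  expect_equal(sort(unique(diff(variants) %% 4)), 1)
  # determinism
  expect_identical(sch, generate_schedule(cfg, seed = 11))
  expect_equal(12 * 20, sum(lengths(lapply(sch, `[[`, "classes"))))
  expect_error(task_config(trials_per_block = 30), "integer")
})

test_that("realized payouts depend on the chosen urn's truth", {
  blk <- list(block = 1, variant = 1,
              truth = c(blue = "good", yellow = "bad"),
              classes = c("likely-congruent", "unlikely-incongruent",
                          "noninf-zero", rep("noninf-positive", 17)))
  expect_equal(realize_trial(blk, 1, "blue")$payout, 50)    # good, congruent
  expect_equal(realize_trial(blk, 1, "yellow")$payout, -50) # mirror case
  # unlikely events indicate the opposite of the truth
  expect_equal(realize_trial(blk, 2, "blue")$payout, 40)    # indicates bad
  expect_equal(urn_events(1)$long_indication[realize_trial(blk, 2, "blue")$event],
               "bad")
  expect_equal(realize_trial(blk, 3, "blue")$payout, 0)
  expect_equal(realize_trial(blk, 3, "yellow")$payout, 0)
})

test_that("scheduled event frequencies match the table probabilities", {
  # fixed-urn observer over many blocks: empirical frequencies of events
  # drawn from good urns must match p_good (chi-squared GOF not rejected)
  cfg <- task_config(n_blocks = 500, trials_per_block = 20, rng_seed = 5)
  sch <- generate_schedule(cfg)
  counts <- integer(7)
  for (b in sch) {
    if (b$truth[["blue"]] != "good") next
    for (t in seq_along(b$classes)) {
      out <- realize_trial(b, t, "blue")
      counts[out$event] <- counts[out$event] + 1L
    }
  }
  # blue is good in roughly half of the 500 blocks
  expect_gte(sum(counts), 4000)
  gof <- suppressWarnings(
    stats::chisq.test(counts, p = urn_events(1)$p_good))
  expect_gt(gof$p.value, 0.01)
})

test_that("session scoring sums payouts, bonuses and converts to euros", {
  s <- toy_session(rep(7L, 20))               # all +50 draws
  s$gambles$response <- c("good", "bad")      # both correct
  tot <- score_session(s)
  expect_equal(tot$points, 20 * 50 + 10)
  expect_equal(tot$euros, (20 * 50 + 10) * 0.03)
  # 30 points -> 0.9 EUR at 3 cents per point
  expect_equal(30 * s$config$cents_per_point / 100, 0.9)
  s$gambles$response <- "abstain"
  expect_equal(score_session(s)$points_bonus, 0)
  s$gambles$response <- c("bad", "good")      # both wrong
  expect_equal(score_session(s)$points_bonus, -10)
  s2 <- s; s2$trials <- s2$trials[-1, ]
  expect_error(score_session(s2), "incomplete")
})
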