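# the eight experienced profitabilities from the worked example,
# padded with NA for the thirteen unexplored machines
worked_example <- c(0.024, 0.050, 0.070, 0.001, 0.003, 0.030, 0.082, 0.010,
                    rep(NA_real_, 13))

test_that("unplayed games inherit the mean experienced profitability", {
  pv <- profitability_vector(worked_example)
  expect_equal(sum(pv[1:8]), 0.270)
  expect_equal(unname(pv[9:21]), rep(0.03375, 13))

  one <- profitability_vector(c(0.06, rep(NA, 20)))
  expect_equal(unname(one), rep(0.06, 21))

  two <- profitability_vector(c(0.02, 0.04, rep(NA, 19)))
  expect_equal(unname(two[3:21]), rep(0.03, 19))

  none <- profitability_vector(rep(NA_real_, 21))
  expect_true(isTRUE(attr(none, "all_tie")))
})

test_that("tie-averaged ranking reproduces the worked example", {
  ranks <- rank_with_ties(profitability_vector(worked_example))
  expect_equal(ranks[7], 1)   # 0.082
  expect_equal(ranks[3], 2)   # 0.070
  expect_equal(ranks[2], 3)   # 0.050
  expect_equal(unname(ranks[9:21]), rep(10, 13))  # tie over ranks 4..16
  expect_equal(ranks[6], 17)  # 0.030
  expect_equal(ranks[1], 18)  # 0.024
  expect_equal(ranks[8], 19)  # 0.010
  expect_equal(ranks[5], 20)  # 0.003
  expect_equal(ranks[4], 21)  # 0.001
})

test_that("tie handling matches the printed conventions", {
  expect_equal(rank_with_ties(rep(0.06, 21)), rep(11, 21))
  # two equal values occupying positions 12 and 13 both get 12.5
  vals <- c(seq(1, 0.58, length.out = 11), 0.5, 0.5, seq(0.4, 0.1, length.out = 8))
  expect_equal(rank_with_ties(vals)[12:13], c(12.5, 12.5))
  expect_error(rank_with_ties(c(1, NA, 3)), "finite")
})

test_that("rank sums are conserved for arbitrary tie patterns", {
  set.seed(402)
  for (i in 1:25) {
    x <- sample(round(runif(21, 0, 0.1), sample(1:3, 1)), 21, replace = TRUE)
    r <- rank_with_ties(x)
    expect_equal(sum(r), 231)
    expect_true(all(tapply(r, x, function(v) length(unique(v))) == 1))
  }
})

test_that("sum normalization behaves as the rejected variant should", {
  shares <- sum_normalize(rep(0.06, 21))
  expect_equal(shares, rep(0.06 / 1.26, 21))
  expect_lt(abs(shares[1] - 0.047), 1e-3)
  expect_equal(sum(shares), 1, tolerance = 1e-12)
  expect_equal(sum_normalize(c(1, rep(0, 20)))[1], 1)
  set.seed(7)
  x <- runif(21)
  expect_equal(sum(sum_normalize(x)), 1, tolerance = 1e-12)
  expect_error(sum_normalize(rep(0, 21)), "sum to 0")
})

test_that("decision value is the documented affine rank map", {
  expect_equal(decision_value(1), 100)
  expect_equal(decision_value(21), 0)
  expect_equal(decision_value(11), 50)
  expect_equal(decision_value(12.5), 42.5)
  expect_error(decision_value(0.5), "rank")
})

test_that("experienced profitability is cumulative, pre-t, and per second", {
  log <- toy_log(list("corsi_basic", 0, 500, 30))
  expect_equal(observed_profitability(log, "corsi_basic", 600), 0.06)
  expect_equal(observed_profitability(log, "stroop_color", 600), NA_real_)
  # uniform within-segment interpolation: half the segment, half the tickets
  expect_equal(observed_profitability(log, "corsi_basic", 250), 0.06)
  zero <- toy_log(list("gonogo_fast", 0, 100, 0))
  expect_equal(observed_profitability(zero, "gonogo_fast", 100), 0)
  expect_error(observed_profitability(log, "no_such_game", 10,
                                      catalog = default_catalog()), "unknown game_id")
  expect_error(observed_profitability(log, "corsi_basic", 1801), "t must lie")
})

test_that("uninformative sessions score exactly 50", {
  one_game <- toy_log(list("corsi_basic", 0, 1800, 120))
  expect_equal(dmx_score(one_game)$dmx_score, 50)
  expect_equal(dmx_score(one_game, "sum")$dmx_score, 50)
  expect_equal(dmx_score(toy_log())$dmx_score, 50)
})

test_that("the engine matches the brute-force oracle on the two-game script", {
  cat <- default_catalog()
  ab <- toy_log(list("corsi_basic", 0, 600, 60),      # 0.10 tickets/s
                list("stroop_color", 600, 1800, 12))  # 0.01 tickets/s
  ba <- toy_log(list("stroop_color", 0, 1200, 12),
                list("corsi_basic", 1200, 1800, 60))
  r_ab <- dmx_score(ab, catalog = cat)
  r_ba <- dmx_score(ba, catalog = cat)
  expect_equal(r_ab$dmx_score, oracle_dmx(ab, cat), tolerance = 1e-9)
  expect_equal(r_ba$dmx_score, oracle_dmx(ba, cat), tolerance = 1e-9)
  # staying with the discovered-better game scores strictly higher
  expect_gt(r_ba$dmx_score, r_ab$dmx_score)
})

test_that("engine equals the exhaustive oracle on random toy sessions", {
  cat <- default_catalog()
  set.seed(911)
  for (i in 1:12) {
    log <- random_toy_log(cat, duration_s = 60)
    expect_equal(dmx_score(log, catalog = cat)$decision_values,
                 oracle_dmx_values(log, cat))
  }
})

test_that("timeline invariants hold on simulated sessions", {
  cat <- default_catalog()
  log <- simulate_session(cat, agent_policy("explore_then_exploit",
                                            choice_accuracy = 0.6), seed = 31)
  log <- clean_session_log(log)$log
  tl <- dmx_timeline(log, cat)
  expect_equal(unname(rowSums(tl$ranks)), rep(231, 1800))
  expect_true(all(tl$values >= 0 & tl$values <= 100))
  res <- dmx_score(log, catalog = cat)
  expect_gte(res$dmx_score, 0)
  expect_lte(res$dmx_score, 100)
  expect_equal(length(res$decision_values), 1800L)
})

test_that("rank-variant scores are invariant to rescaling all tickets", {
  cat <- default_catalog()
  log <- simulate_session(cat, agent_policy("uniform_random_switcher"), seed = 77)
  log <- clean_session_log(log)$log
  scaled <- log
  scaled$segments$tickets <- scaled$segments$tickets * 3.7
  expect_equal(dmx_score(scaled, catalog = cat)$dmx_score,
               dmx_score(log, catalog = cat)$dmx_score)
})

test_that("discovering and exploiting the best game scores at least 50", {
  # sample three games, learn that the first is best, return and stay
  log <- toy_log(list("corsi_basic", 0, 120, 60),
                 list("stroop_color", 125, 245, 12),
                 list("gonogo_fast", 250, 370, 6),
                 list("corsi_basic", 375, 1800, 700))
  expect_gte(dmx_score(log)$dmx_score, 50)
})

test_that("uncleaned over-budget logs are rejected", {
  log <- toy_log(list("corsi_basic", 0, 1900, 100))
  expect_error(dmx_score(log), "clean_session_log")
})
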