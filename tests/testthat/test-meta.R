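test_that("Fisher z transform matches the printed per-study effects", {
  # z-scale effect sizes printed for the Tickets-DMX pair
  expect_lt(abs(fisher_z(0.593) - 0.682), 1e-3)
  expect_lt(abs(fisher_z(0.686) - 0.841), 1e-3)
  expect_equal(fisher_z(0), 0)
  # printed standard errors arise from 1/sqrt(n - 3)
  expect_lt(abs(se_fisher(60) - 0.132), 1e-3)
  expect_lt(abs(se_fisher(76) - 0.117), 1e-3)
  expect_error(fisher_z(1), "< 1")
  expect_error(se_fisher(3), ">= 4")
})

test_that("Fisher z round-trips within 1e-12", {
  r <- c(-0.95, -0.5, 0, 0.123, 0.593, 0.686, 0.99)
  expect_equal(inv_fisher_z(fisher_z(r)), r, tolerance = 1e-12)
})

test_that("fixed-effect pooling reproduces the published pooled effects", {
  tickets_dmx <- pool_fixed(list(
    effect_size("s1", "fisher_z", r = 0.593, n = 60),
    effect_size("s2", "fisher_z", r = 0.686, n = 76)
  ))
  expect_lt(abs(tickets_dmx$pooled_estimate - 0.771), 5e-4)
  expect_lt(abs(tickets_dmx$ci_low - 0.599), 5e-4)
  expect_lt(abs(tickets_dmx$ci_high - 0.943), 5e-4)

  # the published means row is heterogeneous: fixed-effect arithmetic
  # gives 1462.01, while the printed 1462.1 (and its CI) is the
  # DerSimonian-Laird random-effects answer
  fe_mean <- pool_fixed(list(
    effect_size("s1", "mean", estimate = 1508.7, se = 63.2),
    effect_size("s2", "mean", estimate = 1418.8, se = 60.8)
  ))
  expect_lt(abs(fe_mean$pooled_estimate - 1462.1), 0.15)
  dl_mean <- pool_effects(list(
    effect_size("s1", "mean", estimate = 1508.7, se = 63.2),
    effect_size("s2", "mean", estimate = 1418.8, se = 60.8)
  ), method = "dl")
  expect_lt(abs(dl_mean$pooled_estimate - 1462.1), 0.05)
  expect_gt(dl_mean$tau2, 0)
})

test_that("pooling identities and invariances hold", {
  e <- function(x, s) effect_size("s", "mean", estimate = x, se = s)
  # two identical effects pool to themselves with se/sqrt(2)
  same <- pool_fixed(list(e(3.2, 0.4), e(3.2, 0.4)))
  expect_equal(same$pooled_estimate, 3.2)
  expect_equal(same$pooled_se, 0.4 / sqrt(2))
  # order invariance
  a <- pool_fixed(list(e(1, 0.2), e(2, 0.5), e(1.4, 0.3)))
  b <- pool_fixed(list(e(1.4, 0.3), e(1, 0.2), e(2, 0.5)))
  expect_equal(a$pooled_estimate, b$pooled_estimate)
  # convexity: pooled estimate between the study extremes, se below min
  expect_gte(a$pooled_estimate, 1)
  expect_lte(a$pooled_estimate, 2)
  expect_lte(a$pooled_se, 0.2)
  # a nearly weightless study changes nothing appreciable
  c_ <- pool_fixed(list(e(1, 0.2), e(2, 0.5), e(1.4, 0.3), e(50, 1e6)))
  expect_equal(c_$pooled_estimate, a$pooled_estimate, tolerance = 1e-6)
  # mixed kinds refuse to pool
  expect_error(pool_fixed(list(e(1, 0.2),
                               effect_size("s", "fisher_z", r = 0.1, n = 10))),
               "mixed")
})

test_that("the bundled two-study table pools to the published overall column", {
  studies <- dmx_example_studies()
  expect_equal(nrow(studies), 30L)

  # fixed-effect pooling matches every homogeneous (tau2 = 0) row
  fe <- meta_table(studies, method = "fixed")
  fe_vals <- setNames(fe$pooled, fe$label)
  expect_equal(round(unname(fe_vals["tickets_dmx"]), 3), 0.771)
  expect_equal(round(unname(fe_vals["tickets_crt"]), 3), 0.249)
  expect_equal(round(unname(fe_vals["dmx_switches"]), 3), 0.530)
  expect_equal(round(unname(fe_vals["tickets_switches"]), 3), 0.677)
  expect_equal(round(unname(fe_vals["dmx_games"]), 3), 0.352)
  expect_equal(round(unname(fe_vals["tickets_age"]), 3), -0.228)
  expect_equal(round(unname(fe_vals["dmx_mean"]), 1), 52.2)

  # the full published overall column (including the two heterogeneous
  # rows fixed-effect cannot match) is DerSimonian-Laird random-effects
  dl <- meta_table(studies, method = "dl")
  dl_vals <- setNames(dl$pooled, dl$label)
  published <- c(tickets_mean = 1462.1, dmx_mean = 52.2,
                 tickets_age = -0.228, tickets_dmx = 0.771,
                 tickets_games = 0.399, tickets_switches = 0.677,
                 tickets_crt = 0.249, tickets_aomtb = 0.117,
                 tickets_ncs = 0.129, dmx_age = -0.154,
                 dmx_games = 0.352, dmx_switches = 0.530,
                 dmx_crt = 0.039, dmx_aomtb = -0.012, dmx_ncs = -0.077)
  for (lab in names(published)) {
    tol <- if (lab %in% c("tickets_mean", "dmx_mean")) 0.05 else 5e-4
    expect_lt(abs(dl_vals[[lab]] - published[[lab]]), tol)
  }
  # the published Tickets-mean CI is the random-effects one
  row <- dl[dl$label == "tickets_mean", ]
  expect_lt(abs(row$ci_low - 1374.2), 0.2)
  expect_lt(abs(row$ci_high - 1550.1), 0.2)

  # pooled correlations are reported on the z scale with a back-transform
  expect_equal(fe$pooled_r[fe$label == "tickets_dmx"],
               tanh(fe$pooled[fe$label == "tickets_dmx"]))
})

test_that("meta_table accepts raw correlation inputs", {
  df <- data.frame(study = c("s1", "s2"), label = "pair",
                   kind = "correlation", estimate = c(0.593, 0.686),
                   se = NA_real_, n = c(60, 76))
  res <- meta_table(df)
  expect_lt(abs(res$pooled - 0.771), 5e-4)
  expect_equal(res$k, 2L)
})
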