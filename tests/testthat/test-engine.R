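test_that("cycle plans have well-formed outgoing probabilities", {
  p <- fixture_params()
  for (s in c("aspirin", "no_aspirin")) for (k in c(0, 5, 24, 39)) {
    plan <- build_cycle(p, s, k)
    expect_equal(plan$age, 60 + k)
    for (st in c("well", "post_gi_bleed", "mi_year1", "stroke_year1",
                 "mi_later", "stroke_later", "dead")) {
      out <- plan[[st]]
      expect_true(all(out >= 0 & out <= 1))
      expect_equal(sum(out), 1, tolerance = 1e-12)
    }
  }
  expect_error(build_cycle(p, "aspirin", 40), "out of range")
  expect_error(build_cycle(p, "aspirin", -1), "out of range")
})

test_that("first-cycle well-state probabilities reproduce the base inputs", {
  p <- fixture_params()
  plan <- build_cycle(p, "no_aspirin", 0)
  expect_equal(plan$well[["death"]], 0.0133)
  expect_equal(plan$well[["mi"]], rate_to_prob(0.0031))
  expect_equal(plan$well[["stroke"]], rate_to_prob(0.0042))
  gi <- rate_to_prob(0.0018)
  expect_equal(plan$well[["gi_fatal"]], gi * 0.03)
  expect_equal(plan$well[["gi_nonfatal"]], gi * 0.97)
  # close to the raw annual rates (exponential conversion is ~identity here)
  expect_equal(plan$well[["mi"]], 0.0031, tolerance = 2e-3)
  # aspirin applies each odds ratio on the odds scale
  pa <- build_cycle(p, "aspirin", 0)
  expect_equal(pa$well[["mi"]], apply_odds_ratio(rate_to_prob(0.0031), 0.98))
  expect_equal(pa$well[["stroke"]],
               apply_odds_ratio(rate_to_prob(0.0042), 0.88))
  expect_equal(pa$well[["gi_fatal"]] + pa$well[["gi_nonfatal"]],
               apply_odds_ratio(rate_to_prob(0.0018), 1.57))
  expect_equal(pa$well[["death"]],
               apply_odds_ratio(0.0133, p$values$or_death))
  # post-event mortality carries the death OR too (patients stay on aspirin)
  expect_equal(pa$mi_year1[["death"]],
               apply_odds_ratio(0.188, p$values$or_death))
  # ... but not the post-bleed tunnel, where aspirin is discontinued
  expect_equal(pa$post_gi_bleed[["death"]], 0.0133)
})

test_that("neutral odds ratios make the aspirin cycle plan identical", {
  p <- set_params(fixture_params(), or_mi = 1, or_stroke = 1,
                  or_gi_bleed = 1, or_death = 1)
  pa <- build_cycle(p, "aspirin", 3)
  pn <- build_cycle(p, "no_aspirin", 3)
  pa$strategy <- pn$strategy
  expect_equal(pa, pn)
})

test_that("cohort trace conserves occupancy with absorbing death", {
  p <- fixture_params()
  for (s in c("aspirin", "no_aspirin")) {
    tr <- run_cohort(p, s)
    expect_equal(nrow(tr), 40)
    expect_true(all(abs(occupancy_sums(tr) - 1) < 1e-10))
    expect_true(all(diff(tr$dead) >= 0))
    occ_cols <- c("well", "post_gi_bleed", "post_mi", "post_stroke", "dead")
    expect_true(all(as.matrix(tr[occ_cols]) >= 0 &
                      as.matrix(tr[occ_cols]) <= 1))
  }
})

test_that("a risk-free cohort stays well and accrues utility exactly", {
  p <- zero_risk_params()
  tr <- run_cohort(p, "no_aspirin")
  expect_true(all(tr$well == 1))
  expect_true(all(tr$dead == 0))
  expect_equal(trace_totals(tr)[["qaly"]], 40 * 0.876)
  expect_equal(trace_totals(tr)[["cost"]], 0)
  # discounted total matches the closed-form annuity
  expect_equal(trace_totals(tr)[["qaly_disc"]],
               0.876 * sum(1.03^-(0:39)))
})

test_that("a neutral aspirin strategy is indistinguishable from no aspirin", {
  p <- neutral_aspirin_params()
  ta <- run_cohort(p, "aspirin")
  tb <- run_cohort(p, "no_aspirin")
  attr(ta, "strategy") <- attr(tb, "strategy")
  expect_equal(ta, tb)
})

test_that("discounting never increases totals and vanishes at rate zero", {
  p <- fixture_params()
  for (s in c("aspirin", "no_aspirin")) {
    tt <- trace_totals(run_cohort(p, s))
    expect_lte(tt[["cost_disc"]], tt[["cost"]])
    expect_lte(tt[["qaly_disc"]], tt[["qaly"]])
  }
  p0 <- set_params(p, discount_rate = 0)
  tt <- trace_totals(run_cohort(p0, "aspirin"))
  expect_equal(tt[["cost_disc"]], tt[["cost"]])
  expect_equal(tt[["qaly_disc"]], tt[["qaly"]])
})

test_that("outcomes respond monotonically to key inputs", {
  p <- fixture_params()
  qal <- vapply(c(0.85, 0.94, 1, 1.04), function(or_value)
    trace_totals(run_cohort(set_params(p, or_death = or_value),
                            "aspirin"))[["qaly_disc"]], numeric(1))
  expect_true(all(diff(qal) < 0))
  cost <- vapply(c(3477, 4346, 5216), function(cv)
    trace_totals(run_cohort(set_params(p, cost_mi = cv),
                            "no_aspirin"))[["cost_disc"]], numeric(1))
  expect_true(all(diff(cost) > 0))
})

test_that("inconsistent inputs (huge adjusting factor) are rejected", {
  p <- set_params(fixture_params(), adjusting_factor = 500)
  expect_error(run_cohort(p, "no_aspirin"), "sum")
})

test_that("compare derives increments, ICER, and the preferred strategy", {
  p <- fixture_params()
  ta <- run_cohort(p, "aspirin")
  tb <- run_cohort(p, "no_aspirin")
  r <- compare(ta, tb, wtp = 30000)
  expect_equal(r$dcost, unname(r$cost[["aspirin"]] - r$cost[["no_aspirin"]]))
  expect_equal(r$dqaly, unname(r$qaly[["aspirin"]] - r$qaly[["no_aspirin"]]))
  expect_equal(r$icer, r$dcost / r$dqaly)
  expect_false(r$dominant || r$dominated)
  expect_identical(r$preferred, "aspirin")
  # identical traces: tie broken to the no-intervention comparator
  tie <- compare(tb, tb, wtp = 30000)
  expect_equal(tie$dcost, 0)
  expect_equal(tie$dqaly, 0)
  expect_true(is.na(tie$icer))
  expect_identical(tie$preferred, "no_aspirin")
  # an ICER above a small threshold flips the preference
  r2 <- compare(ta, tb, wtp = 1000)
  expect_identical(r2$preferred, "no_aspirin")
  # at an ICER exactly equal to the threshold aspirin still wins
  r3 <- compare(ta, tb, wtp = r$icer)
  expect_identical(r3$preferred, "aspirin")
})
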