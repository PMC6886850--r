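row_of <- function(params, nm) {
  params$table[params$table$name == nm, ]
}

test_that("distribution fitting honours the family conventions", {
  p <- fixture_params()
  # uniform: bounded by the published range
  fu <- fit_distribution(row_of(p, "u_dm"))
  set.seed(1)
  x <- sample_distribution(fu, 5000)
  expect_true(all(x >= 0.701 & x <= 1))
  # lognormal: median at base, 95% quantiles recover the published range
  fl <- fit_distribution(row_of(p, "or_gi_bleed"))
  expect_equal(quantile_distribution(fl, 0.5), 1.57)
  expect_equal(quantile_distribution(fl, 0.025), 1.37, tolerance = 0.005)
  expect_equal(quantile_distribution(fl, 0.975), 1.80, tolerance = 0.005)
  # beta: method of moments reproduces mean and sd
  fb <- fit_distribution(row_of(p, "p_death_mi_year1"))
  a <- fb$pars[["shape1"]]; b <- fb$pars[["shape2"]]
  expect_equal(a / (a + b), 0.188)
  expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))),
               (0.24 - 0.15) / 3.92)
  # a nearly degenerate beta collapses onto the base value
  tight <- data.frame(name = "x", base = 0.3, low = 0.29999,
                      high = 0.30001, dist = "beta")
  set.seed(2)
  expect_equal(mean(sample_distribution(fit_distribution(tight), 1000)),
               0.3, tolerance = 1e-4)
  # infeasible beta moments are rejected
  wide <- data.frame(name = "x", base = 0.5, low = 0, high = 4,
                     dist = "beta")
  expect_error(fit_distribution(wide), "infeasible")
  expect_error(fit_distribution(row_of(p, "adjusting_factor")), "fixed")
})

test_that("large samples recover the fitted moments", {
  p <- fixture_params()
  set.seed(7)
  for (nm in c("rate_mi", "discontinuation", "cost_gi_bleed", "u_dm")) {
    fd <- fit_distribution(row_of(p, nm))
    x <- sample_distribution(fd, 1e5)
    target <- switch(fd$family,
                     beta = row_of(p, nm)$base,
                     lognormal = row_of(p, nm)$base,  # median
                     uniform = (row_of(p, nm)$low + row_of(p, nm)$high) / 2)
    got <- if (fd$family == "lognormal") stats::median(x) else mean(x)
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(got - target), max(3 * se, 3 * 1.25 * se))
  }
})

test_that("the PSA is reproducible and collapses onto the base case", {
  p <- fixture_params()
  a <- run_psa(p, n_sims = 50, seed = 5)
  b <- run_psa(p, n_sims = 50, seed = 5)
  expect_equal(a, b)
  expect_equal(a$n_redraws, 0L)
  # all-point-mass distributions reproduce the deterministic result
  pm <- p
  pm$table$dist[pm$table$dist != "fixed"] <- "uniform"
  pm$table$low <- pm$table$base
  pm$table$high <- pm$table$base
  psa0 <- run_psa(pm, n_sims = 8, seed = 1)
  bc <- base_case(p)
  expect_true(all(abs(psa0$dcost - bc$dcost) < 1e-9))
  expect_true(all(abs(psa0$dqaly - bc$dqaly) < 1e-9))
})

test_that("PSA summaries are normalized and internally consistent", {
  p <- fixture_params()
  psa <- run_psa(p, n_sims = 400, seed = 31)
  qd <- quadrants(psa)
  expect_equal(sum(qd), 1, tolerance = 1e-12)
  expect_true(all(qd >= 0))
  cc <- ceac(psa, wtp_grid = seq(0, 50000, by = 5000))
  expect_true(all(abs(cc$p_aspirin + cc$p_no_aspirin - 1) < 1e-12))
  # at zero WTP the NMB rule reduces to "cheaper wins"
  expect_equal(ceac(psa, 0)$p_aspirin, mean(psa$dcost < 0))
  # percentile CIs bracket the means
  s <- psa$summary
  expect_gt(s$mean_dcost, s$ci_dcost[1])
  expect_lt(s$mean_dcost, s$ci_dcost[2])
  expect_gt(s$mean_dqaly, s$ci_dqaly[1])
  expect_lt(s$mean_dqaly, s$ci_dqaly[2])
  expect_gte(evpi(psa), 0)
  expect_error(ceac(psa, numeric(0)), "nonempty")
})

test_that("EVPI matches hand enumeration on a two-simulation toy result", {
  toy <- list(
    cost = matrix(c(100, 300, 0, 0), 2, 2,
                  dimnames = list(NULL, c("aspirin", "no_aspirin"))),
    qaly = matrix(c(1.1, 0.9, 1.0, 1.0), 2, 2,
                  dimnames = list(NULL, c("aspirin", "no_aspirin"))),
    wtp = 10000
  )
  # NMB aspirin: 10900, 8700; none: 10000, 10000
  # E[max] = (10900 + 10000) / 2 = 10450; max(E) = max(9800, 10000)
  expect_equal(evpi(toy, 10000), 10450 - 10000)
  # a strategy dominant in every simulation has zero EVPI
  toy$cost[2, "aspirin"] <- 0
  toy$qaly[2, "aspirin"] <- 1.2
  # NMB aspirin: 10900, 12000 both above none
  expect_equal(evpi(toy, 10000), 0)
})

test_that("PSA draws stay within the families' supports", {
  p <- fixture_params()
  psa <- run_psa(p, n_sims = 200, seed = 77)
  d <- psa$draws
  expect_true(all(d$rate_mi > 0 & d$rate_mi < 1))
  expect_true(all(d$discontinuation > 0 & d$discontinuation < 1))
  expect_true(all(d$or_gi_bleed > 0))
  expect_true(all(d$u_dm >= 0.701 & d$u_dm <= 1))
  expect_true(all(d$hosp_days_gi_bleed >= 13 & d$hosp_days_gi_bleed <= 18))
  expect_true(all(d$cost_mi > 0))
  # fixed parameters are never drawn
  expect_false("adjusting_factor" %in% names(d))
  expect_false("discount_rate" %in% names(d))
})
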