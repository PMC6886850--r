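#' Probabilistic sensitivity analysis
#'
#' Fits a sampling distribution to every non-fixed parameter from its base
#' value and range, propagates joint parameter uncertainty through the
#' cohort model by Monte Carlo, and summarizes the results as incremental
#' means with percentile confidence intervals, cost-effectiveness-plane
#' quadrant fractions, an acceptability curve, and the expected value of
#' perfect information.
#'
#' Ranges are read as 95% intervals (z-width 3.92) on the scale relevant to
#' each family: beta by method of moments with mean at the base value and
#' sd `(high - low) / 3.92`; lognormal with the median at the base value
#' and log-sd `(ln high - ln low) / 3.92`; uniform on `[low, high]`.
#' Parameters are drawn independently; the adjusting factor and the
#' age-specific mortality table are held fixed (no distribution is given
#' for them).
#'
#' @name psa
NULL

#' Fit a sampling distribution to one parameter
#'
#' @param p a single-row data.frame (or row-like list) with `name`, `base`,
#'   `low`, `high`, `dist`.
#' @return a `ce_dist` list: `family`, `pars` (family-specific), `name`.
#' @export
fit_distribution <- function(p) {
  if (p$dist == "fixed") stop("cannot fit a distribution to a fixed parameter")
  pars <- switch(p$dist,
    beta = {
      m <- p$base
      s <- (p$high - p$low) / 3.92
      if (s <= 0) stop("degenerate range for beta parameter ", p$name)
      if (s^2 >= m * (1 - m))
        stop("beta moments infeasible for ", p$name,
             " (sd^2 >= m(1-m))")
      nu <- m * (1 - m) / s^2 - 1
      c(shape1 = m * nu, shape2 = (1 - m) * nu)
    },
    lognormal = {
      if (p$low <= 0) stop("lognormal parameter ", p$name,
                           " needs a positive range")
      c(meanlog = log(p$base), sdlog = (log(p$high) - log(p$low)) / 3.92)
    },
    uniform = c(min = p$low, max = p$high),
    stop("unknown distribution family: ", p$dist)
  )
  structure(list(family = p$dist, pars = pars, name = p$name),
            class = "ce_dist")
}

#' Sample from a fitted distribution
#'
#' @param fd a `ce_dist` from [fit_distribution()].
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_distribution <- function(fd, n) {
  pa <- fd$pars
  switch(fd$family,
    beta = stats::rbeta(n, pa[["shape1"]], pa[["shape2"]]),
    lognormal = stats::rlnorm(n, pa[["meanlog"]], pa[["sdlog"]]),
    uniform = stats::runif(n, pa[["min"]], pa[["max"]]),
    stop("unknown distribution family: ", fd$family))
}

#' Quantile function of a fitted distribution
#'
#' @param fd a `ce_dist`.
#' @param prob probabilities.
#' @return quantiles.
#' @export
quantile_distribution <- function(fd, prob) {
  pa <- fd$pars
  switch(fd$family,
    beta = stats::qbeta(prob, pa[["shape1"]], pa[["shape2"]]),
    lognormal = stats::qlnorm(prob, pa[["meanlog"]], pa[["sdlog"]]),
    uniform = stats::qunif(prob, pa[["min"]], pa[["max"]]),
    stop("unknown distribution family: ", fd$family))
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws every non-fixed parameter independently from its fitted
#' distribution `n_sims` times, runs both strategies per draw, and records
#' per-simulation discounted (cost, QALY) pairs. A draw whose parameter set
#' fails validation or makes per-cycle probabilities inconsistent is
#' redrawn (with the redraw count reported); with the packaged ranges this
#' does not occur.
#'
#' @param params a `ce_params` object.
#' @param n_sims number of Monte Carlo simulations.
#' @param seed integer seed; the whole result is reproducible given
#'   `seed`.
#' @param wtp willingness-to-pay threshold used for the headline quadrant
#'   and EVPI summaries.
#' @return a `ce_psa` list: `n_sims`, `seed`, `wtp`, `draws` (data.frame of
#'   sampled parameters), `cost` and `qaly` (n x 2 matrices, columns
#'   aspirin / no_aspirin), `dcost`, `dqaly`, `summary` (means and
#'   percentile 95% CIs of the increments), `n_redraws`.
#' @export
run_psa <- function(params, n_sims = 10000, seed = 1L,
                    wtp = params$values$wtp) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  tab <- params$table
  vary <- tab[tab$dist != "fixed", ]
  dists <- lapply(seq_len(nrow(vary)), function(i) fit_distribution(vary[i, ]))
  names(dists) <- vary$name

  set.seed(seed)
  draws <- as.data.frame(lapply(dists, sample_distribution, n = n_sims))
  cost <- matrix(NA_real_, n_sims, 2,
                 dimnames = list(NULL, STRATEGIES))
  qaly <- matrix(NA_real_, n_sims, 2,
                 dimnames = list(NULL, STRATEGIES))
  n_redraws <- 0L
  for (i in seq_len(n_sims)) {
    repeat {
      ok <- tryCatch({
        pi <- set_params(params, as.list(draws[i, , drop = FALSE]))
        for (s in STRATEGIES) {
          tt <- trace_totals(run_cohort(pi, s))
          cost[i, s] <- tt[["cost_disc"]]
          qaly[i, s] <- tt[["qaly_disc"]]
        }
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      n_redraws <- n_redraws + 1L
      draws[i, ] <- vapply(dists, sample_distribution, numeric(1), n = 1)
    }
  }
  dcost <- cost[, "aspirin"] - cost[, "no_aspirin"]
  dqaly <- qaly[, "aspirin"] - qaly[, "no_aspirin"]
  summary <- list(
    mean_cost = colMeans(cost), mean_qaly = colMeans(qaly),
    mean_dcost = mean(dcost), mean_dqaly = mean(dqaly),
    ci_dcost = stats::quantile(dcost, c(0.025, 0.975), names = FALSE),
    ci_dqaly = stats::quantile(dqaly, c(0.025, 0.975), names = FALSE)
  )
  structure(list(n_sims = n_sims, seed = seed, wtp = wtp, draws = draws,
                 cost = cost, qaly = qaly, dcost = dcost, dqaly = dqaly,
                 summary = summary, n_redraws = n_redraws),
            class = "ce_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that each strategy
#' has the highest net monetary benefit `wtp x QALY - cost` across the
#' simulations (an exact NMB tie is credited to the comparator).
#'
#' @param result a `ce_psa`.
#' @param wtp_grid willingness-to-pay grid, USD per QALY.
#' @return a `ce_ceac` data.frame: `wtp`, `p_aspirin`, `p_no_aspirin`
#'   (rows sum to 1).
#' @export
ceac <- function(result, wtp_grid = seq(0, 50000, by = 1000)) {
  if (!length(wtp_grid)) stop("wtp_grid must be nonempty")
  p_asp <- vapply(wtp_grid, function(l)
    mean(l * result$dqaly - result$dcost > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, p_aspirin = p_asp,
                       p_no_aspirin = 1 - p_asp),
            class = c("ce_ceac", "data.frame"))
}

#' Expected value of perfect information
#'
#' `EVPI = E[max_s NMB_s] - max_s E[NMB_s]` at the given
#' willingness-to-pay: the expected net-monetary-benefit gain from
#' resolving all parameter uncertainty before choosing a strategy.
#' Non-negative by construction.
#'
#' @param result a `ce_psa`.
#' @param wtp willingness-to-pay, USD per QALY.
#' @return EVPI in USD (per patient).
#' @export
evpi <- function(result, wtp = result$wtp) {
  nmb <- wtp * result$qaly - result$cost
  mean(pmax(nmb[, 1], nmb[, 2])) - max(colMeans(nmb))
}

#' Cost-effectiveness-plane quadrant fractions
#'
#' Fractions of simulations in the four categories of the incremental
#' cost-effectiveness plane (aspirin vs none): more QALYs at lower cost
#' (dominant); more QALYs at higher cost with ICER at or below the
#' threshold; more QALYs at higher cost with ICER above the threshold; and
#' fewer (or equal) QALYs. The four fractions sum to 1.
#'
#' @param result a `ce_psa`.
#' @param wtp willingness-to-pay, USD per QALY.
#' @return named numeric vector `dominant`, `ce_below_wtp`,
#'   `above_wtp`, `fewer_qalys`.
#' @export
quadrants <- function(result, wtp = result$wtp) {
  dq <- result$dqaly; dc <- result$dcost
  more <- dq > 0
  dominant <- more & dc <= 0
  ce <- more & dc > 0 & dc / dq <= wtp
  above <- more & dc > 0 & dc / dq > wtp
  fewer <- !more
  c(dominant = mean(dominant), ce_below_wtp = mean(ce),
    above_wtp = mean(above), fewer_qalys = mean(fewer))
}

#' Plain-list PSA summary (JSON-ready)
#'
#' @param result a `ce_psa`.
#' @param wtp_grid grid for the acceptability curve.
#' @return a nested list of scalars/vectors suitable for
#'   `jsonlite::write_json()`.
#' @export
psa_summary <- function(result, wtp_grid = seq(0, 50000, by = 1000)) {
  qd <- quadrants(result)
  cc <- ceac(result, wtp_grid)
  list(
    n_sims = result$n_sims, seed = result$seed, wtp = result$wtp,
    n_redraws = result$n_redraws,
    mean_cost = as.list(result$summary$mean_cost),
    mean_qaly = as.list(result$summary$mean_qaly),
    mean_dcost = result$summary$mean_dcost,
    mean_dqaly = result$summary$mean_dqaly,
    ci95_dcost = result$summary$ci_dcost,
    ci95_dqaly = result$summary$ci_dqaly,
    p_aspirin_ce_at_wtp =
      mean(result$wtp * result$dqaly - result$dcost > 0),
    quadrants = as.list(qd),
    evpi = evpi(result),
    ceac = list(wtp = cc$wtp, p_aspirin = cc$p_aspirin)
  )
}

#' @export
print.ce_psa <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ce_psa> %d simulations (seed %d)\n", x$n_sims, x$seed))
  cat(sprintf("  mean cost  aspirin %7.0f  none %7.0f\n",
              s$mean_cost[["aspirin"]], s$mean_cost[["no_aspirin"]]))
  cat(sprintf("  mean QALYs aspirin %7.2f  none %7.2f\n",
              s$mean_qaly[["aspirin"]], s$mean_qaly[["no_aspirin"]]))
  cat(sprintf("  dcost %5.0f (95%% CI %.0f to %.0f)\n",
              s$mean_dcost, s$ci_dcost[1], s$ci_dcost[2]))
  cat(sprintf("  dQALY %6.3f (95%% CI %.3f to %.3f)\n",
              s$mean_dqaly, s$ci_dqaly[1], s$ci_dqaly[2]))
  cat(sprintf("  P(aspirin cost-effective at %d/QALY) = %.2f%%\n",
              x$wtp, 100 * mean(x$wtp * x$dqaly - x$dcost > 0)))
  cat(sprintf("  EVPI = %.0f USD\n", evpi(x)))
  invisible(x)
}
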