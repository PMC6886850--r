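#' Deterministic sensitivity analyses
#'
#' One-way (tornado) analysis over every non-fixed parameter's range,
#' threshold analysis on the all-cause-death odds ratio by bisection, the
#' no-aspirin-disutility scenario, and the event-rate adjusting-factor
#' scan.
#'
#' @name deterministic_sa
NULL

#' One-way sensitivity analysis
#'
#' Re-runs the incremental comparison with each non-fixed parameter set to
#' its range low and high in turn, all others held at base. Results are
#' ordered by the span of the incremental net monetary benefit
#' `wtp x dQALY - dcost` across the two ends, which stays well defined
#' where the ICER is undefined or the aspirin arm is dominated.
#'
#' @param params a `ce_params` object.
#' @param wtp willingness-to-pay threshold, USD per QALY.
#' @return a `ce_oneway` data.frame, one row per parameter: values and
#'   results at both ends (`icer_low`, `icer_high` are `NA` when dQALY is
#'   0), preferred strategy at each end, and `nmb_span`.
#' @export
one_way <- function(params, wtp = params$values$wtp) {
  tab <- params$table
  vary <- tab[tab$dist != "fixed" & tab$low < tab$high, ]
  rows <- lapply(seq_len(nrow(vary)), function(i) {
    nm <- vary$name[i]
    ends <- lapply(c(vary$low[i], vary$high[i]), function(val) {
      pi <- set_params(params, stats::setNames(list(val), nm))
      r <- base_case(pi)
      list(inmb = wtp * r$dqaly - r$dcost, icer = r$icer,
           pref = r$preferred)
    })
    data.frame(name = nm, low = vary$low[i], high = vary$high[i],
               icer_low = ends[[1]]$icer, icer_high = ends[[2]]$icer,
               inmb_low = ends[[1]]$inmb, inmb_high = ends[[2]]$inmb,
               preferred_low = ends[[1]]$pref,
               preferred_high = ends[[2]]$pref,
               nmb_span = abs(ends[[2]]$inmb - ends[[1]]$inmb))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$nmb_span), ]
  rownames(out) <- NULL
  structure(out, wtp = wtp, class = c("ce_oneway", "data.frame"))
}

#' Threshold analysis on the all-cause-death odds ratio
#'
#' Locates, by bisection over `interval`, (a) the death odds ratio at which
#' the aspirin-vs-none ICER crosses the willingness-to-pay threshold
#' (incremental net monetary benefit changes sign while aspirin still gains
#' QALYs) and (b) the odds ratio at which the QALY gain itself crosses zero
#' — beyond it aspirin is dominated (costlier and less effective). Both
#' quantities are continuous and monotone in the odds ratio on this
#' interval.
#'
#' @param params a `ce_params` object.
#' @param wtp willingness-to-pay threshold; `Inf` makes crossing (a)
#'   coincide with (b).
#' @param tol absolute tolerance on the odds-ratio scale.
#' @param interval numeric length-2 search interval for the odds ratio.
#' @return a `ce_threshold` list: `or_icer_crosses_wtp`,
#'   `or_dominance_onset` (either `NA` if no sign change in the interval),
#'   `wtp`, `tol`, `interval`, and `regimes`, a data.frame labelling the
#'   partition of the interval.
#' @export
threshold_or_death <- function(params, wtp = params$values$wtp, tol = 1e-4,
                               interval = c(0.85, 1.10)) {
  if (tol <= 0) stop("tol must be positive")
  delta <- function(or_value) {
    pi <- set_params(params, or_death = or_value)
    r <- base_case(pi)
    c(dq = r$dqaly, f = if (is.infinite(wtp)) r$dqaly
      else wtp * r$dqaly - r$dcost)
  }
  bisect <- function(g) {
    lo <- interval[1]; hi <- interval[2]
    glo <- g(lo); ghi <- g(hi)
    if (sign(glo) == sign(ghi)) return(NA_real_)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (sign(g(mid)) == sign(glo)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  or_wtp <- bisect(function(x) delta(x)["f"])
  or_dom <- bisect(function(x) delta(x)["dq"])
  regimes <- data.frame(
    from = c(interval[1], or_wtp, or_dom),
    to = c(or_wtp, or_dom, interval[2]),
    regime = c("aspirin cost-effective",
               "aspirin more effective but ICER above WTP",
               "aspirin dominated")
  )
  regimes <- regimes[!is.na(regimes$from) & !is.na(regimes$to), ]
  structure(list(or_icer_crosses_wtp = or_wtp,
                 or_dominance_onset = or_dom,
                 wtp = wtp, tol = tol, interval = interval,
                 regimes = regimes),
            class = "ce_threshold")
}

#' @export
print.ce_threshold <- function(x, ...) {
  cat("threshold analysis, all-cause-death odds ratio on [",
      x$interval[1], ", ", x$interval[2], "]\n", sep = "")
  cat(sprintf("  ICER crosses WTP %0.f at OR = %.4f\n",
              x$wtp, x$or_icer_crosses_wtp))
  cat(sprintf("  dominance onset (dQALY = 0) at OR = %.4f\n",
              x$or_dominance_onset))
  invisible(x)
}

#' Scenario: no disutility of taking aspirin
#'
#' Re-runs the base case with the aspirin-taking disutility set to zero.
#' The QALY gain of aspirin rises by the discounted well-state exposure
#' times the removed disutility, so the ICER falls strictly below the
#' base-case ICER.
#'
#' @param params a `ce_params` object.
#' @return a `ce_result`.
#' @export
scenario_no_disutility <- function(params) {
  base_case(set_params(params, du_aspirin = 0))
}

#' Adjusting-factor scan on clinical event rates
#'
#' Scales all four clinical event rates (nonfatal MI, nonfatal stroke, GI
#' bleeding — on the rate scale before probability conversion — and
#' background all-cause death, on the odds scale) simultaneously by each
#' factor, and reports the incremental comparison. Emulates an older or
#' higher-risk cohort (factor > 1) or a lower-risk one (factor < 1);
#' post-event transition mortalities are left untouched.
#'
#' @param params a `ce_params` object.
#' @param factors numeric vector of multipliers.
#' @return a `ce_scan` data.frame: `factor`, per-strategy discounted
#'   cost/QALYs, `dcost`, `dqaly`, `icer`, `preferred`.
#' @export
adjusting_factor_scan <- function(params,
                                  factors = seq(0.5, 2, by = 0.15)) {
  if (any(factors <= 0)) stop("factors must be positive")
  rows <- lapply(factors, function(f) {
    r <- base_case(set_params(params, adjusting_factor = f))
    data.frame(factor = f,
               cost_aspirin = unname(r$cost[1]),
               qaly_aspirin = unname(r$qaly[1]),
               cost_none = unname(r$cost[2]),
               qaly_none = unname(r$qaly[2]),
               dcost = r$dcost, dqaly = r$dqaly, icer = r$icer,
               preferred = r$preferred)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("ce_scan", "data.frame"))
}
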