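#' Markov cohort engine
#'
#' Five health states — well, post-GI-bleeding, post-MI, post-stroke, dead —
#' advanced in yearly cycles from the start age. First-year post-event
#' mortality is encoded with one-cycle tunnel sub-states for entry into
#' post-MI and post-stroke; post-GI-bleeding is itself a one-cycle tunnel
#' whose survivors return to well. Per-cycle rewards (costs, QALYs) accrue
#' to the state distribution at the end of the cycle's transitions, with
#' one-time event costs and the GI-bleed QALY decrement charged in the
#' cycle of incidence; cycle-k quantities are discounted by
#' `(1 + discount)^-k` with a 0-based cycle index. No half-cycle correction
#' is applied.
#'
#' @name markov_engine
NULL

STATES <- c("well", "post_gi_bleed", "mi_year1", "mi_later", "stroke_year1",
            "stroke_later", "dead")

STRATEGIES <- c("aspirin", "no_aspirin")

match_strategy <- function(strategy) match.arg(strategy, STRATEGIES)

# background mortality for one age: age-band probability with the adjusting
# factor applied on the odds scale (identity at factor 1)
background_mortality <- function(params, age) {
  q <- mortality_at_age(params$mortality, age)
  af <- params$values$adjusting_factor
  if (af == 1) q else apply_odds_ratio(q, af)
}

# per-cycle transition probabilities shared by build_cycle / run_cohort /
# microsim_oracle; vectors over the k cycles requested (0-based indices)
cycle_probs <- function(params, strategy, cycles) {
  v <- params$values
  aspirin <- strategy == "aspirin"
  af <- v$adjusting_factor
  ages <- v$start_age + cycles
  q_bg <- vapply(ages, function(a) background_mortality(params, a),
                 numeric(1))
  p_mi <- rate_to_prob(v$rate_mi * af)
  p_stroke <- rate_to_prob(v$rate_stroke * af)
  p_gi <- rate_to_prob(v$rate_gi_bleed * af)
  d_mi1 <- v$p_death_mi_year1
  d_st1 <- v$p_death_stroke_year1
  d_post <- rep(v$p_death_post_event, length(cycles))
  if (aspirin) {
    p_mi <- apply_odds_ratio(p_mi, v$or_mi)
    p_stroke <- apply_odds_ratio(p_stroke, v$or_stroke)
    p_gi <- apply_odds_ratio(p_gi, v$or_gi_bleed)
    q_well <- apply_odds_ratio(q_bg, v$or_death)
    # post-event patients remain on aspirin (drug cost folded into the
    # yearly management cost), so the all-cause-death OR applies there too;
    # not in the post-bleed tunnel, where aspirin is discontinued
    d_mi1 <- apply_odds_ratio(d_mi1, v$or_death)
    d_st1 <- apply_odds_ratio(d_st1, v$or_death)
    d_post <- apply_odds_ratio(d_post, v$or_death)
  } else {
    q_well <- q_bg
  }
  out_total <- q_well + p_mi + p_stroke + p_gi
  if (any(out_total > 1))
    stop("well-state event probabilities sum to ",
         round(max(out_total), 4), " > 1 at cycle ",
         cycles[which(out_total > 1)[1]],
         "; inputs inconsistent (adjusting factor too large?)")
  list(ages = ages, q_bg = q_bg, q_well = q_well, p_mi = p_mi,
       p_stroke = p_stroke, p_gi = p_gi, cf = v$p_death_gi_bleed,
       d_mi1 = d_mi1, d_st1 = d_st1, d_post = d_post,
       out_total = out_total)
}

#' Per-cycle transition plan
#'
#' Computes every outgoing transition probability for cycle `k` (0-based;
#' cohort age = start age + k). Baseline event probabilities are the annual
#' rates times the adjusting factor, converted via [rate_to_prob()]; under
#' the aspirin strategy each is transformed by [apply_odds_ratio()] with its
#' odds ratio, and all-cause mortality (background in the well state, and
#' the post-event mortalities, since those patients stay on aspirin) by the
#' death odds ratio. The GI-bleed probability is split into a fatal
#' fraction (the case fatality) and a nonfatal fraction entering the
#' one-cycle post-bleed tunnel, where aspirin is discontinued (no death
#' odds ratio, background mortality only).
#'
#' @param params a `ce_params` object.
#' @param strategy `"aspirin"` or `"no_aspirin"`.
#' @param k 0-based cycle index.
#' @return a `ce_cycle` list of named outgoing-probability vectors, each
#'   summing to 1 over destinations.
#' @export
build_cycle <- function(params, strategy, k) {
  strategy <- match_strategy(strategy)
  if (length(k) != 1 || k < 0 || k >= params$values$horizon)
    stop("cycle index out of range")
  pr <- cycle_probs(params, strategy, k)
  structure(list(
    cycle = k, age = pr$ages, strategy = strategy,
    well = c(death = pr$q_well, mi = pr$p_mi, stroke = pr$p_stroke,
             gi_fatal = pr$p_gi * pr$cf,
             gi_nonfatal = pr$p_gi * (1 - pr$cf),
             stay = 1 - pr$out_total),
    post_gi_bleed = c(death = pr$q_bg, to_well = 1 - pr$q_bg),
    mi_year1 = c(death = pr$d_mi1, to_later = 1 - pr$d_mi1),
    stroke_year1 = c(death = pr$d_st1, to_later = 1 - pr$d_st1),
    mi_later = c(death = pr$d_post, stay = 1 - pr$d_post),
    stroke_later = c(death = pr$d_post, stay = 1 - pr$d_post),
    dead = c(dead = 1)
  ), class = "ce_cycle")
}

#' Run the cohort model
#'
#' Advances the full cohort (starting 100% well) through `horizon` yearly
#' cycles under one strategy and returns the cohort trace: per cycle, the
#' end-of-cycle state occupancy, the incident-event fractions, and the
#' undiscounted and discounted cost and QALY streams.
#'
#' Costs per cycle: aspirin drug cost (12 x monthly cost) for the adherent
#' fraction `(1 - discontinuation)` of the well state under aspirin;
#' one-time event costs at incidence (all incident bleeds are costed,
#' including the fatal fraction, since the hospitalization occurs); yearly
#' post-MI / post-stroke management costs for the occupants of those states
#' (aspirin medication is included in those management costs, so no
#' separate drug cost there, and none in the post-bleed tunnel year).
#' QALYs per cycle: occupancy-weighted state utilities, minus the one-time
#' GI-bleed decrement `du_gi_bleed x hosp_days / 365` per incident bleed,
#' minus the aspirin disutility for the whole well-state cohort under
#' aspirin (the disutility is not reduced by the discontinuation rate; see
#' the methods vignette).
#'
#' @param params a `ce_params` object.
#' @param strategy `"aspirin"` or `"no_aspirin"`.
#' @return a `ce_trace` data.frame (one row per cycle) with attributes
#'   `totals` (discounted and undiscounted cost/QALY sums), `strategy`, and
#'   `final` (end-of-horizon occupancy over the internal states).
#' @export
run_cohort <- function(params, strategy) {
  strategy <- match_strategy(strategy)
  v <- params$values
  horizon <- v$horizon
  aspirin <- strategy == "aspirin"
  ks <- seq_len(horizon) - 1
  pr <- cycle_probs(params, strategy, ks)
  disc <- (1 + v$discount_rate)^-ks

  drug_cost <- if (aspirin)
    12 * v$cost_aspirin_month * (1 - v$discontinuation) else 0
  u_well <- v$u_dm - if (aspirin) v$du_aspirin else 0
  u_mi <- v$u_dm - v$du_post_mi
  u_stroke <- v$u_dm - v$du_post_stroke
  gi_decrement <- v$du_gi_bleed * v$hosp_days_gi_bleed / 365

  occ <- c(well = 1, gi = 0, mi1 = 0, mi2 = 0, st1 = 0, st2 = 0, dead = 0)
  rows <- matrix(0, nrow = horizon, ncol = 16,
                 dimnames = list(NULL, c(
                   "well", "post_gi_bleed", "post_mi", "post_stroke", "dead",
                   "inc_mi", "inc_stroke", "inc_gi_bleed", "inc_gi_death",
                   "inc_other_death", "cost", "qaly", "cost_disc",
                   "qaly_disc", "mi_year1", "stroke_year1")))
  for (k in seq_len(horizon)) {
    inc_mi <- occ[["well"]] * pr$p_mi
    inc_st <- occ[["well"]] * pr$p_stroke
    inc_gi <- occ[["well"]] * pr$p_gi
    inc_gi_death <- inc_gi * pr$cf
    deaths_other <- occ[["well"]] * pr$q_well[k] +
      occ[["gi"]] * pr$q_bg[k] +
      occ[["mi1"]] * pr$d_mi1 + occ[["st1"]] * pr$d_st1 +
      (occ[["mi2"]] + occ[["st2"]]) * pr$d_post[k]

    occ <- c(
      well = occ[["well"]] * (1 - pr$out_total[k]) +
        occ[["gi"]] * (1 - pr$q_bg[k]),
      gi = inc_gi - inc_gi_death,
      mi1 = inc_mi,
      mi2 = occ[["mi1"]] * (1 - pr$d_mi1) +
        occ[["mi2"]] * (1 - pr$d_post[k]),
      st1 = inc_st,
      st2 = occ[["st1"]] * (1 - pr$d_st1) +
        occ[["st2"]] * (1 - pr$d_post[k]),
      dead = occ[["dead"]] + deaths_other + inc_gi_death
    )

    cost <- occ[["well"]] * drug_cost +
      inc_mi * v$cost_mi + inc_st * v$cost_stroke +
      inc_gi * v$cost_gi_bleed +
      (occ[["mi1"]] + occ[["mi2"]]) * v$cost_post_mi_year +
      (occ[["st1"]] + occ[["st2"]]) * v$cost_post_stroke_year
    qaly <- occ[["well"]] * u_well + occ[["gi"]] * v$u_dm +
      (occ[["mi1"]] + occ[["mi2"]]) * u_mi +
      (occ[["st1"]] + occ[["st2"]]) * u_stroke -
      inc_gi * gi_decrement

    rows[k, ] <- c(occ[["well"]], occ[["gi"]], occ[["mi1"]] + occ[["mi2"]],
                   occ[["st1"]] + occ[["st2"]], occ[["dead"]],
                   inc_mi, inc_st, inc_gi, inc_gi_death, deaths_other,
                   cost, qaly, cost * disc[k], qaly * disc[k],
                   occ[["mi1"]], occ[["st1"]])
  }
  trace <- cbind(data.frame(cycle = ks, age = pr$ages),
                 as.data.frame(rows))
  structure(trace,
            strategy = strategy,
            final = occ,
            totals = c(cost = sum(trace$cost), qaly = sum(trace$qaly),
                       cost_disc = sum(trace$cost_disc),
                       qaly_disc = sum(trace$qaly_disc)),
            class = c("ce_trace", "data.frame"))
}

#' Discounted and undiscounted totals of a trace
#'
#' @param trace a `ce_trace`.
#' @return named numeric vector `cost`, `qaly`, `cost_disc`, `qaly_disc`.
#' @export
trace_totals <- function(trace) attr(trace, "totals")

#' Incremental cost-effectiveness comparison
#'
#' Compares two cohort traces (intervention vs comparator): incremental
#' discounted cost and QALYs, the ICER where defined, dominance, and the
#' preferred strategy at a willingness-to-pay threshold. The preferred
#' strategy is the most effective one whose ICER against the next-best
#' non-dominated alternative does not exceed the threshold (an ICER exactly
#' at the threshold counts as acceptable); with zero QALY difference the
#' cheaper strategy is preferred, and an exact tie goes to the comparator
#' (no intervention by default).
#'
#' @param trace_a `ce_trace` for the intervention (aspirin).
#' @param trace_b `ce_trace` for the comparator (no aspirin).
#' @param wtp willingness-to-pay threshold, USD per QALY.
#' @return a `ce_result` list: `cost`, `qaly` (named per strategy),
#'   `dcost`, `dqaly`, `icer`, `dominant`, `dominated`, `preferred`, `wtp`.
#' @export
compare <- function(trace_a, trace_b, wtp = 30000) {
  ta <- trace_totals(trace_a); tb <- trace_totals(trace_b)
  sa <- attr(trace_a, "strategy"); sb <- attr(trace_b, "strategy")
  dcost <- unname(ta["cost_disc"] - tb["cost_disc"])
  dqaly <- unname(ta["qaly_disc"] - tb["qaly_disc"])
  icer <- if (dqaly != 0) dcost / dqaly else NA_real_
  dominant <- dqaly > 0 && dcost < 0   # a dominates b
  dominated <- dqaly < 0 && dcost > 0  # a dominated by b
  preferred <- if (dqaly > 0) {
    if (dcost <= 0 || dcost / dqaly <= wtp) sa else sb
  } else if (dqaly < 0) {
    # a saves money but loses QALYs: acceptable only if savings per QALY
    # forgone exceed the threshold
    if (dcost >= 0 || dcost / dqaly <= wtp) sb else sa
  } else {
    if (dcost < 0) sa else sb
  }
  structure(list(
    cost = stats::setNames(c(ta[["cost_disc"]], tb[["cost_disc"]]),
                           c(sa, sb)),
    qaly = stats::setNames(c(ta[["qaly_disc"]], tb[["qaly_disc"]]),
                           c(sa, sb)),
    dcost = dcost, dqaly = dqaly, icer = unname(icer),
    dominant = dominant, dominated = dominated,
    preferred = preferred, wtp = wtp
  ), class = "ce_result")
}

#' Base-case analysis
#'
#' Runs both strategies on one parameter set and returns the incremental
#' comparison at the parameter set's willingness-to-pay threshold.
#'
#' @param params a `ce_params` object.
#' @return a `ce_result` with the two traces attached as attribute
#'   `traces`.
#' @export
base_case <- function(params) {
  ta <- run_cohort(params, "aspirin")
  tb <- run_cohort(params, "no_aspirin")
  res <- compare(ta, tb, wtp = params$values$wtp)
  attr(res, "traces") <- list(aspirin = ta, no_aspirin = tb)
  res
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  for (s in names(x$cost))
    cat(sprintf("  %-11s cost %8.0f USD   QALYs %6.2f\n",
                s, x$cost[[s]], x$qaly[[s]]))
  cat(sprintf("  incremental  %+.0f USD, %+.4f QALYs\n", x$dcost, x$dqaly))
  if (x$dominant) {
    cat("  aspirin dominates (cheaper, more effective)\n")
  } else if (x$dominated) {
    cat("  aspirin dominated (costlier, less effective)\n")
  } else if (is.finite(x$icer)) {
    cat(sprintf("  ICER %.0f USD/QALY\n", x$icer))
  }
  cat(sprintf("  preferred at WTP %.0f: %s\n", x$wtp, x$preferred))
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' One row per cycle with end-of-cycle occupancies, incident events, and
#' cost/QALY streams (undiscounted and discounted).
#'
#' @param trace a `ce_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(cbind(strategy = attr(trace, "strategy"),
                         as.data.frame(trace)),
                   path, row.names = FALSE)
  invisible(path)
}
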