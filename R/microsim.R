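#' Individual-level microsimulation oracle
#'
#' Simulates `n_patients` independent patients through the same transition
#' rules, reward conventions, and discounting as [run_cohort()]. As the
#' number of patients grows, mean state occupancy, cost and QALYs converge
#' to the cohort-model values, so this serves as an independent Monte Carlo
#' cross-check of the deterministic engine (it shares only the per-cycle
#' transition probabilities via the same internal constructor; the dynamics
#' are realized by sampling, not matrix recursion).
#'
#' @param params a `ce_params` object.
#' @param strategy `"aspirin"` or `"no_aspirin"`.
#' @param n_patients number of simulated patients.
#' @param seed integer seed (deterministic output for a given seed).
#' @return a `ce_microsim` list: `n`, `mean_cost`, `mean_qaly` (discounted
#'   per-patient means), `se_cost`, `se_qaly` (standard errors), `trace`
#'   (per-cycle mean end-of-cycle occupancy over the five aggregated
#'   states), and `events` (per-cycle mean incident-event fractions).
#' @export
microsim_oracle <- function(params, strategy, n_patients, seed = 1L) {
  strategy <- match_strategy(strategy)
  if (n_patients < 1) stop("n_patients must be >= 1")
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

  # states: 1 well, 2 post-GI tunnel, 3 MI year 1, 4 MI later,
  #         5 stroke year 1, 6 stroke later, 7 dead
  state <- rep(1L, n_patients)
  cost <- numeric(n_patients)
  qaly <- numeric(n_patients)
  occ <- matrix(0, horizon, 5,
                dimnames = list(NULL, c("well", "post_gi_bleed", "post_mi",
                                        "post_stroke", "dead")))
  ev <- matrix(0, horizon, 4,
               dimnames = list(NULL, c("inc_mi", "inc_stroke",
                                       "inc_gi_bleed", "inc_gi_death")))
  set.seed(seed)
  for (k in seq_len(horizon)) {
    alive <- state != 7L
    if (!any(alive)) {
      occ[k:horizon, "dead"] <- 1
      break
    }
    u <- stats::runif(n_patients)
    new <- state
    cyc_cost <- numeric(n_patients)
    cyc_qaly <- numeric(n_patients)

    w <- state == 1L
    if (any(w)) {
      th <- cumsum(c(pr$q_well[k], pr$p_mi, pr$p_stroke,
                     pr$p_gi * pr$cf, pr$p_gi * (1 - pr$cf)))
      uw <- u[w]
      dest <- ifelse(uw < th[1], 7L,
              ifelse(uw < th[2], 3L,
              ifelse(uw < th[3], 5L,
              ifelse(uw < th[4], 7L,
              ifelse(uw < th[5], 2L, 1L)))))
      new[w] <- dest
      is_mi <- uw >= th[1] & uw < th[2]
      is_st <- uw >= th[2] & uw < th[3]
      is_gi <- uw >= th[3] & uw < th[5]
      is_gi_death <- uw >= th[3] & uw < th[4]
      ev[k, ] <- ev[k, ] + c(sum(is_mi), sum(is_st), sum(is_gi),
                             sum(is_gi_death))
      cyc_cost[w] <- is_mi * v$cost_mi + is_st * v$cost_stroke +
        is_gi * v$cost_gi_bleed
      cyc_qaly[w] <- -is_gi * gi_decrement
    }
    g <- state == 2L
    if (any(g)) new[g] <- ifelse(u[g] < pr$q_bg[k], 7L, 1L)
    m1 <- state == 3L
    if (any(m1)) new[m1] <- ifelse(u[m1] < pr$d_mi1, 7L, 4L)
    m2 <- state == 4L
    if (any(m2)) new[m2] <- ifelse(u[m2] < pr$d_post[k], 7L, 4L)
    s1 <- state == 5L
    if (any(s1)) new[s1] <- ifelse(u[s1] < pr$d_st1, 7L, 6L)
    s2 <- state == 6L
    if (any(s2)) new[s2] <- ifelse(u[s2] < pr$d_post[k], 7L, 6L)

    # state rewards on the end-of-cycle state, as in the cohort engine
    cyc_cost <- cyc_cost + (new == 1L) * drug_cost +
      (new == 3L | new == 4L) * v$cost_post_mi_year +
      (new == 5L | new == 6L) * v$cost_post_stroke_year
    cyc_qaly <- cyc_qaly + (new == 1L) * u_well + (new == 2L) * v$u_dm +
      (new == 3L | new == 4L) * u_mi +
      (new == 5L | new == 6L) * u_stroke
    cost <- cost + disc[k] * cyc_cost
    qaly <- qaly + disc[k] * cyc_qaly
    state <- new
    occ[k, ] <- c(mean(state == 1L), mean(state == 2L),
                  mean(state == 3L | state == 4L),
                  mean(state == 5L | state == 6L), mean(state == 7L))
  }
  ev <- ev / n_patients
  structure(list(
    n = n_patients, strategy = strategy, seed = seed,
    mean_cost = mean(cost), mean_qaly = mean(qaly),
    se_cost = stats::sd(cost) / sqrt(n_patients),
    se_qaly = stats::sd(qaly) / sqrt(n_patients),
    trace = cbind(data.frame(cycle = ks), as.data.frame(occ)),
    events = cbind(data.frame(cycle = ks), as.data.frame(ev))
  ), class = "ce_microsim")
}

#' @export
print.ce_microsim <- function(x, ...) {
  cat(sprintf(paste0("<ce_microsim> %s, n = %d: discounted cost %.1f ",
                     "(se %.2f), QALYs %.3f (se %.4f)\n"),
              x$strategy, x$n, x$mean_cost, x$se_cost, x$mean_qaly,
              x$se_qaly))
  invisible(x)
}
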