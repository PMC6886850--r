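#' Rate and probability transforms
#'
#' Conversions between cumulative trial event proportions, constant annual
#' event rates, and per-cycle transition probabilities, plus odds-ratio
#' application to baseline risks. These are the standard exponential
#' (constant-hazard) identities used to turn trial follow-up data into
#' yearly Markov transition probabilities.
#'
#' @name epi_transforms
NULL

#' Annual event rate from a cumulative proportion
#'
#' Under a constant hazard, a cumulative event proportion `p` observed over
#' `t` years implies an annual rate `r = -ln(1 - p) / t`.
#'
#' @param p cumulative event proportion in \[0, 1).
#' @param t follow-up in years (> 0).
#' @return annual event rate (events per person-year).
#' @export
#' @examples
#' annual_rate(0.096, 7.4)
annual_rate <- function(p, t) {
  if (any(p < 0) || any(p >= 1)) stop("p must lie in [0, 1)")
  if (any(t <= 0)) stop("t must be positive")
  -log(1 - p) / t
}

#' Transition probability from an annual rate
#'
#' Inverse of [annual_rate()]: `p = 1 - exp(-r * dt)`. With `dt = 1` this is
#' the yearly Markov transition probability implied by a constant annual
#' rate.
#'
#' @param r annual rate (>= 0).
#' @param dt cycle length in years.
#' @return transition probability.
#' @export
rate_to_prob <- function(r, dt = 1) {
  if (any(r < 0)) stop("rate must be non-negative")
  1 - exp(-r * dt)
}

#' Participant-weighted pooling of trial event rates
#'
#' Converts each trial's cumulative proportion to an annual rate with
#' [annual_rate()] and combines the per-trial rates as a mean weighted by
#' the number of participants. This documents the derivation path of the
#' pooled baseline rates shipped in the fixture; it is not re-run at model
#' time.
#'
#' @param summaries data.frame with columns `trial`, `n`, `p` (cumulative
#'   proportion), `t` (follow-up years).
#' @return pooled annual rate.
#' @export
pool_trials <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) < 1)
    stop("need at least one trial summary")
  stopifnot(all(c("n", "p", "t") %in% names(summaries)))
  if (any(summaries$n <= 0)) stop("participant counts must be positive")
  r <- annual_rate(summaries$p, summaries$t)
  sum(summaries$n * r) / sum(summaries$n)
}

#' Apply an odds ratio to a baseline probability
#'
#' Converts `p0` to odds, multiplies by the odds ratio, and converts back:
#' `p1 = OR * o / (1 + OR * o)` with `o = p0 / (1 - p0)`. Exact on the odds
#' scale; for small `p0` this is close to `OR * p0`.
#'
#' @param p0 baseline probability in \[0, 1).
#' @param or_value odds ratio (> 0).
#' @return adjusted probability in \[0, 1).
#' @export
#' @examples
#' apply_odds_ratio(0.0018, 1.57)
apply_odds_ratio <- function(p0, or_value) {
  if (any(p0 < 0) || any(p0 >= 1)) stop("p0 must lie in [0, 1)")
  if (any(or_value <= 0)) stop("odds ratio must be strictly positive")
  o <- or_value * p0 / (1 - p0)
  o / (1 + o)
}
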