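# shared fixture: the packaged base-case parameter set, loaded once
.fixture_env <- new.env()

fixture_params <- function() {
  if (is.null(.fixture_env$params))
    .fixture_env$params <- default_parameters()
  .fixture_env$params
}

# a parameter set with every clinical event rate and all mortality zeroed:
# the cohort can never leave the well state (bypasses file validation,
# which requires mortality in (0,1), deliberately)
zero_risk_params <- function() {
  p <- fixture_params()
  p <- set_params(p, rate_mi = 0, rate_stroke = 0, rate_gi_bleed = 0)
  p$mortality$p <- rep(0, nrow(p$mortality))
  p
}

# neutral aspirin arm: no effect, no cost, no disutility
neutral_aspirin_params <- function() {
  set_params(fixture_params(), or_mi = 1, or_stroke = 1, or_gi_bleed = 1,
             or_death = 1, cost_aspirin_month = 0, du_aspirin = 0)
}

occupancy_sums <- function(trace) {
  trace$well + trace$post_gi_bleed + trace$post_mi + trace$post_stroke +
    trace$dead
}
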