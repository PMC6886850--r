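#' Model parameters
#'
#' A `ce_params` object bundles every input of the decision model: the
#' parameter table (base value, range, sampling distribution family, units),
#' a named list of current values, and the age-specific all-cause mortality
#' table. The packaged fixture (`default_parameters()`) carries the
#' base-case inputs of the aspirin primary-prevention model: annual event
#' rates in diabetes patients not on aspirin, odds ratios for aspirin versus
#' none, post-event mortality, utilities/disutilities, 2019-USD costs, a 3%
#' annual discount rate, a 30,000 USD/QALY willingness-to-pay threshold, a
#' 40-cycle horizon and a start age of 60.
#'
#' @name ce_params
NULL

PARAM_NAMES <- c(
  "rate_mi", "rate_stroke", "rate_gi_bleed",
  "or_mi", "or_stroke", "or_gi_bleed", "or_death",
  "discontinuation", "adjusting_factor",
  "p_death_mi_year1", "p_death_stroke_year1", "p_death_post_event",
  "p_death_gi_bleed", "hosp_days_gi_bleed",
  "u_dm", "du_gi_bleed", "du_post_mi", "du_post_stroke", "du_aspirin",
  "cost_aspirin_month", "cost_gi_bleed", "cost_mi", "cost_stroke",
  "cost_post_mi_year", "cost_post_stroke_year",
  "discount_rate", "wtp", "horizon", "start_age"
)

PROB_PARAMS <- c(
  "rate_mi", "rate_stroke", "rate_gi_bleed", "discontinuation",
  "p_death_mi_year1", "p_death_stroke_year1", "p_death_post_event",
  "p_death_gi_bleed", "discount_rate"
)
UTILITY_PARAMS <- c("u_dm", "du_gi_bleed", "du_post_mi", "du_post_stroke",
                    "du_aspirin")
COST_PARAMS <- c("cost_aspirin_month", "cost_gi_bleed", "cost_mi",
                 "cost_stroke", "cost_post_mi_year", "cost_post_stroke_year")
DIST_FAMILIES <- c("beta", "lognormal", "uniform", "fixed")

#' Load model parameters from a YAML file
#'
#' Reads a parameter file (one entry per parameter with keys
#' `name`/`base`/`low`/`high`/`dist`/`units` plus a `mortality` table of
#' `{age_lo, age_hi, p}` bands) and returns a validated `ce_params` object.
#' Unknown or missing parameter names, inverted ranges, out-of-range
#' probabilities or utilities, and malformed mortality tables are rejected
#' with an error naming the offending entry.
#'
#' @param path path to a YAML parameter file; defaults to the packaged
#'   base-case fixture.
#' @return a `ce_params` object: list with elements `table` (data.frame of
#'   name/base/low/high/dist/units), `values` (named list of current
#'   values), `mortality` (data.frame age_lo/age_hi/p) and `currency`.
#' @export
load_parameters <- function(path = system.file("extdata", "parameters.yaml",
                                               package = "aspirindm")) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$parameters)) stop("parameter file has no 'parameters' block")
  tab <- do.call(rbind, lapply(raw$parameters, function(p) {
    need <- c("name", "base", "low", "high", "dist", "units")
    miss <- setdiff(need, names(p))
    if (length(miss))
      stop("parameter entry missing field(s) ", paste(miss, collapse = ", "))
    data.frame(name = p$name, base = as.numeric(p$base),
               low = as.numeric(p$low), high = as.numeric(p$high),
               dist = p$dist, units = p$units, stringsAsFactors = FALSE)
  }))
  mort <- do.call(rbind, lapply(raw$mortality, function(b)
    data.frame(age_lo = b$age_lo, age_hi = as.numeric(b$age_hi),
               p = b$p)))
  params <- new_ce_params(tab, mort, currency = raw$currency)
  validate_parameters(params)
  params
}

new_ce_params <- function(table, mortality, currency = NULL) {
  values <- as.list(stats::setNames(table$base, table$name))
  structure(list(table = table, values = values, mortality = mortality,
                 currency = currency),
            class = "ce_params")
}

#' @rdname load_parameters
#' @export
default_parameters <- function() load_parameters()

#' Validate a parameter set
#'
#' Checks the structural invariants of a `ce_params` object: the full
#' parameter roster is present with no unknown names; `low <= base <= high`
#' for every entry; probabilities, rates and utilities lie in \[0, 1\];
#' costs are non-negative; odds ratios are strictly positive; every
#' state disutility is below the baseline diabetes utility; `fixed`
#' parameters (other than those with a scenario-scan range) have
#' `low == high == base`; and the mortality table is contiguous,
#' nondecreasing, and starts no later than the cohort start age.
#'
#' @param params a `ce_params` object.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "ce_params"))
  tab <- params$table
  v <- params$values
  unknown <- setdiff(tab$name, PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(PARAM_NAMES, tab$name)
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$name))
    stop("duplicated parameter name(s)")
  bad <- tab$name[tab$low > tab$base | tab$base > tab$high]
  if (length(bad))
    stop("range must satisfy low <= base <= high for: ",
         paste(bad, collapse = ", "))
  if (!all(tab$dist %in% DIST_FAMILIES))
    stop("unknown distribution family: ",
         paste(setdiff(tab$dist, DIST_FAMILIES), collapse = ", "))
  for (nm in PROB_PARAMS)
    if (v[[nm]] < 0 || v[[nm]] > 1)
      stop(nm, " must lie in [0, 1], got ", v[[nm]])
  for (nm in UTILITY_PARAMS)
    if (v[[nm]] < 0 || v[[nm]] > 1)
      stop(nm, " must lie in [0, 1], got ", v[[nm]])
  for (nm in COST_PARAMS)
    if (v[[nm]] < 0) stop(nm, " must be non-negative")
  for (nm in c("or_mi", "or_stroke", "or_gi_bleed", "or_death"))
    if (v[[nm]] <= 0) stop(nm, " must be strictly positive")
  for (nm in c("du_gi_bleed", "du_post_mi", "du_post_stroke", "du_aspirin"))
    if (v[[nm]] >= v$u_dm)
      stop("disutility ", nm, " must be below the baseline utility u_dm")
  ln <- tab$name[tab$dist == "lognormal"]
  if (any(tab$low[tab$name %in% ln] <= 0))
    stop("lognormal parameters must be strictly positive")
  mort <- params$mortality
  if (is.null(mort) || nrow(mort) < 1) stop("mortality table is empty")
  if (any(mort$p <= 0 | mort$p >= 1))
    stop("mortality probabilities must lie in (0, 1)")
  if (is.unsorted(mort$p))
    stop("mortality must be nondecreasing with age")
  if (nrow(mort) > 1 &&
      any(mort$age_lo[-1] != mort$age_hi[-nrow(mort)] + 1))
    stop("mortality age bands must be contiguous")
  if (mort$age_lo[1] > v$start_age)
    stop("mortality table must start at or below the cohort start age")
  invisible(params)
}

#' Read or replace parameter values
#'
#' `param_value()` extracts a single current value; `set_params()` returns a
#' copy of the object with the given values replaced (ranges and
#' distribution families untouched), re-validated.
#'
#' @param params a `ce_params` object.
#' @param name parameter name.
#' @param ... `name = value` pairs to replace.
#' @return the value, or a modified `ce_params`.
#' @export
param_value <- function(params, name) {
  if (!name %in% names(params$values)) stop("no such parameter: ", name)
  params$values[[name]]
}

#' @rdname param_value
#' @export
set_params <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 1L && is.null(names(repl)) && is.list(repl[[1L]]))
    repl <- repl[[1L]]
  for (nm in names(repl)) {
    if (!nm %in% names(params$values)) stop("no such parameter: ", nm)
    params$values[[nm]] <- repl[[nm]]
  }
  validate_values(params)
  params
}

# value-only re-validation: used after perturbations that step outside the
# table's low/high (one-way SA uses the range itself; PSA draws may exceed a
# 95% range legitimately).
validate_values <- function(params) {
  v <- params$values
  for (nm in PROB_PARAMS)
    if (v[[nm]] < 0 || v[[nm]] > 1)
      stop(nm, " must lie in [0, 1], got ", v[[nm]])
  for (nm in UTILITY_PARAMS)
    if (v[[nm]] < 0 || v[[nm]] > 1)
      stop(nm, " must lie in [0, 1], got ", v[[nm]])
  for (nm in COST_PARAMS)
    if (v[[nm]] < 0) stop(nm, " must be non-negative")
  for (nm in c("or_mi", "or_stroke", "or_gi_bleed", "or_death"))
    if (v[[nm]] <= 0) stop(nm, " must be strictly positive")
  invisible(params)
}

#' Age-specific background mortality
#'
#' Looks up the annual all-cause death probability for a given age in the
#' banded mortality table. Ages beyond the last band take the last band's
#' value (the final band is open-ended); ages below the first band are an
#' error.
#'
#' @param mortality a mortality table (`data.frame` with `age_lo`, `age_hi`,
#'   `p`) or a `ce_params` object.
#' @param age age in years.
#' @return annual death probability.
#' @export
#' @examples
#' p <- default_parameters()
#' mortality_at_age(p, 60)   # 0.0133
#' mortality_at_age(p, 99)   # 0.2263 (open last band)
mortality_at_age <- function(mortality, age) {
  if (inherits(mortality, "ce_params")) mortality <- mortality$mortality
  if (age < mortality$age_lo[1])
    stop("age ", age, " below the first mortality band (",
         mortality$age_lo[1], ")")
  i <- findInterval(age, mortality$age_lo)
  mortality$p[i]
}

#' Serialize parameters back to YAML
#'
#' Writes a `ce_params` object in the same YAML layout as the packaged
#' fixture, so that `load_parameters(write_parameters(p, f))` round-trips.
#'
#' @param params a `ce_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  tab <- params$table
  tab$base <- vapply(seq_len(nrow(tab)), function(i) {
    val <- params$values[[tab$name[i]]]
    if (is.null(val)) tab$base[i] else val
  }, numeric(1))
  plist <- lapply(seq_len(nrow(tab)), function(i)
    list(name = tab$name[i], base = tab$base[i], low = tab$low[i],
         high = tab$high[i], dist = tab$dist[i], units = tab$units[i]))
  mort <- params$mortality
  mlist <- lapply(seq_len(nrow(mort)), function(i)
    list(age_lo = mort$age_lo[i],
         age_hi = if (is.finite(mort$age_hi[i])) mort$age_hi[i] else ".inf",
         p = mort$p[i]))
  out <- list(currency = params$currency, parameters = plist,
              mortality = mlist)
  yaml::write_yaml(out, path,
                   handlers = list(character = function(x)
                     if (identical(x, ".inf")) ".inf" else x))
  # yaml::write_yaml quotes ".inf"; patch to bare token so read_yaml sees Inf
  txt <- readLines(path)
  txt <- gsub("'\\.inf'", ".inf", txt)
  writeLines(txt, path)
  invisible(path)
}

#' Draw a random valid parameter set
#'
#' Samples every non-fixed parameter uniformly within its `[low, high]`
#' range (fixed parameters keep their base value) and returns the modified
#' `ce_params`. This generator exists for property testing — every draw
#' satisfies the parameter-set invariants by construction — and is
#' deterministic given `seed`. It is unrelated to the PSA sampler, which
#' uses the fitted beta/lognormal/uniform distributions.
#'
#' @param seed integer seed.
#' @param ranges a `ce_params` supplying ranges (default: packaged fixture).
#' @return a `ce_params` with perturbed values.
#' @export
random_parameter_set <- function(seed, ranges = default_parameters()) {
  tab <- ranges$table
  out <- ranges
  rng <- local({
    set.seed(seed)
    stats::runif(nrow(tab))
  })
  for (i in seq_len(nrow(tab))) {
    if (tab$dist[i] == "fixed") next
    out$values[[tab$name[i]]] <- tab$low[i] + rng[i] * (tab$high[i] - tab$low[i])
  }
  validate_values(out)
  out
}

#' @export
print.ce_params <- function(x, ...) {
  cat("<ce_params> ", nrow(x$table), " parameters, ",
      nrow(x$mortality), " mortality bands\n", sep = "")
  cat("  horizon ", x$values$horizon, " yearly cycles from age ",
      x$values$start_age, ", discount ", x$values$discount_rate,
      ", WTP ", x$values$wtp, " USD/QALY\n", sep = "")
  invisible(x)
}
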