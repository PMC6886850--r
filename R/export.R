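#' Machine-readable result export
#'
#' CSV/JSON writers for the analysis drivers: full precision is kept in the
#' machine-readable files; rounding (whole USD, QALYs to 2 decimals, ICERs
#' to whole USD/QALY) is applied only in printed tables.
#'
#' @name reporting
NULL

#' Serialize a `ce_result` to JSON
#'
#' @param result a `ce_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  out <- list(
    cost = as.list(result$cost), qaly = as.list(result$qaly),
    dcost = result$dcost, dqaly = result$dqaly, icer = result$icer,
    dominant = result$dominant, dominated = result$dominated,
    preferred = result$preferred, wtp = result$wtp
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Base-case table in publication layout
#'
#' One row per strategy with rounded cost, incremental cost, QALYs,
#' incremental QALYs and ICER (comparator row first).
#'
#' @param result a `ce_result`.
#' @return a data.frame.
#' @export
format_base_case <- function(result) {
  s <- names(result$cost)
  data.frame(
    strategy = c(s[2], s[1]),
    cost_usd = round(c(result$cost[[2]], result$cost[[1]])),
    incremental_cost = c(NA, round(result$dcost)),
    qalys = round(c(result$qaly[[2]], result$qaly[[1]]), 2),
    incremental_qalys = c(NA, round(result$dqaly, 2)),
    icer_usd_per_qaly = c(NA, round(result$icer))
  )
}
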