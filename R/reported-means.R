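#' Reported line-by-diet means from the divergent-RFI selection study
#'
#' Line means of profit (EUR/pig), the four per-kg-live-weight impact
#' categories (kg CO2 eq, g SO2 eq, g P eq, m2a crop eq), fattening feed
#' cost (EUR), carcass weight (kg) and lean meat percentage, as reported for
#' the two RFI-divergent lines under the reference and the three optimized
#' diets.  These printed means are inputs for the derived line-gap and
#' zero-profit-sensitivity worked examples ([derived_line_metrics()],
#' [zero_profit_sensitivity()]); they are not produced by this package's
#' simulator.
#'
#' @return tibble with columns `line_id`, `diet`, `profit`, `gwp`, `ap`,
#'   `ep`, `lo`, `fattening_feed_cost_eur`, `carcass_kg`, `lmp_pct`.
#' @export
reported_line_means <- function() {
  path <- system.file("extdata", "reported_line_means.csv", package = "porkopt",
                      mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
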