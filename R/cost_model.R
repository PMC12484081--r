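#' Relative IQ cost: percent of lifetime earnings lost
#'
#' Monetizes a mean IQ-point loss as the mean percent of lifetime earnings
#' foregone per person aged 0-19. The US reference loss per IQ point
#' (`econ$e_us`) is scaled by the country's returns to education relative to
#' the US (`ret_edu / econ$r_us`), a proxy for the relative economic return
#' to cognitive skills:
#'
#' `min(cap_pct, 100 * mean_iq_loss * e_us * ret_edu / r_us)`
#'
#' @param mean_iq_loss mean IQ points lost per young person (non-negative;
#'   vectorized).
#' @param econ an [economic_params] object.
#' @param ret_edu country returns to education, fraction per year of
#'   schooling (vectorized).
#' @return Percent of lifetime earnings, capped at `econ$cap_pct`.
#' @examples
#' relative_iq_cost(2, economic_params(e_us = 0.02, r_us = 0.06), 0.09) # 6
#' @export
relative_iq_cost <- function(mean_iq_loss, econ, ret_edu) {
  stopifnot(inherits(econ, "economic_params"))
  if (any(is.na(mean_iq_loss)) || any(mean_iq_loss < 0)) {
    stop("mean_iq_loss must be non-negative", call. = FALSE)
  }
  if (any(is.na(ret_edu)) || any(ret_edu < 0)) {
    stop("ret_edu must be non-negative", call. = FALSE)
  }
  pmin(econ$cap_pct, 100 * mean_iq_loss * econ$e_us * ret_edu / econ$r_us)
}

#' Absolute annual cost in 2021 international dollars
#'
#' `relative_cost_pct / 100 * gdp_pc * pop_0_19`: the relative loss applied
#' to the country's GDP per capita (PPP, constant 2021 international
#' dollars) across its population aged 0-19, an annual flow.
#'
#' @param relative_cost_pct percent of lifetime earnings (vectorized).
#' @param gdp_pc GDP per capita, $/person/yr.
#' @param pop_0_19 persons aged 0-19.
#' @return Dollars per year.
#' @examples
#' absolute_cost(6, 10000, 1e6) # 6e8
#' @export
absolute_cost <- function(relative_cost_pct, gdp_pc, pop_0_19) {
  if (any(is.na(relative_cost_pct)) || any(relative_cost_pct < 0) ||
      any(is.na(gdp_pc)) || any(gdp_pc < 0) ||
      any(is.na(pop_0_19)) || any(pop_0_19 < 0)) {
    stop("all inputs must be non-negative", call. = FALSE)
  }
  relative_cost_pct / 100 * gdp_pc * pop_0_19
}

#' Summarize per-country results by continent and globally
#'
#' Produces the summary-table analogue of a results column: per-continent
#' mean relative cost (population-weighted by `pop_0_19` or unweighted), the
#' global total of absolute costs, and the median/min/max of country
#' relative costs (the "median country" statistic).
#'
#' @param results data frame with `iso3`, `mean_iq_loss`,
#'   `relative_cost_pct`, `absolute_cost` (one row per country).
#' @param records the matching country records (same `iso3` key set).
#' @param weighting `"population"` (default) or `"unweighted"` continent
#'   means.
#' @return An object of class `summary_table`: tibble `continent_means`
#'   (`continent`, `mean_relative_cost_pct`, `n`), scalars `global_total`,
#'   `median_pct`, `min_pct`, `max_pct`, and the `weighting` used.
#' @export
summarize_results <- function(results, records,
                              weighting = c("population", "unweighted")) {
  weighting <- match.arg(weighting)
  if (nrow(results) == 0L) stop("no results to summarize", call. = FALSE)
  if (!setequal(results$iso3, records$iso3) ||
      nrow(results) != nrow(records)) {
    stop("results and records must be keyed by the same iso3 set", call. = FALSE)
  }
  merged <- dplyr::inner_join(
    results,
    records[, c("iso3", "continent", "pop_0_19")],
    by = "iso3")
  cont <- merged %>%
    dplyr::group_by(.data$continent) %>%
    dplyr::summarise(
      mean_relative_cost_pct = if (weighting == "population") {
        if (sum(.data$pop_0_19) == 0) mean(.data$relative_cost_pct)
        else stats::weighted.mean(.data$relative_cost_pct, .data$pop_0_19)
      } else mean(.data$relative_cost_pct),
      total_absolute_cost = sum(.data$absolute_cost),
      n = dplyr::n(),
      .groups = "drop") %>%
    dplyr::arrange(match(.data$continent, continent_labels()))
  structure(list(
    continent_means = cont,
    global_total = sum(merged$absolute_cost),
    median_pct = stats::median(merged$relative_cost_pct),
    min_pct = min(merged$relative_cost_pct),
    max_pct = max(merged$relative_cost_pct),
    weighting = weighting
  ), class = "summary_table")
}

#' @export
print.summary_table <- function(x, ...) {
  cat("<summary_table> (", x$weighting, "-weighted continent means)\n", sep = "")
  print(as.data.frame(x$continent_means))
  cat(sprintf("Global total: $%s/yr\n",
              format(round(x$global_total), big.mark = ",", scientific = FALSE)))
  cat(sprintf("Country relative cost: median %.2f%%, range %.2f%%-%.2f%%\n",
              x$median_pct, x$min_pct, x$max_pct))
  invisible(x)
}
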