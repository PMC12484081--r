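#' Scenario specification
#'
#' A scenario is a named transformation of the inputs and assumptions used
#' in the exposure-approximation and dose-response steps. The named suite
#' (see [default_scenarios()]) mirrors the seven-column sensitivity layout:
#'
#' * `baseline` — degenerate distribution at the country mean BLL.
#' * `log-normal` — full distributional integration: log-normal fitted from
#'   (mean, share above 5 µg/dL), falling back to the two-exceedance fit
#'   when the mean-based fit is infeasible.
#' * `lower_bound` — baseline exposure with a lower-bound dose-response
#'   (reduced slope, positive no-effect threshold).
#' * `lower_ci` / `upper_ci` — degenerate at the lower/upper BLL interval
#'   bound (input-data variation).
#' * `increase_5` / `increase_10` — BLL location multiplied by 1.05 / 1.10
#'   before the distribution is built (an exposure increase, not a cost
#'   multiplier — the distinction matters under a nonlinear dose-response).
#'
#' @param name scenario name (unique within a suite).
#' @param family `"degenerate"` or `"lognormal"`.
#' @param mean_source which BLL field feeds the location: `"bll_mean"`,
#'   `"bll_lo"` or `"bll_hi"`.
#' @param bll_multiplier non-negative multiplier applied to the BLL location
#'   before distribution construction.
#' @param dr_variant optional [dose_response] override for this scenario.
#' @param root_policy root selection for the log-normal mean+exceedance fit,
#'   see [fit_lognormal_mean_exceedance()].
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name,
                          family = c("degenerate", "lognormal"),
                          mean_source = c("bll_mean", "bll_lo", "bll_hi"),
                          bll_multiplier = 1,
                          dr_variant = NULL,
                          root_policy = "smaller_sigma") {
  family <- match.arg(family)
  mean_source <- match.arg(mean_source)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("scenario name must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(bll_multiplier) || length(bll_multiplier) != 1L ||
      is.na(bll_multiplier) || bll_multiplier < 0) {
    stop("bll_multiplier must be a single non-negative number", call. = FALSE)
  }
  if (!is.null(dr_variant) && !inherits(dr_variant, "dose_response")) {
    stop("dr_variant must be a dose_response object or NULL", call. = FALSE)
  }
  structure(list(name = name, family = family, mean_source = mean_source,
                 bll_multiplier = as.numeric(bll_multiplier),
                 dr_variant = dr_variant, root_policy = root_policy),
            class = "scenario_spec")
}

#' The default seven-scenario sensitivity suite
#'
#' @param lower_bound_dr the dose-response used by the `lower_bound`
#'   scenario (default [default_dose_response]`("lower_bound")`).
#' @return Named list of [scenario_spec] objects.
#' @export
default_scenarios <- function(lower_bound_dr = default_dose_response("lower_bound")) {
  specs <- list(
    scenario_spec("baseline"),
    scenario_spec("log-normal", family = "lognormal",
                  root_policy = "match_second_exceedance"),
    scenario_spec("lower_bound", dr_variant = lower_bound_dr),
    scenario_spec("lower_ci", mean_source = "bll_lo"),
    scenario_spec("upper_ci", mean_source = "bll_hi"),
    scenario_spec("increase_5", bll_multiplier = 1.05),
    scenario_spec("increase_10", bll_multiplier = 1.10)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Apply a scenario to one country record
#'
#' Builds the exposure distribution (and the effective dose-response) a
#' scenario prescribes for one country. The BLL location is taken from
#' `spec$mean_source`, scaled by `spec$bll_multiplier`, and wrapped in the
#' scenario's distribution family. For the log-normal family the fit uses
#' (scaled mean, `p_gt5`); if that pair is infeasible, or `p_gt5` is absent,
#' the two-exceedance fit from (`p_gt5`, `p_gt10`) is tried (with the mean
#' rescaling applied as a location shift `log(multiplier)` on `mu`).
#'
#' @param record a single-row country record (tibble row or list).
#' @param spec a [scenario_spec].
#' @param dr the suite-level [dose_response]; `spec$dr_variant` overrides.
#' @return List with `dist` (an [exposure_dist]), `dr` (the effective
#'   [dose_response]) and `fit_note` (diagnostic string: which constructor
#'   and root were used).
#' @export
apply_scenario <- function(record, spec, dr = default_dose_response()) {
  stopifnot(inherits(spec, "scenario_spec"))
  eff_dr <- spec$dr_variant %||% dr
  loc <- record[[spec$mean_source]]
  if (is.null(loc) || is.na(loc)) {
    stop(sprintf("country %s: field %s required by scenario '%s' is absent",
                 record$iso3, spec$mean_source, spec$name), call. = FALSE)
  }
  loc <- loc * spec$bll_multiplier
  if (spec$family == "degenerate") {
    return(list(dist = dist_degenerate(loc), dr = eff_dr,
                fit_note = sprintf("degenerate@%.6g", loc)))
  }
  # log-normal family
  p5 <- record$p_gt5
  p10 <- record$p_gt10
  have_p5 <- !is.null(p5) && !is.na(p5) && p5 > 0 && p5 < 1
  have_p10 <- !is.null(p10) && !is.na(p10) && p10 > 0 && p10 < 1
  policy <- spec$root_policy
  if (policy == "match_second_exceedance" && !have_p10) policy <- "smaller_sigma"
  fit_from_mean <- function() {
    fit_lognormal_mean_exceedance(loc, p5, threshold = 5,
                                  root_policy = policy, p2 = p10)
  }
  if (have_p5) {
    fit <- tryCatch(fit_from_mean(), error = function(e) e)
    if (inherits(fit, "exposure_dist")) {
      note <- sprintf("lognormal:mean+p5 (%s, margin %.3g)", policy,
                      attr(fit, "feasibility_margin"))
      return(list(dist = fit, dr = eff_dr, fit_note = note))
    }
    if (have_p10 && p10 < p5) {
      fit2 <- fit_lognormal_two_exceedances(p5, p10)
      # honor the multiplier as a location shift in the log domain
      if (spec$bll_multiplier != 1) {
        if (spec$bll_multiplier == 0) {
          return(list(dist = dist_degenerate(0), dr = eff_dr,
                      fit_note = "degenerate@0 (zero multiplier)"))
        }
        fit2 <- dist_lognormal(fit2$params$mu + log(spec$bll_multiplier),
                               fit2$params$sigma)
      }
      return(list(dist = fit2, dr = eff_dr,
                  fit_note = paste0("lognormal:p5+p10 fallback (",
                                    conditionMessage(fit), ")")))
    }
    stop(sprintf("country %s, scenario '%s': %s", record$iso3, spec$name,
                 conditionMessage(fit)), call. = FALSE)
  }
  stop(sprintf("country %s: scenario '%s' needs exceedance data (p_gt5) for a log-normal fit",
               record$iso3, spec$name), call. = FALSE)
}

#' Run one scenario over a country table
#'
#' Executes the exposure-approximation, dose-response and monetization steps
#' for every country under one scenario. Deterministic for fixed inputs;
#' per-country failures are collected and reported together.
#'
#' @param records validated country records (tibble, one row per country).
#' @param spec a [scenario_spec].
#' @param dr suite-level [dose_response].
#' @param econ an [economic_params].
#' @param quad a [quad_settings].
#' @return Tibble with one row per country: `iso3`, `scenario`,
#'   `mean_iq_loss`, `relative_cost_pct`, `absolute_cost`, `fit_note`.
#' @export
run_scenario <- function(records, spec, dr = default_dose_response(),
                         econ = economic_params(), quad = quad_settings()) {
  failures <- character(0)
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    res <- tryCatch({
      app <- apply_scenario(rec, spec, dr)
      loss <- expected_iq_loss(app$dist, app$dr, quad)
      rel <- relative_iq_cost(loss, econ, rec$ret_edu)
      abs_ <- absolute_cost(rel, rec$gdp_pc, rec$pop_0_19)
      tibble::tibble(iso3 = rec$iso3, scenario = spec$name,
                     mean_iq_loss = loss, relative_cost_pct = rel,
                     absolute_cost = abs_, fit_note = app$fit_note)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("%s: %s", rec$iso3, res))
    } else {
      rows[[i]] <- res
    }
  }
  if (length(failures) > 0L) {
    stop("scenario '", spec$name, "' failed for ", length(failures),
         " country(ies):\n  ", paste(failures, collapse = "\n  "), call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Run the full sensitivity suite
#'
#' Runs every scenario in `suite` and assembles the continent-by-scenario
#' matrix: six continent rows of mean relative cost (percent) plus a Global
#' row of total absolute cost per scenario.
#'
#' @param records validated country records.
#' @param suite named list of [scenario_spec] objects (unique names).
#' @param dr,econ,quad shared model settings, as in [run_scenario()].
#' @param weighting continent-mean weighting, see [summarize_results()].
#' @return An object of class `sensitivity_matrix`: list with
#'   `matrix` (tibble, rows = continents + Global, one column per scenario),
#'   `results` (long per-country tibble across scenarios), `summaries`
#'   (per-scenario [summarize_results()] objects) and `weighting`.
#' @export
run_sensitivity_suite <- function(records, suite = default_scenarios(),
                                  dr = default_dose_response(),
                                  econ = economic_params(),
                                  quad = quad_settings(),
                                  weighting = c("population", "unweighted")) {
  weighting <- match.arg(weighting)
  nm <- vapply(suite, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("scenario names must be unique", call. = FALSE)
  all_results <- list()
  summaries <- list()
  for (spec in suite) {
    res <- run_scenario(records, spec, dr = dr, econ = econ, quad = quad)
    all_results[[spec$name]] <- res
    summaries[[spec$name]] <- summarize_results(res, records, weighting)
  }
  present <- intersect(continent_labels(), unique(records$continent))
  mat <- tibble::tibble(region = c(present, "Global"))
  for (name in nm) {
    s <- summaries[[name]]
    col <- s$continent_means$mean_relative_cost_pct[
      match(present, s$continent_means$continent)]
    mat[[name]] <- c(col, s$global_total)
  }
  structure(list(matrix = mat, results = dplyr::bind_rows(all_results),
                 summaries = summaries, weighting = weighting),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat("<sensitivity_matrix> continent mean relative cost (%) by scenario;\n",
      "Global row is total absolute cost ($/yr); ", x$weighting,
      "-weighted\n", sep = "")
  print(as.data.frame(x$matrix), digits = 4)
  invisible(x)
}
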