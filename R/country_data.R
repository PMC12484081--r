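#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Closed vocabulary for continent aggregation keys.
CONTINENTS <- c("Africa", "Asia", "Europe", "North America", "Oceania",
                "South/Central America")

#' Continent labels used for aggregation
#'
#' The six labels form a closed vocabulary; any other spelling is rejected at
#' read time so aggregation keys can never silently fragment.
#'
#' @return Character vector of the six continent labels.
#' @export
continent_labels <- function() CONTINENTS

default_schema <- function() {
  c(iso3 = "iso3", name = "name", continent = "continent",
    bll_mean = "bll_mean", bll_lo = "bll_lo", bll_hi = "bll_hi",
    p_gt5 = "p_gt5", p_gt10 = "p_gt10",
    gdp_pc = "gdp_pc", pop_0_19 = "pop0_19", ret_edu = "ret_edu")
}

#' Validate a table of country records
#'
#' Checks the typed invariants row by row:
#' `0 <= bll_lo <= bll_mean <= bll_hi`; `0 <= p_gt10 <= p_gt5 <= 1` when both
#' are present; `gdp_pc > 0`, `pop_0_19 >= 0`, `ret_edu > 0`; continent in
#' the closed six-label vocabulary; `iso3` unique three-letter codes.
#'
#' @param records a data frame of country records (package column names).
#' @return The input, invisibly, if valid; otherwise an error naming the
#'   offending iso3 and field.
#' @export
validate_country_records <- function(records) {
  required <- c("iso3", "name", "continent", "bll_mean", "bll_lo", "bll_hi",
                "gdp_pc", "pop_0_19", "ret_edu")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("p_gt5", "p_gt10")) {
    if (!opt %in% names(records)) records[[opt]] <- NA_real_
  }
  dup <- records$iso3[duplicated(records$iso3)]
  if (length(dup) > 0L) {
    stop("duplicate iso3 code(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  note <- function(iso3, field, msg) {
    problems <<- c(problems, sprintf("%s [%s]: %s", iso3, field, msg))
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    iso3 <- as.character(r$iso3)
    if (is.na(iso3) || nchar(iso3) != 3L) note(iso3, "iso3", "must be a 3-letter code")
    if (is.na(r$continent) || !r$continent %in% CONTINENTS) {
      note(iso3, "continent",
           sprintf("'%s' not one of: %s", r$continent,
                   paste(CONTINENTS, collapse = "; ")))
    }
    if (any(is.na(c(r$bll_mean, r$bll_lo, r$bll_hi)))) {
      note(iso3, "bll", "mean and interval bounds are mandatory")
    } else if (!(0 <= r$bll_lo && r$bll_lo <= r$bll_mean && r$bll_mean <= r$bll_hi)) {
      note(iso3, "bll", sprintf("need 0 <= lo <= mean <= hi, got lo=%g mean=%g hi=%g",
                                r$bll_lo, r$bll_mean, r$bll_hi))
    }
    if (!is.na(r$p_gt5) && (r$p_gt5 < 0 || r$p_gt5 > 1)) {
      note(iso3, "p_gt5", "must lie in [0, 1]")
    }
    if (!is.na(r$p_gt10) && (r$p_gt10 < 0 || r$p_gt10 > 1)) {
      note(iso3, "p_gt10", "must lie in [0, 1]")
    }
    if (!is.na(r$p_gt5) && !is.na(r$p_gt10) && r$p_gt10 > r$p_gt5) {
      note(iso3, "p_gt10", sprintf("exceedance at 10 (%g) cannot exceed exceedance at 5 (%g)",
                                   r$p_gt10, r$p_gt5))
    }
    if (is.na(r$gdp_pc) || r$gdp_pc <= 0) note(iso3, "gdp_pc", "must be > 0")
    if (is.na(r$pop_0_19) || r$pop_0_19 < 0 || r$pop_0_19 != round(r$pop_0_19)) {
      note(iso3, "pop_0_19", "must be a non-negative integer count")
    }
    if (is.na(r$ret_edu) || r$ret_edu <= 0) note(iso3, "ret_edu", "must be > 0")
  }
  if (length(problems) > 0L) {
    stop("invalid country record(s):\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(records)
}

#' Read a per-country input table
#'
#' Reads a comma-separated, UTF-8 table with one row per country: exposure
#' summaries (mean BLL with interval bounds, optional exceedance shares at 5
#' and 10 µg/dL) and economic covariates (GDP per capita in constant 2021
#' international dollars, population aged 0-19, returns to education). Empty
#' cells in the optional exceedance columns are kept as `NA`, never coerced
#' to 0 (0 is a meaningful exceedance value).
#'
#' @param path CSV file path; a header row is required.
#' @param schema named character vector mapping package field names to file
#'   column names; defaults to the canonical header
#'   `iso3,name,continent,bll_mean,bll_lo,bll_hi,p_gt5,p_gt10,gdp_pc,pop0_19,ret_edu`.
#' @return A tibble of validated country records in file order.
#' @export
read_country_table <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE, show_col_types = FALSE)
  optional <- c("p_gt5", "p_gt10")
  missing_cols <- setdiff(unname(schema[!names(schema) %in% optional]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- tibble::tibble(.rows = nrow(raw))
  for (field in names(schema)) {
    col <- schema[[field]]
    records[[field]] <- if (col %in% names(raw)) raw[[col]] else NA_real_
  }
  records$iso3 <- as.character(records$iso3)
  records$name <- as.character(records$name)
  records$continent <- as.character(records$continent)
  for (numcol in setdiff(names(records), c("iso3", "name", "continent"))) {
    records[[numcol]] <- as.numeric(records[[numcol]])
  }
  validate_country_records(records)
  records
}

#' Write a result table
#'
#' Writes a delimited (CSV) result table with stable column order and full
#' double precision (well beyond 10 significant digits), so a write/read
#' round trip is lossless.
#'
#' @param results non-empty data frame of per-country results.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("results must be a non-empty data frame", call. = FALSE)
  }
  readr::write_csv(results, path)
  invisible(path)
}

#' Economic valuation parameters
#'
#' * `e_us` — fractional lifetime-earnings loss per IQ point in the US
#'   reference economy (EPA-style human-capital valuation). Default 0.02
#'   (2% of lifetime earnings per IQ point), implementer-supplied from the
#'   public valuation literature.
#' * `r_us` — US returns to education, fraction per year of schooling.
#'   Default 0.10, the conventional US Mincerian return.
#' * `cap_pct` — ceiling on the relative cost in percent (default 100:
#'   foregone earnings cannot exceed earnings).
#'
#' @param e_us,r_us strictly positive fractions.
#' @param cap_pct in (0, 100].
#' @return An object of class `economic_params`.
#' @export
economic_params <- function(e_us = 0.02, r_us = 0.10, cap_pct = 100) {
  if (!is.numeric(e_us) || length(e_us) != 1L || is.na(e_us) || e_us <= 0) {
    stop("e_us must be > 0", call. = FALSE)
  }
  if (!is.numeric(r_us) || length(r_us) != 1L || is.na(r_us) || r_us <= 0) {
    stop("r_us must be > 0", call. = FALSE)
  }
  if (!is.numeric(cap_pct) || length(cap_pct) != 1L || is.na(cap_pct) ||
      cap_pct <= 0 || cap_pct > 100) {
    stop("cap_pct must lie in (0, 100]", call. = FALSE)
  }
  structure(list(e_us = e_us, r_us = r_us, cap_pct = cap_pct),
            class = "economic_params")
}

#' @export
print.economic_params <- function(x, ...) {
  cat(sprintf("<economic_params> e_us = %g, r_us = %g, cap_pct = %g%%\n",
              x$e_us, x$r_us, x$cap_pct))
  invisible(x)
}

default_config <- function() {
  list(
    economic = economic_params(),
    dose_response = default_dose_response("central"),
    scenarios = default_scenarios(),
    quad = quad_settings(),
    seed = 1L,
    weighting = "population"
  )
}

dr_from_list <- function(x) {
  if (inherits(x, "dose_response")) return(x)
  dose_response(form = x$form %||% "loglinear",
                coefficients = unlist(x$coefficients),
                knots = if (!is.null(x$knots)) unlist(x$knots),
                threshold = x$threshold %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a full run configuration
#'
#' Reads a YAML or JSON configuration file (dispatch on file extension) and
#' fills defaults for anything omitted. Recognized top-level keys:
#' `economic` (`e_us`, `r_us`, `cap_pct`), `dose_response` (`form`,
#' `coefficients`, `knots`, `threshold`), `scenarios` (list of scenario
#' definitions, see [scenario_spec()]), `quad` (`nodes`, `rel_tol`,
#' `max_nodes`), `seed`, `weighting` (`"population"` or `"unweighted"`).
#' Unknown keys are rejected; out-of-range values error through the type
#' constructors.
#'
#' @param path configuration file path (`.yaml`/`.yml` or `.json`); `NULL`
#'   returns the full default configuration.
#' @return A named list: `economic`, `dose_response`, `scenarios`, `quad`,
#'   `seed`, `weighting`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- c("economic", "dose_response", "scenarios", "quad", "seed", "weighting")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$economic)) {
    e <- raw$economic
    bad <- setdiff(names(e), c("e_us", "r_us", "cap_pct"))
    if (length(bad) > 0L) stop("unknown economic key(s): ",
                               paste(bad, collapse = ", "), call. = FALSE)
    cfg$economic <- economic_params(e_us = e$e_us %||% 0.02,
                                    r_us = e$r_us %||% 0.10,
                                    cap_pct = e$cap_pct %||% 100)
  }
  if (!is.null(raw$dose_response)) cfg$dose_response <- dr_from_list(raw$dose_response)
  if (!is.null(raw$quad)) {
    q <- raw$quad
    cfg$quad <- quad_settings(nodes = q$nodes %||% 128L,
                              rel_tol = q$rel_tol %||% 1e-9,
                              max_nodes = q$max_nodes %||% 1024L)
  }
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  if (!is.null(raw$weighting)) {
    cfg$weighting <- match.arg(raw$weighting, c("population", "unweighted"))
  }
  if (!is.null(raw$scenarios)) {
    cfg$scenarios <- lapply(raw$scenarios, function(s) {
      scenario_spec(name = s$name,
                    family = s$family %||% "degenerate",
                    mean_source = s$mean_source %||% "bll_mean",
                    bll_multiplier = s$bll_multiplier %||% 1,
                    dr_variant = if (!is.null(s$dr_variant)) dr_from_list(s$dr_variant))
    })
    names(cfg$scenarios) <- vapply(cfg$scenarios, `[[`, character(1), "name")
  }
  cfg
}

#' Serialize a run configuration
#'
#' Writes the configuration back out (YAML), so a load/serialize/load cycle
#' is semantically identical. Used by the CLI to echo the effective
#' configuration into the run manifest.
#'
#' @param cfg configuration list as returned by [load_config()].
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  as_plain <- function(x) {
    if (inherits(x, c("economic_params", "dose_response", "quad_settings",
                      "scenario_spec"))) {
      lapply(unclass(x), as_plain)
    } else if (is.list(x)) {
      lapply(x, as_plain)
    } else x
  }
  out <- list(economic = as_plain(cfg$economic),
              dose_response = as_plain(cfg$dose_response),
              scenarios = unname(lapply(cfg$scenarios, as_plain)),
              quad = as_plain(cfg$quad),
              seed = cfg$seed,
              weighting = cfg$weighting)
  drop_null <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, drop_null)
    x[!vapply(x, is.null, logical(1))]
  }
  yaml::write_yaml(drop_null(out), path)
  invisible(path)
}
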