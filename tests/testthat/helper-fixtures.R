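# Small in-code fixtures shared across tests.

# A hand-computable two-country world: country TOY has degenerate BLL 4,
# linear slope 0.5 gives IQ loss 2; with e_us 0.02, r_us 0.06, ret_edu 0.09
# the relative cost is 2 * 0.02 * 1.5 * 100 = 6%, and with gdp 10,000 and
# pop 1e6 the absolute cost is $6e8/yr. Country ZRO has zero exposure.
toy_records <- function() {
  tibble::tibble(
    iso3 = c("TOY", "ZRO"),
    name = c("Toyland", "Zeroland"),
    continent = c("Europe", "Europe"),
    bll_mean = c(4, 0), bll_lo = c(4, 0), bll_hi = c(4, 0),
    p_gt5 = NA_real_, p_gt10 = NA_real_,
    gdp_pc = c(10000, 20000), pop_0_19 = c(1e6, 5e5),
    ret_edu = c(0.09, 0.09)
  )
}

toy_econ <- function() economic_params(e_us = 0.02, r_us = 0.06, cap_pct = 100)

toy_linear_dr <- function() dose_response("linear", 0.5)

write_toy_csv <- function(records = toy_records(), path = tempfile(fileext = ".csv")) {
  out <- records
  names(out)[names(out) == "pop_0_19"] <- "pop0_19"
  readr::write_csv(out, path, na = "")
  path
}

# Random valid lognormal parameters on the scale of country BLL data.
random_lognormal_params <- function(n) {
  tibble::tibble(
    mu = stats::runif(n, log(0.5), log(15)),
    sigma = stats::runif(n, 0.2, 1.2)
  )
}
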