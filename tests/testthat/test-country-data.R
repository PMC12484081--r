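test_that("a well-formed file parses to identical records", {
  path <- write_toy_csv()
  rec <- read_country_table(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$iso3, c("TOY", "ZRO"))
  expect_equal(rec$bll_mean, c(4, 0))
  expect_equal(rec$gdp_pc, c(10000, 20000))
  expect_true(all(is.na(rec$p_gt5)))   # empty cells stay absent, never 0
  expect_equal(rec$ret_edu, c(0.09, 0.09))
})

test_that("write/read round trip is lossless at full precision", {
  rec <- toy_records()
  rec$bll_mean <- c(4.123456789012345, 1.987654321098765)
  rec$bll_lo <- rec$bll_mean; rec$bll_hi <- rec$bll_mean
  path <- write_toy_csv(rec)
  back <- read_country_table(path)
  expect_equal(back$bll_mean, rec$bll_mean, tolerance = 1e-12)

  res <- tibble::tibble(iso3 = "TOY", scenario = "baseline",
                        mean_iq_loss = 2.000000000123,
                        relative_cost_pct = 6.000000000456,
                        absolute_cost = 6.00000000089e8)
  rpath <- tempfile(fileext = ".csv")
  write_results(res, rpath)
  back2 <- readr::read_csv(rpath, show_col_types = FALSE)
  expect_equal(back2$relative_cost_pct, res$relative_cost_pct, tolerance = 1e-12)
  expect_error(write_results(res[0, ], tempfile()), "non-empty")
})

test_that("schema and invariant violations are reported with iso3 and field", {
  rec <- toy_records()
  rec$p_gt5[1] <- 0.1; rec$p_gt10[1] <- 0.3   # ordering violation
  path <- write_toy_csv(rec)
  err <- tryCatch(read_country_table(path), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "TOY")
  expect_match(conditionMessage(err), "p_gt10")

  # missing mandatory column named in the error
  raw <- readr::read_csv(write_toy_csv(), show_col_types = FALSE)
  raw$gdp_pc <- NULL
  p2 <- tempfile(fileext = ".csv")
  readr::write_csv(raw, p2, na = "")
  expect_error(read_country_table(p2), "gdp_pc")

  # duplicate iso3
  rec2 <- toy_records()
  rec2$iso3 <- c("TOY", "TOY")
  expect_error(read_country_table(write_toy_csv(rec2)), "duplicate iso3")

  # continent outside the closed vocabulary
  rec3 <- toy_records()
  rec3$continent[2] <- "Antarctica"
  expect_error(read_country_table(write_toy_csv(rec3)), "Antarctica")
})

test_that("validation accepts exactly the rows satisfying the invariants", {
  set.seed(99)
  for (i in 1:60) {
    rec <- toy_records()[1, ]
    m <- runif(1, 0.5, 15)
    rec$bll_mean <- m
    rec$bll_lo <- m * runif(1, 0.5, 1)
    rec$bll_hi <- m * runif(1, 1, 1.5)
    rec$p_gt5 <- runif(1)
    rec$p_gt10 <- runif(1, 0, rec$p_gt5)
    expect_silent(validate_country_records(rec))

    bad <- rec
    field <- sample(c("order", "gdp", "pop", "ret", "p"), 1)
    if (field == "order") bad$bll_lo <- bad$bll_hi + 1
    if (field == "gdp") bad$gdp_pc <- -1
    if (field == "pop") bad$pop_0_19 <- -5
    if (field == "ret") bad$ret_edu <- 0
    if (field == "p") { bad$p_gt5 <- 0.1; bad$p_gt10 <- 0.9 }
    expect_error(validate_country_records(bad), "invalid country record")
  }
})

test_that("economic_params enforces its ranges", {
  e <- economic_params()
  expect_equal(e$e_us, 0.02)
  expect_equal(e$r_us, 0.10)
  expect_equal(e$cap_pct, 100)
  expect_error(economic_params(e_us = 0), "e_us")
  expect_error(economic_params(r_us = -1), "r_us")
  expect_error(economic_params(cap_pct = 150), "cap_pct")
  expect_error(economic_params(cap_pct = 0), "cap_pct")
})

test_that("config loading fills defaults, rejects unknown keys and bad ranges", {
  cfg <- load_config(NULL)
  expect_s3_class(cfg$economic, "economic_params")
  expect_s3_class(cfg$dose_response, "dose_response")
  expect_equal(names(cfg$scenarios),
               c("baseline", "log-normal", "lower_bound", "lower_ci",
                 "upper_ci", "increase_5", "increase_10"))
  expect_equal(cfg$weighting, "population")

  # minimal YAML: only one economic override, everything else defaulted
  y <- tempfile(fileext = ".yaml")
  writeLines("economic:\n  e_us: 0.03", y)
  cfg2 <- load_config(y)
  expect_equal(cfg2$economic$e_us, 0.03)
  expect_equal(cfg2$economic$r_us, 0.10)
  expect_equal(cfg2$quad$nodes, 128L)

  writeLines("economic:\n  cap_pct: 150", y)
  expect_error(load_config(y), "cap_pct")

  writeLines("not_a_key: 1", y)
  expect_error(load_config(y), "unknown config key")

  # JSON dialect works too
  j <- tempfile(fileext = ".json")
  writeLines('{"seed": 7, "weighting": "unweighted"}', j)
  cfg3 <- load_config(j)
  expect_equal(cfg3$seed, 7L)
  expect_equal(cfg3$weighting, "unweighted")
})

test_that("a config survives a serialize/load cycle semantically intact", {
  cfg <- load_config(NULL)
  cfg$economic <- economic_params(e_us = 0.025, r_us = 0.08, cap_pct = 90)
  cfg$dose_response <- dose_response("loglinear", 2.5, threshold = 1)
  cfg$seed <- 42L
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- load_config(path)
  expect_equal(cfg2$economic, cfg$economic)
  expect_equal(cfg2$dose_response$form, cfg$dose_response$form)
  expect_equal(cfg2$dose_response$coefficients, cfg$dose_response$coefficients)
  expect_equal(cfg2$dose_response$threshold, cfg$dose_response$threshold)
  expect_equal(cfg2$seed, 42L)
  expect_equal(vapply(cfg2$scenarios, `[[`, character(1), "name"),
               vapply(cfg$scenarios, `[[`, character(1), "name"))
})
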