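test_that("exceedance matches the normal-CDF oracle and point-mass logic", {
  # degenerate point mass: indicator of point > threshold
  expect_equal(exceedance(dist_degenerate(4), 5), 0)
  expect_equal(exceedance(dist_degenerate(4), 3), 1)
  expect_equal(exceedance(make_degenerate(3.5), 3.5), 0) # strict exceedance

  # lognormal: oracle is the standard-normal CDF at (log(t) - mu)/sigma
  d <- dist_lognormal(1.2, 0.6)
  expect_equal(exceedance(d, 5), 1 - pnorm((log(5) - 1.2) / 0.6))
  expect_equal(exceedance(d, 5), 0.2474, tolerance = 5e-4)

  # monotone non-increasing in threshold
  ts <- seq(0.5, 30, length.out = 50)
  excs <- vapply(ts, function(t) exceedance(d, t), numeric(1))
  expect_true(all(diff(excs) <= 0))

  expect_error(exceedance(d, 0), "threshold")
  expect_error(exceedance(d, -1), "threshold")
})

test_that("distribution_mean gives the analytic family means", {
  expect_equal(distribution_mean(dist_degenerate(7.5)), 7.5)
  expect_equal(distribution_mean(dist_lognormal(1.2, 0.6)), exp(1.38))
  expect_equal(distribution_mean(dist_lognormal(1.2, 0.6)), 3.9749, tolerance = 1e-4)
  expect_equal(distribution_mean(dist_normal(6, 1)), 6)
})

test_that("mean+exceedance fit satisfies both constraints and honours root policy", {
  m <- exp(1.38)            # mean of lognormal(1.2, 0.6)
  p <- 1 - pnorm((log(5) - 1.2) / 0.6)

  fit_s <- fit_lognormal_mean_exceedance(m, p, 5, root_policy = "smaller_sigma")
  expect_equal(fit_s$params$sigma, 0.6, tolerance = 1e-10)
  expect_equal(fit_s$params$mu, 1.2, tolerance = 1e-10)
  expect_equal(distribution_mean(fit_s), m, tolerance = 1e-10)
  expect_equal(exceedance(fit_s, 5), p, tolerance = 1e-10)

  # the larger root also satisfies both constraints (verified directly)
  fit_l <- fit_lognormal_mean_exceedance(m, p, 5, root_policy = "larger_sigma")
  expect_gt(fit_l$params$sigma, fit_s$params$sigma)
  expect_equal(fit_l$params$sigma, 0.7648, tolerance = 1e-4)
  expect_equal(distribution_mean(fit_l), m, tolerance = 1e-10)
  expect_equal(exceedance(fit_l, 5), p, tolerance = 1e-10)

  # match_second_exceedance picks the root consistent with the share above 10
  p10 <- 1 - pnorm((log(10) - 1.2) / 0.6)
  fit_m <- fit_lognormal_mean_exceedance(m, p, 5,
                                         root_policy = "match_second_exceedance",
                                         p2 = p10)
  expect_equal(fit_m$params$sigma, 0.6, tolerance = 1e-10)
  expect_error(
    fit_lognormal_mean_exceedance(m, p, 5, root_policy = "match_second_exceedance"),
    "p2")
})

test_that("mean+exceedance fit rejects infeasible pairs with the admissible range", {
  # a lognormal with mean equal to the threshold cannot put 90% of its mass
  # above it (the quadratic has no positive sigma root)
  expect_error(fit_lognormal_mean_exceedance(5, 0.9, 5),
               "sigma root|infeasible")
  err <- tryCatch(fit_lognormal_mean_exceedance(2, 0.45, 5), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "outside")

  expect_error(fit_lognormal_mean_exceedance(3, 0, 5), "strictly inside")
  expect_error(fit_lognormal_mean_exceedance(3, 1, 5), "strictly inside")
  expect_error(fit_lognormal_mean_exceedance(-1, 0.2, 5), "positive")
})

test_that("feasibility boundary returns sigma equal to z", {
  # at the discriminant-zero edge, mean = threshold * exp(-z^2/2), sigma = z
  z <- 0.8
  p <- 1 - pnorm(z)
  m <- 5 * exp(-z^2 / 2)
  fit <- fit_lognormal_mean_exceedance(m, p, 5)
  expect_equal(fit$params$sigma, z, tolerance = 1e-7)
  expect_equal(attr(fit, "feasibility_margin"), 0, tolerance = 1e-12)
})

test_that("two-exceedance fit inverts the closed-form forward map", {
  p5 <- 1 - pnorm((log(5) - 1.2) / 0.6)
  p10 <- 1 - pnorm((log(10) - 1.2) / 0.6)
  expect_equal(p10, 0.03306, tolerance = 1e-4)
  fit <- fit_lognormal_two_exceedances(p5, p10)
  expect_equal(fit$params$mu, 1.2, tolerance = 1e-10)
  expect_equal(fit$params$sigma, 0.6, tolerance = 1e-10)
  expect_equal(exceedance(fit, 5), p5, tolerance = 1e-10)
  expect_equal(exceedance(fit, 10), p10, tolerance = 1e-10)

  expect_error(fit_lognormal_two_exceedances(0.5, 0.5), "ordering")
  expect_error(fit_lognormal_two_exceedances(0.2, 0.3), "ordering")
  expect_error(fit_lognormal_two_exceedances(0, 0.1), "strictly inside")
})

test_that("forward-then-fit round trip recovers random parameters", {
  set.seed(42)
  pars <- random_lognormal_params(300)
  for (i in seq_len(nrow(pars))) {
    mu <- pars$mu[i]; sigma <- pars$sigma[i]
    m <- exp(mu + sigma^2 / 2)
    p5 <- pnorm((log(5) - mu) / sigma, lower.tail = FALSE)
    p10 <- pnorm((log(10) - mu) / sigma, lower.tail = FALSE)
    if (p5 <= 1e-12 || p5 >= 1 - 1e-12 || p10 <= 1e-12) next

    f2 <- fit_lognormal_two_exceedances(p5, p10)
    expect_equal(f2$params$mu, mu, tolerance = 1e-8)
    expect_equal(f2$params$sigma, sigma, tolerance = 1e-8)

    f1 <- fit_lognormal_mean_exceedance(m, p5, 5,
                                        root_policy = "match_second_exceedance",
                                        p2 = p10)
    expect_equal(f1$params$mu, mu, tolerance = 1e-8)
    expect_equal(f1$params$sigma, sigma, tolerance = 1e-8)
  }
})

test_that("fitted sigma is monotone in the exceedance share at fixed mean", {
  m <- 3
  ps <- seq(0.02, 0.15, by = 0.01) # feasible, below-threshold mean branch
  sigmas <- vapply(ps, function(p) {
    fit_lognormal_mean_exceedance(m, p, 5, root_policy = "smaller_sigma")$params$sigma
  }, numeric(1))
  expect_true(all(diff(sigmas) > 0))
})

test_that("constructors validate their parameters", {
  expect_error(dist_degenerate(-1), "non-negative")
  expect_error(dist_lognormal(1, 0), "positive")
  expect_error(dist_normal(5, -1), "positive")
  expect_error(make_degenerate(-0.1), "non-negative")
  expect_s3_class(dist_degenerate(0), "exposure_dist")
})
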