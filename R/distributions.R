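#' Exposure distribution constructors
#'
#' An `exposure_dist` is a parametric model of the blood lead level (BLL)
#' distribution among 0-19-year-olds in one country. Three families are
#' supported:
#'
#' * `degenerate` — a point mass at the country mean; every child is assigned
#'   the mean BLL.
#' * `normal` — location/scale on the µg/dL scale; because BLL is
#'   non-negative, integration routines truncate this family at 0 and
#'   renormalize.
#' * `lognormal` — `mu` (log-µg/dL) and `sigma` (dimensionless), the family
#'   used for full distributional integration.
#'
#' @param point,location µg/dL, non-negative.
#' @param scale,sigma strictly positive dispersion parameter.
#' @param mu log-scale location (log µg/dL); may be any real number.
#' @return An object of class `exposure_dist`.
#' @examples
#' dist_lognormal(1.2, 0.6)
#' dist_degenerate(3.5)
#' @name exposure_dist
NULL

new_exposure_dist <- function(family, params) {
  structure(list(family = family, params = params), class = "exposure_dist")
}

#' @rdname exposure_dist
#' @export
dist_degenerate <- function(point) {
  if (!is.numeric(point) || length(point) != 1L || is.na(point) || point < 0) {
    stop("degenerate point mass must be a single non-negative number", call. = FALSE)
  }
  new_exposure_dist("degenerate", list(point = as.numeric(point)))
}

#' @rdname exposure_dist
#' @export
dist_normal <- function(location, scale) {
  if (!is.numeric(location) || length(location) != 1L || is.na(location) || location < 0) {
    stop("normal location must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0) {
    stop("normal scale must be strictly positive", call. = FALSE)
  }
  new_exposure_dist("normal", list(location = as.numeric(location),
                                   scale = as.numeric(scale)))
}

#' @rdname exposure_dist
#' @export
dist_lognormal <- function(mu, sigma) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu)) {
    stop("lognormal mu must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop("lognormal sigma must be strictly positive", call. = FALSE)
  }
  new_exposure_dist("lognormal", list(mu = as.numeric(mu),
                                      sigma = as.numeric(sigma)))
}

#' Point mass at a country mean BLL
#'
#' Baseline representation: everyone in the country carries the mean BLL.
#'
#' @param mean country mean BLL in µg/dL, non-negative.
#' @return A degenerate `exposure_dist`.
#' @export
make_degenerate <- function(mean) dist_degenerate(mean)

#' @export
print.exposure_dist <- function(x, ...) {
  p <- vapply(x$params, function(v) format(v, digits = 6), character(1))
  cat("<exposure_dist> ", x$family, "(",
      paste(names(p), p, sep = " = ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Exceedance fraction of an exposure distribution
#'
#' Share of the population with BLL strictly above `threshold`, e.g. the
#' fraction of children above 5 µg/dL (the US level of concern, 2012-2021).
#'
#' @param dist an [exposure_dist] object.
#' @param threshold BLL threshold in µg/dL, strictly positive.
#' @return Fraction in \[0, 1\].
#' @examples
#' exceedance(dist_lognormal(1.2, 0.6), 5) # ~0.2474
#' @export
exceedance <- function(dist, threshold) {
  stopifnot(inherits(dist, "exposure_dist"))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0) {
    stop("threshold must be a single positive number (µg/dL)", call. = FALSE)
  }
  switch(dist$family,
    degenerate = as.numeric(dist$params$point > threshold),
    lognormal = stats::pnorm((log(threshold) - dist$params$mu) / dist$params$sigma,
                             lower.tail = FALSE),
    normal = {
      # truncated at 0, renormalized
      loc <- dist$params$location; sc <- dist$params$scale
      upper <- stats::pnorm(threshold, loc, sc, lower.tail = FALSE)
      below0 <- stats::pnorm(0, loc, sc)
      upper / (1 - below0)
    })
}

#' Analytic mean of an exposure distribution
#'
#' For the log-normal family this is `exp(mu + sigma^2/2)`; for the normal
#' family the pre-truncation location is returned (the truncation correction
#' is applied only inside integration).
#'
#' @param dist an [exposure_dist] object.
#' @return Mean BLL in µg/dL.
#' @export
distribution_mean <- function(dist) {
  stopifnot(inherits(dist, "exposure_dist"))
  switch(dist$family,
    degenerate = dist$params$point,
    lognormal = exp(dist$params$mu + dist$params$sigma^2 / 2),
    normal = dist$params$location)
}

#' Fit a log-normal BLL distribution from a mean and one exceedance share
#'
#' Finds `(mu, sigma)` such that the log-normal mean equals `mean` and
#' `P(BLL > threshold) = p`. With `z = qnorm(1 - p)`, `sigma` solves the
#' quadratic `sigma^2/2 - z*sigma + log(threshold/mean) = 0` and
#' `mu = log(threshold) - sigma*z`. When the country mean lies below the
#' threshold the quadratic can have two positive roots; `root_policy`
#' selects:
#'
#' * `"smaller_sigma"` (default) — the less dispersed solution; under a
#'   concave dose-response this is the conservative choice.
#' * `"larger_sigma"` — the more dispersed solution.
#' * `"match_second_exceedance"` — the root whose implied exceedance at
#'   `threshold2` is closest (squared error) to `p2`; requires `p2`.
#'
#' @param mean country mean BLL, µg/dL, > 0.
#' @param p exceedance fraction at `threshold`, strictly inside (0, 1).
#' @param threshold µg/dL, > 0 (default 5).
#' @param root_policy root selection rule, see Details.
#' @param p2,threshold2 second exceedance share and its threshold (default
#'   10 µg/dL), used only by `"match_second_exceedance"`.
#' @return A lognormal [exposure_dist] reproducing both constraints to
#'   near machine precision, with attributes `roots` (candidate sigmas) and
#'   `feasibility_margin` (the quadratic discriminant).
#' @examples
#' fit_lognormal_mean_exceedance(exp(1.38), 0.2474, 5)
#' @export
fit_lognormal_mean_exceedance <- function(mean, p, threshold = 5,
                                          root_policy = c("smaller_sigma",
                                                          "larger_sigma",
                                                          "match_second_exceedance"),
                                          p2 = NULL, threshold2 = 10) {
  root_policy <- match.arg(root_policy)
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean) || mean <= 0) {
    stop("mean must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop("exceedance p must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be positive", call. = FALSE)
  }
  z <- stats::qnorm(p, lower.tail = FALSE)
  disc <- z^2 + 2 * log(mean / threshold)
  if (disc < 0) {
    # admissible p range for this mean: |z| >= sqrt(2*log(threshold/mean))
    zmin <- sqrt(2 * log(threshold / mean))
    p_lo <- stats::pnorm(zmin, lower.tail = FALSE)
    p_hi <- stats::pnorm(-zmin, lower.tail = FALSE)
    stop(sprintf(paste0("infeasible mean/exceedance pair: with mean %.6g and ",
                        "threshold %.6g the exceedance must lie outside ",
                        "(%.6g, %.6g)"), mean, threshold, p_lo, p_hi),
         call. = FALSE)
  }
  roots <- sort(c(z - sqrt(disc), z + sqrt(disc)))
  roots <- roots[roots > 0]
  if (length(roots) == 0L) {
    stop("no positive sigma root; exceedance is inconsistent with the mean",
         call. = FALSE)
  }
  sigma <- if (length(roots) == 1L) {
    roots
  } else {
    switch(root_policy,
      smaller_sigma = roots[1L],
      larger_sigma = roots[2L],
      match_second_exceedance = {
        if (is.null(p2) || is.na(p2)) {
          stop("root_policy 'match_second_exceedance' requires p2", call. = FALSE)
        }
        err <- vapply(roots, function(s) {
          mu_s <- log(threshold) - s * z
          (stats::pnorm((log(threshold2) - mu_s) / s, lower.tail = FALSE) - p2)^2
        }, numeric(1))
        roots[which.min(err)]
      })
  }
  mu <- log(threshold) - sigma * z
  out <- dist_lognormal(mu, sigma)
  attr(out, "roots") <- roots
  attr(out, "feasibility_margin") <- disc
  out
}

#' Fit a log-normal BLL distribution from two exceedance shares
#'
#' Closed-form two-quantile fit: with `zk = qnorm(1 - pk)`,
#' `sigma = (log(t2) - log(t1)) / (z2 - z1)` and `mu = log(t1) - sigma*z1`.
#'
#' @param p5 exceedance fraction at `t1` (default threshold 5 µg/dL).
#' @param p10 exceedance fraction at `t2` (default threshold 10 µg/dL);
#'   must be strictly smaller than `p5`.
#' @param t1,t2 thresholds in µg/dL with `t2 > t1 > 0`.
#' @return A lognormal [exposure_dist] reproducing both exceedances.
#' @examples
#' fit_lognormal_two_exceedances(0.2474, 0.03306)
#' @export
fit_lognormal_two_exceedances <- function(p5, p10, t1 = 5, t2 = 10) {
  for (p in list(p5 = p5, p10 = p10)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
      stop("exceedance fractions must lie strictly inside (0, 1)", call. = FALSE)
    }
  }
  if (!(t2 > t1 && t1 > 0)) stop("thresholds must satisfy t2 > t1 > 0", call. = FALSE)
  if (p10 >= p5) {
    stop("exceedance ordering violated: need p10 < p5 (mass above 10 µg/dL ",
         "cannot exceed mass above 5 µg/dL)", call. = FALSE)
  }
  z1 <- stats::qnorm(p5, lower.tail = FALSE)
  z2 <- stats::qnorm(p10, lower.tail = FALSE)
  sigma <- (log(t2) - log(t1)) / (z2 - z1)
  mu <- log(t1) - sigma * z1
  dist_lognormal(mu, sigma)
}
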