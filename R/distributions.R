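#' Distribution specification
#'
#' A lightweight container describing the sampling distribution assumed for
#' one model input in the probabilistic sensitivity analysis: Beta for
#' probabilities and utilities, Gamma for costs, lognormal for multiplicative
#' risk parameters, normal for log odds ratios.
#'
#' @param family one of `"beta"`, `"gamma"`, `"lognormal"`, `"normal"`.
#' @param ... family-specific hyperparameters (`shape1`/`shape2` for beta,
#'   `shape`/`scale` for gamma, `meanlog`/`sdlog` for lognormal,
#'   `mean`/`sd` for normal).
#' @param anchor_mean,anchor_ci_low,anchor_ci_high optional anchors recording
#'   the published or assumed mean and 95% interval the spec was fitted to.
#' @return an object of class `dist_spec`.
#' @export
dist_spec <- function(family, ..., anchor_mean = NA_real_,
                      anchor_ci_low = NA_real_, anchor_ci_high = NA_real_) {
  family <- match.arg(family, c("beta", "gamma", "lognormal", "normal"))
  hyper <- list(...)
  needed <- switch(family,
    beta = c("shape1", "shape2"),
    gamma = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"),
    normal = c("mean", "sd")
  )
  missing <- setdiff(needed, names(hyper))
  if (length(missing)) {
    stop("dist_spec('", family, "') requires hyperparameters: ",
         paste(missing, collapse = ", "))
  }
  if (family %in% c("beta", "gamma")) {
    for (h in needed) {
      if (!is.finite(hyper[[h]]) || hyper[[h]] <= 0) {
        stop("dist_spec: hyperparameter '", h, "' must be positive, got ",
             hyper[[h]])
      }
    }
  } else {
    sd_par <- if (family == "normal") "sd" else "sdlog"
    if (!is.finite(hyper[[sd_par]]) || hyper[[sd_par]] < 0) {
      stop("dist_spec: hyperparameter '", sd_par, "' must be non-negative")
    }
  }
  if (!is.na(anchor_ci_low) && !is.na(anchor_ci_high) && !is.na(anchor_mean)) {
    if (anchor_mean < anchor_ci_low || anchor_mean > anchor_ci_high) {
      stop("dist_spec: anchor_mean must lie inside [anchor_ci_low, anchor_ci_high]")
    }
  }
  structure(
    list(family = family, hyper = hyper[needed],
         anchor_mean = anchor_mean, anchor_ci_low = anchor_ci_low,
         anchor_ci_high = anchor_ci_high),
    class = "dist_spec"
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  hy <- paste(names(x$hyper), signif(unlist(x$hyper), 5), sep = " = ",
              collapse = ", ")
  cat("<dist_spec ", x$family, ": ", hy, ">\n", sep = "")
  invisible(x)
}

#' Mean of a distribution spec
#' @param spec a [dist_spec()].
#' @return the analytic mean of the distribution.
#' @export
spec_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  h <- spec$hyper
  switch(spec$family,
    beta = h$shape1 / (h$shape1 + h$shape2),
    gamma = h$shape * h$scale,
    lognormal = exp(h$meanlog + h$sdlog^2 / 2),
    normal = h$mean
  )
}

#' Quantiles of a distribution spec
#' @param spec a [dist_spec()].
#' @param p vector of probabilities.
#' @export
spec_quantile <- function(spec, p) {
  stopifnot(inherits(spec, "dist_spec"))
  h <- spec$hyper
  switch(spec$family,
    beta = stats::qbeta(p, h$shape1, h$shape2),
    gamma = stats::qgamma(p, shape = h$shape, scale = h$scale),
    lognormal = stats::qlnorm(p, h$meanlog, h$sdlog),
    normal = stats::qnorm(p, h$mean, h$sd)
  )
}

#' Draw from a distribution spec
#'
#' Uses the current RNG state; callers are responsible for seeding.
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @export
spec_sample <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  h <- spec$hyper
  switch(spec$family,
    beta = stats::rbeta(n, h$shape1, h$shape2),
    gamma = stats::rgamma(n, shape = h$shape, scale = h$scale),
    lognormal = stats::rlnorm(n, h$meanlog, h$sdlog),
    normal = stats::rnorm(n, h$mean, h$sd)
  )
}

#' Fit a Beta distribution to a mean and 95% interval
#'
#' Moment-matches a Beta distribution to the stated mean, then refines the
#' concentration (effective sample size) numerically so that the 2.5% and
#' 97.5% quantiles reproduce the stated interval as closely as a
#' two-parameter Beta allows, holding the mean exact. Used to turn published
#' point estimates with credible intervals (e.g. annual relapse
#' probabilities) into sampling distributions.
#'
#' @param mean point estimate in (0, 1).
#' @param lo,hi 95% interval bounds, 0 < lo <= mean <= hi < 1.
#' @param tol maximum acceptable root-mean-square residual between the fitted
#'   and requested interval bounds (default 0.25 times the interval
#'   half-width; asymmetric intervals cannot be matched exactly).
#' @return a `dist_spec` of family beta with the anchors recorded.
#' @export
fit_beta_from_mean_ci <- function(mean, lo, hi, tol = NULL) {
  if (!(lo > 0 && hi < 1 && lo <= mean && mean <= hi && mean > 0 && mean < 1)) {
    stop("fit_beta_from_mean_ci: need 0 < lo <= mean <= hi < 1")
  }
  if (lo == hi) stop("fit_beta_from_mean_ci: degenerate interval")
  if (is.null(tol)) tol <- 0.25 * (hi - lo)
  # Parameterize by log concentration kappa; mean fixed => shape1 = mean*kappa.
  resid <- function(log_kappa) {
    k <- exp(log_kappa)
    q <- stats::qbeta(c(0.025, 0.975), mean * k, (1 - mean) * k)
    sqrt(mean((q - c(lo, hi))^2))
  }
  opt <- stats::optimize(resid, interval = c(log(2.1), log(1e9)))
  k <- exp(opt$minimum)
  if (opt$objective > tol) {
    stop(sprintf(
      "fit_beta_from_mean_ci: no Beta with mean %.4g attains interval (%.4g, %.4g); best RMS residual %.4g exceeds tolerance %.4g",
      mean, lo, hi, opt$objective, tol))
  }
  dist_spec("beta", shape1 = mean * k, shape2 = (1 - mean) * k,
            anchor_mean = mean, anchor_ci_low = lo, anchor_ci_high = hi)
}

#' Fit a Gamma distribution to a mean and standard deviation
#'
#' Exact moment match: shape = mean^2 / sd^2, scale = sd^2 / mean. This is
#' the conventional parameterisation for cost inputs in decision-analytic
#' models, where costs are assumed Gamma distributed.
#'
#' @param mean,sd positive mean and standard deviation (GBP).
#' @return a `dist_spec` of family gamma.
#' @export
fit_gamma_from_mean_sd <- function(mean, sd) {
  if (!(is.numeric(mean) && is.numeric(sd) && mean > 0 && sd > 0)) {
    stop("fit_gamma_from_mean_sd: mean and sd must be positive")
  }
  dist_spec("gamma", shape = mean^2 / sd^2, scale = sd^2 / mean,
            anchor_mean = mean)
}

#' Fit a Beta distribution to a mean and standard deviation
#'
#' Exact moment match on [0, 1]; requires sd^2 < mean (1 - mean).
#'
#' @param mean mean in (0, 1).
#' @param sd standard deviation.
#' @return a `dist_spec` of family beta.
#' @export
fit_beta_from_mean_sd <- function(mean, sd) {
  if (!(mean > 0 && mean < 1 && sd > 0)) {
    stop("fit_beta_from_mean_sd: need mean in (0,1) and sd > 0")
  }
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("fit_beta_from_mean_sd: variance too large for a Beta with this mean")
  }
  k <- mean * (1 - mean) / v - 1
  dist_spec("beta", shape1 = mean * k, shape2 = (1 - mean) * k,
            anchor_mean = mean)
}
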