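# Synthetic posterior draws for the relative treatment effects.
#
# The model consumes posterior-style draw matrices of log odds ratios versus
# NRT standard, one column per intervention, for two outcomes: one-year
# sustained abstinence and major adverse neuropsychiatric events (MANE).
# Real posteriors come from a Bayesian network meta-analysis; here they are
# emulated as correlated multivariate normals on the log-OR scale,
# calibrated so that the induced mapped probabilities reproduce published
# (or synthetic) anchor means and intervals.

# Expected mapped probability E[inv_logit(l0 + mu + sd*Z)], Z ~ N(0,1),
# by adaptive quadrature.
mapped_prob_mean <- function(l0, mu, sd) {
  if (sd == 0) return(inv_logit(l0 + mu))
  stats::integrate(function(z) inv_logit(l0 + mu + sd * z) * stats::dnorm(z),
                   -8, 8, rel.tol = 1e-9)$value
}

# Calibrate (mu, sd) of a normal log-OR against an anchor (mean, lo, hi) of
# the mapped probability at baseline p0. The interval fixes sd (interval
# width on the log-odds scale); mu is then solved so the induced mean of the
# mapped probability equals the anchor mean exactly. With two free
# parameters the mean and interval width are matched; interval asymmetry is
# approximate.
calibrate_log_or <- function(p0, mean, lo, hi) {
  l0 <- logit(p0)
  sd <- if (is.na(lo) || is.na(hi)) 0 else (logit(hi) - logit(lo)) / (2 * stats::qnorm(0.975))
  centre <- logit(mean) - l0
  if (sd == 0) return(c(mu = centre, sd = 0))
  f <- function(mu) mapped_prob_mean(l0, mu, sd) - mean
  mu <- stats::uniroot(f, interval = centre + c(-4, 4), extendInt = "yes",
                       tol = 1e-10)$root
  c(mu = mu, sd = sd)
}

#' Generate synthetic posterior draws of relative effects
#'
#' Draws `n` correlated multivariate-normal samples of log odds ratios
#' (versus NRT standard) for each outcome, calibrated so that the mapped
#' one-year probabilities `inv_logit(logit(p0) + log OR)` recover the anchor
#' means within Monte-Carlo tolerance. The NRT-standard column is
#' identically zero; interventions without MANE anchors get an `NA` column,
#' to be resolved through the harm-assumption map at profile-building time.
#'
#' @param abstinence_anchors,mane_anchors data.frames with columns
#'   `intervention_id`, `mean`, `lo`, `hi` (rows of `NA` mean "no direct
#'   evidence"); defaults [default_abstinence_anchors()] /
#'   [default_mane_anchors()].
#' @param baseline_risks the baseline risk list of a [cea_params()] object
#'   (NRT-standard one-year probabilities).
#' @param n number of draws.
#' @param seed RNG seed.
#' @param correlation either a single exchangeable correlation in \[0, 1)
#'   applied across intervention columns (default 0.3), or a full positive
#'   semi-definite correlation matrix.
#' @return an object of class `relative_effects_draws`: list with
#'   `intervention_ids`, draw matrices `log_or_abstinence` and
#'   `log_or_mane` (`n` rows), `n_draws`, `seed`.
#' @export
generate_nma_draws <- function(abstinence_anchors = default_abstinence_anchors(),
                               mane_anchors = default_mane_anchors(),
                               baseline_risks,
                               n, seed = 1L, correlation = 0.3) {
  ids <- abstinence_anchors$intervention_id
  stopifnot(identical(ids, mane_anchors$intervention_id))
  k <- length(ids)
  ref <- "nrt_std"
  if (!ref %in% ids) stop("roster must contain the reference 'nrt_std'")

  corr_chol <- function(m) {
    if (is.matrix(correlation)) {
      R <- correlation[seq_len(m), seq_len(m), drop = FALSE]
    } else {
      R <- matrix(correlation, m, m)
      diag(R) <- 1
    }
    out <- tryCatch(chol(R), error = function(e) {
      stop("correlation matrix decomposition failed (not positive definite): ",
           conditionMessage(e))
    })
    out
  }

  draw_block <- function(anchors, p0) {
    active <- !is.na(anchors$mean) & anchors$intervention_id != ref
    m <- sum(active)
    mus <- sds <- numeric(m)
    aa <- anchors[active, , drop = FALSE]
    for (i in seq_len(m)) {
      cal <- calibrate_log_or(p0, aa$mean[i], aa$lo[i], aa$hi[i])
      mus[i] <- cal["mu"]; sds[i] <- cal["sd"]
    }
    Z <- matrix(stats::rnorm(n * m), n, m)
    if (m > 1) Z <- Z %*% corr_chol(m)
    draws <- sweep(sweep(Z, 2, sds, `*`), 2, mus, `+`)
    out <- matrix(NA_real_, n, length(anchors$intervention_id),
                  dimnames = list(NULL, anchors$intervention_id))
    out[, aa$intervention_id] <- draws
    out[, ref] <- 0
    out
  }

  set.seed(as.integer(seed))
  abst <- draw_block(abstinence_anchors, baseline_risks$p_abstain_nrt_std)
  mane <- draw_block(mane_anchors, baseline_risks$p_depression_nrt_std)

  structure(
    list(intervention_ids = ids, log_or_abstinence = abst,
         log_or_mane = mane, n_draws = n, seed = as.integer(seed)),
    class = "relative_effects_draws"
  )
}

#' @export
print.relative_effects_draws <- function(x, ...) {
  cat("<relative_effects_draws: ", x$n_draws, " draws x ",
      length(x$intervention_ids), " interventions (seed ", x$seed, ")>\n",
      sep = "")
  invisible(x)
}

#' Extract one draw of the relative effects
#'
#' @param draws a `relative_effects_draws` object.
#' @param i draw index.
#' @return list with named vectors `log_or_abstinence` and `log_or_mane`
#'   (the latter with `NA` for interventions without direct evidence),
#'   suitable as the `relative_effects` slot of a [cea_params()] object.
#' @export
re_slice <- function(draws, i) {
  stopifnot(inherits(draws, "relative_effects_draws"),
            i >= 1, i <= draws$n_draws)
  list(log_or_abstinence = draws$log_or_abstinence[i, ],
       log_or_mane = draws$log_or_mane[i, ])
}
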