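# Decision outputs: expected outcomes, dominance-aware frontier, net
# benefit, acceptability curves, rank-o-grams.

#' Expected costs and QALYs per intervention
#'
#' @param m an [nb_matrix()].
#' @return data.frame with `intervention_id`, `cost`, `qaly` (arithmetic
#'   means over draws).
#' @export
expected_outcomes <- function(m) {
  stopifnot(inherits(m, "nb_matrix"))
  if (nrow(m$cost) < 1) stop("expected_outcomes: empty net-benefit matrix")
  data.frame(intervention_id = m$interventions,
             cost = unname(colMeans(m$cost)),
             qaly = unname(colMeans(m$qaly)),
             stringsAsFactors = FALSE)
}

#' Efficiency frontier with simple and extended dominance
#'
#' Standard incremental analysis: interventions are sorted by mean cost;
#' any option with lower QALYs at a higher (or equal) cost than another is
#' dominated; among the rest, options whose sequential incremental
#' cost-effectiveness ratio exceeds that of the next more effective option
#' are removed as extendedly dominated (they are beaten by a mixture of two
#' alternatives), iterating until the frontier's sequential ICERs are
#' strictly increasing.
#'
#' Cost ties keep the higher-QALY member; an exact (cost, QALY) tie
#' collapses onto the first-listed member, the other being labelled
#' dominated.
#'
#' @param points data.frame with columns `intervention_id`, `cost`, `qaly`
#'   (e.g. [expected_outcomes()] output).
#' @return a `frontier_report`: the input ordered by mean cost with added
#'   `status` (`"frontier"`, `"dominated"`, `"extendedly_dominated"`) and
#'   `icer` (sequential ICER versus the previous frontier member; `NA` for
#'   the least-cost anchor and for non-frontier rows).
#' @export
efficiency_frontier <- function(points) {
  stopifnot(all(c("intervention_id", "cost", "qaly") %in% names(points)),
            nrow(points) >= 1)
  pts <- points[order(points$cost, -points$qaly), , drop = FALSE]
  n <- nrow(pts)
  status <- rep("frontier", n)

  # simple dominance: cheaper (or equal-cost) option with >= QALYs exists,
  # at least one relation strict
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    dom <- (pts$cost[others] <= pts$cost[i] &
              pts$qaly[others] >= pts$qaly[i]) &
      (pts$cost[others] < pts$cost[i] | pts$qaly[others] > pts$qaly[i])
    exact_tie_earlier <- others < i & pts$cost[others] == pts$cost[i] &
      pts$qaly[others] == pts$qaly[i]
    if (any(dom) || any(exact_tie_earlier)) status[i] <- "dominated"
  }

  # extended dominance on the surviving candidates
  repeat {
    cand <- which(status == "frontier")
    if (length(cand) <= 2) break
    icers <- diff(pts$cost[cand]) / diff(pts$qaly[cand])
    bad <- which(diff(icers) <= 0)
    if (!length(bad)) break
    # the interior point whose ICER is not lower than the next one is
    # extendedly dominated
    status[cand[bad[1] + 1]] <- "extendedly_dominated"
  }

  cand <- which(status == "frontier")
  icer <- rep(NA_real_, n)
  if (length(cand) > 1) {
    icer[cand[-1]] <- diff(pts$cost[cand]) / diff(pts$qaly[cand])
  }
  out <- data.frame(intervention_id = pts$intervention_id,
                    cost = pts$cost, qaly = pts$qaly,
                    status = status, icer = icer,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("frontier_report", "data.frame")
  out
}

#' Incremental expected net benefit versus a reference intervention
#'
#' Computes, per draw, `NB_i - NB_ref` at the given threshold and reports
#' its mean with a 95% bootstrap percentile interval of the mean (seeded by
#' the caller's RNG state). The reference's ENB is identically zero.
#'
#' @param m an [nb_matrix()].
#' @param wtp willingness-to-pay threshold (GBP/QALY).
#' @param reference reference intervention id (default `"nrt_low"`, the
#'   least-cost option, matching the reporting convention of the published
#'   tables; the methods reference for baseline risks remains NRT
#'   standard).
#' @param boot_R bootstrap resamples for the interval.
#' @return data.frame with `intervention_id`, `enb`, `lo`, `hi`.
#' @export
net_benefit <- function(m, wtp, reference = "nrt_low", boot_R = 1000) {
  stopifnot(inherits(m, "nb_matrix"))
  if (!reference %in% m$interventions) {
    stop("unknown reference intervention: ", reference)
  }
  nb <- net_benefit_draws(m, wtp)
  inc <- nb - nb[, reference]
  n <- nrow(inc)
  means <- colMeans(inc)
  if (boot_R > 0 && n > 1) {
    idx <- matrix(sample.int(n, n * boot_R, replace = TRUE), n, boot_R)
    boot_means <- apply(inc, 2, function(col) {
      colMeans(matrix(col[idx], n, boot_R))
    })
    ci <- apply(boot_means, 2, stats::quantile, probs = c(0.025, 0.975))
  } else {
    ci <- rbind(means, means)
  }
  out <- data.frame(intervention_id = m$interventions,
                    enb = unname(means),
                    lo = unname(ci[1, ]), hi = unname(ci[2, ]),
                    stringsAsFactors = FALSE)
  out[out$intervention_id == reference, c("enb", "lo", "hi")] <- 0
  out
}

#' Cost-effectiveness acceptability curves
#'
#' At each threshold, the fraction of draws in which each intervention
#' attains the maximum net benefit; exact ties split their weight equally.
#' Curves sum to one at every threshold.
#'
#' @param m an [nb_matrix()].
#' @param wtp_grid vector of thresholds.
#' @return data.frame with columns `wtp` and one probability column per
#'   intervention.
#' @export
ceac <- function(m, wtp_grid) {
  stopifnot(inherits(m, "nb_matrix"), length(wtp_grid) >= 1)
  n <- nrow(m$cost)
  out <- vapply(wtp_grid, function(l) {
    nb <- net_benefit_draws(m, l)
    best <- nb == matrixStats_rowMax(nb)
    w <- best / rowSums(best)
    colSums(w) / n
  }, numeric(length(m$interventions)))
  out <- t(out)
  colnames(out) <- m$interventions
  data.frame(wtp = wtp_grid, out, check.names = FALSE)
}

# rowMaxs without a matrixStats dependency
matrixStats_rowMax <- function(x) {
  do.call(pmax, as.data.frame(x))
}

#' Rank-o-gram: the distribution of cost-effectiveness ranks
#'
#' Ranks interventions by net benefit within each draw (rank 1 = highest
#' net benefit); exact ties share their probability mass equally over the
#' rank positions the tied group spans. Returns the rank-probability
#' matrix (doubly stochastic) together with each intervention's median rank
#' and interquartile range.
#'
#' @param m an [nb_matrix()].
#' @param wtp willingness-to-pay threshold.
#' @return list of class `rankogram` with `prob` (interventions x ranks
#'   matrix), `median_rank`, `rank_iqr` (2-row matrix: 25% and 75%
#'   quantiles), and `wtp`.
#' @export
rankogram <- function(m, wtp) {
  stopifnot(inherits(m, "nb_matrix"))
  nb <- net_benefit_draws(m, wtp)
  n <- nrow(nb)
  k <- ncol(nb)
  prob <- matrix(0, k, k, dimnames = list(m$interventions,
                                          paste0("rank", seq_len(k))))
  for (d in seq_len(n)) {
    v <- nb[d, ]
    r_min <- rank(-v, ties.method = "min")
    for (g in unique(r_min)) {
      members <- which(r_min == g)
      span <- g:(g + length(members) - 1)
      prob[members, span] <- prob[members, span] +
        1 / (n * length(members))
    }
  }
  cum <- t(apply(prob, 1, cumsum))
  q_rank <- function(p) apply(cum, 1, function(cw) which(cw >= p - 1e-12)[1])
  structure(list(prob = prob,
                 median_rank = q_rank(0.5),
                 rank_iqr = rbind(q25 = q_rank(0.25), q75 = q_rank(0.75)),
                 wtp = wtp),
            class = "rankogram")
}

#' @export
print.rankogram <- function(x, ...) {
  cat("<rankogram at WTP £", format(x$wtp, big.mark = ","), ">\n", sep = "")
  df <- data.frame(median = x$median_rank, q25 = x$rank_iqr["q25", ],
                   q75 = x$rank_iqr["q75", ])
  print(df)
  invisible(x)
}
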