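## Rejection-ABC estimation of the isolation-with-migration parameters.
##
## Parameters are drawn from uniform box priors, the full multilocus
## design is simulated for each draw, and the draws whose summary-stat
## vectors lie closest (normalized Euclidean distance) to the observed
## vector are retained.  This is a desk-scale stand-in for full-likelihood
## MCMC over the same six-parameter model: the posterior sample targets
## the same demography but conditions on summary statistics.

#' Default uniform box priors for the IM parameters
#'
#' Upper bounds mirror typical run settings for closely related sand-fly
#' sibling populations (theta up to 10, t up to 5, m up to 25).
#'
#' @param thetaMax,tMax,mMax upper bounds of the uniform priors.
#' @return named list of c(lo, hi) ranges for theta1, theta2, thetaA, t,
#'   m1, m2.
#' @export
imPriors <- function(thetaMax = 10, tMax = 5, mMax = 25) {
  list(theta1 = c(0.01, thetaMax), theta2 = c(0.01, thetaMax),
       thetaA = c(0.01, thetaMax), t = c(0.001, tMax),
       m1 = c(0, mMax), m2 = c(0, mMax))
}

.draw_prior <- function(priors, nSims) {
  as.data.frame(lapply(priors, function(r) runif(nSims, r[1], r[2])))
}

.abc_distance <- function(simStats, obs) {
  keep <- is.finite(obs)
  sims <- simStats[, keep, drop = FALSE]
  obs <- obs[keep]
  scl <- apply(sims, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  ok <- rowSums(!is.finite(sims)) == 0L
  d <- rep(Inf, nrow(sims))
  d[ok] <- sqrt(colSums(((t(sims[ok, , drop = FALSE]) - obs) / scl)^2))
  d
}

#' Rejection-ABC estimation of IM parameters
#'
#' @param observed named summary-stat vector of the observed dataset, as
#'   returned by [datasetSummaryStats()].
#' @param design data.frame with per-locus columns \code{n1}, \code{n2},
#'   \code{length} describing the sampling design to simulate.
#' @param priors box priors as from [imPriors()].
#' @param nSims number of prior draws (>= 100).
#' @param acceptFrac fraction of draws retained (closest distances).
#' @param statSubset \code{"all"} uses the full summary vector in the
#'   distance; \code{"means"} restricts it to the across-locus mean
#'   components.  With few loci the across-locus variance components are
#'   dominated by sampling noise, so focused reanalyses (for example a
#'   migration-only refinement with the demography priors collapsed to
#'   point estimates) resolve better on the means alone.
#' @param seed integer seed.
#' @return list with \code{posterior} (data.frame of accepted draws with
#'   their distances), \code{acceptFrac}, \code{nSims},
#'   \code{posteriorMeans} and \code{posteriorMedians}.
#' @export
abcEstimate <- function(observed, design, priors = imPriors(),
                        nSims = 2000L, acceptFrac = 0.05,
                        statSubset = c("all", "means"), seed = 1L) {
  if (nSims < 100L) stop("nSims too small for rejection ABC")
  if (all(!is.finite(observed))) stop("degenerate observed statistics")
  statSubset <- match.arg(statSubset)
  set.seed(seed)
  draws <- .draw_prior(priors, nSims)
  simStats <- matrix(NA_real_, nrow = nSims, ncol = length(observed),
                     dimnames = list(NULL, names(observed)))
  for (i in seq_len(nSims)) {
    p <- imParams(draws$theta1[i], draws$theta2[i], draws$thetaA[i],
                  draws$t[i], draws$m1[i], draws$m2[i])
    simStats[i, ] <- .sim_dataset_stats(p, design)
  }
  use <- if (statSubset == "means")
    grep("^mean_", colnames(simStats)) else seq_len(ncol(simStats))
  d <- .abc_distance(simStats[, use, drop = FALSE], observed[use])
  nAcc <- max(1L, ceiling(acceptFrac * nSims))
  idx <- order(d)[seq_len(nAcc)]
  post <- cbind(draws[idx, , drop = FALSE], distance = d[idx])
  list(posterior = post, acceptFrac = acceptFrac, nSims = nSims,
       posteriorMeans = colMeans(post[, names(priors), drop = FALSE]),
       posteriorMedians = apply(post[, names(priors), drop = FALSE], 2,
                                median))
}

#' Collapse demography priors to point estimates for migration refinement
#'
#' Returns a prior box where theta1, theta2, thetaA and t are pinned to
#' the supplied point estimates (degenerate ranges) while the migration
#' priors are kept, so a second [abcEstimate()] call performs a
#' conditional rejection pass over (m1, m2) only.
#'
#' @param demography named vector or list with theta1, theta2, thetaA, t.
#' @param mMax upper bound of the migration priors.
#' @return a prior list as from [imPriors()].
#' @export
migrationRefinePriors <- function(demography, mMax = 25) {
  pin <- function(v) c(v, v)
  d <- as.list(demography)
  list(theta1 = pin(d$theta1), theta2 = pin(d$theta2),
       thetaA = pin(d$thetaA), t = pin(d$t),
       m1 = c(0, mMax), m2 = c(0, mMax))
}

#' Per-locus migration-rate profiles by rejection ABC
#'
#' With the shared demography (theta1, theta2, thetaA, t) fixed, each
#' locus gets its own rejection-ABC posterior over (m1, m2), driven by
#' that locus's own summary statistics.  Loci whose accepted draws span
#' most of the prior range are flagged as flat (weak divergence plus
#' extensive gene flow gives a diffuse posterior).
#'
#' @param perLocusStats matrix/data.frame, one row per locus, columns
#'   pi1, pi2, fst, Ss, Sf, Sx1, Sx2, dxy (as from per-locus calls of the
#'   popgen layer).
#' @param demography an \linkS4class{IMParams} whose migration slots are
#'   ignored.
#' @param design per-locus data.frame with \code{n1}, \code{n2},
#'   \code{length} (rows parallel to \code{perLocusStats}).
#' @param mPrior c(lo, hi) uniform prior for both migration rates.
#' @param nSims prior draws per locus.
#' @param acceptFrac accepted fraction.
#' @param flatSpanFrac accepted-draw quantile span (5-95%) above this
#'   fraction of the prior range flags a flat posterior.
#' @param seed integer seed (per-locus streams derived by locus index).
#' @return data.frame per locus: posterior medians \code{m1}, \code{m2},
#'   central spans, and logical \code{flat1}, \code{flat2}.
#' @export
perLocusMigrationProfile <- function(perLocusStats, demography, design,
                                     mPrior = c(0, 25), nSims = 1000L,
                                     acceptFrac = 0.05, flatSpanFrac = 0.8,
                                     seed = 1L) {
  perLocusStats <- as.matrix(perLocusStats)
  nLoci <- nrow(perLocusStats)
  out <- vector("list", nLoci)
  for (l in seq_len(nLoci)) {
    obs <- perLocusStats[l, ]
    if (all(!is.finite(obs)) || all(obs == 0, na.rm = TRUE)) {
      out[[l]] <- data.frame(m1 = NA_real_, m2 = NA_real_,
                             span1 = NA_real_, span2 = NA_real_,
                             flat1 = TRUE, flat2 = TRUE)
      next
    }
    set.seed(seed + 1000L * l)
    m1s <- runif(nSims, mPrior[1], mPrior[2])
    m2s <- runif(nSims, mPrior[1], mPrior[2])
    sims <- matrix(NA_real_, nSims, length(obs),
                   dimnames = list(NULL, names(obs)))
    for (i in seq_len(nSims)) {
      cc <- .sim_im_counts(design$n1[l], design$n2[l],
                           demography@theta1, demography@theta2,
                           demography@thetaA, demography@t,
                           m1s[i], m2s[i])
      sims[i, ] <- .locus_stats_from_counts(cc$c1, cc$c2, design$n1[l],
                                            design$n2[l], design$length[l])
    }
    d <- .abc_distance(sims, obs)
    idx <- order(d)[seq_len(max(1L, ceiling(acceptFrac * nSims)))]
    span <- function(x) diff(quantile(x, c(0.05, 0.95))) / diff(mPrior)
    out[[l]] <- data.frame(
      m1 = median(m1s[idx]), m2 = median(m2s[idx]),
      span1 = span(m1s[idx]), span2 = span(m2s[idx]),
      flat1 = span(m1s[idx]) > flatSpanFrac,
      flat2 = span(m2s[idx]) > flatSpanFrac)
  }
  res <- do.call(rbind, out)
  rownames(res) <- rownames(perLocusStats) %||% seq_len(nLoci)
  res
}
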