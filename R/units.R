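## Conversion of scaled IM parameters to demographic units.

#' Build a mutation-rate model for demographic conversions
#'
#' Per-locus per-year rates are
#' \code{mu_i = L_i * (f_syn_i * synRate + (1 - f_syn_i) * nonsynRate)};
#' their geometric mean rescales the IM parameter estimates.  Defaults are
#' the Drosophila melanogaster nuclear synonymous and non-synonymous
#' substitution rates and ten generations per year, as appropriate for
#' neotropical sand flies.
#'
#' @param lociLengths per-locus aligned lengths (bp).
#' @param synFraction per-locus synonymous site fraction (recycled).
#' @param synRate,nonsynRate substitution rates per site per year.
#' @param generationsPerYear generations per year.
#' @param muGeometricMean optional override for the geometric-mean rate
#'   (per locus per year); when supplied, \code{muLocus} is still recorded
#'   but the override is used by [convertUnits()].
#' @return a \linkS4class{MutationRateModel}.
#' @export
mutationRateModel <- function(lociLengths, synFraction = 1,
                              synRate = 1.56e-8, nonsynRate = 1.91e-9,
                              generationsPerYear = 10,
                              muGeometricMean = NULL) {
  if (any(lociLengths <= 0)) stop("all locus lengths must be positive")
  synFraction <- rep_len(synFraction, length(lociLengths))
  mu <- lociLengths * (synFraction * synRate + (1 - synFraction) * nonsynRate)
  gm <- if (is.null(muGeometricMean)) exp(mean(log(mu))) else muGeometricMean
  obj <- new("MutationRateModel", synRate = synRate, nonsynRate = nonsynRate,
             lociLengths = as.numeric(lociLengths),
             synFraction = synFraction, muLocus = mu,
             muGeometricMean = exp(mean(log(mu))),
             generationsPerYear = generationsPerYear)
  # validity ties muGeometricMean to muLocus; store any override afterwards
  if (!is.null(muGeometricMean)) obj@muGeometricMean <- muGeometricMean
  obj
}

#' Geometric mean of per-locus mutation rates
#'
#' @param rates a \linkS4class{MutationRateModel}.
#' @return the geometric mean rate per locus per year.
#' @export
geometricMeanMu <- function(rates) {
  if (length(rates@muLocus) == 0L) stop("no loci in rate model")
  rates@muGeometricMean
}

#' Convert scaled IM parameters to demographic units
#'
#' N_j = theta_j * g / (4 * mu_gm); t_years = t / mu_gm;
#' nm_j = theta_j * m_j / 2 (effective migrant gene copies per generation,
#' 2Nm, into population j).
#'
#' @param params an \linkS4class{IMParams}.
#' @param rates a \linkS4class{MutationRateModel}.
#' @return list with \code{N1}, \code{N2}, \code{NA_} (ancestral size),
#'   \code{tYears}, \code{nm1}, \code{nm2}.
#' @examples
#' rm <- mutationRateModel(300, muGeometricMean = 1.77e-6)
#' p <- imParams(2.9127, 2.056, 0.8661, 0.9463, 0.1375, 1.425)
#' convertUnits(p, rm)$nm2   # 1.4649
#' @export
convertUnits <- function(params, rates) {
  mu <- geometricMeanMu(rates)
  g <- rates@generationsPerYear
  list(N1 = params@theta1 * g / (4 * mu),
       N2 = params@theta2 * g / (4 * mu),
       NA_ = params@thetaA * g / (4 * mu),
       tYears = params@t / mu,
       nm1 = params@theta1 * params@m1 / 2,
       nm2 = params@theta2 * params@m2 / 2)
}

#' Recover scaled parameters from demographic estimates
#'
#' Inverse of [convertUnits()]; useful as a round-trip check.
#'
#' @param est list as returned by [convertUnits()].
#' @param rates a \linkS4class{MutationRateModel}.
#' @return an \linkS4class{IMParams}.
#' @export
invertUnits <- function(est, rates) {
  mu <- geometricMeanMu(rates)
  g <- rates@generationsPerYear
  th1 <- est$N1 * 4 * mu / g
  th2 <- est$N2 * 4 * mu / g
  imParams(theta1 = th1, theta2 = th2, thetaA = est$NA_ * 4 * mu / g,
           t = est$tYears * mu,
           m1 = if (th1 > 0) 2 * est$nm1 / th1 else 0,
           m2 = if (th2 > 0) 2 * est$nm2 / th2 else 0)
}
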