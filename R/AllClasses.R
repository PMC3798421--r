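#' @import methods
#' @useDynLib IMflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats var sd cor pt pchisq optim quantile median rexp rpois
#'   runif rnorm setNames as.dist
#' @importFrom utils read.delim write.table
NULL

#' LocusAlignment: one locus's aligned sequences with population labels
#'
#' Container for a single-locus multiple sequence alignment in which every
#' sequence carries a population label, plus the set of alignment columns
#' that survive site filtering.  All per-locus statistics in the package
#' operate on the \code{keptSites} universe only, so that gap/ambiguity
#' handling (complete deletion of columns) is decided once per locus and
#' applied consistently to every downstream statistic.
#'
#' Coordinates are 1-based column indices internally and in reports.
#'
#' @slot locusName single character, the locus identifier.
#' @slot sequences a \code{\link[Biostrings]{DNAStringSet}} of equal-length
#'   aligned sequences; names are unique sequence identifiers.
#' @slot population character vector parallel to \code{sequences}, the
#'   population label of each sequence.
#' @slot keptSites strictly increasing integer vector of alignment columns
#'   retained by site filtering (initially all columns).
#'
#' @seealso [readLocusAlignment()], [filterSites()], [polymorphismSummary()]
#' @export
setClass("LocusAlignment",
  representation(
    locusName  = "character",
    sequences  = "DNAStringSet",
    population = "character",
    keptSites  = "integer"
  )
)

setValidity("LocusAlignment", function(object) {
  msg <- character()
  if (length(object@locusName) != 1L)
    msg <- c(msg, "locusName must be a single string")
  n <- length(object@sequences)
  if (n > 0) {
    w <- Biostrings::width(object@sequences)
    if (length(unique(w)) > 1L)
      msg <- c(msg, "aligned sequences must all have the same length")
    if (is.null(names(object@sequences)) ||
        anyDuplicated(names(object@sequences)))
      msg <- c(msg, "sequence ids must be present and unique")
    if (length(object@population) != n)
      msg <- c(msg, "population labels must parallel the sequences")
    L <- w[1]
    ks <- object@keptSites
    if (length(ks) && (any(ks < 1L) || any(ks > L) || is.unsorted(ks, strictly = TRUE)))
      msg <- c(msg, "keptSites must be strictly increasing within [1, length]")
  }
  if (length(msg)) msg else TRUE
})

#' IMParams: the six-parameter isolation-with-migration model state
#'
#' Parameters of the two-population isolation-with-migration (IM) model:
#' an ancestral population of scaled size \code{thetaA} splits at scaled
#' time \code{t} into populations of current sizes \code{theta1} and
#' \code{theta2} that exchange migrants at scaled rates \code{m1} and
#' \code{m2}.  All quantities are in mutational units: theta = 4*N*mu per
#' locus, t = years * mu_per_year, m = (per-generation migration
#' probability) / mu.  Direction convention: \code{m1} is the backward rate
#' at which lineages sampled in population 1 trace their ancestry into
#' population 2 (gene flow *into* population 1 forward in time), so the
#' effective number of migrant gene copies per generation into population j
#' is 2Nm_j = theta_j * m_j / 2.
#'
#' @slot theta1,theta2,thetaA scaled population mutation parameters (>= 0).
#' @slot t scaled splitting time (>= 0).
#' @slot m1,m2 scaled migration rates (>= 0).
#'
#' @seealso [IMParams()], [simulateIMLocus()], [convertUnits()]
#' @export
setClass("IMParams",
  representation(
    theta1 = "numeric", theta2 = "numeric", thetaA = "numeric",
    t = "numeric", m1 = "numeric", m2 = "numeric"
  )
)

setValidity("IMParams", function(object) {
  v <- c(object@theta1, object@theta2, object@thetaA,
         object@t, object@m1, object@m2)
  if (length(v) != 6L || anyNA(v) || any(!is.finite(v)))
    return("all six parameters must be single finite numbers")
  if (any(v < 0)) return("all parameters must be non-negative")
  TRUE
})

#' MutationRateModel: per-locus mutation rates and their geometric mean
#'
#' Holds the substitution-rate model used to convert scaled IM parameters
#' into demographic units: synonymous and non-synonymous rates per site per
#' year, per-locus aligned lengths and synonymous site fractions, the
#' implied per-locus per-year rates, their geometric mean, and the number
#' of generations per year.
#'
#' @slot synRate,nonsynRate substitution rates per site per year.
#' @slot lociLengths numeric vector of per-locus lengths (bp).
#' @slot synFraction per-locus fraction of sites evolving at the
#'   synonymous rate.
#' @slot muLocus per-locus mutation rates per year.
#' @slot muGeometricMean geometric mean of \code{muLocus}.
#' @slot generationsPerYear generations per year.
#'
#' @seealso [mutationRateModel()], [geometricMeanMu()], [convertUnits()]
#' @export
setClass("MutationRateModel",
  representation(
    synRate = "numeric", nonsynRate = "numeric",
    lociLengths = "numeric", synFraction = "numeric",
    muLocus = "numeric", muGeometricMean = "numeric",
    generationsPerYear = "numeric"
  )
)

setValidity("MutationRateModel", function(object) {
  if (any(c(object@synRate, object@nonsynRate, object@muLocus,
            object@muGeometricMean, object@generationsPerYear) <= 0))
    return("all rates must be positive")
  if (length(object@muLocus) != length(object@lociLengths))
    return("muLocus must parallel lociLengths")
  mu <- exp(mean(log(object@muLocus)))
  if (abs(mu - object@muGeometricMean) > 1e-9 * mu)
    return("muGeometricMean must equal the geometric mean of muLocus")
  TRUE
})
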