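#' @rdname LocusAlignment-class
#' @param x,object a \code{LocusAlignment}
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("keptSites", function(x) standardGeneric("keptSites"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("populationOf", function(x) standardGeneric("populationOf"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("alignedLength", function(x) standardGeneric("alignedLength"))

#' @export
#' @rdname LocusAlignment-class
setMethod("locusName", "LocusAlignment", function(x) x@locusName)

#' @export
#' @rdname LocusAlignment-class
setMethod("keptSites", "LocusAlignment", function(x) x@keptSites)

#' @export
#' @rdname LocusAlignment-class
setMethod("populationOf", "LocusAlignment",
          function(x) setNames(x@population, names(x@sequences)))

#' @export
#' @rdname LocusAlignment-class
setMethod("nSequences", "LocusAlignment", function(x) length(x@sequences))

#' @export
#' @rdname LocusAlignment-class
setMethod("alignedLength", "LocusAlignment", function(x)
  if (length(x@sequences)) Biostrings::width(x@sequences)[1] else 0L)

setMethod("show", "LocusAlignment", function(object) {
  cat("LocusAlignment '", object@locusName, "': ",
      nSequences(object), " sequences x ", alignedLength(object),
      " columns (", length(object@keptSites), " kept)\n", sep = "")
  tab <- table(object@population)
  cat("  populations:",
      paste(names(tab), "=", as.integer(tab), collapse = ", "), "\n")
})

setMethod("show", "IMParams", function(object) {
  cat("IMParams: theta1 =", object@theta1, " theta2 =", object@theta2,
      " thetaA =", object@thetaA, "\n          t =", object@t,
      " m1 =", object@m1, " m2 =", object@m2, "\n")
})

setMethod("show", "MutationRateModel", function(object) {
  cat("MutationRateModel:", length(object@muLocus), "loci, mu_gm =",
      format(object@muGeometricMean, digits = 6), "per locus per year,",
      object@generationsPerYear, "generations/year\n")
})

#' Construct an IMParams object
#'
#' @param theta1,theta2,thetaA scaled population mutation parameters
#'   (4 N mu per locus) for the two current populations and the ancestor.
#' @param t scaled splitting time (mutational units).
#' @param m1,m2 scaled migration rates (m/mu), see
#'   \linkS4class{IMParams} for the direction convention.
#' @return an \linkS4class{IMParams} object.
#' @examples
#' imParams(theta1 = 2.9127, theta2 = 2.056, thetaA = 0.8661,
#'          t = 0.9463, m1 = 0.1375, m2 = 1.425)
#' @export
imParams <- function(theta1, theta2, thetaA, t, m1 = 0, m2 = 0) {
  new("IMParams", theta1 = as.numeric(theta1), theta2 = as.numeric(theta2),
      thetaA = as.numeric(thetaA), t = as.numeric(t),
      m1 = as.numeric(m1), m2 = as.numeric(m2))
}
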