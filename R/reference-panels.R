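## Published reference panels for the Lutzomyia longipalpis species
## complex: per-locus summaries for 21 nuclear loci in two sympatric
## populations from Sobral (1S, 2S; northeastern Brazil) and two
## allopatric populations from Lapinha and Pancas (southeastern Brazil).
## These drive the comparison layer in panel-bypass mode and provide
## realistic defaults for the synthetic-study generator.

.extdata <- function(name)
  system.file("extdata", name, package = "IMflow", mustWork = TRUE)

#' Published per-locus polymorphism panel (21 nuclear loci)
#'
#' Aligned lengths, sample sizes, segregating sites, per-site pi and
#' Watterson's theta for four Brazilian populations of the Lutzomyia
#' longipalpis complex (Sobral 1S, Sobral 2S, Lapinha, Pancas).
#'
#' @return data.frame, one row per locus.
#' @export
lutzLocusPanel <- function()
  read.delim(.extdata("longipalpis_locus_panel.tsv"),
             stringsAsFactors = FALSE)

#' Published per-locus FST differentiation panel
#'
#' Per-locus Hudson-type FST, permutation significance class, shared
#' (Ss) and fixed (Sf) site counts for the sympatric pair (Sobral 1S vs
#' Sobral 2S) and the allopatric pair (Lapinha vs Pancas).
#'
#' @return data.frame with columns \code{locus}, \code{fst_symp},
#'   \code{sig_symp}, \code{Ss_symp}, \code{Sf_symp}, \code{fst_allo},
#'   \code{sig_allo}, \code{Ss_allo}, \code{Sf_allo}.
#' @export
lutzFstPanel <- function()
  read.delim(.extdata("longipalpis_fst_panel.tsv"),
             stringsAsFactors = FALSE)

#' Published isolation-with-migration parameter estimates
#'
#' Scaled IM parameter point estimates (and 90% intervals) for the
#' sympatric comparison (population 1 = Sobral 1S, population 2 =
#' Sobral 2S) and the allopatric comparison (population 1 = Pancas,
#' population 2 = Lapinha).
#'
#' @param comparison \code{"sympatric"} or \code{"allopatric"}; NULL
#'   returns the full table.
#' @return an \linkS4class{IMParams} for one comparison, or the raw
#'   data.frame when \code{comparison} is NULL.
#' @export
lutzIMEstimates <- function(comparison = c("sympatric", "allopatric")) {
  tab <- read.delim(.extdata("longipalpis_im_estimates.tsv"),
                    stringsAsFactors = FALSE)
  if (is.null(comparison)) return(tab)
  comparison <- match.arg(comparison)
  tab <- tab[tab$comparison == comparison, ]
  est <- setNames(tab$estimate, tab$parameter)
  imParams(est["theta1"], est["theta2"], est["thetaA"],
           est["t"], est["m1"], est["m2"])
}
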