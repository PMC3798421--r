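## Orchestration: ingest -> per-locus stats -> differentiation -> HKA ->
## comparison layer -> NRB -> (optional) ABC + unit conversions, with all
## report tables written as TSV and the population tree as newick.

#' Comparison-layer statistics from a per-locus FST panel (bypass mode)
#'
#' Runs the sympatric-versus-allopatric comparison layer directly from a
#' precomputed per-locus FST/Ss/Sf panel, without sequences: mean-FST
#' contrast with t test, ranked normalized-difference correlation,
#' exceedance count, and fixed/shared site totals.
#'
#' @param panel data.frame with columns \code{locus}, \code{fst_symp},
#'   \code{fst_allo} and optionally \code{Ss_symp}, \code{Sf_symp},
#'   \code{Ss_allo}, \code{Sf_allo}; defaults to the published panel
#'   [lutzFstPanel()].
#' @return list with \code{contrast} (from [meanFstContrast()]),
#'   \code{rank_vs_symp}, \code{rank_vs_allo} (from
#'   [normalizedDiffRankCorrelation()]), \code{n_sympatric_exceed}, and
#'   when the site columns are present \code{Sf_total_symp},
#'   \code{Sf_total_allo}, \code{Ss_zero_symp}, \code{Ss_zero_allo}
#'   (counts of loci without shared polymorphism).
#' @examples
#' cp <- comparePanel(lutzFstPanel())
#' round(cp$rank_vs_symp$r, 3)   # -0.896
#' @export
comparePanel <- function(panel = lutzFstPanel()) {
  out <- list(contrast = meanFstContrast(panel),
              rank_vs_symp = normalizedDiffRankCorrelation(panel, "vs_symp"),
              rank_vs_allo = normalizedDiffRankCorrelation(panel, "vs_allo"),
              n_sympatric_exceed = countSympatricExceed(panel))
  if (all(c("Sf_symp", "Sf_allo", "Ss_symp", "Ss_allo") %in% names(panel))) {
    out$Sf_total_symp <- sum(panel$Sf_symp)
    out$Sf_total_allo <- sum(panel$Sf_allo)
    out$Ss_zero_symp <- sum(panel$Ss_symp == 0)
    out$Ss_zero_allo <- sum(panel$Ss_allo == 0)
  }
  out
}

#' Run the full multilocus divergence/introgression analysis
#'
#' Orchestrates every stage on a four-population dataset (as generated by
#' [generateStudy()] or read from FASTA + popmap): per-locus polymorphism
#' and neutrality tables, pairwise differentiation with permutation
#' significance for the sympatric and allopatric pairs, the multilocus
#' HKA test per pair, the mean-FST NJ tree with locus bootstrap, the
#' ranked normalized-difference statistic, non-recombining-block
#' extraction, and (optionally) rejection-ABC demographic estimation with
#' unit conversions.  Stages are pure functions of their inputs and the
#' seed; independent stages continue when one fails, and errors are
#' collected in the result.
#'
#' @param dataset output of [generateStudy()], or a directory path
#'   containing per-locus FASTA files plus \code{popmap.tsv}.
#' @param pairs named list with \code{symp} and \code{allo}, each a
#'   2-vector of population labels (pop1, pop2).
#' @param nPerm FST permutations per locus (default 1000).
#' @param B locus-bootstrap replicates for the tree (default 100).
#' @param abcSims prior draws for ABC; 0 skips the ABC stage.
#' @param rates a \linkS4class{MutationRateModel} for unit conversion
#'   (NULL: built from the dataset's locus lengths with the default
#'   geometric-mean rate 1.77e-6).
#' @param seed integer seed governing permutations, bootstrap and ABC.
#' @param outDir optional directory for the report files
#'   (\code{table1.tsv}, \code{table2.tsv}, \code{table3.tsv},
#'   \code{table4.tsv}, \code{fig2.nwk}, \code{fig2_support.tsv},
#'   \code{fig4.tsv}, \code{nrb_ledger.tsv}).
#' @return list with elements \code{polymorphism}, \code{neutrality},
#'   \code{differentiation}, \code{hka}, \code{tree}, \code{compare},
#'   \code{nrb}, \code{abc} (NULL when skipped), \code{errors}.
#' @export
runFullAnalysis <- function(dataset,
                            pairs = list(symp = c("Sobral1S", "Sobral2S"),
                                         allo = c("Lapinha", "Pancas")),
                            nPerm = 1000L, B = 100L, abcSims = 0L,
                            rates = NULL, seed = 1L, outDir = NULL) {
  if (is.character(dataset)) dataset <- .read_study_dir(dataset)
  loci <- dataset$loci
  if (length(loci) == 0L) stop("validation error: dataset has no loci")
  allPops <- unique(unlist(lapply(loci[[1]], function(a) a@population)))
  need <- unlist(pairs)
  if (!all(need %in% allPops))
    stop("validation error: pairs reference unknown populations: ",
         paste(setdiff(need, allPops), collapse = ", "))
  errors <- character()
  res <- list()

  safely <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, paste0(tag, ": ", conditionMessage(e)))
      NULL
    })
  }

  halves <- function(l) list(l$symp, l$allo)
  popAln <- function(l, popn) {
    for (h in halves(l))
      if (popn %in% h@population) return(subsetPopulations(h, popn))
    stop("population not found: ", popn)
  }

  res$polymorphism <- safely("polymorphism", {
    do.call(rbind, lapply(names(loci), function(nm) {
      do.call(rbind, lapply(allPops, function(popn) {
        ps <- polymorphismSummary(filterSites(popAln(loci[[nm]], popn)))
        data.frame(locus = nm, population = popn, length = ps$L,
                   n = ps$n, S = ps$S, pi = ps$pi, thetaW = ps$thetaW)
      }))
    }))
  })

  res$neutrality <- safely("neutrality", {
    do.call(rbind, lapply(names(loci), function(nm) {
      do.call(rbind, lapply(allPops, function(popn) {
        aln <- filterSites(popAln(loci[[nm]], popn))
        data.frame(locus = nm, population = popn, D = tajimasD(aln),
                   R2 = ramosOnsinsR2(aln))
      }))
    }))
  })

  pairRows <- function(pairName) {
    pr <- pairs[[pairName]]
    do.call(rbind, lapply(seq_along(loci), function(l) {
      alnA <- filterSites(popAln(loci[[l]], pr[1]))
      alnB <- filterSites(popAln(loci[[l]], pr[2]))
      row <- popPairDiff(alnA, alnB, nPerm = nPerm, seed = seed + l)
      row$pair <- pairName
      row$locus <- names(loci)[l]
      row
    }))
  }
  res$differentiation <- safely("differentiation", {
    rbind(pairRows("symp"), pairRows("allo"))
  })

  res$hka <- safely("hka", {
    lapply(pairs, function(pr) {
      lp <- lapply(seq_along(loci), function(l)
        list(filterSites(popAln(loci[[l]], pr[1])),
             filterSites(popAln(loci[[l]], pr[2]))))
      hkaFit(hkaInput(lp))[c("chi2", "df", "p", "T", "f")]
    })
  })

  res$tree <- safely("tree", {
    combos <- utils::combn(allPops, 2L)
    perLocus <- do.call(rbind, lapply(seq_along(loci), function(l) {
      do.call(rbind, lapply(seq_len(ncol(combos)), function(ci) {
        alnA <- filterSites(popAln(loci[[l]], combos[1, ci]))
        alnB <- filterSites(popAln(loci[[l]], combos[2, ci]))
        data.frame(locus = names(loci)[l], pop1 = combos[1, ci],
                   pop2 = combos[2, ci], fst = hudsonFst(alnA, alnB))
      }))
    }))
    locusBootstrapSupport(perLocus, B = B, seed = seed)
  })

  res$compare <- safely("compare", {
    diffTab <- res$differentiation
    if (is.null(diffTab)) stop("differentiation stage failed")
    s <- diffTab[diffTab$pair == "symp", ]
    a <- diffTab[diffTab$pair == "allo", ]
    panel <- data.frame(locus = s$locus,
                        fst_symp = s$fst, Ss_symp = s$Ss, Sf_symp = s$Sf,
                        fst_allo = a$fst[match(s$locus, a$locus)],
                        Ss_allo = a$Ss[match(s$locus, a$locus)],
                        Sf_allo = a$Sf[match(s$locus, a$locus)])
    panel <- panel[!is.na(panel$fst_symp) & !is.na(panel$fst_allo) &
                     panel$fst_allo != 0, ]
    comparePanel(panel)
  })

  res$nrb <- safely("nrb", {
    do.call(rbind, lapply(names(loci), function(nm) {
      aln <- filterSites(loci[[nm]]$symp)
      r <- extractNrb(aln)
      data.frame(locus = nm, start = r$block[1], end = r$block[2],
                 nSites = r$nSites, nRetained = length(r$retainedIds),
                 nDropped = length(r$droppedIds),
                 dropped = paste(r$droppedIds, collapse = ","),
                 degenerate = r$degenerate)
    }))
  })

  res$abc <- if (abcSims > 0L) safely("abc", {
    pr <- pairs$symp
    lociPairs <- lapply(seq_along(loci), function(l)
      list(filterSites(popAln(loci[[l]], pr[1])),
           filterSites(popAln(loci[[l]], pr[2]))))
    obs <- datasetSummaryStats(lociPairs)
    design <- data.frame(
      n1 = vapply(lociPairs, function(x) nSequences(x[[1]]), integer(1)),
      n2 = vapply(lociPairs, function(x) nSequences(x[[2]]), integer(1)),
      length = vapply(lociPairs, function(x) length(keptSites(x[[1]])),
                      numeric(1)))
    est <- abcEstimate(obs, design, nSims = abcSims, seed = seed)
    if (is.null(rates))
      rates <- mutationRateModel(design$length, muGeometricMean = 1.77e-6)
    pm <- est$posteriorMeans
    est$demography <- convertUnits(
      imParams(pm["theta1"], pm["theta2"], pm["thetaA"],
               pm["t"], pm["m1"], pm["m2"]), rates)
    est
  }) else NULL

  res$errors <- errors
  if (!is.null(outDir)) .write_reports(res, outDir)
  res
}

.read_study_dir <- function(dir) {
  pm <- readPopulationMap(file.path(dir, "popmap.tsv"))
  fas <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(fas) == 0L) stop("no FASTA files in ", dir)
  loci <- lapply(fas, function(fa) {
    aln <- readLocusAlignment(fa, pm)
    # split into the two pair halves by population label order
    pops <- unique(aln@population)
    list(symp = subsetPopulations(aln, pops[1:2]),
         allo = subsetPopulations(aln, pops[3:4]))
  })
  names(loci) <- sub("\\.fasta$", "", basename(fas))
  list(loci = loci)
}

.write_reports <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) if (!is.null(x))
    write.table(x, file.path(outDir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(res$polymorphism, "table1.tsv")
  wt(res$neutrality, "table2.tsv")
  wt(res$differentiation, "table3.tsv")
  wt(res$nrb, "nrb_ledger.tsv")
  if (!is.null(res$tree)) {
    ape::write.tree(res$tree$tree, file.path(outDir, "fig2.nwk"))
    wt(data.frame(split = names(res$tree$support),
                  support = unname(res$tree$support)), "fig2_support.tsv")
  }
  if (!is.null(res$compare)) {
    cp <- res$compare
    wt(data.frame(
      statistic = c("mean_fst_symp", "sd_fst_symp", "mean_fst_allo",
                    "sd_fst_allo", "t", "t_p", "r_vs_symp", "r_vs_symp_p",
                    "r_vs_allo", "n_sympatric_exceed"),
      value = c(cp$contrast$mean_symp, cp$contrast$sd_symp,
                cp$contrast$mean_allo, cp$contrast$sd_allo,
                cp$contrast$t, cp$contrast$p, cp$rank_vs_symp$r,
                cp$rank_vs_symp$p, cp$rank_vs_allo$r,
                cp$n_sympatric_exceed)), "fig4.tsv")
  }
  if (!is.null(res$abc)) {
    pm <- res$abc$posteriorMeans
    dem <- res$abc$demography
    wt(data.frame(parameter = c(names(pm), "N1", "N2", "NA", "t_years",
                                "nm1", "nm2"),
                  value = c(unname(pm), dem$N1, dem$N2, dem$NA_,
                            dem$tYears, dem$nm1, dem$nm2)), "table4.tsv")
  }
  if (!is.null(res$hka)) {
    hk <- do.call(rbind, lapply(names(res$hka), function(nm)
      data.frame(pair = nm, chi2 = res$hka[[nm]]$chi2,
                 df = res$hka[[nm]]$df, p = res$hka[[nm]]$p)))
    wt(hk, "hka.tsv")
  }
  invisible(outDir)
}
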