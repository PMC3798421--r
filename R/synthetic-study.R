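## Synthetic four-population study generator.
##
## Generates complete stand-ins for a four-population, 21-locus
## multilocus study: two species pairs (one sympatric, one allopatric),
## each simulated under its own isolation-with-migration history, with
## per-locus migration-rate heterogeneity in the sympatric pair
## ("barrier" loci with multiplier 0, freely introgressing loci above 1).
## Ground-truth parameters ride along with every dataset.

#' Configuration for a synthetic four-population study
#'
#' Defaults emulate the published 21-locus design: the published aligned
#' lengths and per-population sample sizes, species-pair IM histories set
#' to the published scaled estimates, and a heterogeneous per-locus
#' migration multiplier vector for the sympatric pair (about one third of
#' loci are barrier loci with multiplier 0; the rest draw lognormal
#' multipliers with unit median).  Per-locus theta is scaled by locus
#' length relative to the panel's geometric-mean length, so longer loci
#' carry proportionally more scaled mutation.
#'
#' @param lociTable data.frame with columns \code{locus},
#'   \code{length_bp}, and per-population sample sizes \code{n_S1S},
#'   \code{n_S2S}, \code{n_Lap}, \code{n_Pan}; defaults to
#'   [lutzLocusPanel()].
#' @param sympatricParams,allopatricParams \linkS4class{IMParams} for the
#'   two pair histories; default to [lutzIMEstimates()].
#' @param migrationMultipliers per-locus non-negative multipliers applied
#'   to both sympatric migration rates; NULL draws them from the default
#'   mixture using \code{seed}.
#' @param barrierFraction fraction of loci with multiplier 0 when
#'   multipliers are drawn.
#' @param asymmetryFactor extra factor applied to the sympatric m2 (the
#'   direction receiving more migrants); default 1 keeps the asymmetry of
#'   \code{sympatricParams}.
#' @param seed integer seed.
#' @return list of class \code{studyConfig}.
#' @export
studyConfig <- function(lociTable = lutzLocusPanel(),
                        sympatricParams = lutzIMEstimates("sympatric"),
                        allopatricParams = lutzIMEstimates("allopatric"),
                        migrationMultipliers = NULL,
                        barrierFraction = 1 / 3,
                        asymmetryFactor = 1,
                        seed = 1L) {
  nLoci <- nrow(lociTable)
  if (is.null(migrationMultipliers)) {
    set.seed(seed)
    mult <- exp(rnorm(nLoci, 0, 1))
    barrier <- sample.int(nLoci, round(barrierFraction * nLoci))
    mult[barrier] <- 0
    migrationMultipliers <- mult
  }
  if (length(migrationMultipliers) != nLoci || any(migrationMultipliers < 0))
    stop("migrationMultipliers must be ", nLoci, " non-negative values")
  structure(list(lociTable = lociTable,
                 sympatricParams = sympatricParams,
                 allopatricParams = allopatricParams,
                 migrationMultipliers = migrationMultipliers,
                 asymmetryFactor = asymmetryFactor,
                 seed = as.integer(seed)),
            class = "studyConfig")
}

.scale_params <- function(p, thetaScale, m1, m2) {
  imParams(p@theta1 * thetaScale, p@theta2 * thetaScale,
           p@thetaA * thetaScale, p@t, m1, m2)
}

#' Generate a synthetic four-population multilocus dataset
#'
#' Per locus, two independent IM simulations: the sympatric pair
#' (Sobral1S, Sobral2S) with per-locus migration multipliers and the
#' asymmetry factor, and the allopatric pair (Lapinha, Pancas) with its
#' own low-migration history.  Optionally writes the same FASTA + popmap
#' layout the reader consumes, plus a ground-truth sidecar (JSON text).
#'
#' @param config a [studyConfig()].
#' @param outDir optional directory; when given, per-locus FASTA files,
#'   \code{popmap.tsv} and \code{truth.json} are written there.
#' @return list with \code{loci} (per locus: \code{symp} and \code{allo}
#'   \linkS4class{LocusAlignment}s), \code{truth} (config parameters plus
#'   realized per-locus mutation counts), and \code{dir}.
#' @export
generateStudy <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "studyConfig"))
  lt <- config$lociTable
  nLoci <- nrow(lt)
  Lgm <- exp(mean(log(lt$length_bp)))
  sp <- config$sympatricParams
  ap <- config$allopatricParams
  loci <- vector("list", nLoci)
  realized <- data.frame(locus = lt$locus, S_symp = NA_integer_,
                         S_allo = NA_integer_,
                         m_multiplier = config$migrationMultipliers)
  for (l in seq_len(nLoci)) {
    sc <- lt$length_bp[l] / Lgm
    mult <- config$migrationMultipliers[l]
    pSymp <- .scale_params(sp, sc, sp@m1 * mult,
                           sp@m2 * mult * config$asymmetryFactor)
    pAllo <- .scale_params(ap, sc, ap@m1, ap@m2)
    alnS <- simulateIMLocus(pSymp, n1 = lt$n_S1S[l], n2 = lt$n_S2S[l],
                            length = lt$length_bp[l],
                            seed = config$seed + 2L * l,
                            popNames = c("Sobral1S", "Sobral2S"))
    alnA <- simulateIMLocus(pAllo, n1 = lt$n_Lap[l], n2 = lt$n_Pan[l],
                            length = lt$length_bp[l],
                            seed = config$seed + 2L * l + 1L,
                            popNames = c("Lapinha", "Pancas"))
    alnS@locusName <- alnA@locusName <- lt$locus[l]
    names(alnS@sequences) <- paste0(lt$locus[l], "_", names(alnS@sequences))
    names(alnA@sequences) <- paste0(lt$locus[l], "_", names(alnA@sequences))
    realized$S_symp[l] <- nrow(attr(alnS, "mutationCounts"))
    realized$S_allo[l] <- nrow(attr(alnA, "mutationCounts"))
    loci[[l]] <- list(symp = alnS, allo = alnA)
  }
  names(loci) <- lt$locus
  truth <- list(
    sympatricParams = .params_list(sp),
    allopatricParams = .params_list(ap),
    migrationMultipliers = config$migrationMultipliers,
    asymmetryFactor = config$asymmetryFactor,
    thetaLengthScaling = "theta_i = theta * L_i / geomMean(L)",
    seed = config$seed,
    realized = realized)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    popmap <- NULL
    for (l in seq_len(nLoci)) {
      both <- c(as.character(loci[[l]]$symp@sequences),
                as.character(loci[[l]]$allo@sequences))
      # pad to common length in case of nothing: lengths already equal
      fa <- file.path(outDir, paste0(lt$locus[l], ".fasta"))
      writeLines(paste0(">", names(both), "\n", both), fa)
      popmap <- rbind(popmap, data.frame(
        id = c(names(loci[[l]]$symp@sequences),
               names(loci[[l]]$allo@sequences)),
        pop = c(loci[[l]]$symp@population, loci[[l]]$allo@population)))
    }
    write.table(popmap, file.path(outDir, "popmap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns"),
               file.path(outDir, "truth.json"))
  }
  list(loci = loci, truth = truth, dir = outDir)
}

.params_list <- function(p)
  list(theta1 = p@theta1, theta2 = p@theta2, thetaA = p@thetaA,
       t = p@t, m1 = p@m1, m2 = p@m2)

#' Check a generated dataset against the published polymorphism envelope
#'
#' Per locus and population, per-site pi must fall in [0, 0.05] and S in
#' [0, 60] (the envelope of the published 21-locus panel).
#'
#' @param dataset output of [generateStudy()].
#' @param piMax,sMax envelope bounds.
#' @return list with \code{fractionInside}, \code{violations}
#'   (data.frame of offending locus x population cells) and \code{nCells}.
#' @export
checkPolymorphismEnvelope <- function(dataset, piMax = 0.05, sMax = 60) {
  if (length(dataset$loci) == 0L) stop("empty dataset")
  rows <- list()
  for (nm in names(dataset$loci)) {
    for (half in c("symp", "allo")) {
      aln <- dataset$loci[[nm]][[half]]
      for (popn in unique(aln@population)) {
        sub <- subsetPopulations(aln, popn)
        ps <- polymorphismSummary(sub)
        rows[[length(rows) + 1L]] <- data.frame(
          locus = nm, population = popn, S = ps$S, pi = ps$pi)
      }
    }
  }
  cells <- do.call(rbind, rows)
  bad <- cells$pi > piMax | cells$S > sMax
  list(fractionInside = mean(!bad), violations = cells[bad, , drop = FALSE],
       nCells = nrow(cells))
}
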