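## Per-locus polymorphism, neutrality and two-population differentiation
## statistics.  Everything operates on the kept-site universe of a
## LocusAlignment (complete deletion of gapped/ambiguous columns upstream),
## so counts and per-site scalings are consistent across statistics.

# integer-coded kept-site matrix: rows sequences, values 1..k alleles
.coded_matrix <- function(aln) {
  m <- alignmentMatrix(aln)
  matrix(match(m, c("A", "C", "G", "T")), nrow = nrow(m),
         dimnames = dimnames(m))
}

# per-column allele counts (4 x sites) from a coded matrix
.allele_counts <- function(code) {
  apply(code, 2L, function(col) tabulate(col, nbins = 4L))
}

# unnormalised mean pairwise difference within a coded matrix
.pi_total <- function(code) {
  n <- nrow(code)
  if (n < 2L) stop("input error: need >= 2 sequences")
  if (ncol(code) == 0L) return(NA_real_)
  cc <- .allele_counts(code)
  sum((n^2 - colSums(cc^2)) / (n * (n - 1)))
}

#' Segregating sites of a locus
#'
#' @param aln a \linkS4class{LocusAlignment} (>= 2 sequences, non-empty
#'   \code{keptSites}).
#' @return list with \code{count} and \code{sites} (1-based alignment
#'   columns with >= 2 distinct residues among kept sites).
#' @export
segregatingSites <- function(aln) {
  if (nSequences(aln) < 2L) stop("input error: need >= 2 sequences")
  code <- .coded_matrix(aln)
  seg <- apply(code, 2L, function(col) length(unique(col)) > 1L)
  list(count = sum(seg), sites = keptSites(aln)[seg])
}

#' Nucleotide diversity (pi, per site)
#'
#' Mean over all sequence pairs of the per-pair difference count on kept
#' sites, divided by the number of kept sites.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return per-site pi; \code{NA} (with a warning) if no kept sites.
#' @export
nucleotideDiversity <- function(aln) {
  if (length(keptSites(aln)) == 0L) {
    warning("pi undefined: no kept sites in '", locusName(aln), "'")
    return(NA_real_)
  }
  .pi_total(.coded_matrix(aln)) / length(keptSites(aln))
}

#' Watterson's theta (per site)
#'
#' S / (a1 * L) with a1 = sum_{i=1}^{n-1} 1/i and L the kept length.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return per-site Watterson estimator.
#' @export
wattersonTheta <- function(aln) {
  n <- nSequences(aln)
  S <- segregatingSites(aln)$count
  S / (sum(1 / seq_len(n - 1)) * length(keptSites(aln)))
}

#' Tajima's D
#'
#' Standardised difference between the pairwise-difference and
#' segregating-sites diversity estimators, using the classical
#' finite-sample constants computed from n.  Undefined (NA) when S = 0.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return D, or \code{NA_real_} when there is no segregating variation.
#' @export
tajimasD <- function(aln) {
  code <- .coded_matrix(aln)
  n <- nrow(code)
  S <- sum(apply(code, 2L, function(col) length(unique(col)) > 1L))
  if (S == 0L) return(NA_real_)
  k <- .pi_total(code)
  cst <- .tajima_constants(n)
  (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

.tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Distribution of the number of distinct alleles under the neutral model
#'
#' P(K >= k) for the Ewens sampling distribution with parameter theta,
#' computed by the numerically stable convolution of independent Bernoulli
#' indicators K = sum_i Bern(theta/(theta+i-1)), i = 1..n (equivalent to
#' the unsigned-Stirling-number form |s(n,k)| theta^k / theta^(n)).
#'
#' @param n sample size.
#' @param theta scaled mutation parameter (> 0).
#' @param k threshold allele count.
#' @return P(K >= k).
#' @export
ewensKTail <- function(n, theta, k) {
  p <- theta / (theta + seq_len(n) - 1)   # p[1] = 1
  dist <- 1                               # P(K = 0) before any draw
  for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
  sum(dist[seq.int(k + 1L, n + 1L)])
}

#' Fu's Fs
#'
#' Haplotype-number neutrality statistic: with theta estimated by the mean
#' pairwise difference, S' = P(K >= k_obs) under the Ewens distribution and
#' Fs = ln(S'/(1-S')).  When S' underflows to 0 or 1 the log-odds is
#' clamped and flagged.
#'
#' @param aln a \linkS4class{LocusAlignment} with S > 0 and n >= 3.
#' @param clamp absolute bound used when S' hits the boundary.
#' @return list with \code{Fs}, \code{Sprime}, \code{kHaplotypes}, and
#'   logical \code{clamped}.
#' @export
fusFs <- function(aln, clamp = 1e3) {
  code <- .coded_matrix(aln)
  n <- nrow(code)
  if (n < 3L) stop("input error: Fu's Fs needs n >= 3")
  theta <- .pi_total(code)
  if (!is.na(theta) && theta == 0)
    stop("input error: Fu's Fs undefined without variation")
  k_obs <- nrow(unique(code))
  Sp <- ewensKTail(n, theta, k_obs)
  clamped <- FALSE
  if (Sp <= 0 || Sp >= 1) {
    clamped <- TRUE
    Fs <- if (Sp >= 1) clamp else -clamp
  } else {
    Fs <- log(Sp / (1 - Sp))
    if (!is.finite(Fs)) { clamped <- TRUE; Fs <- sign(Fs) * clamp }
  }
  list(Fs = Fs, Sprime = Sp, kHaplotypes = k_obs, clamped = clamped)
}

# per-sequence singleton load: number of sites where the sequence carries
# an allele seen exactly once
.singleton_counts <- function(code) {
  n <- nrow(code)
  U <- integer(n)
  for (j in seq_len(ncol(code))) {
    cnt <- tabulate(code[, j], nbins = 4L)
    singles <- which(cnt == 1L)
    for (a in singles) U[code[, j] == a] <- U[code[, j] == a] + 1L
  }
  U
}

#' Ramos-Onsins and Rozas' R2
#'
#' R2 = sqrt(mean_i (U_i - pi_total/2)^2) / S, where U_i is the number of
#' singleton mutations carried by sequence i.  Low values indicate
#' population growth.  Undefined (NA) when S = 0.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return R2 or \code{NA_real_}.
#' @export
ramosOnsinsR2 <- function(aln) {
  code <- .coded_matrix(aln)
  n <- nrow(code)
  S <- sum(apply(code, 2L, function(col) length(unique(col)) > 1L))
  if (S == 0L) return(NA_real_)
  U <- .singleton_counts(code)
  k <- .pi_total(code)
  sqrt(sum((U - k / 2)^2) / n) / S
}

#' Per-locus polymorphism summary
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return list with \code{n}, \code{L} (kept sites), \code{S}, \code{pi}
#'   (per site), \code{thetaW} (per site), \code{piTotal} (count scale),
#'   \code{singletonCounts} and \code{kHaplotypes}.
#' @export
polymorphismSummary <- function(aln) {
  code <- .coded_matrix(aln)
  n <- nrow(code); L <- ncol(code)
  S <- sum(apply(code, 2L, function(col) length(unique(col)) > 1L))
  k <- .pi_total(code)
  list(n = n, L = L, S = S,
       pi = if (L > 0) k / L else NA_real_,
       thetaW = if (L > 0) S / (sum(1 / seq_len(n - 1)) * L) else NA_real_,
       piTotal = k,
       singletonCounts = .singleton_counts(code),
       kHaplotypes = nrow(unique(code)))
}

.check_same_universe <- function(alnA, alnB) {
  if (!identical(keptSites(alnA), keptSites(alnB)) ||
      alignedLength(alnA) != alignedLength(alnB))
    stop("kept-site universes differ between the two populations")
}

# mean between-population pairwise difference, count scale
.dxy_total <- function(codeA, codeB) {
  n1 <- nrow(codeA); n2 <- nrow(codeB)
  ccA <- .allele_counts(codeA); ccB <- .allele_counts(codeB)
  sum((n1 * n2 - colSums(ccA * ccB)) / (n1 * n2))
}

#' Dxy: average between-population substitutions per site
#'
#' @param alnA,alnB \linkS4class{LocusAlignment}s of the two populations,
#'   same locus and identical \code{keptSites}.
#' @return per-site Dxy.
#' @export
dxy <- function(alnA, alnB) {
  .check_same_universe(alnA, alnB)
  L <- length(keptSites(alnA))
  if (L == 0L) return(NA_real_)
  .dxy_total(.coded_matrix(alnA), .coded_matrix(alnB)) / L
}

#' Classify polymorphic and fixed sites between two populations
#'
#' Each kept column is placed in exactly one category: \code{Sf} (each
#' population monomorphic, for different residues), \code{Ss} (both
#' polymorphic, with the same >= 2 residues segregating in both),
#' \code{Sx1} / \code{Sx2} (polymorphic in exactly one population).
#' Columns monomorphic for the same residue contribute nothing.  A column
#' polymorphic in both populations but without two residues in common
#' (impossible for biallelic data) does not meet the shared definition; to
#' keep the categories a partition it is assigned to the exclusive tally
#' of the population with more segregating residues (ties to \code{Sx1})
#' and counted in \code{ambiguousShared}.
#'
#' @param alnA,alnB \linkS4class{LocusAlignment}s with a shared kept-site
#'   universe.
#' @return list with \code{Ss}, \code{Sf}, \code{Sx1}, \code{Sx2} and
#'   \code{ambiguousShared} (count of doubly polymorphic columns without
#'   two common residues).
#' @export
classifyPolymorphisms <- function(alnA, alnB) {
  .check_same_universe(alnA, alnB)
  codeA <- .coded_matrix(alnA); codeB <- .coded_matrix(alnB)
  Ss <- Sf <- Sx1 <- Sx2 <- amb <- 0L
  for (j in seq_len(ncol(codeA))) {
    aA <- unique(codeA[, j]); aB <- unique(codeB[, j])
    pA <- length(aA) > 1L; pB <- length(aB) > 1L
    if (!pA && !pB) {
      if (aA != aB) Sf <- Sf + 1L
    } else if (pA && pB) {
      if (length(intersect(aA, aB)) >= 2L) Ss <- Ss + 1L
      else {
        amb <- amb + 1L
        if (length(aA) >= length(aB)) Sx1 <- Sx1 + 1L else Sx2 <- Sx2 + 1L
      }
    } else if (pA) Sx1 <- Sx1 + 1L
    else Sx2 <- Sx2 + 1L
  }
  list(Ss = Ss, Sf = Sf, Sx1 = Sx1, Sx2 = Sx2, ambiguousShared = amb)
}

.hudson_fst_from_codes <- function(codeA, codeB) {
  Hw <- (.pi_total(codeA) + .pi_total(codeB)) / 2
  Hb <- .dxy_total(codeA, codeB)
  if (Hb == 0) return(NA_real_)
  1 - Hw / Hb
}

#' Hudson's FST between two populations
#'
#' FST = 1 - Hw/Hb with Hw the mean of the two within-population mean
#' pairwise differences and Hb the between-population mean pairwise
#' difference.  Slightly negative estimates are reported as computed.
#'
#' @param alnA,alnB \linkS4class{LocusAlignment}s with >= 2 sequences each
#'   and a shared kept-site universe.
#' @return FST, or \code{NA_real_} when there is no variation at all
#'   (Hb = 0).
#' @export
hudsonFst <- function(alnA, alnB) {
  .check_same_universe(alnA, alnB)
  if (nSequences(alnA) < 2L || nSequences(alnB) < 2L)
    stop("input error: need >= 2 sequences per population")
  .hudson_fst_from_codes(.coded_matrix(alnA), .coded_matrix(alnB))
}

#' Permutation test of FST
#'
#' Sequences are shuffled between the two population labels (sample sizes
#' preserved); p = (1 + #permuted FST >= observed) / (nPerm + 1).
#'
#' @param alnA,alnB the two populations' alignments.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with \code{fst} (observed) and \code{p}.
#' @export
fstPermutationTest <- function(alnA, alnB, nPerm = 1000L, seed = 1L) {
  if (nPerm <= 0L) stop("degenerate test: nPerm must be positive")
  .check_same_universe(alnA, alnB)
  codeA <- .coded_matrix(alnA); codeB <- .coded_matrix(alnB)
  obs <- .hudson_fst_from_codes(codeA, codeB)
  if (is.na(obs)) return(list(fst = NA_real_, p = NA_real_))
  pooled <- rbind(codeA, codeB)
  n1 <- nrow(codeA); n <- nrow(pooled)
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(nPerm)) {
    idx <- sample.int(n)
    f <- .hudson_fst_from_codes(pooled[idx[seq_len(n1)], , drop = FALSE],
                                pooled[idx[-seq_len(n1)], , drop = FALSE])
    if (!is.na(f) && f >= obs) ge <- ge + 1L
  }
  list(fst = obs, p = (1 + ge) / (nPerm + 1))
}

#' Two-population differentiation record for one locus
#'
#' Convenience wrapper assembling Hudson's FST with permutation p,
#' shared/fixed/exclusive site counts and Dxy into one row.
#'
#' @inheritParams fstPermutationTest
#' @return one-row data.frame with columns \code{locus}, \code{fst},
#'   \code{fst_p}, \code{Ss}, \code{Sf}, \code{Sx1}, \code{Sx2},
#'   \code{dxy}.
#' @export
popPairDiff <- function(alnA, alnB, nPerm = 1000L, seed = 1L) {
  pt <- fstPermutationTest(alnA, alnB, nPerm = nPerm, seed = seed)
  cl <- classifyPolymorphisms(alnA, alnB)
  data.frame(locus = locusName(alnA), fst = pt$fst, fst_p = pt$p,
             Ss = cl$Ss, Sf = cl$Sf, Sx1 = cl$Sx1, Sx2 = cl$Sx2,
             dxy = dxy(alnA, alnB), stringsAsFactors = FALSE)
}
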