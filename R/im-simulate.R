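## Two-population isolation-with-migration coalescent under infinite sites.
##
## Time scaling: time is measured in units of 1/mu generations (mutational
## units), so with theta = 4*N*mu per locus the pair-coalescence rate within
## population j is 2/theta_j, the per-lineage backward migration rate is m_j
## (lineages sampled in population j move their ancestry to the other
## population), and mutations fall on branches as a Poisson process of rate
## 1 per lineage per unit time.  Under this convention E[pi] = theta for
## n = 2, E[S] = theta * a_n, and the effective number of migrant gene
## copies per generation is 2Nm_j = theta_j * m_j / 2, matching the scaled
## parameter estimates this package converts with convertUnits().

# Fast core: simulate the genealogy and return, for every mutation, the
# number of descendant sample copies in population 1 (c1) and 2 (c2).
# Only descendant counts are tracked, never tip identities.  The compiled
# implementation carries the work; the R twin below (same algorithm) backs
# the cross-implementation consistency test.
.sim_im_counts <- function(n1, n2, theta1, theta2, thetaA, tSplit, m1, m2)
  .sim_im_counts_cpp(n1, n2, theta1, theta2, thetaA, tSplit, m1, m2)

.sim_im_counts_r <- function(n1, n2, theta1, theta2, thetaA, tSplit, m1, m2) {
  stopifnot(n1 + n2 >= 2, theta1 > 0, theta2 > 0, thetaA > 0,
            tSplit >= 0, m1 >= 0, m2 >= 0)
  a1 <- c(rep(1L, n1), rep(0L, n2))   # pop-1 descendant copies per lineage
  a2 <- c(rep(0L, n1), rep(1L, n2))
  pop <- c(rep(1L, n1), rep(2L, n2))
  time <- 0
  merged <- tSplit <= 0
  if (merged) pop[] <- 0L
  cap <- 256L; nmut <- 0L
  mc1 <- integer(cap); mc2 <- integer(cap)
  add_muts <- function(idx) {
    nn <- length(idx)
    if (nmut + nn > cap) {
      while (nmut + nn > cap) cap <<- cap * 2L
      length(mc1) <<- cap; length(mc2) <<- cap
    }
    mc1[nmut + seq_len(nn)] <<- a1[idx]
    mc2[nmut + seq_len(nn)] <<- a2[idx]
    nmut <<- nmut + nn
  }
  drop_muts <- function(dt) {
    k <- length(pop)
    nm <- rpois(1L, k * dt)
    if (nm > 0L) add_muts(sample.int(k, nm, replace = TRUE))
  }
  while (length(pop) > 1L) {
    k <- length(pop)
    if (!merged) {
      i1 <- which(pop == 1L); i2 <- which(pop == 2L)
      k1 <- length(i1); k2 <- length(i2)
      rates <- c(k1 * (k1 - 1) / theta1, k2 * (k2 - 1) / theta2,
                 k1 * m1, k2 * m2)
      tot <- sum(rates)
      dt <- if (tot > 0) rexp(1L, tot) else Inf
      if (time + dt >= tSplit) {            # cross the split: merge pops
        drop_muts(tSplit - time)
        time <- tSplit
        pop[] <- 0L
        merged <- TRUE
        next
      }
      drop_muts(dt)
      time <- time + dt
      ev <- sample.int(4L, 1L, prob = rates)
      if (ev == 1L) {                        # coalescence in pop 1
        pr <- i1[sample.int(k1, 2L)]
        a1[pr[1]] <- a1[pr[1]] + a1[pr[2]]
        a2[pr[1]] <- a2[pr[1]] + a2[pr[2]]
        a1 <- a1[-pr[2]]; a2 <- a2[-pr[2]]; pop <- pop[-pr[2]]
      } else if (ev == 2L) {
        pr <- i2[sample.int(k2, 2L)]
        a1[pr[1]] <- a1[pr[1]] + a1[pr[2]]
        a2[pr[1]] <- a2[pr[1]] + a2[pr[2]]
        a1 <- a1[-pr[2]]; a2 <- a2[-pr[2]]; pop <- pop[-pr[2]]
      } else if (ev == 3L) {                 # lineage in pop 1 -> pop 2
        pop[i1[sample.int(k1, 1L)]] <- 2L
      } else {
        pop[i2[sample.int(k2, 1L)]] <- 1L
      }
    } else {                                 # ancestral population
      dt <- rexp(1L, k * (k - 1) / thetaA)
      drop_muts(dt)
      time <- time + dt
      pr <- sample.int(k, 2L)
      a1[pr[1]] <- a1[pr[1]] + a1[pr[2]]
      a2[pr[1]] <- a2[pr[1]] + a2[pr[2]]
      a1 <- a1[-pr[2]]; a2 <- a2[-pr[2]]; pop <- pop[-pr[2]]
    }
  }
  list(c1 = mc1[seq_len(nmut)], c2 = mc2[seq_len(nmut)])
}

# Per-locus summary statistics straight from mutation descendant counts.
# L is the locus length in bp used for per-site scalings.
.locus_stats_from_counts <- function(c1, c2, n1, n2, L) {
  seg1 <- c1 > 0L & c1 < n1
  seg2 <- c2 > 0L & c2 < n2
  pi1 <- sum(2 * c1 * (n1 - c1)) / (n1 * (n1 - 1)) / L
  pi2 <- sum(2 * c2 * (n2 - c2)) / (n2 * (n2 - 1)) / L
  HbTot <- sum(c1 * (n2 - c2) + (n1 - c1) * c2) / (n1 * n2)
  HwTot <- (sum(2 * c1 * (n1 - c1)) / (n1 * (n1 - 1)) +
            sum(2 * c2 * (n2 - c2)) / (n2 * (n2 - 1))) / 2
  fst <- if (HbTot > 0) 1 - HwTot / HbTot else NA_real_
  c(pi1 = pi1, pi2 = pi2, fst = fst,
    Ss = sum(seg1 & seg2),
    Sf = sum((c1 == n1 & c2 == 0L) | (c1 == 0L & c2 == n2)),
    Sx1 = sum(seg1 & !seg2),
    Sx2 = sum(seg2 & !seg1),
    dxy = HbTot / L)
}

#' Simulate one locus under the isolation-with-migration model
#'
#' Structured coalescent backward in time: pair-coalescence rate
#' 2/theta_j within population j, per-lineage backward migration rate
#' m_j, merger into the ancestral population (pair rate 2/thetaA) at
#' scaled time t; mutations fall as a Poisson process of rate 1 per
#' lineage per unit branch length and are mapped onto distinct,
#' uniformly chosen alignment columns (infinite sites).
#'
#' @param params an \linkS4class{IMParams}.
#' @param n1,n2 sample sizes in populations 1 and 2.
#' @param length locus length in bp (alignment columns).
#' @param seed integer seed; set before all randomness.
#' @param popNames labels for the two populations.
#' @param maxRetries retries when the mutation count exceeds
#'   \code{length} (infinite-sites violation) before erroring.
#' @return a \linkS4class{LocusAlignment} with attribute
#'   \code{"mutationCounts"} (data.frame of per-mutation descendant
#'   counts c1, c2 and columns).
#' @examples
#' p <- imParams(2, 2, 1, 1, 0.5, 0.5)
#' aln <- simulateIMLocus(p, n1 = 5, n2 = 5, length = 300, seed = 7)
#' segregatingSites(aln)$count
#' @export
simulateIMLocus <- function(params, n1, n2, length, seed = NULL,
                            popNames = c("pop1", "pop2"), maxRetries = 20L) {
  stopifnot(is(params, "IMParams"), length >= 1)
  if (!is.null(seed)) set.seed(seed)
  for (tryi in seq_len(maxRetries)) {
    sim <- .sim_im_tips(n1, n2, params@theta1, params@theta2, params@thetaA,
                        params@t, params@m1, params@m2)
    if (length(sim$carriers) <= length) {
      S <- length(sim$carriers)
      cols <- if (S > 0) sort(sample.int(length, S)) else integer(0)
      anc <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      m <- matrix(rep(anc, each = n1 + n2), nrow = n1 + n2)
      for (s in seq_len(S)) {
        der <- sample(setdiff(c("A", "C", "G", "T"), anc[cols[s]]), 1L)
        m[sim$carriers[[s]], cols[s]] <- der
      }
      ids <- c(if (n1 > 0) paste0(popNames[1], "_", seq_len(n1)),
               if (n2 > 0) paste0(popNames[2], "_", seq_len(n2)))
      aln <- locusAlignment("simulated",
                            setNames(apply(m, 1L, paste0, collapse = ""), ids),
                            c(rep(popNames[1], n1), rep(popNames[2], n2)))
      attr(aln, "mutationCounts") <- data.frame(
        column = cols,
        c1 = vapply(sim$carriers, function(x) sum(x <= n1), integer(1)),
        c2 = vapply(sim$carriers, function(x) sum(x > n1), integer(1)))
      return(aln)
    }
  }
  stop("infinite-sites violation: more mutations than columns after ",
       maxRetries, " retries; enlarge the locus length")
}

# Tip-tracking variant of the core (needed to emit actual haplotypes).
.sim_im_tips <- function(n1, n2, theta1, theta2, thetaA, tSplit, m1, m2) {
  stopifnot(theta1 > 0, theta2 > 0, thetaA > 0)
  lin <- lapply(seq_len(n1 + n2), identity)
  pop <- c(rep(1L, n1), rep(2L, n2))
  time <- 0
  merged <- tSplit <= 0
  if (merged) pop[] <- 0L
  carriers <- list()
  drop_muts <- function(dt) {
    k <- length(pop)
    nm <- rpois(1L, k * dt)
    if (nm > 0L)
      carriers[length(carriers) + seq_len(nm)] <<-
        lin[sample.int(k, nm, replace = TRUE)]
  }
  merge_pair <- function(pr) {
    lin[[pr[1]]] <<- c(lin[[pr[1]]], lin[[pr[2]]])
    lin[[pr[2]]] <<- NULL
    pop <<- pop[-pr[2]]
  }
  while (length(pop) > 1L) {
    k <- length(pop)
    if (!merged) {
      i1 <- which(pop == 1L); i2 <- which(pop == 2L)
      k1 <- length(i1); k2 <- length(i2)
      rates <- c(k1 * (k1 - 1) / theta1, k2 * (k2 - 1) / theta2,
                 k1 * m1, k2 * m2)
      tot <- sum(rates)
      dt <- if (tot > 0) rexp(1L, tot) else Inf
      if (time + dt >= tSplit) {
        drop_muts(tSplit - time)
        time <- tSplit; pop[] <- 0L; merged <- TRUE
        next
      }
      drop_muts(dt); time <- time + dt
      ev <- sample.int(4L, 1L, prob = rates)
      if (ev == 1L) merge_pair(i1[sample.int(k1, 2L)])
      else if (ev == 2L) merge_pair(i2[sample.int(k2, 2L)])
      else if (ev == 3L) pop[i1[sample.int(k1, 1L)]] <- 2L
      else pop[i2[sample.int(k2, 1L)]] <- 1L
    } else {
      dt <- rexp(1L, k * (k - 1) / thetaA)
      drop_muts(dt); time <- time + dt
      merge_pair(sample.int(k, 2L))
    }
  }
  list(carriers = carriers)
}

#' Summary-statistic vector for a multilocus dataset
#'
#' For every locus pair (population 1 alignment, population 2 alignment)
#' the per-locus statistics pi1, pi2, FST, Ss, Sf, Sx1, Sx2 and Dxy are
#' computed; the dataset vector is their mean and variance across loci
#' (NA-aware for FST at invariant loci).
#'
#' @param lociPairs list of two-element lists of
#'   \linkS4class{LocusAlignment}s (population 1, population 2), sharing
#'   kept sites within a locus.
#' @return named numeric vector \code{mean_*}, \code{var_*} for the eight
#'   statistics, plus \code{n_fst_defined}.
#' @export
datasetSummaryStats <- function(lociPairs) {
  if (length(lociPairs) < 1L) stop("need >= 1 locus")
  per <- t(vapply(lociPairs, function(pr) {
    alnA <- pr[[1]]; alnB <- pr[[2]]
    cl <- classifyPolymorphisms(alnA, alnB)
    c(pi1 = nucleotideDiversity(alnA), pi2 = nucleotideDiversity(alnB),
      fst = hudsonFst(alnA, alnB), Ss = cl$Ss, Sf = cl$Sf,
      Sx1 = cl$Sx1, Sx2 = cl$Sx2, dxy = dxy(alnA, alnB))
  }, numeric(8)))
  .summarise_stat_rows(per)
}

.summarise_stat_rows <- function(per) {
  mn <- apply(per, 2L, mean, na.rm = TRUE)
  vr <- apply(per, 2L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1L) var(x) else 0
  })
  c(setNames(mn, paste0("mean_", colnames(per))),
    setNames(vr, paste0("var_", colnames(per))),
    n_fst_defined = sum(!is.na(per[, "fst"])))
}

# Simulate a whole multilocus design and return the dataset summary vector
# without materialising alignments (ABC fast path).
.sim_dataset_stats <- function(params, design) {
  per <- t(mapply(function(n1, n2, L) {
    cc <- .sim_im_counts(n1, n2, params@theta1, params@theta2,
                         params@thetaA, params@t, params@m1, params@m2)
    .locus_stats_from_counts(cc$c1, cc$c2, n1, n2, L)
  }, design$n1, design$n2, design$length))
  .summarise_stat_rows(per)
}

## Single-population coalescent helpers (neutrality null distributions).

# Genealogy intervals for one panmictic population of scaled size theta:
# list of per-interval durations and the lineage tip sets active in each.
.coalescent_intervals <- function(n, theta = 1) {
  lin <- lapply(seq_len(n), identity)
  dts <- numeric(n - 1L)
  sets <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(lin)
    dts[step] <- rexp(1L, k * (k - 1) / theta)
    sets[[step]] <- lin
    pr <- sample.int(k, 2L)
    lin[[pr[1]]] <- c(lin[[pr[1]]], lin[[pr[2]]])
    lin[[pr[2]]] <- NULL
  }
  list(dt = dts, sets = sets)
}

# One neutral replicate conditional on n and S: throw S mutations uniformly
# on the genealogy's branches; returns the n x S 0/1 haplotype matrix.
.neutral_fixed_s_matrix <- function(n, S) {
  g <- .coalescent_intervals(n)
  kvec <- vapply(g$sets, length, integer(1))
  w <- kvec * g$dt
  m <- matrix(0L, nrow = n, ncol = S)
  if (S > 0L) {
    iv <- sample.int(length(w), S, replace = TRUE, prob = w)
    for (s in seq_len(S)) {
      sets <- g$sets[[iv[s]]]
      m[sets[[sample.int(length(sets), 1L)]], s] <- 1L
    }
  }
  m
}

.stats_from_binary <- function(m) {
  n <- nrow(m); S <- ncol(m)
  cnt <- colSums(m)
  piTot <- sum(2 * cnt * (n - cnt)) / (n * (n - 1))
  cst <- .tajima_constants(n)
  D <- if (S > 0) (piTot - S / cst$a1) /
    sqrt(cst$e1 * S + cst$e2 * S * (S - 1)) else NA_real_
  singles <- cnt == 1L | cnt == (n - 1L)
  U <- integer(n)
  for (j in which(singles)) {
    carrier <- if (cnt[j] == 1L) which(m[, j] == 1L) else which(m[, j] == 0L)
    U[carrier] <- U[carrier] + 1L
  }
  R2 <- if (S > 0) sqrt(sum((U - piTot / 2)^2) / n) / S else NA_real_
  k_obs <- nrow(unique(m))
  c(D = D, R2 = R2, piTot = piTot, k = k_obs)
}

#' Coalescent null distribution test for neutrality statistics
#'
#' Simulates the standard neutral coalescent conditional on the observed
#' sample size and number of segregating sites (mutations placed uniformly
#' on the genealogy) and returns two-tailed (D, Fs) or lower-tail (R2)
#' p-values for Tajima's D, Fu's Fs and R2.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param nrep number of coalescent replicates.
#' @param seed integer seed.
#' @return list with observed \code{D}, \code{Fs}, \code{R2} and p-values
#'   \code{p_D}, \code{p_Fs}, \code{p_R2} (NA when the statistic is
#'   undefined).
#' @export
neutralityTest <- function(aln, nrep = 10000L, seed = 1L) {
  obs_D <- tajimasD(aln)
  obs_R2 <- ramosOnsinsR2(aln)
  S <- segregatingSites(aln)$count
  n <- nSequences(aln)
  if (S == 0L)
    return(list(D = NA_real_, Fs = NA_real_, R2 = NA_real_,
                p_D = NA_real_, p_Fs = NA_real_, p_R2 = NA_real_))
  obs_Fs <- fusFs(aln)$Fs
  set.seed(seed)
  sim <- t(vapply(seq_len(nrep), function(b) {
    st <- .stats_from_binary(.neutral_fixed_s_matrix(n, S))
    Sp <- ewensKTail(n, max(st[["piTot"]], 1e-12), st[["k"]])
    Fs <- if (Sp > 0 && Sp < 1) log(Sp / (1 - Sp)) else sign(Sp - 0.5) * 1e3
    c(D = st[["D"]], Fs = Fs, R2 = st[["R2"]])
  }, numeric(3)))
  twoTail <- function(x, obs)
    min(1, 2 * min(mean(x <= obs, na.rm = TRUE), mean(x >= obs, na.rm = TRUE)))
  list(D = obs_D, Fs = obs_Fs, R2 = obs_R2,
       p_D = twoTail(sim[, "D"], obs_D),
       p_Fs = twoTail(sim[, "Fs"], obs_Fs),
       p_R2 = mean(sim[, "R2"] <= obs_R2, na.rm = TRUE))
}
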