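## Sympatric-versus-allopatric comparison layer: mean-FST contrast, the
## ranked normalized-difference statistic, exceedance counts, and the
## locus-bootstrapped neighbor-joining tree on mean FST.

.check_panel <- function(panel) {
  req <- c("locus", "fst_symp", "fst_allo")
  if (!all(req %in% names(panel)))
    stop("panel needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(panel$locus)) stop("duplicate locus names in panel")
  invisible(panel)
}

#' Mean-FST contrast between a sympatric and an allopatric pair
#'
#' Arithmetic means and sample SDs of the per-locus FST vectors, with an
#' equal-variance two-sample t test; sign convention
#' t = (mean_symp - mean_allo)/SE, two-sided p.
#'
#' @param panel data.frame with columns \code{locus}, \code{fst_symp},
#'   \code{fst_allo}.
#' @return list with \code{mean_symp}, \code{sd_symp}, \code{mean_allo},
#'   \code{sd_allo}, \code{t}, \code{df}, \code{p}.
#' @export
meanFstContrast <- function(panel) {
  .check_panel(panel)
  x <- panel$fst_symp; y <- panel$fst_allo
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need >= 2 loci")
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  t <- if (se > 0) (mean(x) - mean(y)) / se else 0
  df <- nx + ny - 2L
  p <- if (se > 0) 2 * pt(-abs(t), df) else 1
  list(mean_symp = mean(x), sd_symp = sd(x),
       mean_allo = mean(y), sd_allo = sd(y),
       t = t, df = df, p = p)
}

#' Rank correlation of normalized FST differences with FST
#'
#' d_i = (fst_allo_i - fst_symp_i)/fst_allo_i is ranked ascending against
#' the ranks of the chosen FST vector (average ranks on ties); r is the
#' Pearson correlation of the two rank vectors (Spearman), with a
#' two-sided p from the t approximation on n - 2 df.  A strongly negative
#' r in the \code{"vs_symp"} direction is the signature of differential
#' introgression: loci that already differentiate the sympatric pair gain
#' little extra differentiation in allopatry.
#'
#' @param panel data.frame with \code{fst_symp}, \code{fst_allo}.
#' @param direction rank d against the sympatric (\code{"vs_symp"}) or
#'   allopatric (\code{"vs_allo"}) FST vector.
#' @return list with \code{r}, \code{p}, \code{n}, \code{sum_d2}
#'   (sum of squared rank differences, for the tie-free case).
#' @export
normalizedDiffRankCorrelation <- function(panel,
                                          direction = c("vs_symp", "vs_allo")) {
  .check_panel(panel)
  direction <- match.arg(direction)
  if (any(panel$fst_allo == 0)) stop("fst_allo contains zeros: d undefined")
  n <- nrow(panel)
  if (n < 3L) stop("need >= 3 loci")
  d <- (panel$fst_allo - panel$fst_symp) / panel$fst_allo
  v <- if (direction == "vs_symp") panel$fst_symp else panel$fst_allo
  rd <- rank(d); rv <- rank(v)
  if (sd(rd) == 0 || sd(rv) == 0) {
    warning("constant rank vector: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n, sum_d2 = NA_real_))
  }
  r <- cor(rd, rv)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2), n = n,
       sum_d2 = sum((rd - rv)^2))
}

#' Count loci where the sympatric pair exceeds the allopatric pair
#'
#' @param panel data.frame with \code{fst_symp}, \code{fst_allo}.
#' @return integer count of loci with fst_symp > fst_allo.
#' @export
countSympatricExceed <- function(panel) {
  .check_panel(panel)
  sum(panel$fst_symp > panel$fst_allo)
}

#' Mean-FST distance matrix over all population pairs
#'
#' Entrywise mean of per-locus FST across loci for every population pair;
#' negative means are floored at zero for tree building (flagged).
#'
#' @param perLocus data.frame with columns \code{locus}, \code{pop1},
#'   \code{pop2}, \code{fst}; every pair must be present for each locus.
#' @return list with \code{d} (symmetric matrix, zero diagonal),
#'   \code{labels}, and \code{floored} (pairs whose mean was negative).
#' @export
meanFstMatrix <- function(perLocus) {
  labs <- sort(unique(c(perLocus$pop1, perLocus$pop2)))
  k <- length(labs)
  d <- matrix(0, k, k, dimnames = list(labs, labs))
  floored <- character()
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    sel <- (perLocus$pop1 == labs[i] & perLocus$pop2 == labs[j]) |
           (perLocus$pop1 == labs[j] & perLocus$pop2 == labs[i])
    if (!any(sel)) stop("missing pair: ", labs[i], " - ", labs[j])
    m <- mean(perLocus$fst[sel], na.rm = TRUE)
    if (is.nan(m)) stop("pair ", labs[i], "-", labs[j], " has no defined FST")
    if (m < 0) {
      floored <- c(floored, paste0(labs[i], "-", labs[j]))
      m <- 0
    }
    d[i, j] <- d[j, i] <- m
  }
  list(d = d, labels = labs, floored = floored)
}

#' Neighbor-joining tree from a mean-FST distance matrix
#'
#' Saitou-Nei neighbor joining via \code{\link[ape]{nj}}; taxa are
#' presented in label order so tie handling is deterministic.
#'
#' @param dm output of [meanFstMatrix()], or a symmetric matrix.
#' @return an \code{ape} \code{phylo} object (unrooted).
#' @export
njFstTree <- function(dm) {
  d <- if (is.list(dm)) dm$d else dm
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  if (nrow(d) < 3L) stop("need >= 3 taxa")
  ape::nj(as.dist(d))
}

# bipartitions (as canonical label strings) of an unrooted phylo tree
.tree_splits <- function(tree) {
  labs <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  out <- character()
  for (p in parts) {
    side <- sort(attr(parts, "labels")[p])
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) next
    comp <- setdiff(labs, side)
    canon <- if (paste(side, collapse = ",") < paste(comp, collapse = ","))
      side else comp
    out <- c(out, paste(canon, collapse = ","))
  }
  unique(out)
}

#' Locus-bootstrap support for the mean-FST NJ tree
#'
#' Resamples loci with replacement B times, rebuilds the mean-FST matrix
#' and its NJ tree, and reports for every internal split of the point tree
#' the percentage of bootstrap trees containing it.
#'
#' @param perLocus per-locus FST table as in [meanFstMatrix()].
#' @param B number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return list with \code{tree} (point NJ tree), \code{support} (named
#'   percentage per split, names are comma-joined taxon sets), and
#'   \code{B}.
#' @export
locusBootstrapSupport <- function(perLocus, B = 100L, seed = 1L) {
  if (B <= 0L) stop("B must be positive")
  loci <- unique(perLocus$locus)
  if (length(loci) < 2L) stop("need >= 2 loci to bootstrap")
  point <- njFstTree(meanFstMatrix(perLocus))
  splits <- .tree_splits(point)
  hits <- setNames(numeric(length(splits)), splits)
  set.seed(seed)
  for (b in seq_len(B)) {
    res <- sample(loci, length(loci), replace = TRUE)
    boot_rows <- do.call(rbind, lapply(seq_along(res), function(i) {
      rows <- perLocus[perLocus$locus == res[i], , drop = FALSE]
      rows$locus <- paste0(rows$locus, "_b", i)
      rows
    }))
    bt <- njFstTree(meanFstMatrix(boot_rows))
    bs <- .tree_splits(bt)
    hits[splits %in% bs] <- hits[splits %in% bs] + 1
  }
  list(tree = point, support = 100 * hits / B, B = B)
}
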