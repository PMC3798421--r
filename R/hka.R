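## Multilocus HKA goodness-of-fit test, two-population design.
##
## Moment model per locus i (a(n) = sum_{j<n} 1/j):
##   E[S1_i] = theta_i * a(n1_i)
##   E[S2_i] = f * theta_i * a(n2_i)
##   E[D_i]  = theta_i * (T + (1+f)/2)
## with variances Var[S_j] = E[S_j] + (scale*theta_i)^2 * b(n_j)
## (b(n) = sum_{j<n} 1/j^2, scale = 1 or f) and
## Var[D] = E[D] + (theta_i*(1+f)/2)^2.  The chi-square statistic sums
## (obs-exp)^2/var over the 3L cells; df = 2L - 2 (3L cells minus L fitted
## theta_i minus T and f, plus one dependency across the moment system).

.hka_an <- function(n) sum(1 / seq_len(n - 1))
.hka_bn <- function(n) sum(1 / seq_len(n - 1)^2)

# closed-form theta_i given (T, f) from the per-locus total moment equation
.hka_thetas <- function(S1, S2, D, a1, a2, T, f) {
  (S1 + S2 + D) / (a1 + f * a2 + T + (1 + f) / 2)
}

.hka_objective <- function(par, S1, S2, D, a1, a2) {
  T <- par[1]; f <- par[2]
  if (T < 0 || f <= 0) return(1e12)
  th <- .hka_thetas(S1, S2, D, a1, a2, T, f)
  g1 <- sum(S2) - f * sum(th * a2)
  g2 <- sum(D) - sum(th * (T + (1 + f) / 2))
  g1^2 + g2^2
}

#' Multilocus HKA test for two populations
#'
#' Fits the HKA moment system (per-locus mutation parameters theta_i, a
#' relative size f of population 2, and a scaled divergence time T) to
#' per-locus segregating-site counts in the two populations and their
#' mean pairwise divergence, then computes the goodness-of-fit chi-square
#' over the 3L observation cells.
#'
#' @param input data.frame with one row per locus and columns \code{S1},
#'   \code{S2} (segregating sites in populations 1 and 2), \code{D} (mean
#'   between-population pairwise divergence, count scale), \code{n1},
#'   \code{n2} (sample sizes) and optionally \code{locus} and \code{L}.
#' @param tol convergence tolerance on the moment residuals.
#' @return list with \code{chi2}, \code{df} (= 2L - 2), \code{p},
#'   \code{T}, \code{f}, \code{theta} (per retained locus), \code{expected}
#'   (data.frame of expected S1, S2, D), \code{excluded} (loci dropped for
#'   having S1 = S2 = D = 0).
#' @examples
#' inp <- data.frame(S1 = c(10, 20), S2 = c(12, 18), D = c(8, 15),
#'                   n1 = c(10, 10), n2 = c(12, 12))
#' hkaFit(inp)$df
#' @export
hkaFit <- function(input, tol = 1e-10) {
  req <- c("S1", "S2", "D", "n1", "n2")
  if (!all(req %in% names(input))) stop("missing columns: ",
                                        paste(setdiff(req, names(input)), collapse = ", "))
  zero <- with(input, S1 == 0 & S2 == 0 & D == 0)
  if (any(zero)) {
    warning(sum(zero), " locus/loci with S1 = S2 = D = 0 excluded from HKA")
    input <- input[!zero, , drop = FALSE]
  }
  L <- nrow(input)
  if (L < 2L) stop("HKA needs >= 2 informative loci")
  S1 <- input$S1; S2 <- input$S2; D <- input$D
  a1 <- vapply(input$n1, .hka_an, numeric(1))
  a2 <- vapply(input$n2, .hka_an, numeric(1))
  b1 <- vapply(input$n1, .hka_bn, numeric(1))
  b2 <- vapply(input$n2, .hka_bn, numeric(1))

  starts <- expand.grid(T = c(0.5, 2, 10, 50), f = c(0.25, 1, 4))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- optim(c(starts$T[s], starts$f[s]), .hka_objective,
                 S1 = S1, S2 = S2, D = D, a1 = a1, a2 = a2,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish with BFGS from the best start
  best <- tryCatch(
    optim(best$par, .hka_objective, S1 = S1, S2 = S2, D = D,
          a1 = a1, a2 = a2, method = "BFGS",
          control = list(reltol = 1e-15, maxit = 2000)),
    error = function(e) best)
  scale2 <- (sum(S1) + sum(S2) + sum(D))^2
  if (best$value > tol * max(1, scale2))
    stop("HKA solver failed to converge; residual^2 = ",
         format(best$value), " for totals (",
         sum(S1), ", ", sum(S2), ", ", sum(D), ")")
  T <- best$par[1]; f <- best$par[2]
  th <- .hka_thetas(S1, S2, D, a1, a2, T, f)
  eS1 <- th * a1
  eS2 <- f * th * a2
  eD <- th * (T + (1 + f) / 2)
  vS1 <- eS1 + th^2 * b1
  vS2 <- eS2 + (f * th)^2 * b2
  vD <- eD + (th * (1 + f) / 2)^2
  chi2 <- sum((S1 - eS1)^2 / vS1) + sum((S2 - eS2)^2 / vS2) +
    sum((D - eD)^2 / vD)
  df <- 2L * L - 2L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       T = T, f = f, theta = th,
       expected = data.frame(locus = if (!is.null(input$locus)) input$locus
                             else seq_len(L),
                             eS1 = eS1, eS2 = eS2, eD = eD),
       excluded = sum(zero))
}

#' Assemble HKA input from per-locus alignment pairs
#'
#' @param lociPairs list of two-element lists of
#'   \linkS4class{LocusAlignment}s (population 1, population 2).
#' @return data.frame suitable for [hkaFit()]: per-locus S1, S2, D
#'   (count-scale mean pairwise divergence), n1, n2, L.
#' @export
hkaInput <- function(lociPairs) {
  do.call(rbind, lapply(lociPairs, function(pr) {
    alnA <- pr[[1]]; alnB <- pr[[2]]
    L <- length(keptSites(alnA))
    data.frame(locus = locusName(alnA),
               S1 = segregatingSites(alnA)$count,
               S2 = segregatingSites(alnB)$count,
               D = dxy(alnA, alnB) * L,
               n1 = nSequences(alnA), n2 = nSequences(alnB), L = L,
               stringsAsFactors = FALSE)
  }))
}
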