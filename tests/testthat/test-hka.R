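# independent brute-force solve of the same moment system: the L + 2
# equations are the per-locus totals, the pooled S2 equation and the
# pooled D equation; minimise their squared residuals jointly over
# (T, f, theta_1..L) from a grid of starts (zero at the exact solution)
oracle_hka_fit <- function(S1, S2, D, n1, n2) {
  a <- function(n) sum(1 / seq_len(n - 1))
  a1 <- vapply(n1, a, numeric(1)); a2 <- vapply(n2, a, numeric(1))
  L <- length(S1)
  obj <- function(par) {
    T <- par[1]; f <- par[2]; th <- par[-(1:2)]
    if (T < 0 || f <= 0 || any(th <= 0)) return(1e10)
    tot <- S1 + S2 + D - th * (a1 + f * a2 + T + (1 + f) / 2)
    g1 <- sum(S2) - f * sum(th * a2)
    g2 <- sum(D) - sum(th * (T + (1 + f) / 2))
    sum(tot^2) + g1^2 + g2^2
  }
  best <- NULL
  for (T0 in c(1, 5, 20)) for (f0 in c(0.5, 1, 2)) {
    th0 <- pmax((S1 + S2 + D) / (a1 + f0 * a2 + T0 + (1 + f0) / 2), 1e-3)
    fit <- optim(c(T0, f0, th0), obj, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-15))
    fit <- optim(fit$par, obj, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(T = best$par[1], f = best$par[2], theta = best$par[-(1:2)],
       value = best$value)
}

test_that("HKA chi-square vanishes at exact expectations and df = 2L - 2", {
  a <- function(n) sum(1 / seq_len(n - 1))
  th <- c(2, 4); Tt <- 3; f <- 0.8
  n1 <- c(10, 12); n2 <- c(9, 14)
  inp <- data.frame(S1 = th * sapply(n1, a), S2 = f * th * sapply(n2, a),
                    D = th * (Tt + (1 + f) / 2), n1 = n1, n2 = n2)
  fit <- hkaFit(inp)
  expect_lt(fit$chi2, 1e-8)
  expect_equal(fit$df, 2L)
  expect_equal(fit$T, Tt, tolerance = 1e-5)
  expect_equal(fit$f, f, tolerance = 1e-5)
  expect_equal(fit$theta, th, tolerance = 1e-5)

  # 21 loci: df = 40
  th21 <- seq(0.5, 4.5, length.out = 21)
  n21a <- rep(20, 21); n21b <- rep(25, 21)
  inp21 <- data.frame(S1 = th21 * sapply(n21a, a),
                      S2 = f * th21 * sapply(n21b, a),
                      D = th21 * (Tt + (1 + f) / 2), n1 = n21a, n2 = n21b)
  fit21 <- hkaFit(inp21)
  expect_equal(fit21$df, 40L)
  expect_lt(fit21$chi2, 1e-6)
  expect_gt(fit21$p, 0.99)
})

test_that("HKA fit equals an independent joint optimiser on noisy data", {
  set.seed(31)
  a <- function(n) sum(1 / seq_len(n - 1))
  for (rep in 1:3) {
    n1 <- sample(8:20, 3, replace = TRUE)
    n2 <- sample(8:20, 3, replace = TRUE)
    th <- runif(3, 1, 4); Tt <- runif(1, 1, 6); f <- runif(1, 0.5, 2)
    S1 <- rpois(3, th * sapply(n1, a)) + 1
    S2 <- rpois(3, f * th * sapply(n2, a)) + 1
    D <- rpois(3, th * (Tt + (1 + f) / 2)) + 1
    inp <- data.frame(S1 = S1, S2 = S2, D = D, n1 = n1, n2 = n2)
    fit <- hkaFit(inp)
    orc <- oracle_hka_fit(S1, S2, D, n1, n2)
    expect_equal(fit$T, orc$T, tolerance = 1e-4)
    expect_equal(fit$f, orc$f, tolerance = 1e-4)
    expect_equal(fit$theta, orc$theta, tolerance = 1e-4)
  }
})

test_that("HKA statistic is invariant to locus order and drops empty loci", {
  set.seed(37)
  a <- function(n) sum(1 / seq_len(n - 1))
  n1 <- c(10, 14, 12, 16); n2 <- c(11, 9, 15, 13)
  th <- c(1, 2, 3, 1.5)
  S1 <- rpois(4, th * sapply(n1, a)) + 1
  S2 <- rpois(4, th * sapply(n2, a)) + 1
  D <- rpois(4, th * 4) + 1
  inp <- data.frame(S1 = S1, S2 = S2, D = D, n1 = n1, n2 = n2)
  f1 <- hkaFit(inp)
  f2 <- hkaFit(inp[c(3, 1, 4, 2), ])
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-6)

  withzero <- rbind(inp, data.frame(S1 = 0, S2 = 0, D = 0, n1 = 10, n2 = 10))
  expect_warning(f3 <- hkaFit(withzero), "excluded")
  expect_equal(f3$chi2, f1$chi2, tolerance = 1e-8)
})

test_that("neutral isolation data are not rejected more often than nominal", {
  # simulate 12 replicate datasets from the no-migration model matching
  # the HKA assumptions; reject at the 5% chi-square cut
  set.seed(41)
  rejections <- 0L
  nrep <- 12L
  for (r in seq_len(nrep)) {
    pairs <- lapply(1:6, function(l) {
      aln <- simulateIMLocus(imParams(2, 2, 2, 4, 0, 0), 10, 10, 500)
      list(subsetPopulations(aln, "pop1"), subsetPopulations(aln, "pop2"))
    })
    fit <- hkaFit(hkaInput(pairs))
    if (fit$p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 3L)  # nominal 0.6 + Monte-Carlo slack
})
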