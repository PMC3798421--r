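test_that("simulator calibration matches coalescent closed forms", {
  # isolated population, n = 2: E[pi] = theta
  set.seed(201)
  theta <- 2
  pis <- replicate(10000,
    length(IMflow:::.sim_im_counts(2, 0, theta, 1, 1, 1e6, 0, 0)$c1))
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - theta), 3 * se)

  # E[S] = theta * a_n for n = 8
  Ss <- replicate(4000,
    length(IMflow:::.sim_im_counts(8, 0, 1.5, 1, 1, 1e6, 0, 0)$c1))
  expect_lt(abs(mean(Ss) - 1.5 * sum(1 / (1:7))), 3 * sd(Ss) / sqrt(4000))
})

test_that("model collapses to panmixia at t = 0 and isolates at large t", {
  set.seed(203)
  fsts <- replicate(2000, {
    cc <- IMflow:::.sim_im_counts(6, 6, 2, 2, 2, 0, 0, 0)
    IMflow:::.locus_stats_from_counts(cc$c1, cc$c2, 6, 6, 500)[["fst"]]
  })
  expect_lt(abs(mean(fsts, na.rm = TRUE)), 0.02)

  iso <- replicate(300, {
    cc <- IMflow:::.sim_im_counts(6, 6, 2, 2, 1, 8, 0, 0)
    st <- IMflow:::.locus_stats_from_counts(cc$c1, cc$c2, 6, 6, 500)
    c(st[["Ss"]], st[["Sf"]])
  })
  expect_lt(mean(iso[1, ]), 0.05)   # shared polymorphism vanishes
  expect_gt(mean(iso[2, ]), 3)      # fixed differences accumulate
})

test_that("migration monotonically erodes differentiation", {
  set.seed(207)
  grid <- c(0, 0.5, 2, 8)
  mfst <- sapply(grid, function(m) {
    mean(replicate(800, {
      cc <- IMflow:::.sim_im_counts(8, 8, 2, 2, 1, 3, m, m)
      IMflow:::.locus_stats_from_counts(cc$c1, cc$c2, 8, 8, 500)[["fst"]]
    }), na.rm = TRUE)
  })
  expect_true(all(diff(mfst) < 0))
  mss <- sapply(grid, function(m) {
    mean(replicate(800, {
      cc <- IMflow:::.sim_im_counts(8, 8, 2, 2, 1, 3, m, m)
      IMflow:::.locus_stats_from_counts(cc$c1, cc$c2, 8, 8, 500)[["Ss"]]
    }))
  })
  expect_true(all(diff(mss) > 0))
})

test_that("compiled and R genealogy cores agree in distribution", {
  set.seed(211)
  a <- replicate(1500, length(
    IMflow:::.sim_im_counts_cpp(6, 6, 2, 1, 1, 0.8, 0.5, 2)$c1))
  b <- replicate(1500, length(
    IMflow:::.sim_im_counts_r(6, 6, 2, 1, 1, 0.8, 0.5, 2)$c1))
  expect_lt(abs(mean(a) - mean(b)),
            3 * sqrt(var(a) / 1500 + var(b) / 1500))
})

test_that("alignment emission is deterministic, respects infinite sites,
           and matches the count-level statistics", {
  p <- imParams(2, 2, 1, 1, 0.5, 1)
  a1 <- simulateIMLocus(p, 6, 6, 300, seed = 9)
  a2 <- simulateIMLocus(p, 6, 6, 300, seed = 9)
  expect_identical(as.character(a1@sequences), as.character(a2@sequences))

  mc <- attr(a1, "mutationCounts")
  expect_equal(segregatingSites(a1)$count, nrow(mc))
  # per-column allele counts in the alignment equal the genealogy record
  m <- alignmentMatrix(a1)
  for (i in seq_len(nrow(mc))) {
    k <- mc$c1[i] + mc$c2[i]
    expect_equal(sort(as.integer(table(m[, mc$column[i]]))),
                 sort(c(12L - k, k)))
  }

  expect_error(simulateIMLocus(imParams(50, 50, 50, 10, 0, 0), 10, 10, 2,
                               seed = 1, maxRetries = 3),
               "infinite-sites")
})

test_that("dataset summary statistics compose the audited per-locus calls", {
  set.seed(223)
  mk <- function() {
    aln <- simulateIMLocus(imParams(2, 2, 1, 1, 0.5, 0.5), 5, 5, 200)
    list(subsetPopulations(aln, "pop1"), subsetPopulations(aln, "pop2"))
  }
  prs <- list(mk(), mk())
  st <- datasetSummaryStats(prs)
  hand_fst <- c(hudsonFst(prs[[1]][[1]], prs[[1]][[2]]),
                hudsonFst(prs[[2]][[1]], prs[[2]][[2]]))
  expect_equal(unname(st["mean_fst"]), mean(hand_fst, na.rm = TRUE))
  cl1 <- classifyPolymorphisms(prs[[1]][[1]], prs[[1]][[2]])
  cl2 <- classifyPolymorphisms(prs[[2]][[1]], prs[[2]][[2]])
  expect_equal(unname(st["mean_Ss"]), mean(c(cl1$Ss, cl2$Ss)))
  expect_equal(unname(st["var_Sf"]), var(c(cl1$Sf, cl2$Sf)))

  dup <- datasetSummaryStats(list(prs[[1]], prs[[1]]))
  expect_true(all(dup[grep("^var_", names(dup))] == 0))
})

test_that("neutrality null distributions centre near zero and reject at
           roughly nominal rates on neutral data", {
  set.seed(227)
  Ds <- ps <- numeric(60)
  for (i in 1:60) {
    aln <- simulateIMLocus(imParams(3, 3, 3, 0, 0, 0), 12, 0, 400)
    aln <- subsetPopulations(aln, "pop1")
    Ds[i] <- tajimasD(aln)
    if (i <= 25) ps[i] <- neutralityTest(aln, nrep = 400, seed = i)$p_D
  }
  Ds <- Ds[!is.na(Ds)]
  expect_lt(abs(mean(Ds)), 3 * sd(Ds) / sqrt(length(Ds)) + 0.15)
  expect_lte(sum(ps[1:25] < 0.05, na.rm = TRUE), 4L)
})
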