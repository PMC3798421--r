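test_that("segregating sites and diversity match hand enumeration", {
  aln <- locusAlignment("t", c(a = "ACGT", b = "ACGA", c = "ACGT", d = "CCGT"),
                        rep("P", 4))
  ss <- segregatingSites(aln)
  expect_equal(ss$count, 2L)
  expect_equal(ss$sites, c(1L, 4L))

  same <- locusAlignment("t", c(a = "ACGT", b = "ACGT"), rep("P", 2))
  expect_equal(segregatingSites(same)$count, 0L)
  expect_equal(nucleotideDiversity(same), 0)

  two <- locusAlignment("t", c(a = "ACGTACGTAA", b = "ACGTACGTAC"), rep("P", 2))
  expect_equal(nucleotideDiversity(two), 0.1)

  # 3 sequences, pairwise differences {1,1,2} over 10 sites
  three <- locusAlignment("t", c(a = "AAAAAAAAAA", b = "CAAAAAAAAA",
                                 c = "AACAAAAAAA"), rep("P", 3))
  expect_equal(nucleotideDiversity(three), (4 / 3) / 10, tolerance = 1e-12)

  expect_error(segregatingSites(locusAlignment("t", c(a = "ACGT"), "P")),
               "input error")
})

test_that("pi, theta, FST, Dxy agree with brute-force oracles to 1e-12", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    L <- sample(5:20, 1)
    pops <- rep(c("A", "B"), length.out = n)
    # biased alphabet so columns are often polymorphic but not saturated
    aln <- random_alignment(n, L, pops, alphabet = c("A", "A", "C", "G", "T"))
    m <- aln_char_matrix(aln)
    expect_equal(nucleotideDiversity(aln), oracle_pi(m), tolerance = 1e-12)
    alnA <- subsetPopulations(aln, "A")
    alnB <- subsetPopulations(aln, "B")
    mA <- aln_char_matrix(alnA); mB <- aln_char_matrix(alnB)
    expect_equal(dxy(alnA, alnB), oracle_dxy(mA, mB), tolerance = 1e-12)
    if (nrow(mA) >= 2 && nrow(mB) >= 2)
      expect_equal(hudsonFst(alnA, alnB), oracle_fst(mA, mB),
                   tolerance = 1e-12)
    S <- segregatingSites(aln)$count
    a1 <- sum(1 / seq_len(n - 1))
    expect_equal(wattersonTheta(aln), S / (a1 * L), tolerance = 1e-12)
  }
})

test_that("statistics are invariant under sequence reordering", {
  set.seed(7)
  aln <- random_alignment(6, 15)
  perm <- sample(names(aln@sequences))
  shuf <- subsetSequences(aln, perm)
  expect_equal(nucleotideDiversity(shuf), nucleotideDiversity(aln))
  expect_equal(wattersonTheta(shuf), wattersonTheta(aln))
  expect_equal(tajimasD(shuf), tajimasD(aln))
})

test_that("Tajima's D: undefined at S = 0, negative for all-singleton data,
           exact against an independent constants oracle", {
  mono <- locusAlignment("t", c(a = "ACGT", b = "ACGT", c = "ACGT",
                                d = "ACGT"), rep("P", 4))
  expect_true(is.na(tajimasD(mono)))

  # n = 6, five singleton sites: skewed frequency spectrum, D < 0
  base <- strrep("A", 12)
  seqs <- vapply(1:6, function(i) {
    s <- strsplit(base, "")[[1]]
    if (i <= 5) s[i] <- "T"
    paste0(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:6)
  singl <- locusAlignment("t", seqs, rep("P", 6))
  expect_lt(tajimasD(singl), 0)

  set.seed(55)
  for (rep in 1:10) {
    aln <- random_alignment(10, 25, rep("P", 10),
                            alphabet = c("A", "A", "A", "C", "G"))
    expect_equal(tajimasD(aln), oracle_tajima(aln_char_matrix(aln)),
                 tolerance = 1e-12)
  }
  # D = 0 exactly when pi_total = S/a1 (construction: n = 4, one site at
  # frequency 2/4 gives pi_total = 4/3... verify the identity numerically)
  aln <- locusAlignment("t", c(a = "AT", b = "AT", c = "AA", d = "AA"),
                        rep("P", 4))
  S <- segregatingSites(aln)$count
  piT <- nucleotideDiversity(aln) * 2
  a1 <- sum(1 / (1:3))
  D <- tajimasD(aln)
  expect_equal(sign(D), sign(piT - S / a1))
})

test_that("Ewens tail probability equals the Stirling-number summation", {
  expect_equal(ewensKTail(5, 1, 1), 1, tolerance = 1e-12)
  for (n in c(5, 8, 12)) for (theta in c(0.5, 1, 3)) for (k in c(2, 3, n)) {
    expect_equal(ewensKTail(n, theta, k), oracle_ewens_tail(n, theta, k),
                 tolerance = 1e-10)
  }
})

test_that("Fu's Fs: boundary clamp at one haplotype class, negative for
           star-like data, exact Ewens tail", {
  # every sequence its own haplotype (k = n): strongly negative Fs
  seqs <- c(a = "TAAAAA", b = "ATAAAA", c = "AATAAA", d = "AAATAA",
            e = "AAAATA")
  star <- locusAlignment("t", seqs, rep("P", 5))
  fs <- fusFs(star)
  expect_equal(fs$kHaplotypes, 5L)
  expect_lt(fs$Fs, 0)

  # n = 5, theta-hat from the data, k = 3: agree with Stirling oracle
  aln <- locusAlignment("t", c(a = "AATT", b = "AATT", c = "ATTT",
                               d = "ATTT", e = "TTTT"), rep("P", 5))
  fs2 <- fusFs(aln)
  m <- aln_char_matrix(aln)
  th <- oracle_pi_total(m)
  expect_equal(fs2$Sprime, oracle_ewens_tail(5, th, 3), tolerance = 1e-10)
  expect_equal(fs2$Fs, log(fs2$Sprime / (1 - fs2$Sprime)), tolerance = 1e-12)
  expect_false(fs2$clamped)
})

test_that("R2 matches its definition on hand-checkable cases", {
  # n = 2, one difference: U = (1,1), pi_total = 1, S = 1
  two <- locusAlignment("t", c(a = "AAAA", b = "AAAT"), rep("P", 2))
  expect_equal(ramosOnsinsR2(two), sqrt(((1 - 0.5)^2 * 2) / 2) / 1,
               tolerance = 1e-12)

  # no singletons, pi_total = 2 -> R2 = 1/S
  aln <- locusAlignment("t", c(a = "AATT", b = "AATT", c = "TTAA",
                               d = "TTAA"), rep("P", 4))
  m <- aln_char_matrix(aln)
  expect_equal(oracle_pi_total(m), 8 / 3)  # sanity on the fixture
  # construct the exact no-singleton pi_total = 2 case: 2 sites at 2/4
  aln2 <- locusAlignment("t", c(a = "TT", b = "TA", c = "AT", d = "AA"),
                         rep("P", 4))
  expect_equal(nucleotideDiversity(aln2) * 2, 4 / 3, tolerance = 1e-12)
  U0 <- rep(0, 4)
  expect_equal(ramosOnsinsR2(aln2),
               sqrt(sum((U0 - (4 / 3) / 2)^2) / 4) / 2, tolerance = 1e-12)

  mono <- locusAlignment("t", c(a = "AC", b = "AC"), rep("P", 2))
  expect_true(is.na(ramosOnsinsR2(mono)))
})

test_that("polymorphic-site classification partitions informative columns", {
  A <- locusAlignment("t", c(a1 = "AATA", a2 = "ATTA", a3 = "AATA"),
                      rep("P1", 3))
  B <- locusAlignment("t", c(b1 = "TATA", b2 = "TTTA", b3 = "TATG"),
                      rep("P2", 3))
  cl <- classifyPolymorphisms(A, B)
  # col1: A fixed 'A', B fixed 'T' -> Sf; col2: both segregate A/T -> Ss
  # col3: monomorphic identical; col4: B segregates A/G only -> Sx2
  expect_equal(cl$Sf, 1L)
  expect_equal(cl$Ss, 1L)
  expect_equal(cl$Sx1, 0L)
  expect_equal(cl$Sx2, 1L)

  set.seed(19)
  for (rep in 1:15) {
    aln <- random_alignment(6, 12, rep(c("A", "B"), each = 3),
                            alphabet = c("A", "A", "T"))
    alnA <- subsetPopulations(aln, "A"); alnB <- subsetPopulations(aln, "B")
    cl <- classifyPolymorphisms(alnA, alnB)
    m <- aln_char_matrix(aln)
    informative <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
    fixed_same <- 0L
    expect_equal(cl$Ss + cl$Sf + cl$Sx1 + cl$Sx2, informative - fixed_same)
  }
})

test_that("Hudson FST hits 1 at reciprocal fixation and its permutation
           test behaves under the null and the extreme alternative", {
  A <- locusAlignment("t", setNames(rep("AAAA", 8), paste0("a", 1:8)),
                      rep("P1", 8))
  B <- locusAlignment("t", setNames(rep("TTTT", 8), paste0("b", 1:8)),
                      rep("P2", 8))
  expect_equal(hudsonFst(A, B), 1)
  # permuted FST only reaches the observed value when the permutation
  # reconstructs the exact split (2 of choose(16,8) label assignments)
  pt <- fstPermutationTest(A, B, nPerm = 1000, seed = 3)
  expect_lte(pt$p, 0.01)

  expect_error(fstPermutationTest(A, B, nPerm = 0), "degenerate")

  # no variation at all -> undefined
  mono <- locusAlignment("t", c(x = "AAAA", y = "AAAA"), rep("P1", 2))
  mono2 <- locusAlignment("t", c(u = "AAAA", v = "AAAA"), rep("P2", 2))
  expect_true(is.na(hudsonFst(mono, mono2)))

  # null: labels are arbitrary splits of one pool; p roughly uniform
  set.seed(23)
  ps <- replicate(60, {
    aln <- random_alignment(8, 12, rep(c("A", "B"), each = 4),
                            alphabet = c("A", "A", "T"))
    fstPermutationTest(subsetPopulations(aln, "A"),
                       subsetPopulations(aln, "B"),
                       nPerm = 99, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps, na.rm = TRUE), 0.35)
  expect_lt(mean(ps, na.rm = TRUE), 0.65)
})
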