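# Independent brute-force oracles and fixture builders.  Oracles work
# directly on character matrices or plain vectors and share no code with
# the package internals they check.

# random aligned sequences with population labels
random_alignment <- function(n, L, pops = rep(c("A", "B"), length.out = n),
                             alphabet = c("A", "C", "G", "T")) {
  seqs <- vapply(seq_len(n), function(i)
    paste0(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("s", seq_len(n))
  locusAlignment("rand", seqs, pops)
}

aln_char_matrix <- function(aln) {
  m <- alignmentMatrix(aln)
  m
}

# mean pairwise difference per site by explicit pair enumeration
oracle_pi <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2) / ncol(m)
}

oracle_pi_total <- function(m) oracle_pi(m) * ncol(m)

oracle_dxy <- function(mA, mB) {
  tot <- 0
  for (i in seq_len(nrow(mA))) for (j in seq_len(nrow(mB)))
    tot <- tot + sum(mA[i, ] != mB[j, ])
  tot / (nrow(mA) * nrow(mB)) / ncol(mA)
}

oracle_fst <- function(mA, mB) {
  Hw <- (oracle_pi_total(mA) + oracle_pi_total(mB)) / 2
  Hb <- oracle_dxy(mA, mB) * ncol(mA)
  if (Hb == 0) return(NA_real_)
  1 - Hw / Hb
}

# Tajima's D from an independent re-derivation of the 1989 constants
oracle_tajima <- function(m) {
  n <- nrow(m)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(NA_real_)
  k <- oracle_pi_total(m)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# unsigned Stirling numbers of the first kind, |s(n, k)|, by recurrence
oracle_stirling <- function(n) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1
  for (nn in 1:n) for (kk in 1:nn) {
    s[nn + 1, kk + 1] <- s[nn, kk] + (nn - 1) * s[nn, kk + 1]
  }
  s[n + 1, -1]   # |s(n, 1..n)|
}

# Ewens P(K >= k) by direct summation of |s(n,j)| theta^j / theta^(n)
oracle_ewens_tail <- function(n, theta, k) {
  sn <- oracle_stirling(n)
  rising <- prod(theta + 0:(n - 1))
  sum(sn[k:n] * theta^(k:n)) / rising
}

# all four-gamete-violating biallelic site pairs by full enumeration
oracle_fgv_pairs <- function(m) {
  keep <- which(apply(m, 2, function(col) length(unique(col)) == 2))
  out <- NULL
  if (length(keep) >= 2) {
    for (xi in seq_len(length(keep) - 1)) for (yi in seq.int(xi + 1, length(keep))) {
      x <- keep[xi]; y <- keep[yi]
      if (length(unique(paste(m[, x], m[, y]))) == 4)
        out <- rbind(out, c(x, y))
    }
  }
  out
}

# exhaustive NRB search over (contiguous window, sequence subset)
oracle_nrb_score <- function(m, seqWeight = 1, minSeq = 4) {
  n <- nrow(m); L <- ncol(m)
  best <- 0
  subsets <- unlist(lapply(seq.int(max(minSeq, 2), n), function(sz)
    utils::combn(n, sz, simplify = FALSE)), recursive = FALSE)
  for (w1 in 1:L) for (w2 in w1:L) {
    for (rows in subsets) {
      sub <- m[rows, w1:w2, drop = FALSE]
      if (is.null(oracle_fgv_pairs(sub))) {
        sc <- length(rows)^seqWeight * (w2 - w1 + 1)
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# write a small FASTA + popmap pair into a temp dir, return the paths
write_fixture_fasta <- function(seqs, pops, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fix")
    dir.create(dir)
  }
  fa <- file.path(dir, "locus.fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), fa)
  pm <- file.path(dir, "popmap.tsv")
  writeLines(paste(names(seqs), pops, sep = "\t"), pm)
  list(fasta = fa, popmap = pm)
}
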