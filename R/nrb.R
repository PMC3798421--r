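## Four-gamete-compatible non-recombining block (NRB) extraction.
##
## A block is a contiguous interval of kept alignment columns together
## with a retained sequence subset such that no pair of biallelic sites
## exhibits all four haplotypic combinations.  The search maximises
## retained_sequences^seqWeight * retained_sites; exact enumeration over
## (window, sequence subset) is used for small samples, a greedy
## remove-worst-sequence / shrink-window search beyond that.

# biallelic kept columns of a coded matrix; >2-allele columns are excluded
# from compatibility testing (but stay in emitted blocks)
.biallelic_cols <- function(code) {
  nall <- apply(code, 2L, function(col) length(unique(col)))
  which(nall == 2L)
}

#' Four-gamete incompatibility scan
#'
#' Reports all pairs of kept biallelic sites at which all four haplotypic
#' combinations occur among the alignment's sequences.  Sites with more
#' than two residues are flagged and excluded from the pair tests.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @return list with \code{pairs} (two-column matrix of 1-based alignment
#'   column indices, zero rows when compatible) and \code{multiallelic}
#'   (alignment columns skipped for having > 2 residues).
#' @export
fourGameteViolations <- function(aln) {
  code <- .coded_matrix(aln)
  ks <- keptSites(aln)
  nall <- apply(code, 2L, function(col) length(unique(col)))
  bi <- which(nall == 2L)
  multi <- ks[nall > 2L]
  prs <- matrix(integer(0), ncol = 2L,
                dimnames = list(NULL, c("site1", "site2")))
  if (length(bi) >= 2L) {
    # binarise each biallelic column against its first allele
    bm <- vapply(bi, function(j) as.integer(code[, j] == code[1L, j]),
                 integer(nrow(code)))
    for (x in seq_len(length(bi) - 1L)) for (y in seq.int(x + 1L, length(bi))) {
      g <- unique(bm[, x] * 2L + bm[, y])
      if (length(g) == 4L)
        prs <- rbind(prs, c(ks[bi[x]], ks[bi[y]]))
    }
  }
  list(pairs = prs, multiallelic = multi)
}

# violating pairs among retained rows, on the biallelic-column submatrix;
# returns an e x 2 matrix of indices into `cols`
.violation_pairs <- function(bm) {
  nb <- ncol(bm)
  out <- matrix(integer(0), ncol = 2L)
  if (nb < 2L) return(out)
  for (x in seq_len(nb - 1L)) for (y in seq.int(x + 1L, nb)) {
    col <- bm[, x] * 2L + bm[, y]
    if (length(unique(col)) == 4L) out <- rbind(out, c(x, y))
  }
  out
}

.nrb_score <- function(nSeq, nSites, seqWeight) nSeq^seqWeight * nSites

#' Extract the best-scoring non-recombining block
#'
#' Searches over contiguous kept-site windows and sequence subsets for the
#' four-gamete-compatible configuration maximising
#' \code{nSeq^seqWeight * nSites}.  For \code{nSequences(aln) <= exactMax}
#' and at most 30 kept sites the search enumerates all windows x sequence
#' subsets exactly; beyond that a greedy alternation between dropping the
#' sequence implicated in the most remaining violations and shrinking the
#' window is used.
#' Deterministic tie-breaks: more sequences first, then earlier and wider
#' windows; the greedy drops the lexicographically last id among equals.
#'
#' @param aln a filtered \linkS4class{LocusAlignment}.
#' @param seqWeight exponent weighting sequences against sites (default 1).
#' @param exactMax maximum sample size for the exact subset search.
#' @param minSeq minimum retained sequences for a non-degenerate result.
#' @return list with \code{block} (c(start, end), 1-based alignment
#'   columns), \code{retainedIds}, \code{droppedIds}, \code{score},
#'   \code{nSites} (kept sites inside the block), \code{degenerate}
#'   (TRUE when no compatible configuration with \code{minSeq} sequences
#'   and >= 1 site exists), and \code{alignment} (the trimmed
#'   \linkS4class{LocusAlignment}).
#' @export
extractNrb <- function(aln, seqWeight = 1, exactMax = 8L, minSeq = 4L) {
  code <- .coded_matrix(aln)
  ks <- keptSites(aln)
  n <- nrow(code); L <- ncol(code)
  if (L == 0L) stop("no kept sites")
  bi <- .biallelic_cols(code)
  bm_all <- if (length(bi))
    vapply(bi, function(j) as.integer(code[, j] == code[1L, j]),
           integer(n))
  else matrix(integer(0), nrow = n)
  if (!is.matrix(bm_all)) bm_all <- matrix(bm_all, nrow = n)

  compatible <- function(rows, wcols) {
    # wcols: indices into bi (biallelic columns inside current window)
    if (length(wcols) < 2L || length(rows) < 2L) return(TRUE)
    bm <- bm_all[rows, wcols, drop = FALSE]
    nrow(.violation_pairs(bm)) == 0L
  }
  best <- list(score = -Inf)
  consider <- function(rows, w1, w2) {
    nSites <- sum(ks >= ks[w1] & ks <= ks[w2])
    sc <- .nrb_score(length(rows), nSites, seqWeight)
    better <- sc > best$score + 1e-12 ||
      (abs(sc - best$score) <= 1e-12 && !is.null(best$rows) &&
         length(rows) > length(best$rows))
    if (better)
      best <<- list(score = sc, rows = rows, w1 = w1, w2 = w2,
                    nSites = nSites)
  }

  if (n <= exactMax && L <= 30L) {
    # exact search: all contiguous windows x all subsets of >= minSeq rows
    subsets <- list()
    for (sz in seq.int(n, max(minSeq, 2L))) {
      cmb <- utils::combn(n, sz)
      for (ci in seq_len(ncol(cmb))) subsets[[length(subsets) + 1L]] <- cmb[, ci]
    }
    for (w1 in seq_len(L)) for (w2 in seq.int(w1, L)) {
      wcols <- which(bi >= w1 & bi <= w2)
      for (rows in subsets) {
        if (.nrb_score(length(rows), sum(ks >= ks[w1] & ks <= ks[w2]),
                       seqWeight) <= best$score + 1e-12 &&
            length(rows) <= length(best$rows %||% integer(0))) next
        if (compatible(rows, wcols)) consider(rows, w1, w2)
      }
    }
  } else {
    # greedy: from the full configuration, repeatedly either drop the
    # sequence implicated in most violations or shrink the window past
    # the most-violating boundary site, keeping the higher-scoring branch
    greedy_state <- function(rows, w1, w2) {
      repeat {
        wcols <- which(bi >= w1 & bi <= w2)
        if (length(wcols) < 2L) break
        bm <- bm_all[rows, wcols, drop = FALSE]
        vp <- .violation_pairs(bm)
        if (nrow(vp) == 0L) break
        # candidate 1: drop the worst sequence (most violations resolved)
        resolved <- vapply(seq_along(rows), function(ri) {
          sub <- rows[-ri]
          nrow(vp) - nrow(.violation_pairs(bm_all[sub, wcols, drop = FALSE]))
        }, integer(1))
        worst <- which(resolved == max(resolved))
        if (length(worst) > 1L) {
          ids <- rownames(code)[rows[worst]]
          worst <- worst[order(ids, decreasing = TRUE)][1L]
        }
        cand_rows <- rows[-worst]
        # candidate 2: shrink window to exclude the boundary-most
        # violating site (whichever side loses fewer kept sites)
        vsites <- sort(unique(as.vector(vp)))
        leftCut <- wcols[vsites[1L]] + 1L
        rightCut <- wcols[vsites[length(vsites)]] - 1L
        sc_drop <- if (length(cand_rows) >= max(minSeq, 2L))
          .nrb_score(length(cand_rows),
                     sum(ks >= ks[w1] & ks <= ks[w2]), seqWeight) else -Inf
        sc_left <- if (leftCut <= w2)
          .nrb_score(length(rows),
                     sum(ks >= ks[leftCut] & ks <= ks[w2]), seqWeight) else -Inf
        sc_right <- if (rightCut >= w1)
          .nrb_score(length(rows),
                     sum(ks >= ks[w1] & ks <= ks[rightCut]), seqWeight) else -Inf
        pick <- which.max(c(sc_drop, sc_left, sc_right))
        if (!is.finite(max(sc_drop, sc_left, sc_right))) break
        if (pick == 1L) rows <- cand_rows
        else if (pick == 2L) w1 <- leftCut
        else w2 <- rightCut
      }
      list(rows = rows, w1 = w1, w2 = w2)
    }
    st <- greedy_state(seq_len(n), 1L, L)
    wc <- which(bi >= st$w1 & bi <= st$w2)
    if (compatible(st$rows, wc) && length(st$rows) >= max(minSeq, 2L))
      consider(st$rows, st$w1, st$w2)
    # also try pure-window solution (no sequence dropped): maximal
    # compatible windows from a left-to-right scan
    for (w1 in unique(c(1L, bi))) {
      w2 <- w1
      while (w2 < L) {
        wcols <- which(bi >= w1 & bi <= (w2 + 1L))
        if (!compatible(seq_len(n), wcols)) break
        w2 <- w2 + 1L
      }
      consider(seq_len(n), w1, w2)
    }
  }

  if (!is.finite(best$score) || is.null(best$rows) ||
      length(best$rows) < minSeq || best$nSites < 1L) {
    return(list(block = c(NA_integer_, NA_integer_),
                retainedIds = character(0),
                droppedIds = rownames(code), score = 0, nSites = 0L,
                degenerate = TRUE, alignment = NULL))
  }
  ids <- rownames(code)[best$rows]
  blockCols <- ks[ks >= ks[best$w1] & ks <= ks[best$w2]]
  sub <- subsetSequences(aln, ids)
  sub@keptSites <- as.integer(blockCols)
  sub@locusName <- paste0(locusName(aln), "_nrb")
  list(block = c(ks[best$w1], ks[best$w2]),
       retainedIds = ids,
       droppedIds = setdiff(rownames(code), ids),
       score = best$score, nSites = length(blockCols),
       degenerate = FALSE, alignment = sub)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Force a block interval computed on one dataset onto another
#'
#' Restricts an alignment's kept sites to a given column interval (used to
#' carry a block chosen on one population pair over to another pair of the
#' same locus, for cross-pair consistency).
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param block integer c(start, end), 1-based alignment columns.
#' @return the alignment with \code{keptSites} restricted to the interval.
#' @export
applyBlock <- function(aln, block) {
  ks <- keptSites(aln)
  aln@keptSites <- ks[ks >= block[1] & ks <= block[2]]
  aln
}
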