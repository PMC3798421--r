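#' Read a two-column population map
#'
#' Reads a tab-separated file mapping sequence identifiers to population
#' labels.  The file has two columns (seq_id, population), no header.
#'
#' @param path path to the TSV file.
#' @return a list with elements \code{assignments} (named character vector,
#'   seq_id -> population) and \code{populations} (unique labels in order of
#'   first appearance).
#' @export
readPopulationMap <- function(path) {
  if (!file.exists(path)) stop("population map not found: ", path)
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   col.names = c("seq_id", "population"))
  if (nrow(df) == 0L) stop("empty population map: ", path)
  if (anyDuplicated(df$seq_id))
    stop("duplicated seq_id in population map: ", path)
  list(assignments = setNames(df$population, df$seq_id),
       populations = unique(df$population))
}

#' Build a LocusAlignment from character data
#'
#' Low-level constructor used by the reader, the simulator and tests.
#'
#' @param locusName locus identifier.
#' @param seqs named character vector of equal-length aligned sequences
#'   (uppercased on entry).
#' @param populations character vector of population labels, parallel to
#'   \code{seqs}.
#' @param keptSites optional integer vector of retained columns; defaults
#'   to all columns.
#' @return a \linkS4class{LocusAlignment}.
#' @export
locusAlignment <- function(locusName, seqs, populations, keptSites = NULL) {
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) > 1L)
    stop("alignment error: records of '", locusName, "' differ in length")
  dss <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(dss))) names(dss) <- names(seqs)
  if (is.null(keptSites)) keptSites <- seq_len(nchar(seqs[1]))
  new("LocusAlignment", locusName = as.character(locusName),
      sequences = dss, population = as.character(populations),
      keptSites = as.integer(keptSites))
}

#' Read one locus alignment from FASTA and attach population labels
#'
#' Records must arrive aligned (equal lengths).  Residues are uppercased;
#' \code{keptSites} is initialised to all columns.
#'
#' @param fastaPath path to a multi-FASTA file.
#' @param popmap population map as returned by [readPopulationMap()].
#' @param locusName locus identifier; defaults to the file name without
#'   extension.
#' @return a \linkS4class{LocusAlignment}.
#' @export
readLocusAlignment <- function(fastaPath, popmap,
                               locusName = sub("\\.[^.]*$", "", basename(fastaPath))) {
  if (!file.exists(fastaPath)) stop("input error: file not found: ", fastaPath)
  dss <- Biostrings::readDNAStringSet(fastaPath)
  if (length(dss) == 0L) stop("input error: empty FASTA: ", fastaPath)
  if (length(dss) < 2L) stop("input error: need >= 2 records in ", fastaPath)
  ids <- sub("\\s.*$", "", names(dss))
  names(dss) <- ids
  if (length(unique(Biostrings::width(dss))) > 1L)
    stop("alignment error: unequal record lengths in ", fastaPath)
  missing <- setdiff(ids, names(popmap$assignments))
  if (length(missing))
    stop("mapping error: ids absent from population map: ",
         paste(missing, collapse = ", "))
  locusAlignment(locusName, setNames(as.character(dss), ids),
                 unname(popmap$assignments[ids]))
}

#' Filter alignment columns for downstream statistics
#'
#' Under the \code{"complete-deletion"} policy every column containing a
#' gap (\code{-}) or ambiguity (\code{N}, or any non-ACGT residue) in any
#' sequence is removed from \code{keptSites}; the sequences themselves are
#' untouched.  \code{"none"} leaves \code{keptSites} unchanged.  The
#' operation is idempotent.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param policy \code{"complete-deletion"} (default) or \code{"none"}.
#' @return the alignment with updated \code{keptSites}.
#' @export
filterSites <- function(aln, policy = c("complete-deletion", "none")) {
  policy <- match.arg(policy)
  if (policy == "none") return(aln)
  m <- alignmentMatrix(aln, sites = aln@keptSites)
  ok <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  kept <- aln@keptSites[ok]
  if (length(kept) == 0L)
    warning("degenerate alignment: all columns of '", aln@locusName,
            "' removed by complete deletion")
  aln@keptSites <- kept
  aln
}

#' Extract the residue matrix of an alignment
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param sites columns to extract (default: \code{keptSites(aln)}).
#' @return character matrix, rows = sequences (named), columns = sites.
#' @export
alignmentMatrix <- function(aln, sites = keptSites(aln)) {
  m <- t(vapply(strsplit(as.character(aln@sequences), ""),
                identity, character(alignedLength(aln))))
  rownames(m) <- names(aln@sequences)
  m[, sites, drop = FALSE]
}

#' Write a LocusAlignment (kept columns optional) back to FASTA
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param path output FASTA path.
#' @param keptOnly if TRUE emit only the kept columns; default FALSE emits
#'   the full alignment.
#' @return invisibly, \code{path}.
#' @export
writeLocusAlignment <- function(aln, path, keptOnly = FALSE) {
  seqs <- aln@sequences
  if (keptOnly) {
    m <- alignmentMatrix(aln)
    seqs <- Biostrings::DNAStringSet(apply(m, 1L, paste0, collapse = ""))
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80L)
  invisible(path)
}

#' Subset a LocusAlignment by sequence ids
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param ids sequence identifiers to keep.
#' @return the subset alignment (keptSites preserved).
#' @export
subsetSequences <- function(aln, ids) {
  idx <- match(ids, names(aln@sequences))
  if (anyNA(idx)) stop("unknown sequence ids: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  new("LocusAlignment", locusName = aln@locusName,
      sequences = aln@sequences[idx], population = aln@population[idx],
      keptSites = aln@keptSites)
}

#' Restrict an alignment's populations
#'
#' Keeps only sequences from the given populations, in their original order.
#'
#' @param aln a \linkS4class{LocusAlignment}.
#' @param populations labels to retain.
#' @return the subset alignment.
#' @export
subsetPopulations <- function(aln, populations) {
  keep <- aln@population %in% populations
  if (!any(keep)) stop("no sequences from populations: ",
                       paste(populations, collapse = ", "))
  new("LocusAlignment", locusName = aln@locusName,
      sequences = aln@sequences[keep], population = aln@population[keep],
      keptSites = aln@keptSites)
}
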