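#' Build an alignment matrix from sequences
#'
#' An alignment is represented throughout the package as a character matrix
#' with one row per haplotype (rownames are sequence ids) and one column per
#' alignment position, holding single upper-case characters.
#'
#' @param x A named character vector of equal-length sequence strings, a
#'   `Biostrings::DNAStringSet`, or a character matrix (returned unchanged
#'   after validation).
#' @return A character matrix of class used as the package's alignment
#'   container.
#' @examples
#' as_alignment(c(a = "ACGT", b = "ACGA"))
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    aln <- x
  } else {
    if (methods::is(x, "DNAStringSet") || methods::is(x, "XStringSet")) {
      x <- stats::setNames(as.character(x), names(x))
    }
    if (!is.character(x)) {
      stop("cannot interpret input as an alignment")
    }
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      stop("sequences have unequal lengths: ", paste(unique(lens), collapse = ", "))
    }
    if (is.null(names(x))) {
      names(x) <- paste0("seq", seq_along(x))
    }
    aln <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(aln) <- names(x)
  }
  storage.mode(aln) <- "character"
  aln[] <- toupper(aln)
  aln
}

#' Collapse alignment rows back to sequence strings
#'
#' @param aln Alignment matrix (see [as_alignment()]).
#' @return Named character vector of sequences.
#' @export
alignment_strings <- function(aln) {
  stats::setNames(apply(aln, 1L, paste0, collapse = ""), rownames(aln))
}

#' Read an alignment from a FASTA file
#'
#' @param path Path to a FASTA file of equal-length (aligned) sequences.
#' @return Alignment matrix.
#' @export
read_fasta_alignment <- function(path) {
  as_alignment(Biostrings::readDNAStringSet(path))
}

#' Write an alignment to a FASTA file
#'
#' @param aln Alignment matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- alignment_strings(aln)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Normalise CDS coordinate intervals
#'
#' Coding-region coordinates are supplied as 1-based inclusive intervals
#' (matching the residue numbering convention of opsin alignments) and used
#' internally as a flat vector of alignment columns in reading-frame order.
#'
#' @param cds_coords A two-column matrix or data.frame of (start, end) pairs,
#'   or a list of length-2 vectors; `NULL` means the whole sequence is coding.
#' @param seq_length Total alignment length, used when `cds_coords` is `NULL`
#'   and for bounds checking.
#' @return Integer vector of coding columns in frame order.
#' @export
cds_columns <- function(cds_coords, seq_length) {
  if (is.null(cds_coords)) {
    return(seq_len(seq_length))
  }
  if (is.data.frame(cds_coords)) cds_coords <- as.matrix(cds_coords[, 1:2])
  if (is.matrix(cds_coords) && nrow(cds_coords) == 0L) return(integer(0))
  if (is.list(cds_coords)) cds_coords <- do.call(rbind, cds_coords)
  if (is.vector(cds_coords) && length(cds_coords) == 2L) {
    cds_coords <- matrix(cds_coords, nrow = 1L)
  }
  cds_coords <- apply(cds_coords, 2L, as.integer)
  if (is.vector(cds_coords)) cds_coords <- matrix(cds_coords, nrow = 1L)
  cols <- integer(0)
  for (i in seq_len(nrow(cds_coords))) {
    s <- cds_coords[i, 1L]; e <- cds_coords[i, 2L]
    if (is.na(s) || is.na(e) || s < 1L || e > seq_length || s > e) {
      stop("invalid CDS interval [", s, ", ", e, "] for length ", seq_length)
    }
    cols <- c(cols, s:e)
  }
  if (anyDuplicated(cols)) stop("CDS intervals overlap")
  cols
}

# Sum over j = 1..n-1 of 1/j (Watterson's correction factor).
harmonic_a <- function(n) {
  if (n < 2) stop("sample size must be at least 2")
  sum(1 / seq_len(n - 1L))
}

# Sum over j = 1..n-1 of 1/j^2 (enters the variance of segregating sites).
harmonic_b <- function(n) {
  if (n < 2) stop("sample size must be at least 2")
  sum(1 / seq_len(n - 1L)^2)
}

# Rows of pairwise difference counts with pairwise deletion of columns where
# either sequence is not a plain base.
.count_diffs <- function(x, y) {
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  sum(x[ok] != y[ok])
}
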