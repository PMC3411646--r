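#' Construct a multiple alignment of plastomes
#'
#' Columns are characters over \{A,C,G,T,N,-\}; all rows have equal length and
#' taxon ids are unique. The gap character is `"-"` only.
#'
#' @param seqs named character vector of aligned sequences (one per taxon).
#' @return an object of class `plastome_alignment`.
#' @export
plastome_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all records must be named with a taxon id")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate taxon ids in alignment")
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase bases in alignment uppercased")
    seqs <- toupper(seqs)
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: records have unequal lengths")
  }
  if (any(grepl("[^ACGTN-]", seqs))) {
    stop("alignment contains characters outside {A,C,G,T,N,-}")
  }
  structure(
    list(taxa = names(seqs), seqs = seqs, ncol = unname(widths[1L])),
    class = "plastome_alignment"
  )
}

#' @export
print.plastome_alignment <- function(x, ...) {
  cat("<plastome_alignment> ", length(x$taxa), " taxa x ", x$ncol,
      " columns\n", sep = "")
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param aln a `plastome_alignment`.
#' @return character matrix, rows = taxa, columns = alignment columns.
#' @export
aln_matrix <- function(aln) {
  stopifnot(inherits(aln, "plastome_alignment"))
  m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  rownames(m) <- aln$taxa
  m
}

aln_chars <- function(aln, taxon) {
  if (!taxon %in% aln$taxa) stop("unknown taxon '", taxon, "'")
  strsplit(aln$seqs[[taxon]], "", fixed = TRUE)[[1L]]
}

#' Map alignment columns to ungapped sequence positions
#'
#' @param aln a `plastome_alignment`.
#' @param taxon taxon id.
#' @return integer vector of length `aln$ncol`: the 1-based ungapped position
#'   of each column in that taxon's sequence, `NA` at gap columns. The map is
#'   strictly increasing over non-gap columns.
#' @export
col_to_pos <- function(aln, taxon) {
  ch <- aln_chars(aln, taxon)
  nongap <- ch != "-"
  out <- rep(NA_integer_, length(ch))
  out[nongap] <- seq_len(sum(nongap))
  out
}

#' Map ungapped sequence positions to alignment columns
#'
#' @inheritParams col_to_pos
#' @return integer vector: element `i` is the alignment column holding the
#'   taxon's `i`-th base.
#' @export
pos_to_col <- function(aln, taxon) {
  which(aln_chars(aln, taxon) != "-")
}

#' Ungapped sequence of one taxon
#'
#' @inheritParams col_to_pos
#' @return the taxon's sequence with gaps removed.
#' @export
ungapped_sequence <- function(aln, taxon) {
  gsub("-", "", aln$seqs[[taxon]], fixed = TRUE)
}

#' Project a multiple alignment onto a taxon pair
#'
#' Keeps the alignment columns where not both taxa are gaps, preserving a
#' back-map to master columns. The ungapped sequences of both taxa are
#' unchanged by projection.
#'
#' @param aln a `plastome_alignment`.
#' @param a,b taxon ids.
#' @return an object of class `pairwise_view`: list with `taxon_a`, `taxon_b`,
#'   `a` and `b` (character vectors of equal length) and `master_cols`
#'   (integer back-map into the master alignment, injective).
#' @export
project_pairwise <- function(aln, a, b) {
  ca <- aln_chars(aln, a)
  cb <- aln_chars(aln, b)
  keep <- !(ca == "-" & cb == "-")
  structure(
    list(taxon_a = a, taxon_b = b,
         a = ca[keep], b = cb[keep],
         master_cols = which(keep)),
    class = "pairwise_view"
  )
}

#' @export
print.pairwise_view <- function(x, ...) {
  cat("<pairwise_view> ", x$taxon_a, " vs ", x$taxon_b, ": ",
      length(x$a), " columns\n", sep = "")
  invisible(x)
}
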