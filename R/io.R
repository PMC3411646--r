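#' Read and write aligned FASTA
#'
#' Aligned FASTA with equal record lengths and `"-"` as the only gap
#' character. Round trips are byte-identical; duplicate ids and ragged rows
#' are rejected; lowercase input is uppercased with a warning.
#'
#' @param path file path.
#' @return `read_alignment()` returns a [plastome_alignment].
#' @export
read_alignment <- function(path) {
  seqs <- read_fasta(path)
  plastome_alignment(seqs)
}

#' @rdname read_alignment
#' @param aln a [plastome_alignment].
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "plastome_alignment"))
  write_fasta(aln$seqs, path)
  invisible(path)
}

#' Read and write (unaligned) FASTA
#'
#' @param path file path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read and write region tables
#'
#' BED-like TSV with header `taxon  region  start  end`; coordinates are
#' 0-based half-open. On read, each taxon's rows are validated to be
#' non-overlapping and sorted.
#'
#' @param path file path.
#' @return `read_regions()` returns a data.frame with columns `taxon`,
#'   `region`, `start`, `end`.
#' @export
read_regions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "region", "start", "end") %in% names(df)))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  for (tx in unique(df$taxon)) {
    r <- df[df$taxon == tx, ]
    r <- r[order(r$start), ]
    if (any(r$end <= r$start)) stop("empty/negative region for '", tx, "'")
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)])) {
      stop("overlapping regions for taxon '", tx, "'")
    }
  }
  df
}

#' @rdname read_regions
#' @param regions data.frame as returned by `read_regions()`.
#' @export
write_regions <- function(regions, path) {
  write.table(regions[, c("taxon", "region", "start", "end")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write gene feature tables (GFF3 subset)
#'
#' Gene features only, 1-based inclusive coordinates in the file (converted to
#' the package's 0-based half-open convention on read), CDS phase 0.
#'
#' @param path file path.
#' @return `read_features()` returns a data.frame with columns `taxon`,
#'   `name`, `start`, `end`, `strand`, `is_cds` (0-based half-open).
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    taxon = as.character(GenomicRanges::seqnames(gr)),
    name = if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    is_cds = as.character(gr$type) == "CDS",
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "+"
  df
}

#' @rdname read_features
#' @param features data.frame as returned by `read_features()`.
#' @export
write_features <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$taxon,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand
  )
  gr$type <- ifelse(features$is_cds, "CDS", "gene")
  gr$ID <- paste0(features$taxon, ":", features$name)
  gr$Name <- features$name
  gr$phase <- ifelse(features$is_cds, 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read and write Newick trees
#'
#' Thin wrappers over ape preserving branch lengths and node labels.
#'
#' @param path file path.
#' @return `read_tree()` returns an `ape::phylo` object.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("unparseable Newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("unparseable Newick file: ", path)
  tr
}

#' @rdname read_tree
#' @param tree an `ape::phylo` object.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read and write simulator event tables
#'
#' TSV with header `branch kind start end length region payload columns
#' mirrored ssr_locus`; `columns` is a comma-separated list of final master
#' alignment columns (1-based).
#'
#' @param path file path.
#' @return `read_event_table()` returns the event data.frame.
#' @export
read_event_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(payload = "character",
                                  columns = "character"))
  df$mirrored <- as.logical(df$mirrored)
  df$payload[is.na(df$payload)] <- ""
  df
}

#' @rdname read_event_table
#' @param events event data.frame.
#' @export
write_event_table <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write taxon group labels
#'
#' TSV with header `taxon  group`; groups are `A_diploid`, `D_diploid`,
#' `allotetraploid`, `outgroup`.
#'
#' @param path file path.
#' @return `read_groups()` returns a named character vector (taxon -> group).
#' @export
read_groups <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "group") %in% names(df)))
  setNames(df$group, df$taxon)
}

#' @rdname read_groups
#' @param groups named character vector (taxon -> group).
#' @export
write_groups <- function(groups, path) {
  write.table(data.frame(taxon = names(groups), group = unname(groups)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
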