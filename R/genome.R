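#' Construct a plastome record
#'
#' A `genome_record` holds one linearized plastome: its sequence, the
#' quadripartite region table (LSC, IRb, SSC, IRa) and, optionally, gene
#' features. All coordinates are 0-based half-open on the linearized genome;
#' the conventional linearization starts at LSC position 0.
#'
#' @param taxon_id single string naming the taxon.
#' @param sequence nucleotide string over A, C, G, T, N. Lowercase input is
#'   uppercased with a warning.
#' @param regions `NULL` or a data.frame with columns `region`, `start`,
#'   `end` whose rows partition `[0, nchar(sequence))`.
#' @param genes `NULL` or a data.frame with columns `name`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`) and `is_cds` (logical); intervals must lie within
#'   the genome.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(taxon_id, sequence, regions = NULL, genes = NULL) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1L, nzchar(taxon_id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (grepl("[a-z]", sequence)) {
    warning("lowercase bases in sequence for '", taxon_id, "' uppercased")
    sequence <- toupper(sequence)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence for '", taxon_id, "' contains characters outside {A,C,G,T,N}")
  }
  len <- nchar(sequence)
  if (!is.null(regions)) regions <- validate_regions(regions, len, taxon_id)
  if (!is.null(genes)) genes <- validate_genes(genes, len, taxon_id)
  structure(
    list(taxon_id = taxon_id, sequence = sequence,
         regions = regions, genes = genes),
    class = "genome_record"
  )
}

validate_regions <- function(regions, len, taxon_id = "?") {
  stopifnot(is.data.frame(regions),
            all(c("region", "start", "end") %in% names(regions)))
  regions <- regions[order(regions$start), c("region", "start", "end")]
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (any(regions$start < 0L) || any(regions$end > len) ||
      any(regions$end <= regions$start)) {
    stop("invalid region coordinates for '", taxon_id, "'")
  }
  if (regions$start[1L] != 0L || regions$end[nrow(regions)] != len ||
      (nrow(regions) > 1L &&
       any(regions$start[-1L] != regions$end[-nrow(regions)]))) {
    stop("regions do not partition [0, ", len, ") for '", taxon_id, "'")
  }
  rownames(regions) <- NULL
  regions
}

validate_genes <- function(genes, len, taxon_id = "?") {
  stopifnot(is.data.frame(genes),
            all(c("name", "start", "end") %in% names(genes)))
  if (is.null(genes$strand)) genes$strand <- "+"
  if (is.null(genes$is_cds)) genes$is_cds <- TRUE
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start < 0L) || any(genes$end > len) ||
      any(genes$end <= genes$start)) {
    stop("gene intervals outside [0, ", len, ") for '", taxon_id, "'")
  }
  rownames(genes) <- NULL
  genes[, c("name", "start", "end", "strand", "is_cds")]
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$taxon_id, ": ", nchar(x$sequence), " bp",
      if (!is.null(x$regions)) paste0(", ", nrow(x$regions), " regions"),
      if (!is.null(x$genes)) paste0(", ", nrow(x$genes), " genes"),
      "\n", sep = "")
  invisible(x)
}

seq_chars <- function(x) {
  s <- if (inherits(x, "genome_record")) x$sequence else x
  strsplit(s, "", fixed = TRUE)[[1L]]
}

#' AT content of a sequence or genome
#'
#' Fraction (A+T)/(A+C+G+T); N bases are excluded from both numerator and
#' denominator.
#'
#' @param x a `genome_record`, a nucleotide string, or a character vector of
#'   single bases.
#' @param region optional region name; when `x` is a `genome_record` with a
#'   region table, the fraction is computed over that region only.
#' @return a single numeric fraction in `[0, 1]` (NaN for an all-N input).
#' @export
at_content <- function(x, region = NULL) {
  if (inherits(x, "genome_record") && !is.null(region)) {
    stopifnot(!is.null(x$regions))
    r <- x$regions[x$regions$region == region, ]
    if (nrow(r) == 0L) stop("region '", region, "' not present")
    chars <- unlist(lapply(seq_len(nrow(r)), function(i) {
      seq_chars(substr(x$sequence, r$start[i] + 1L, r$end[i]))
    }))
  } else {
    chars <- if (is.character(x) && length(x) > 1L) x else seq_chars(x)
  }
  n_at <- sum(chars == "A" | chars == "T")
  n_tot <- sum(chars %in% c("A", "C", "G", "T"))
  if (n_tot == 0L) return(NaN)
  n_at / n_tot
}

#' Distances from genes to region junctions
#'
#' For each named gene, reports the signed distance from the gene to each of
#' its flanking region junctions. A positive distance is the gap in bp between
#' the gene end and the junction; 0 means the gene ends exactly at the
#' junction; a negative value means the gene extends across the junction and
#' its magnitude is the overlap length on the far side.
#'
#' @param genome a `genome_record` with both `regions` and `genes`.
#' @param boundary_genes character vector of gene names to report.
#' @return data.frame with columns `gene`, `junction`, `side`
#'   (`"left"`/`"right"`), `distance`.
#' @export
junction_distances <- function(genome, boundary_genes) {
  stopifnot(inherits(genome, "genome_record"),
            !is.null(genome$regions), !is.null(genome$genes))
  reg <- genome$regions
  # interior junction points (0-based position where the next region starts)
  jpos <- reg$end[-nrow(reg)]
  jname <- paste(reg$region[-nrow(reg)], reg$region[-1L], sep = "/")
  out <- list()
  for (g in boundary_genes) {
    row <- genome$genes[genome$genes$name == g, ]
    if (nrow(row) == 0L) stop("gene '", g, "' not found in '",
                              genome$taxon_id, "'")
    for (i in seq_len(nrow(row))) {
      s <- row$start[i]; e <- row$end[i]
      # nearest junction at or left of the gene midpoint, and at or right
      left_j <- which(jpos <= s)
      right_j <- which(jpos >= e)
      cross_j <- which(jpos > s & jpos < e)
      if (length(cross_j)) {
        for (j in cross_j) {
          out[[length(out) + 1L]] <- data.frame(
            gene = g, junction = jname[j], side = "across",
            distance = -(e - jpos[j]), stringsAsFactors = FALSE)
        }
      }
      if (length(left_j)) {
        j <- max(left_j)
        out[[length(out) + 1L]] <- data.frame(
          gene = g, junction = jname[j], side = "left",
          distance = s - jpos[j], stringsAsFactors = FALSE)
      }
      if (length(right_j)) {
        j <- min(right_j)
        out[[length(out) + 1L]] <- data.frame(
          gene = g, junction = jname[j], side = "right",
          distance = jpos[j] - e, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
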