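#' SSR detection threshold sets
#'
#' Minimum total repeat length (bp) per motif unit length 1..5. Preset `"A"`
#' is \{8, 8, 9, 12, 15\} and preset `"B"` \{10, 10, 12, 16, 20\}, the two
#' definitions used for chloroplast SSR surveys.
#'
#' @param set `"A"`, `"B"`, or a named numeric vector with entries
#'   `"1"`..`"5"`.
#' @return named integer vector of minimum locus lengths by unit length.
#' @export
ssr_thresholds <- function(set = "A") {
  if (is.character(set) && length(set) == 1L) {
    set <- switch(set,
                  A = c(`1` = 8L, `2` = 8L, `3` = 9L, `4` = 12L, `5` = 15L),
                  B = c(`1` = 10L, `2` = 10L, `3` = 12L, `4` = 16L, `5` = 20L),
                  stop("unknown threshold set; use \"A\" or \"B\""))
  }
  stopifnot(is.numeric(set), all(c("1", "2", "3", "4", "5") %in% names(set)),
            all(set > 0))
  out <- as.integer(set[c("1", "2", "3", "4", "5")])
  names(out) <- as.character(1:5)
  out
}

#' Canonical SSR motif
#'
#' The lexicographically smallest rotation of the motif on the given strand.
#' Reverse-complement motifs are NOT collapsed: `"TA"` canonicalizes to
#' `"AT"` (a rotation) but `"CT"` does not become `"AG"`.
#'
#' @param motif motif string (1-5 bp).
#' @return canonical motif string.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    u <- nchar(m)
    if (u == 1L) return(m)
    rots <- vapply(seq_len(u), function(i) {
      paste0(substr(m, i, u), substr(m, 1L, i - 1L))
    }, character(1L))
    min(rots)
  }, character(1L), USE.NAMES = FALSE)
}

# TRUE if motif is a repetition of a shorter motif (non-primitive)
is_primitive_motif <- function(m) {
  u <- nchar(m)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && strrep(substr(m, 1L, d), u %/% d) == m) return(FALSE)
  }
  TRUE
}

#' Find perfect microsatellites (SSRs)
#'
#' Deterministic left-to-right scan for maximal perfect tandem repeats of
#' primitive motifs of unit length 1-5. A run is reported at the smallest
#' unit length that generates it (a 10-A run is one mononucleotide locus, not
#' a dinucleotide "AA" locus); a trailing partial unit is excluded, so locus
#' length is always a multiple of the unit length; the locus is kept when its
#' length meets the threshold for its unit length.
#'
#' @param genome a `genome_record` or a nucleotide string.
#' @param thresholds a threshold set (see [ssr_thresholds()]).
#' @return data.frame with `taxon`, `motif` (canonical), `raw_motif` (as it
#'   appears at the locus start), `unit`, `start`, `end` (0-based half-open,
#'   ungapped), `length`, `region` (`NA` without a region table).
#' @export
find_ssrs <- function(genome, thresholds = ssr_thresholds("A")) {
  thresholds <- ssr_thresholds(thresholds)
  taxon <- if (inherits(genome, "genome_record")) genome$taxon_id else NA_character_
  chars <- seq_chars(genome)
  n <- length(chars)
  out <- list()
  for (u in 1:5) {
    min_len <- thresholds[[as.character(u)]]
    if (n < min_len || n <= u) next
    same <- chars[seq_len(n - u)] == chars[(u + 1L):n] &
      chars[seq_len(n - u)] %in% c("A", "C", "G", "T")
    r <- rle(same)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & (r$lengths + u) >= min_len)
    for (h in hit) {
      s <- starts[h]                      # 1-based start of the repeat span
      span <- r$lengths[h] + u            # full matched span incl. partials
      len <- u * (span %/% u)             # drop trailing partial unit
      if (len < min_len) next
      motif <- paste(chars[s:(s + u - 1L)], collapse = "")
      if (!is_primitive_motif(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        taxon = taxon, motif = canonical_motif(motif), raw_motif = motif,
        unit = u, start = s - 1L, end = s - 1L + len, length = len,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    res <- data.frame(taxon = character(), motif = character(),
                      raw_motif = character(), unit = integer(),
                      start = integer(), end = integer(), length = integer(),
                      region = character(), stringsAsFactors = FALSE)
    return(res)
  }
  res <- do.call(rbind, out)
  # drop loci of unit u whose span is contained in a locus of smaller unit
  # with the same generating run (e.g. the "AA" view of a poly-A run)
  res <- res[order(res$unit, res$start), ]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (res$unit[i] == 1L) next
    inside <- which(res$unit < res$unit[i] &
                    res$start <= res$start[i] & res$end >= res$end[i])
    if (length(inside)) keep[i] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$start, res$unit), , drop = FALSE]
  res$region <- NA_character_
  if (inherits(genome, "genome_record") && !is.null(genome$regions)) {
    reg <- genome$regions[order(genome$regions$start), ]
    idx <- pmax(findInterval(res$start, reg$start), 1L)
    res$region <- reg$region[idx]
  }
  rownames(res) <- NULL
  res
}

#' Group homologous SSR loci across an alignment
#'
#' Loci from different taxa are grouped when their alignment-column spans
#' overlap by at least one column and their canonical motifs match. Each
#' locus belongs to at most one group (overlap is closed transitively).
#'
#' @param aln a [plastome_alignment].
#' @param ssr_lists data.frame of per-taxon SSR loci (rows from
#'   [find_ssrs()], with valid `taxon`), or a list of such data.frames.
#' @return the combined loci data.frame with added columns `col_start`,
#'   `col_end` (master columns, 1-based inclusive) and `group` (integer id).
#' @export
ssr_locus_homology <- function(aln, ssr_lists) {
  loci <- if (is.data.frame(ssr_lists)) ssr_lists else do.call(rbind, ssr_lists)
  if (nrow(loci) == 0L) {
    loci$col_start <- integer(0L); loci$col_end <- integer(0L)
    loci$group <- integer(0L)
    return(loci)
  }
  stopifnot(all(loci$taxon %in% aln$taxa))
  p2c <- lapply(setNames(aln$taxa, aln$taxa), function(tx) pos_to_col(aln, tx))
  cs <- integer(nrow(loci)); ce <- integer(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    cols <- p2c[[loci$taxon[i]]]
    if (loci$end[i] > length(cols)) {
      stop("SSR locus outside sequence for taxon '", loci$taxon[i], "'")
    }
    cs[i] <- cols[loci$start[i] + 1L]
    ce[i] <- cols[loci$end[i]]
  }
  loci$col_start <- cs
  loci$col_end <- ce
  # sweep within each motif: chained column-overlap defines a group
  ord <- order(loci$motif, loci$col_start)
  gid <- integer(nrow(loci))
  cur <- 0L
  cur_motif <- ""
  cur_end <- -1L
  for (k in ord) {
    if (loci$motif[k] != cur_motif || loci$col_start[k] > cur_end) {
      cur <- cur + 1L
      cur_motif <- loci$motif[k]
      cur_end <- loci$col_end[k]
    } else {
      cur_end <- max(cur_end, loci$col_end[k])
    }
    gid[k] <- cur
  }
  loci$group <- gid
  loci
}

#' SSR polymorphism and conservation statistics
#'
#' A homology group is polymorphic for a taxon pair when the two taxa carry
#' different repeat lengths at the locus (absence counts as length 0), and
#' completely conserved when every taxon in `taxa` carries the locus at an
#' identical length.
#'
#' @param groups data.frame from [ssr_locus_homology()].
#' @param taxa all taxa under comparison.
#' @return list with `pairwise` (symmetric matrix of polymorphic-locus counts
#'   per pair), `group_lengths` (groups x taxa length matrix), `conserved`
#'   (logical per group), and `by_class` (data.frame per unit length: total
#'   groups, conserved count, conserved rate).
#' @export
polymorphism_stats <- function(groups, taxa) {
  gids <- sort(unique(groups$group))
  len_mat <- matrix(0L, nrow = length(gids), ncol = length(taxa),
                    dimnames = list(as.character(gids), taxa))
  for (i in seq_len(nrow(groups))) {
    len_mat[as.character(groups$group[i]), groups$taxon[i]] <-
      groups$length[i]
  }
  conserved <- apply(len_mat, 1L, function(v) length(unique(v)) == 1L && v[1L] > 0L)
  n <- length(taxa)
  pw <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cnt <- sum(len_mat[, i] != len_mat[, j])
      pw[i, j] <- cnt
      pw[j, i] <- cnt
    }
  }
  unit_of_group <- tapply(groups$unit, groups$group, function(u) u[1L])
  by_class <- do.call(rbind, lapply(1:5, function(u) {
    ids <- names(unit_of_group)[unit_of_group == u]
    tot <- length(ids)
    cons <- sum(conserved[ids])
    data.frame(unit = u, n_groups = tot, n_conserved = cons,
               conserved_rate = if (tot > 0L) cons / tot else NaN)
  }))
  list(pairwise = pw, group_lengths = len_mat, conserved = conserved,
       by_class = by_class)
}

#' Attribute short indels to SSR polymorphism
#'
#' For a taxon pair, counts the 1-3-bp indel events whose master-column span
#' intersects an SSR homology group that is polymorphic for the pair.
#'
#' @param indel_events data.frame from [extract_indels()] for the pair.
#' @param groups data.frame from [ssr_locus_homology()].
#' @param a,b the taxon pair.
#' @return list with `n_short`, `n_attributed`, `n_unattributed`,
#'   `attributed_fraction` (NaN when there are no 1-3-bp events).
#' @export
attribute_short_indels <- function(indel_events, groups, a, b) {
  short <- indel_events[indel_events$length <= 3L, , drop = FALSE]
  n_short <- nrow(short)
  if (n_short == 0L) {
    return(list(n_short = 0L, n_attributed = 0L, n_unattributed = 0L,
                attributed_fraction = NaN))
  }
  # polymorphic groups for this pair (absence = length 0)
  len_a <- tapply(ifelse(groups$taxon == a, groups$length, 0L),
                  groups$group, max)
  len_b <- tapply(ifelse(groups$taxon == b, groups$length, 0L),
                  groups$group, max)
  poly_ids <- names(len_a)[len_a != len_b]
  gp <- groups[as.character(groups$group) %in% poly_ids, , drop = FALSE]
  attributed <- vapply(seq_len(n_short), function(i) {
    any(short$start[i] <= gp$col_end + 1L & short$end[i] >= gp$col_start - 1L)
  }, logical(1L))
  n_att <- sum(attributed)
  list(n_short = n_short, n_attributed = n_att,
       n_unattributed = n_short - n_att,
       attributed_fraction = n_att / n_short)
}
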