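BASES <- c("A", "C", "G", "T")
TRANSITION_PAIRS <- c("A/G", "C/T")
PAIR_TYPES <- c("A/C", "A/G", "A/T", "C/G", "C/T", "G/T")

# region label of a master column, using the reference taxon's coordinates;
# gap columns take the region of the nearest preceding base
region_of_cols <- function(aln, taxon, cols, regions) {
  r <- regions[regions$taxon == taxon, , drop = FALSE]
  if (nrow(r) == 0L || length(cols) == 0L) {
    return(rep(NA_character_, length(cols)))
  }
  r <- r[order(r$start), ]
  c2p <- col_to_pos(aln, taxon)
  filled <- cummax(ifelse(is.na(c2p), 0L, c2p))
  pos <- pmax(filled[cols], 1L)
  idx <- pmax(findInterval(pos - 1L, r$start), 1L)
  r$region[idx]
}

#' Count substitutions between a pair of aligned genomes
#'
#' One substitution event per column where both taxa carry distinct bases in
#' \{A,C,G,T\}; columns containing N or a gap in either taxon are excluded.
#'
#' @param view a [project_pairwise()] view.
#' @param aln the master alignment (needed with `regions` to label events).
#' @param regions optional region table (`taxon`, `region`, `start`, `end`);
#'   events are labelled with the region of the first taxon of the pair.
#' @return list with `events` (data.frame: `master_col`, `base_a`, `base_b`,
#'   `class`, `pair_type`, `region`) and `summary` (data.frame: `n`, `si`,
#'   `sv`, `si_sv` and one count per unordered base pair type). `si_sv` is
#'   NaN when there are no transversions and no transitions.
#' @export
count_substitutions <- function(view, aln = NULL, regions = NULL) {
  stopifnot(inherits(view, "pairwise_view"))
  ok <- view$a %in% BASES & view$b %in% BASES & view$a != view$b
  idx <- which(ok)
  a <- view$a[idx]; b <- view$b[idx]
  pair <- ifelse(a < b, paste(a, b, sep = "/"), paste(b, a, sep = "/"))
  cls <- ifelse(pair %in% TRANSITION_PAIRS, "transition", "transversion")
  reg <- if (!is.null(regions) && !is.null(aln)) {
    region_of_cols(aln, view$taxon_a, view$master_cols[idx], regions)
  } else rep(NA_character_, length(idx))
  events <- data.frame(master_col = view$master_cols[idx],
                       base_a = a, base_b = b, class = cls, pair_type = pair,
                       region = reg, stringsAsFactors = FALSE)
  si <- sum(cls == "transition")
  sv <- sum(cls == "transversion")
  type_counts <- vapply(PAIR_TYPES, function(p) sum(pair == p), integer(1L))
  summary <- data.frame(n = length(idx), si = si, sv = sv,
                        si_sv = if (si + sv == 0L) NaN else si / sv,
                        t(type_counts), check.names = FALSE)
  names(summary)[5:10] <- PAIR_TYPES
  list(events = events, summary = summary)
}

#' Extract pairwise indel events
#'
#' Each maximal run of gap characters in exactly one taxon of the view is one
#' indel event. Runs touching either end of the alignment are excluded
#' (alignment ends are linearization artifacts). Events carry the bases of
#' the ungapped taxon and the region of their left flank.
#'
#' @inheritParams count_substitutions
#' @return data.frame with columns `start`, `end` (master columns, 1-based
#'   inclusive), `length`, `gapped_taxon` (`"a"` or `"b"`), `bases`, `region`.
#' @export
extract_indels <- function(view, aln = NULL, regions = NULL) {
  stopifnot(inherits(view, "pairwise_view"))
  gap_a <- view$a == "-"
  gap_b <- view$b == "-"
  state <- ifelse(gap_a, "a", ifelse(gap_b, "b", "."))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "." & starts > 1L & ends < length(state)
  starts <- starts[keep]; ends <- ends[keep]
  gapped <- r$values[keep]
  n <- length(starts)
  if (n == 0L) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      gapped_taxon = character(), bases = character(),
                      region = character(), stringsAsFactors = FALSE))
  }
  bases <- vapply(seq_len(n), function(i) {
    src <- if (gapped[i] == "a") view$b else view$a
    paste(src[starts[i]:ends[i]], collapse = "")
  }, character(1L))
  reg <- if (!is.null(regions) && !is.null(aln)) {
    region_of_cols(aln, view$taxon_a, view$master_cols[pmax(starts - 1L, 1L)],
                   regions)
  } else rep(NA_character_, n)
  data.frame(start = view$master_cols[starts], end = view$master_cols[ends],
             length = ends - starts + 1L, gapped_taxon = gapped,
             bases = bases, region = reg, stringsAsFactors = FALSE)
}

#' Divergence percentage
#'
#' `100 * total_bp / alignment_len`: the percentage of the aligned length
#' affected by substitutions (or covered by indels, when `total_bp` is a
#' summed indel length).
#'
#' @param total_bp total substituted or indel-covered bases.
#' @param alignment_len alignment length in bp (> 0).
#' @return percentage (numeric scalar).
#' @export
divergence_percent <- function(total_bp, alignment_len) {
  stopifnot(alignment_len > 0)
  100 * total_bp / alignment_len
}

#' Per-kb event rate
#'
#' @param count number of events.
#' @param len_kb region length in kb.
#' @return events per kb.
#' @export
per_kb_rate <- function(count, len_kb) {
  stopifnot(len_kb > 0)
  count / len_kb
}

#' Pairwise divergence summary
#'
#' Substitution and indel accounting for one taxon pair: counts, summed indel
#' length, Si/Sv, S/I and divergence percentages on the master alignment
#' length.
#'
#' @param aln a [plastome_alignment].
#' @param a,b taxon ids.
#' @param regions optional region table.
#' @return one-row data.frame of class `pairwise_divergence`.
#' @export
pairwise_divergence <- function(aln, a, b, regions = NULL) {
  view <- project_pairwise(aln, a, b)
  subs <- count_substitutions(view, aln, regions)
  ind <- extract_indels(view, aln, regions)
  n_sub <- subs$summary$n
  n_ind <- nrow(ind)
  len_ind <- sum(ind$length)
  out <- data.frame(
    taxon_a = a, taxon_b = b,
    n_substitutions = n_sub,
    total_indel_events = n_ind,
    total_indel_length = len_ind,
    si_sv = subs$summary$si_sv,
    s_i = if (n_ind > 0L) n_sub / n_ind else NaN,
    subst_divergence_pct = divergence_percent(n_sub, aln$ncol),
    indel_divergence_pct = divergence_percent(len_ind, aln$ncol),
    stringsAsFactors = FALSE)
  class(out) <- c("pairwise_divergence", class(out))
  out
}

#' Per-region substitution and indel rates for a pair
#'
#' Counts substitutions and indel events per region between two taxa and
#' reports per-kb rates over LSC, SSC and IR. The inverted repeat is reported
#' once: counts and lengths of the two copies are pooled and divided by two,
#' which equals a per-copy rate under concerted IR evolution.
#'
#' @param aln a [plastome_alignment].
#' @param regions region table covering at least taxon `a`.
#' @param a,b taxon ids.
#' @return data.frame with columns `region` (`LSC`, `SSC`, `IR`), `length_bp`,
#'   `n_substitutions`, `n_indels`, `sub_rate_per_kb`, `indel_rate_per_kb`.
#' @export
per_region_stats <- function(aln, regions, a, b) {
  r <- regions[regions$taxon == a, , drop = FALSE]
  if (nrow(r) == 0L) stop("no region map for reference taxon '", a, "'")
  validate_regions(r[, c("region", "start", "end")],
                   nchar(ungapped_sequence(aln, a)), a)
  view <- project_pairwise(aln, a, b)
  subs <- count_substitutions(view, aln, regions)
  ind <- extract_indels(view, aln, regions)
  lens <- setNames(r$end - r$start, r$region)
  pool <- function(labels) {
    c(LSC = sum(labels == "LSC"), SSC = sum(labels == "SSC"),
      IR = sum(labels %in% c("IRa", "IRb")) / 2)
  }
  sub_counts <- pool(subs$events$region)
  ind_counts <- pool(ind$region)
  len_bp <- c(LSC = unname(lens["LSC"]), SSC = unname(lens["SSC"]),
              IR = unname((lens["IRb"] + lens["IRa"]) / 2))
  data.frame(region = c("LSC", "SSC", "IR"),
             length_bp = unname(len_bp),
             n_substitutions = unname(sub_counts),
             n_indels = unname(ind_counts),
             sub_rate_per_kb = unname(sub_counts / (len_bp / 1000)),
             indel_rate_per_kb = unname(ind_counts / (len_bp / 1000)),
             stringsAsFactors = FALSE)
}

#' Pairwise substitution/indel matrix
#'
#' Square matrix over the given taxa with indel event counts above the
#' diagonal and total substitution counts below it, the presentation used for
#' whole-plastome comparisons.
#'
#' @param aln a [plastome_alignment].
#' @param taxa taxa to include (default: all).
#' @return integer matrix with `NA` on the diagonal.
#' @export
pairwise_matrix <- function(aln, taxa = NULL) {
  if (is.null(taxa)) taxa <- aln$taxa
  stopifnot(length(taxa) >= 2L, all(taxa %in% aln$taxa))
  n <- length(taxa)
  m <- matrix(NA_integer_, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      view <- project_pairwise(aln, taxa[i], taxa[j])
      m[i, j] <- nrow(extract_indels(view))
      m[j, i] <- count_substitutions(view)$summary$n
    }
  }
  m
}

#' Sliding AT content versus divergence profile
#'
#' Windows of `at_window` columns advanced by `div_step` columns. AT content
#' excludes gaps and N from the denominator; divergence is the fraction of
#' informative columns (>= 2 taxa with bases, no gap or N among them counted)
#' showing >= 2 distinct bases.
#'
#' @param aln a [plastome_alignment].
#' @param at_window window width in columns (default 100).
#' @param div_step step between window starts in columns (default 10).
#' @return data.frame with `start`, `end` (1-based columns), `at_content`,
#'   `divergence`.
#' @export
sliding_at_vs_divergence <- function(aln, at_window = 100L, div_step = 10L) {
  stopifnot(at_window >= 1L, div_step >= 1L)
  if (at_window > aln$ncol) stop("window larger than alignment")
  m <- aln_matrix(aln)
  is_base <- m %in% BASES
  dim(is_base) <- dim(m)
  is_at <- m %in% c("A", "T")
  dim(is_at) <- dim(m)
  # per-column: informative (all non-gap/N rows >= 2) and variable
  col_at <- colSums(is_at)
  col_bases <- colSums(is_base)
  col_var <- vapply(seq_len(ncol(m)), function(j) {
    b <- m[is_base[, j], j]
    length(unique(b)) >= 2L
  }, logical(1L))
  col_inf <- colSums(is_base) >= 2L
  starts <- seq(1L, aln$ncol - at_window + 1L, by = div_step)
  out <- lapply(starts, function(s) {
    cols <- s:(s + at_window - 1L)
    n_inf <- sum(col_inf[cols])
    data.frame(
      start = s, end = s + at_window - 1L,
      at_content = sum(col_at[cols]) / max(sum(col_bases[cols]), 1L),
      divergence = if (n_inf > 0L) sum(col_var[cols] & col_inf[cols]) / n_inf
                   else NA_real_)
  })
  do.call(rbind, out)
}
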