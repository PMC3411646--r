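#' Multi-taxon indel loci
#'
#' Maximal column spans where at least one taxon is gapped and the set of
#' gapped taxa is constant across the span. Nested or overlapping gaps are
#' split into separate loci wherever the gapped set changes.
#'
#' @param aln a [plastome_alignment].
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `length`, `gapped_taxa` (comma-separated), `n_gapped`, and logical
#'   `boundary_exact` (every gapped taxon's own maximal gap run coincides
#'   with the locus span, i.e. boundaries are not ragged).
#' @export
multi_taxon_indel_loci <- function(aln) {
  m <- aln_matrix(aln)
  gap <- m == "-"
  dim(gap) <- dim(m)
  any_gap <- colSums(gap) > 0L
  if (!any(any_gap)) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      gapped_taxa = character(), n_gapped = integer(),
                      boundary_exact = logical(), stringsAsFactors = FALSE))
  }
  # pattern key per column: which taxa are gapped ("" when none)
  key <- character(ncol(m))
  key[any_gap] <- apply(gap[, any_gap, drop = FALSE], 2L, function(g) {
    paste(which(g), collapse = ",")
  })
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != ""
  starts <- starts[keep]; ends <- ends[keep]
  patt <- r$values[keep]
  n <- length(starts)
  taxa_idx <- lapply(strsplit(patt, ",", fixed = TRUE), as.integer)
  gapped_taxa <- vapply(taxa_idx, function(ix) {
    paste(aln$taxa[ix], collapse = ",")
  }, character(1L))
  exact <- vapply(seq_len(n), function(i) {
    ix <- taxa_idx[[i]]
    left_ok <- starts[i] == 1L || !any(gap[ix, starts[i] - 1L])
    right_ok <- ends[i] == ncol(m) || !any(gap[ix, ends[i] + 1L])
    left_ok && right_ok
  }, logical(1L))
  data.frame(start = starts, end = ends, length = ends - starts + 1L,
             gapped_taxa = gapped_taxa,
             n_gapped = lengths(taxa_idx),
             boundary_exact = exact, stringsAsFactors = FALSE)
}

#' Group labels for polarization
#'
#' Validates a taxon -> group mapping for the staged polarization rules:
#' exactly one outgroup, and non-empty A-diploid, D-diploid and
#' allotetraploid groups.
#'
#' @param groups named character vector with values in `A_diploid`,
#'   `D_diploid`, `allotetraploid`, `outgroup`.
#' @return the validated mapping (class `group_labels`).
#' @export
group_labels <- function(groups) {
  stopifnot(is.character(groups), !is.null(names(groups)))
  valid <- c("A_diploid", "D_diploid", "allotetraploid", "outgroup")
  if (!all(groups %in% valid)) {
    stop("group labels must be one of: ", paste(valid, collapse = ", "))
  }
  if (sum(groups == "outgroup") != 1L) stop("exactly one outgroup required")
  for (g in setdiff(valid, "outgroup")) {
    if (!any(groups == g)) stop("group '", g, "' is empty")
  }
  structure(groups, class = "group_labels")
}

set_eq <- function(x, y) length(x) == length(y) && setequal(x, y)

#' Polarize indel loci against an outgroup
#'
#' Implements the staged polarization rules for a four-group design
#' (A-genome diploids, D-genome diploids, allotetraploids, one outgroup).
#' For each locus the set of gap-sharing taxa determines lineage, stage and
#' polarity:
#'
#' * D lineage, stage 1: both D genomes differ from outgroup+A+allotetraploids
#'   (gap shared by D = deletion; sequence unique to D = insertion);
#'   stage 2: a single D genome differs.
#' * A lineage, stage 1: A genomes and all allotetraploids jointly differ from
#'   D + outgroup (before allotetraploid formation); stage 2: the A genomes
#'   alone differ (after allotetraploid formation); stage 3: a single A
#'   genome differs.
#' * Allotetraploids, stage 1: all allotetraploids differ from A + D +
#'   outgroup; stage 2: a subset of allotetraploids differs, accepted only if
#'   the subset is a clade of the supplied tree (otherwise flagged as a
#'   homoplasy candidate and left unpolarized).
#'
#' Ragged boundaries (a sharing taxon's gap run extending past the locus) and
#' patterns matching no rule are reported as `unpolarized` with a reason. The
#' SSR mask marks loci as SSR-associated; such loci polarize only when a
#' single stage rule matches, which the pattern rules guarantee.
#'
#' @param loci data.frame from [multi_taxon_indel_loci()].
#' @param groups a [group_labels()] mapping (or named character vector).
#' @param tree optional `ape::phylo` used to test allotetraploid stage-2
#'   subsets for monophyly; without a tree all such subsets are accepted.
#' @param ssr_mask optional data.frame with `start`, `end` master-column
#'   spans of length-variable SSR loci.
#' @return data.frame: `start`, `end`, `length`, `polarity` (`insertion`,
#'   `deletion`, `unpolarized`), `lineage` (`A`, `D`, `AD`,
#'   `terminal:<taxon>`, or `NA`), `stage`, `taxa` (the taxa carrying the
#'   event), `ssr_associated`, `reason`.
#' @export
polarize_indels <- function(loci, groups, tree = NULL, ssr_mask = NULL) {
  groups <- group_labels(unclass(groups))
  all_taxa <- names(groups)
  og <- names(groups)[groups == "outgroup"]
  A <- names(groups)[groups == "A_diploid"]
  D <- names(groups)[groups == "D_diploid"]
  AD <- names(groups)[groups == "allotetraploid"]

  ad_is_clade <- function(subset) {
    if (is.null(tree)) return(TRUE)
    if (length(subset) == 1L) return(TRUE)
    node <- ape::getMRCA(tree, subset)
    tips <- tree$tip.label[unlist(phangorn_descendants(tree, node))]
    set_eq(intersect(tips, all_taxa), subset)
  }

  n <- nrow(loci)
  polarity <- rep("unpolarized", n)
  lineage <- rep(NA_character_, n)
  stage <- rep(NA_integer_, n)
  taxa_out <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  ssr_assoc <- rep(FALSE, n)
  if (!is.null(ssr_mask) && nrow(ssr_mask) > 0L && n > 0L) {
    for (i in seq_len(n)) {
      ssr_assoc[i] <- any(loci$start[i] <= ssr_mask$end &
                          loci$end[i] >= ssr_mask$start)
    }
  }

  classify <- function(G) {
    # G: taxa sharing the gap. The event carriers are G (deletion) or the
    # complement of G (insertion: everyone else, incl. outgroup, is gapped).
    S <- setdiff(all_taxa, G)
    if (!og %in% G) {
      # outgroup has sequence: G is a derived deletion candidate
      if (set_eq(G, D)) return(list("deletion", "D", 1L, G))
      if (length(G) == 1L && G %in% D) {
        return(list("deletion", paste0("terminal:", G), 2L, G))
      }
      if (set_eq(G, c(A, AD))) return(list("deletion", "A", 1L, G))
      if (set_eq(G, A)) return(list("deletion", "A", 2L, G))
      if (length(G) == 1L && G %in% A) {
        return(list("deletion", paste0("terminal:", G), 3L, G))
      }
      if (set_eq(G, AD)) return(list("deletion", "AD", 1L, G))
      if (length(G) >= 1L && all(G %in% AD)) {
        if (!ad_is_clade(G)) return(list("unpolarized", NA, NA,
                                         "homoplasy_candidate"))
        st <- 2L
        lin <- if (length(G) == 1L) paste0("terminal:", G) else "AD"
        return(list("deletion", lin, st, G))
      }
      return(list("unpolarized", NA, NA, "no_rule"))
    }
    # outgroup gapped: S (the sequence carriers) hold a derived insertion
    if (set_eq(S, D)) return(list("insertion", "D", 1L, S))
    if (length(S) == 1L && S %in% D) {
      return(list("insertion", paste0("terminal:", S), 2L, S))
    }
    if (set_eq(S, c(A, AD))) return(list("insertion", "A", 1L, S))
    if (set_eq(S, A)) return(list("insertion", "A", 2L, S))
    if (length(S) == 1L && S %in% A) {
      return(list("insertion", paste0("terminal:", S), 3L, S))
    }
    if (set_eq(S, AD)) return(list("insertion", "AD", 1L, S))
    if (length(S) >= 1L && all(S %in% AD)) {
      if (!ad_is_clade(S)) return(list("unpolarized", NA, NA,
                                       "homoplasy_candidate"))
      lin <- if (length(S) == 1L) paste0("terminal:", S) else "AD"
      return(list("insertion", lin, 2L, S))
    }
    list("unpolarized", NA, NA, "no_rule")
  }

  for (i in seq_len(n)) {
    G <- strsplit(loci$gapped_taxa[i], ",", fixed = TRUE)[[1L]]
    if (!all(G %in% all_taxa)) {
      reason[i] <- "unlabeled_taxon"
      next
    }
    if (!isTRUE(loci$boundary_exact[i])) {
      reason[i] <- "ragged_boundary"
      next
    }
    res <- classify(G)
    if (res[[1L]] == "unpolarized") {
      reason[i] <- res[[4L]]
    } else {
      polarity[i] <- res[[1L]]
      lineage[i] <- res[[2L]]
      stage[i] <- res[[3L]]
      taxa_out[i] <- paste(sort(res[[4L]]), collapse = ",")
    }
  }
  data.frame(start = loci$start, end = loci$end, length = loci$length,
             polarity = polarity, lineage = lineage, stage = stage,
             taxa = taxa_out, ssr_associated = ssr_assoc, reason = reason,
             stringsAsFactors = FALSE)
}

# tip descendants of a node (node may be a tip)
phangorn_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, phangorn_descendants, tree = tree))
}

#' Assign polarized indels to tree branches
#'
#' Maps each polarized event to the unique branch implied by its carrier
#' taxa: the edge above the most recent common ancestor of the carriers (the
#' pendant edge for terminal events).
#'
#' @param polarized data.frame from [polarize_indels()].
#' @param tree rooted `ape::phylo` whose tips include every carrier taxon;
#'   internal nodes should be labelled (unlabelled nodes get `node<k>`).
#' @return list with `events` (the polarized input plus a `branch` column:
#'   child-node label of the assigned edge, `NA` when unassigned) and
#'   `branch_counts` (data.frame per branch: `n_insertions`, `bp_insertions`,
#'   `n_deletions`, `bp_deletions`).
#' @export
assign_events_to_branches <- function(polarized, tree) {
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    tree$node.label <- paste0("node", seq_len(tree$Nnode) + ntip)
  }
  node_name <- c(tree$tip.label, tree$node.label)
  branch <- rep(NA_character_, nrow(polarized))
  for (i in seq_len(nrow(polarized))) {
    if (polarized$polarity[i] == "unpolarized") next
    taxa <- strsplit(polarized$taxa[i], ",", fixed = TRUE)[[1L]]
    if (!all(taxa %in% tree$tip.label)) next
    node <- if (length(taxa) == 1L) {
      match(taxa, tree$tip.label)
    } else {
      ape::getMRCA(tree, taxa)
    }
    # the event lies on the edge above this node
    branch[i] <- node_name[node]
  }
  ev <- polarized
  ev$branch <- branch
  assigned <- ev[!is.na(ev$branch), , drop = FALSE]
  if (nrow(assigned) > 0L) {
    branches <- sort(unique(assigned$branch))
    bc <- data.frame(branch = branches, stringsAsFactors = FALSE)
    for (pol in c("insertion", "deletion")) {
      x <- assigned[assigned$polarity == pol, ]
      cnt <- tapply(rep(1L, nrow(x)), x$branch, sum)
      bp <- tapply(x$length, x$branch, sum)
      bc[[paste0("n_", pol, "s")]] <- as.integer(ifelse(
        is.na(cnt[branches]), 0L, cnt[branches]))
      bc[[paste0("bp_", pol, "s")]] <- as.integer(ifelse(
        is.na(bp[branches]), 0L, bp[branches]))
    }
  } else {
    bc <- data.frame(branch = character(), n_insertions = integer(),
                     bp_insertions = integer(), n_deletions = integer(),
                     bp_deletions = integer(), stringsAsFactors = FALSE)
  }
  list(events = ev, branch_counts = bc)
}

#' Indel size spectrum
#'
#' @param lengths integer vector of indel lengths (or a data.frame with a
#'   `length` column).
#' @return list with `counts` (named table over exact lengths), `fractions`
#'   (same, normalized), `frac_le_10`, and `frac_1_to_10` (length-10 vector of
#'   the fraction at each length 1..10). Empty input gives empty tables.
#' @export
indel_size_spectrum <- function(lengths) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L) {
    return(list(counts = integer(0L), fractions = numeric(0L),
                frac_le_10 = NaN,
                frac_1_to_10 = setNames(rep(NaN, 10L), 1:10)))
  }
  counts <- table(lengths)
  fr <- counts / sum(counts)
  f110 <- vapply(1:10, function(k) sum(lengths == k) / length(lengths),
                 numeric(1L))
  list(counts = counts, fractions = fr,
       frac_le_10 = sum(lengths <= 10L) / length(lengths),
       frac_1_to_10 = setNames(f110, 1:10))
}

#' Tandem duplication check
#'
#' An indel is a tandem duplication/loss candidate when its bases exactly
#' equal the immediately adjacent upstream or downstream segment of equal
#' length (slipped-strand mispairing signature).
#'
#' @param bases the inserted/retained bases of the event (string).
#' @param flank_up sequence immediately upstream of the event (string; only
#'   its last `nchar(bases)` characters are used).
#' @param flank_down sequence immediately downstream (first `nchar(bases)`
#'   characters used).
#' @return logical.
#' @export
tandem_dup_check <- function(bases, flank_up = "", flank_down = "") {
  k <- nchar(bases)
  if (k == 0L) return(FALSE)
  up_ok <- nchar(flank_up) >= k &&
    substr(flank_up, nchar(flank_up) - k + 1L, nchar(flank_up)) == bases
  down_ok <- nchar(flank_down) >= k && substr(flank_down, 1L, k) == bases
  up_ok || down_ok
}

#' Indel ratio per lineage per million years
#'
#' Standardizes an indel count to events per genome (lineage) per million
#' years of divergence.
#'
#' @param indel_count number of indel events between two genomes.
#' @param divergence_time_my divergence time in million years (> 0).
#' @param n_lineages number of lineages accumulating events (default 2).
#' @return list with `ratio` and `normalization` (a record of the mode).
#' @export
indel_ratio <- function(indel_count, divergence_time_my, n_lineages = 2) {
  stopifnot(divergence_time_my > 0, n_lineages >= 1)
  list(ratio = indel_count / (n_lineages * divergence_time_my),
       normalization = sprintf("events / (%d lineages x MY)",
                               as.integer(n_lineages)))
}
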