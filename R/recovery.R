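#' Evaluate polarization recovery against the simulator truth log
#'
#' Runs locus extraction, staged polarization and branch assignment on a
#' simulation's truth alignment and scores them against the planted indel
#' events. An event is recovered when a polarized locus reproduces its exact
#' column span with the correct polarity and is assigned to the branch the
#' event was planted on. Only events on rule-covered branches enter the
#' denominator: the staged rules cannot polarize changes on the outgroup
#' pendant branch or on the ingroup stem, so events planted there are
#' unpolarizable by construction.
#'
#' @param sim a `plastome_simulation`.
#' @param groups group labels for the tips (see [group_labels()]).
#' @param include_ssr also score planted SSR slippage events (default FALSE:
#'   score substitutions-free insertion/deletion events only).
#' @return list with `n_planted`, `n_recovered`, `recovery` (fraction),
#'   `planted` (per-event data.frame with `recovered` flag), `polarized`
#'   (assigned polarization table).
#' @export
evaluate_polarization_recovery <- function(sim, groups, include_ssr = FALSE) {
  stopifnot(inherits(sim, "plastome_simulation"))
  groups <- group_labels(unclass(groups))
  tree <- sim$tree
  ntip <- length(tree$tip.label)
  node_name <- c(tree$tip.label, tree$node.label)

  loci <- multi_taxon_indel_loci(sim$alignment)
  pol <- polarize_indels(loci, groups, tree = tree)
  asn <- assign_events_to_branches(pol, tree)$events

  kinds <- c("insertion", "deletion")
  if (include_ssr) kinds <- c(kinds, "ssr_expansion", "ssr_contraction")
  planted <- sim$events[sim$events$kind %in% kinds, , drop = FALSE]

  # rule-covered branches: strict descendants of the ingroup crown
  ingroup <- names(groups)[groups != "outgroup"]
  crown <- ape::getMRCA(tree, ingroup)
  covered_nodes <- setdiff(unlist(phangorn_descendants_all(tree, crown)),
                           crown)
  covered <- node_name[covered_nodes]
  planted <- planted[planted$branch %in% covered, , drop = FALSE]

  pol_kind <- ifelse(planted$kind %in% c("insertion", "ssr_expansion"),
                     "insertion", "deletion")
  key_planted <- paste(planted$start, planted$end, planted$length,
                       pol_kind, planted$branch)
  ok_rows <- asn$polarity != "unpolarized" & !is.na(asn$branch)
  key_pol <- paste(asn$start[ok_rows], asn$end[ok_rows],
                   asn$length[ok_rows], asn$polarity[ok_rows],
                   asn$branch[ok_rows])
  planted$recovered <- key_planted %in% key_pol

  list(n_planted = nrow(planted),
       n_recovered = sum(planted$recovered),
       recovery = if (nrow(planted) > 0L) mean(planted$recovered) else NaN,
       planted = planted, polarized = asn)
}

# all descendants (internal + tips) of a node, including the node itself
phangorn_descendants_all <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  c(node, unlist(lapply(kids, phangorn_descendants_all, tree = tree)))
}
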