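#' Pipeline configuration
#'
#' Exactly one of `simulation` (an in-memory simulation request) or `inputs`
#' (paths to a real dataset) must be supplied.
#'
#' @param simulation `NULL` or list with `spec` ([ancestral_spec]), `model`
#'   ([evolution_model]), `tree` (`phylo`), `groups` (named character vector),
#'   optional `mirror_ir` (default TRUE).
#' @param inputs `NULL` or list of paths: `alignment`, `regions`, `tree`,
#'   `groups`, optional `features`.
#' @param thresholds SSR threshold set (`"A"`, `"B"` or named vector).
#' @param calibration `NULL`, a per-site per-year synonymous rate, a
#'   [calibrate_rate()] object, or `list(pair = c(a, b), t_my = <MY>)` to
#'   calibrate from a taxon pair.
#' @param rrt_outgroup taxon used as the reference in Tajima's relative rate
#'   tests (default: the first D-genome diploid when groups are available).
#' @param reference_taxon taxon whose region map anchors per-region rates
#'   (default: first taxon with a region map).
#' @param seed global RNG seed; overrides simulation seeds (spec gets `seed`,
#'   model `seed + 1`).
#' @param out_dir `NULL` or a directory to write the table bundle and
#'   manifest to.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            thresholds = "A", calibration = NULL,
                            rrt_outgroup = NULL, reference_taxon = NULL,
                            seed = 0L, out_dir = NULL) {
  if (is.null(simulation) == is.null(inputs)) {
    stop("supply exactly one of `simulation` or `inputs`")
  }
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation$spec, "ancestral_spec"),
              inherits(simulation$model, "evolution_model"),
              inherits(simulation$tree, "phylo"))
    if (is.null(simulation$mirror_ir)) simulation$mirror_ir <- TRUE
  } else {
    need <- c("alignment", "regions", "tree", "groups")
    missing <- setdiff(need, names(inputs))
    if (length(missing)) {
      stop("missing input paths: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(simulation = simulation, inputs = inputs,
                 thresholds = thresholds, calibration = calibration,
                 rrt_outgroup = rrt_outgroup,
                 reference_taxon = reference_taxon,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full divergence pipeline
#'
#' Orchestrates simulate (optional) -> pairwise divergence -> per-region
#' rates -> indel loci, polarization and branch mapping -> indel size
#' spectrum -> SSR detection, homology, polymorphism and short-indel
#' attribution -> Ks dating (when a calibration is supplied and gene features
#' exist) -> Tajima relative rate tests. Reruns with the same configuration
#' produce identical tables.
#'
#' @param config a [pipeline_config()].
#' @return object of class `plastdiverge_run`: list of result tables plus a
#'   `manifest` describing inputs, seed and decisions in force.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- NULL
  if (!is.null(config$simulation)) {
    s <- config$simulation
    s$spec$rng_seed <- config$seed
    s$model$rng_seed <- config$seed + 1L
    ancestor <- build_ancestral_genome(s$spec)
    sim <- evolve_along_tree(ancestor, s$tree, s$model,
                             mirror_ir = s$mirror_ir)
    aln <- sim$alignment
    genomes <- sim$genomes
    regions <- do.call(rbind, lapply(genomes, function(g) {
      cbind(taxon = g$taxon_id, g$regions)
    }))
    rownames(regions) <- NULL
    tree <- sim$tree
    groups <- s$groups
  } else {
    aln <- read_alignment(config$inputs$alignment)
    regions <- read_regions(config$inputs$regions)
    tree <- read_tree(config$inputs$tree)
    groups <- read_groups(config$inputs$groups)
    feats <- if (!is.null(config$inputs$features)) {
      read_features(config$inputs$features)
    } else NULL
    genomes <- lapply(aln$taxa, function(tx) {
      r <- regions[regions$taxon == tx, c("region", "start", "end")]
      g <- if (!is.null(feats)) {
        f <- feats[feats$taxon == tx, c("name", "start", "end", "strand",
                                        "is_cds")]
        if (nrow(f)) f else NULL
      } else NULL
      genome_record(tx, ungapped_sequence(aln, tx),
                    regions = if (nrow(r)) r else NULL, genes = g)
    })
    names(genomes) <- aln$taxa
  }
  taxa <- aln$taxa

  ## pairwise divergence table + matrix
  pair_rows <- list()
  indel_by_pair <- list()
  for (i in seq_along(taxa)[-length(taxa)]) {
    for (j in (i + 1L):length(taxa)) {
      a <- taxa[i]; b <- taxa[j]
      pair_rows[[length(pair_rows) + 1L]] <-
        pairwise_divergence(aln, a, b, regions)
      view <- project_pairwise(aln, a, b)
      indel_by_pair[[paste(a, b, sep = "|")]] <-
        extract_indels(view, aln, regions)
    }
  }
  pairwise <- do.call(rbind, pair_rows)
  class(pairwise) <- "data.frame"
  matrix_si <- pairwise_matrix(aln, taxa)

  ## per-region rates against the reference taxon
  ref <- config$reference_taxon %||%
    (if (length(unique(regions$taxon))) unique(regions$taxon)[1L] else NULL)
  region_rates <- NULL
  if (!is.null(ref) && ref %in% taxa) {
    rr <- lapply(setdiff(taxa, ref), function(b) {
      cbind(taxon_a = ref, taxon_b = b,
            per_region_stats(aln, regions, ref, b))
    })
    region_rates <- do.call(rbind, rr)
  }

  ## indel loci, polarization, branch mapping, spectrum
  loci <- multi_taxon_indel_loci(aln)
  polarized <- NULL
  branch_counts <- NULL
  if (!is.null(groups)) {
    pol <- polarize_indels(loci, groups, tree = tree)
    asn <- assign_events_to_branches(pol, tree)
    polarized <- asn$events
    branch_counts <- asn$branch_counts
  }
  spectrum <- indel_size_spectrum(loci$length)

  ## SSR analysis
  thresholds <- ssr_thresholds(config$thresholds)
  ssr_loci <- do.call(rbind, lapply(genomes, find_ssrs,
                                    thresholds = thresholds))
  ssr_groups <- ssr_locus_homology(aln, ssr_loci)
  ssr_poly <- if (nrow(ssr_groups) > 0L) {
    polymorphism_stats(ssr_groups, taxa)
  } else NULL
  attribution <- NULL
  if (nrow(ssr_groups) > 0L) {
    att <- lapply(names(indel_by_pair), function(key) {
      ab <- strsplit(key, "|", fixed = TRUE)[[1L]]
      res <- attribute_short_indels(indel_by_pair[[key]], ssr_groups,
                                    ab[1L], ab[2L])
      data.frame(taxon_a = ab[1L], taxon_b = ab[2L],
                 n_short = res$n_short, n_attributed = res$n_attributed,
                 attributed_fraction = res$attributed_fraction,
                 stringsAsFactors = FALSE)
    })
    attribution <- do.call(rbind, att)
  }

  ## Ks dating over concatenated CDS columns of the reference taxon
  dates <- NULL
  calibration_used <- NULL
  cds_cols <- reference_cds_columns(aln, genomes, ref)
  if (!is.null(cds_cols) && !is.null(config$calibration)) {
    cds_seq <- function(tx) {
      paste(aln_chars(aln, tx)[cds_cols], collapse = "")
    }
    ks_pair <- function(a, b) ng86_ka_ks(cds_seq(a), cds_seq(b),
                                         on_stop = "drop")$ks
    cal <- config$calibration
    if (is.list(cal) && !inherits(cal, "rate_calibration")) {
      ksc <- ks_pair(cal$pair[1L], cal$pair[2L])
      calibration_used <- calibrate_rate(ksc, cal$t_my * 1e6,
                                         source = paste(cal$pair,
                                                        collapse = "-"))
    } else if (inherits(cal, "rate_calibration")) {
      calibration_used <- cal
    } else {
      calibration_used <- structure(list(rs = as.numeric(cal),
                                         source = "user-supplied rate"),
                                    class = "rate_calibration")
    }
    if (is.na(calibration_used$rs) || calibration_used$rs <= 0) {
      # degenerate calibration (no synonymous divergence observed): no dates
      calibration_used$note <- "calibration rate <= 0; dating skipped"
    } else {
      rows <- list()
      for (i in seq_along(taxa)[-length(taxa)]) {
        for (j in (i + 1L):length(taxa)) {
          ks <- ks_pair(taxa[i], taxa[j])
          dt <- divergence_time(ks, calibration_used)
          rows[[length(rows) + 1L]] <- data.frame(
            taxon_a = taxa[i], taxon_b = taxa[j], ks = ks, t_my = dt$t_my,
            saturated = dt$saturated, stringsAsFactors = FALSE)
        }
      }
      dates <- do.call(rbind, rows)
    }
  }

  ## Tajima relative rate tests: allotetraploids vs A diploids, D outgroup
  rrt <- NULL
  if (!is.null(groups)) {
    a_taxa <- names(groups)[groups == "A_diploid"]
    ad_taxa <- names(groups)[groups == "allotetraploid"]
    og <- config$rrt_outgroup %||% names(groups)[groups == "D_diploid"][1L]
    if (length(a_taxa) && length(ad_taxa) && !is.null(og) && og %in% taxa) {
      rows <- list()
      for (ad in ad_taxa) {
        for (a in a_taxa) {
          r <- tajima_rrt(aln, ad, a, og)
          rows[[length(rows) + 1L]] <- data.frame(
            lineage_a = ad, lineage_b = a, outgroup = og,
            n_a = r$n_a, n_b = r$n_b, chi_square = r$chi_square,
            p_value = r$p_value, stringsAsFactors = FALSE)
        }
      }
      rrt <- do.call(rbind, rows)
    }
  }

  manifest <- list(
    seed = config$seed,
    mode = if (!is.null(sim)) "simulation" else "real-input",
    taxa = taxa,
    alignment_length = aln$ncol,
    thresholds = as.list(thresholds),
    reference_taxon = ref,
    calibration = if (!is.null(calibration_used)) {
      list(rs = calibration_used$rs, source = calibration_used$source)
    } else NULL,
    decisions = c(
      "terminal gap runs excluded from pairwise indel events",
      "IR counts and lengths pooled over both copies and divided by 2",
      "N columns excluded from substitution and rate denominators",
      "shared gaps require identical span boundaries for polarization",
      "SSR homology: canonical motif equality + >=1 shared alignment column",
      "reverse-complement SSR motifs not collapsed; absence scored length 0"
    )
  )

  res <- structure(
    list(alignment = aln, genomes = genomes, regions = regions, tree = tree,
         groups = groups, simulation = sim,
         pairwise = pairwise, matrix = matrix_si,
         region_rates = region_rates, loci = loci, polarized = polarized,
         branch_counts = branch_counts, spectrum = spectrum,
         ssr_loci = ssr_loci, ssr_groups = ssr_groups, ssr_poly = ssr_poly,
         attribution = attribution, dates = dates, rrt = rrt,
         manifest = manifest),
    class = "plastdiverge_run")
  if (!is.null(config$out_dir)) write_run_bundle(res, config$out_dir)
  res
}

# master columns covered by the reference taxon's CDS features, in gene order
reference_cds_columns <- function(aln, genomes, ref) {
  if (is.null(ref) || !ref %in% aln$taxa) return(NULL)
  g <- genomes[[ref]]
  if (is.null(g$genes) || !any(g$genes$is_cds)) return(NULL)
  cols <- pos_to_col(aln, ref)
  cds <- g$genes[g$genes$is_cds, , drop = FALSE]
  unlist(lapply(seq_len(nrow(cds)), function(i) {
    len <- cds$end[i] - cds$start[i]
    len <- len - (len %% 3L)  # keep frame
    if (len < 3L) return(integer(0L))
    cols[(cds$start[i] + 1L):(cds$start[i] + len)]
  }))
}

#' @export
print.plastdiverge_run <- function(x, ...) {
  cat("<plastdiverge_run> ", length(x$alignment$taxa), " taxa, alignment ",
      x$alignment$ncol, " columns (", x$manifest$mode, " mode, seed ",
      x$manifest$seed, ")\n", sep = "")
  cat("  pairwise comparisons: ", nrow(x$pairwise), "\n", sep = "")
  if (!is.null(x$polarized)) {
    cat("  indel loci: ", nrow(x$loci), " (",
        sum(x$polarized$polarity != "unpolarized"), " polarized)\n", sep = "")
  }
  cat("  SSR loci: ", nrow(x$ssr_loci), "\n", sep = "")
  if (!is.null(x$dates)) cat("  dated pairs: ", nrow(x$dates), "\n", sep = "")
  invisible(x)
}

#' @export
summary.plastdiverge_run <- function(object, ...) {
  x <- object
  cat("Pairwise substitution divergence (%):\n")
  print(summary(x$pairwise$subst_divergence_pct))
  cat("Pairwise indel divergence (%):\n")
  print(summary(x$pairwise$indel_divergence_pct))
  if (!is.null(x$spectrum$frac_1_to_10)) {
    cat("Indel size spectrum, fraction at 1..10 bp:\n")
    print(round(x$spectrum$frac_1_to_10, 3))
  }
  invisible(x)
}

write_run_bundle <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(res$pairwise, "pairwise_divergence.tsv")
  m <- res$matrix
  write.table(cbind(taxon = rownames(m), as.data.frame(m)),
              file.path(out_dir, "pairwise_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$region_rates, "region_rates.tsv")
  wt(res$loci, "indel_loci.tsv")
  wt(res$polarized, "polarized_indels.tsv")
  wt(res$branch_counts, "branch_counts.tsv")
  wt(res$ssr_loci, "ssr_loci.tsv")
  if (!is.null(res$ssr_poly)) {
    pw <- res$ssr_poly$pairwise
    write.table(cbind(taxon = rownames(pw), as.data.frame(pw)),
                file.path(out_dir, "ssr_polymorphism.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    wt(res$ssr_poly$by_class, "ssr_conservation.tsv")
  }
  wt(res$attribution, "short_indel_attribution.tsv")
  wt(res$dates, "dates.tsv")
  wt(res$rrt, "relative_rate_tests.tsv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
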