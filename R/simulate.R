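#' Specification of an ancestral quadripartite plastome
#'
#' Defaults emulate the published chloroplast genomes of diploid and
#' allotetraploid cottons: ~160-kb genomes with an 88.8-kb LSC, 20.3-kb SSC
#' and 25.6-kb inverted repeat, with AT content 64.8% (LSC), 68.3% (SSC) and
#' 57.0% (IR).
#'
#' @param lsc_len,ssc_len,ir_len region lengths in bp (`ir_len` is one IR
#'   copy; the genome carries two reverse-complementary copies).
#' @param at_content named fractions in (0,1) for `LSC`, `SSC`, `IR`.
#' @param n_genes number of CDS gene features to annotate (coordinates only;
#'   placed in the LSC interior, length `gene_len`).
#' @param gene_len CDS length in bp (multiple of 3).
#' @param ssr_seed_loci `NULL` or data.frame with columns `motif` (1-5 bp),
#'   `units` (repeat count) and `region` (`LSC`, `SSC` or `IR`).
#' @param rng_seed integer seed.
#' @return a list of class `ancestral_spec`.
#' @export
ancestral_spec <- function(lsc_len = 88800L, ssc_len = 20300L,
                           ir_len = 25600L,
                           at_content = c(LSC = 0.648, SSC = 0.683, IR = 0.570),
                           n_genes = 0L, gene_len = 300L,
                           ssr_seed_loci = NULL, rng_seed = 1L) {
  stopifnot(lsc_len > 0L, ssc_len > 0L, ir_len > 0L,
            all(c("LSC", "SSC", "IR") %in% names(at_content)),
            all(at_content > 0 & at_content < 1),
            gene_len %% 3L == 0L)
  if (!is.null(ssr_seed_loci)) {
    stopifnot(is.data.frame(ssr_seed_loci),
              all(c("motif", "units", "region") %in% names(ssr_seed_loci)),
              all(nchar(ssr_seed_loci$motif) %in% 1:5),
              all(ssr_seed_loci$units >= 2 | nchar(ssr_seed_loci$motif) == 1),
              all(ssr_seed_loci$region %in% c("LSC", "SSC", "IR", "IRb")))
  }
  structure(list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len), at_content = at_content,
                 n_genes = as.integer(n_genes), gene_len = as.integer(gene_len),
                 ssr_seed_loci = ssr_seed_loci, rng_seed = as.integer(rng_seed)),
            class = "ancestral_spec")
}

random_bases <- function(n, at) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate an ancestral plastome
#'
#' Builds one linearized quadripartite genome: regions LSC, IRb, SSC, IRa in
#' that order, with IRa the exact reverse complement of IRb, region base
#' composition matching the requested AT content, seeded perfect SSR loci and
#' (optionally) stop-free CDS gene annotations.
#'
#' @param spec an [ancestral_spec].
#' @return a `genome_record` (taxon id `"ancestor"`) with an extra
#'   `ssr_loci` element: data.frame of seeded loci (`motif`, `unit`, `start`,
#'   `end`, `region`, 0-based half-open).
#' @export
build_ancestral_genome <- function(spec) {
  stopifnot(inherits(spec, "ancestral_spec"))
  with_seed(spec$rng_seed, {
    lsc <- random_bases(spec$lsc_len, spec$at_content[["LSC"]])
    ssc <- random_bases(spec$ssc_len, spec$at_content[["SSC"]])
    irb <- random_bases(spec$ir_len, spec$at_content[["IR"]])

    region_offsets <- c(LSC = 0L, IRb = spec$lsc_len,
                        SSC = spec$lsc_len + spec$ir_len,
                        IRa = spec$lsc_len + spec$ir_len + spec$ssc_len)
    region_lens <- c(LSC = spec$lsc_len, IRb = spec$ir_len,
                     SSC = spec$ssc_len, IRa = spec$ir_len)
    parts <- list(LSC = lsc, IRb = irb, SSC = ssc)

    # seed SSR loci as perfect repeats, non-overlapping within each region
    ssr_loci <- NULL
    if (!is.null(spec$ssr_seed_loci)) {
      sl <- spec$ssr_seed_loci
      sl$region <- ifelse(sl$region == "IR", "IRb", sl$region)
      sl$motif <- toupper(sl$motif)
      out <- vector("list", nrow(sl))
      cursor <- c(LSC = 0L, IRb = 0L, SSC = 0L)
      for (i in seq_len(nrow(sl))) {
        reg <- sl$region[i]
        u <- nchar(sl$motif[i])
        span <- u * sl$units[i]
        reg_len <- region_lens[[reg]]
        n_in_reg <- sum(sl$region == reg)
        slot <- reg_len %/% (n_in_reg + 1L)
        if (span + 2L > slot) {
          stop("region ", reg, " cannot host all seeded SSR loci")
        }
        cursor[[reg]] <- cursor[[reg]] + 1L
        start <- cursor[[reg]] * slot - span %/% 2L
        rep_chars <- strsplit(strrep(sl$motif[i], sl$units[i]), "",
                              fixed = TRUE)[[1L]]
        parts[[reg]][(start + 1L):(start + span)] <- rep_chars
        # break accidental run extension at the flanks
        alt <- setdiff(c("A", "C", "G", "T"),
                       c(substr(sl$motif[i], 1L, 1L),
                         substr(sl$motif[i], u, u)))[1L]
        parts[[reg]][start] <- alt
        parts[[reg]][start + span + 1L] <- alt
        out[[i]] <- data.frame(motif = sl$motif[i], unit = u,
                               start = region_offsets[[reg]] + start,
                               end = region_offsets[[reg]] + start + span,
                               region = reg, stringsAsFactors = FALSE)
      }
      ssr_loci <- do.call(rbind, out)
    }

    genes <- NULL
    if (spec$n_genes > 0L) {
      avail <- spec$lsc_len - 200L
      step <- avail %/% spec$n_genes
      if (step < spec$gene_len + 10L) stop("LSC too small for requested genes")
      starts <- 100L + (seq_len(spec$n_genes) - 1L) * step
      # stop-free codons so concatenated CDS are usable for Ka/Ks
      codons <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
      for (s in starts) {
        cds <- strsplit(paste(sample(codons, spec$gene_len %/% 3L,
                                     replace = TRUE), collapse = ""),
                        "", fixed = TRUE)[[1L]]
        parts$LSC[(s + 1L):(s + spec$gene_len)] <- cds
      }
      genes <- data.frame(name = sprintf("gene%03d", seq_len(spec$n_genes)),
                          start = starts, end = starts + spec$gene_len,
                          strand = "+", is_cds = TRUE,
                          stringsAsFactors = FALSE)
    }

    ira <- revcomp_chars(parts$IRb)
    seq <- paste(c(parts$LSC, parts$IRb, parts$SSC, ira), collapse = "")
    total <- sum(region_lens)
    regions <- data.frame(
      region = names(region_offsets),
      start = unname(region_offsets),
      end = unname(region_offsets) + unname(region_lens),
      stringsAsFactors = FALSE
    )
    g <- genome_record("ancestor", seq, regions = regions, genes = genes)
    g$ssr_loci <- ssr_loci
    g
  })
}

#' Plastome evolution model
#'
#' Rates are per site per branch-length unit (per locus per unit for SSR
#' slippage). Defaults are calibrated to the divergence observed among cotton
#' plastomes on a tree in units of million years: ~0.55% substitution
#' divergence and ~255 indel events per ~160 kb across the A/D split
#' (2 x 3.89 MY), transition:transversion ratio 0.45, an indel size spectrum
#' enriched at 1 bp (~32%) and 5-6 bp, and a 2:1 deletion bias.
#'
#' @param sub_rate expected substitutions per site per branch-length unit.
#' @param ti_tv_bias target transition/transversion (Si/Sv) ratio (> 0).
#' @param indel_rate expected indel events per site per branch-length unit.
#' @param indel_size_dist named or plain numeric vector of probabilities over
#'   indel sizes `1..length(indel_size_dist)`; must sum to 1.
#' @param tandem_dup_fraction fraction of insertions copied from the adjacent
#'   upstream segment (slipped-strand duplication) and of deletions removing
#'   one copy of an adjacent duplication.
#' @param ssr_slippage_rate per-locus per-branch-length-unit rate of one-unit
#'   SSR gain/loss events.
#' @param ins_del_bias insertion:deletion ratio; `P(insertion) =
#'   bias / (1 + bias)`.
#' @param rng_seed integer seed.
#' @return a list of class `evolution_model`.
#' @export
evolution_model <- function(sub_rate = 6.9e-4, ti_tv_bias = 0.45,
                            indel_rate = 2.1e-4,
                            indel_size_dist = c(0.32, 0.08, 0.05, 0.04, 0.20,
                                                0.12, 0.06, 0.05, 0.04, 0.04),
                            tandem_dup_fraction = 0.3,
                            ssr_slippage_rate = 0.05,
                            ins_del_bias = 0.5, rng_seed = 1L) {
  stopifnot(sub_rate >= 0, indel_rate >= 0, ssr_slippage_rate >= 0,
            ti_tv_bias > 0, ins_del_bias > 0,
            tandem_dup_fraction >= 0, tandem_dup_fraction <= 1,
            all(indel_size_dist >= 0),
            abs(sum(indel_size_dist) - 1) < 1e-8)
  structure(list(sub_rate = sub_rate, ti_tv_bias = ti_tv_bias,
                 indel_rate = indel_rate, indel_size_dist = indel_size_dist,
                 tandem_dup_fraction = tandem_dup_fraction,
                 ssr_slippage_rate = ssr_slippage_rate,
                 ins_del_bias = ins_del_bias, rng_seed = as.integer(rng_seed)),
            class = "evolution_model")
}

#' Default cotton-like species tree
#'
#' A rooted 14-taxon tree (2 A-genome diploids, 2 D-genome diploids, 9
#' allotetraploids, 1 outgroup) with named internal nodes and branch lengths
#' in million years, matching the published chloroplast topology: the
#' allotetraploid clade is sister to the A-genome diploids, with the A/D
#' split at 3.89 MY.
#'
#' @return an `ape::phylo` object.
#' @export
default_species_tree <- function() {
  nwk <- paste0(
    "(OUT:10,((D5:0.385,D6:0.385)Dcrown:3.505,((A1:0.13,A2:0.13)Acrown:0.42,",
    "(((AD1:0.02,AD1h:0.02)AD1pair:0.02,AD1l:0.04)AD1crown:0.34,",
    "((AD3:0.26,AD4:0.26)AD34:0.04,(((AD2:0.02,AD2k:0.02)AD2pair:0.02,",
    "AD2y:0.04)AD2crown:0.05,AD5:0.09)AD25:0.21)ADrest:0.08)ADcrown:0.17)",
    "AAD:3.34)ingroup:6.11)root;")
  ape::read.tree(text = nwk)
}

#' Default group labels for the cotton-like tree
#'
#' @return named character vector mapping each taxon of
#'   [default_species_tree()] to its group.
#' @export
default_group_labels <- function() {
  c(A1 = "A_diploid", A2 = "A_diploid",
    D5 = "D_diploid", D6 = "D_diploid",
    AD1 = "allotetraploid", AD1h = "allotetraploid", AD1l = "allotetraploid",
    AD2 = "allotetraploid", AD2k = "allotetraploid", AD2y = "allotetraploid",
    AD3 = "allotetraploid", AD4 = "allotetraploid", AD5 = "allotetraploid",
    OUT = "outgroup")
}

TI_MAP <- c(A = "G", G = "A", C = "T", T = "C")
TV_MAP <- list(A = c("C", "T"), G = c("C", "T"),
               C = c("A", "G"), T = c("A", "G"))

#' Evolve an ancestral plastome along a species tree
#'
#' Simulates substitutions (with transition/transversion bias), indels (with a
#' configurable size spectrum, tandem-duplication fraction and
#' insertion:deletion bias) and SSR slippage (one repeat unit gained or lost
#' per event) along every branch of a rooted tree, maintaining a master truth
#' alignment and a complete event log. Mutations falling in the IRb copy of
#' the inverted repeat are mirrored into IRa (concerted evolution) unless
#' `mirror_ir = FALSE`; mutation positions are never drawn in IRa directly
#' while mirroring is active. Indels never span a region boundary or the
#' linearization origin. An indel overlapping a previous indel on the same
#' branch is re-drawn (up to 100 times, then dropped).
#'
#' @param ancestor a genome from [build_ancestral_genome()].
#' @param tree rooted `ape::phylo` with branch lengths; tip labels become
#'   taxon ids.
#' @param model an [evolution_model].
#' @param mirror_ir logical; mirror IRb mutations into IRa.
#' @return an object of class `plastome_simulation`: list with `genomes`
#'   (named list of `genome_record`s), `alignment` (truth
#'   [plastome_alignment] over the tips), `events` (data.frame event log with
#'   final master-alignment coordinates), `ancestor_row` (ancestor state in
#'   final master coordinates), `col_regions` (region label of every master
#'   column), `tree`, `model`, `mirror_ir`.
#' @export
evolve_along_tree <- function(ancestor, tree, model, mirror_ir = TRUE) {
  stopifnot(inherits(ancestor, "genome_record"),
            inherits(tree, "phylo"), inherits(model, "evolution_model"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (length(tree$tip.label) < 1L) stop("tree has no leaves")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    tree$node.label <- paste0("node", seq_len(nnode) + ntip)
  }
  node_name <- c(tree$tip.label, tree$node.label)

  anc_chars <- seq_chars(ancestor)
  L0 <- length(anc_chars)
  regions <- ancestor$regions
  col_region <- character(L0)
  for (i in seq_len(nrow(regions))) {
    col_region[(regions$start[i] + 1L):regions$end[i]] <- regions$region[i]
  }

  st <- new.env(parent = emptyenv())
  st$ids <- seq_len(L0)
  st$region <- col_region
  st$next_id <- L0 + 1L
  st$partner <- integer(0L)
  st$rows <- vector("list", ntip + nnode)
  st$log <- list()

  # pair ancestral IR columns: IRb[i] <-> IRa[n + 1 - i]
  irb_idx <- which(col_region == "IRb")
  ira_idx <- which(col_region == "IRa")
  partner <- rep(NA_integer_, L0)
  if (length(irb_idx) && length(irb_idx) == length(ira_idx)) {
    partner[irb_idx] <- rev(ira_idx)
    partner[ira_idx] <- rev(irb_idx)
  }
  st$partner <- partner

  grow_partner <- function(k) {
    st$partner <- c(st$partner, rep(NA_integer_, k))
  }

  idx_of_id <- function(id) match(id, st$ids)

  # splice k new columns after master index `after`; returns their ids
  splice_cols <- function(after, payload, region_label, node, mirrored_gap = "-") {
    k <- length(payload)
    new_ids <- seq.int(st$next_id, length.out = k)
    st$next_id <- st$next_id + k
    st$ids <- append(st$ids, new_ids, after = after)
    st$region <- append(st$region, rep(region_label, k), after = after)
    grow_partner(k)
    for (n in seq_along(st$rows)) {
      if (is.null(st$rows[[n]])) next
      fill <- if (n == node) payload else rep(mirrored_gap, k)
      st$rows[[n]] <- append(st$rows[[n]], fill, after = after)
    }
    new_ids
  }

  log_event <- function(branch, kind, ids, region, payload, mirrored = FALSE,
                        ssr_locus = NA_integer_) {
    st$log[[length(st$log) + 1L]] <- list(
      branch = branch, kind = kind, ids = ids, length = length(ids),
      region = region, payload = payload, mirrored = mirrored,
      ssr_locus = ssr_locus)
  }

  # insertion primitive with IR mirroring; returns ids of the primary copy
  do_insertion <- function(node, after_idx, payload, region_label, branch,
                           kind = "insertion", ssr_locus = NA_integer_) {
    anchor_id <- if (after_idx >= 1L) st$ids[after_idx] else NA_integer_
    new_b <- splice_cols(after_idx, payload, region_label, node)
    log_event(branch, kind, new_b, region_label,
              paste(payload, collapse = ""), FALSE, ssr_locus)
    if (mirror_ir && region_label == "IRb" && !is.na(anchor_id) &&
        !is.na(st$partner[anchor_id])) {
      p_idx <- idx_of_id(st$partner[anchor_id])
      mirror_payload <- revcomp_chars(payload)
      new_a <- splice_cols(p_idx - 1L, mirror_payload, "IRa", node)
      k <- length(payload)
      st$partner[new_b] <- rev(new_a)
      st$partner[new_a] <- rev(new_b)
      log_event(branch, kind, new_a, "IRa",
                paste(mirror_payload, collapse = ""), TRUE, ssr_locus)
    }
    new_b
  }

  # deletion primitive with IR mirroring; `idxs` are current master indexes
  do_deletion <- function(node, idxs, region_label, branch,
                          kind = "deletion", ssr_locus = NA_integer_) {
    ids <- st$ids[idxs]
    st$rows[[node]][idxs] <- "-"
    log_event(branch, kind, ids, region_label, "", FALSE, ssr_locus)
    if (mirror_ir && region_label == "IRb") {
      pids <- st$partner[ids]
      pids <- pids[!is.na(pids)]
      if (length(pids)) {
        pidx <- match(pids, st$ids)
        st$rows[[node]][pidx] <- "-"
        log_event(branch, kind, pids, "IRa", "", TRUE, ssr_locus)
      }
    }
  }

  root <- ntip + 1L
  st$rows[[root]] <- anc_chars

  # seed SSR registry (tracked by stable column ids)
  registry0 <- list()
  if (!is.null(ancestor$ssr_loci) && nrow(ancestor$ssr_loci) > 0L) {
    for (i in seq_len(nrow(ancestor$ssr_loci))) {
      r <- ancestor$ssr_loci[i, ]
      registry0[[i]] <- list(motif = r$motif, unit = r$unit,
                             ids = seq.int(r$start + 1L, r$end),
                             region = r$region)
    }
  }
  registry <- vector("list", ntip + nnode)
  registry[[root]] <- registry0

  with_seed(model$rng_seed, {
    tre <- ape::reorder.phylo(tree, "cladewise")
    sizes <- seq_along(model$indel_size_dist)
    p_ins <- model$ins_del_bias / (1 + model$ins_del_bias)
    p_ti <- model$ti_tv_bias / (model$ti_tv_bias + 1)

    for (e in seq_len(nrow(tre$edge))) {
      u <- tre$edge[e, 1L]; v <- tre$edge[e, 2L]
      blen <- tre$edge.length[e]
      branch <- node_name[v]
      row <- st$rows[[u]]
      st$rows[[v]] <- row
      registry[[v]] <- registry[[u]]

      eligible <- function() {
        nongap <- st$rows[[v]] != "-"
        if (mirror_ir) which(nongap & st$region != "IRa") else which(nongap)
      }

      E <- eligible()
      n_sites <- length(E)
      if (n_sites == 0L || blen == 0) next

      ## substitutions
      ns <- min(rpois(1L, model$sub_rate * blen * n_sites), n_sites)
      if (ns > 0L) {
        pos <- E[sample.int(n_sites, ns)]
        for (p in pos) {
          old <- st$rows[[v]][p]
          if (!old %in% c("A", "C", "G", "T")) next
          newb <- if (runif(1L) < p_ti) TI_MAP[[old]] else
            TV_MAP[[old]][sample.int(2L, 1L)]
          st$rows[[v]][p] <- newb
          id <- st$ids[p]
          log_event(branch, "substitution", id, st$region[p], newb)
          if (mirror_ir && st$region[p] == "IRb" && !is.na(st$partner[id])) {
            pi <- idx_of_id(st$partner[id])
            st$rows[[v]][pi] <- comp_chars(newb)
            log_event(branch, "substitution", st$partner[id], "IRa",
                      comp_chars(newb), TRUE)
          }
        }
      }

      ## indels
      blocked <- integer(0L)
      ni <- rpois(1L, model$indel_rate * blen * n_sites)
      for (ev in seq_len(ni)) {
        is_ins <- runif(1L) < p_ins
        k <- sizes[sample.int(length(sizes), 1L,
                              prob = model$indel_size_dist)]
        E <- eligible()
        if (length(E) <= k + 1L) break
        done <- FALSE
        for (try in seq_len(100L)) {
          if (is_ins) {
            j <- sample.int(length(E), 1L)
            anchor <- E[j]
            reg <- st$region[anchor]
            if (st$ids[anchor] %in% blocked) next
            tandem <- runif(1L) < model$tandem_dup_fraction && j > k &&
              st$region[E[j - k]] == reg
            payload <- if (tandem) {
              st$rows[[v]][E[(j - k + 1L):j]]
            } else {
              same_reg <- E[st$region[E] == reg]
              st$rows[[v]][same_reg[sample.int(length(same_reg), k,
                                               replace = TRUE)]]
            }
            new_ids <- do_insertion(v, anchor, payload, reg, branch)
            blocked <- c(blocked, st$ids[anchor], new_ids)
            done <- TRUE
          } else {
            j <- sample.int(length(E) - k + 1L, 1L)
            idxs <- E[j:(j + k - 1L)]
            regs <- st$region[idxs]
            if (length(unique(regs)) != 1L) next
            if (any(st$ids[idxs] %in% blocked)) next
            do_deletion(v, idxs, regs[1L], branch)
            blocked <- c(blocked, st$ids[idxs])
            done <- TRUE
          }
          if (done) break
        }
      }

      ## SSR slippage
      if (model$ssr_slippage_rate > 0 && length(registry[[v]])) {
        for (li in seq_along(registry[[v]])) {
          loc <- registry[[v]][[li]]
          if (mirror_ir && loc$region == "IRa") next
          nsl <- rpois(1L, model$ssr_slippage_rate * blen)
          for (s in seq_len(nsl)) {
            pm <- sort(match(loc$ids, st$ids))
            present <- pm[st$rows[[v]][pm] != "-"]
            u_len <- loc$unit
            if (runif(1L) < 0.5) {
              if (length(present) < u_len) next
              payload <- strsplit(loc$motif, "", fixed = TRUE)[[1L]]
              new_ids <- do_insertion(v, present[length(present)], payload,
                                      loc$region, branch,
                                      kind = "ssr_expansion", ssr_locus = li)
              loc$ids <- c(loc$ids, new_ids)
            } else {
              if (length(present) < 2L * u_len) next
              idxs <- present[(length(present) - u_len + 1L):length(present)]
              do_deletion(v, idxs, loc$region, branch,
                          kind = "ssr_contraction", ssr_locus = li)
            }
          }
          registry[[v]][[li]] <- loc
        }
      }
    }
  })

  ## assemble outputs in final master coordinates
  final_ids <- st$ids
  Lf <- length(final_ids)
  tip_rows <- st$rows[seq_len(ntip)]
  names(tip_rows) <- tree$tip.label

  events <- finalize_event_log(st$log, final_ids)

  aln <- plastome_alignment(
    vapply(tip_rows, paste, character(1L), collapse = ""))

  genomes <- lapply(tree$tip.label, function(tx) {
    tip_genome_from_row(tx, tip_rows[[tx]], st$region, ancestor, final_ids)
  })
  names(genomes) <- tree$tip.label

  structure(
    list(genomes = genomes, alignment = aln, events = events,
         ancestor_row = paste(st$rows[[root]], collapse = ""),
         col_regions = st$region, tree = tree, model = model,
         mirror_ir = mirror_ir),
    class = "plastome_simulation")
}

finalize_event_log <- function(log, final_ids) {
  if (!length(log)) {
    return(data.frame(branch = character(), kind = character(),
                      start = integer(), end = integer(), length = integer(),
                      region = character(), payload = character(),
                      columns = character(), mirrored = logical(),
                      ssr_locus = integer(), stringsAsFactors = FALSE))
  }
  pos_of <- seq_along(final_ids)
  names(pos_of) <- final_ids
  rows <- lapply(log, function(ev) {
    cols <- sort(unname(pos_of[as.character(ev$ids)]))
    data.frame(branch = ev$branch, kind = ev$kind,
               start = cols[1L], end = cols[length(cols)],
               length = ev$length, region = ev$region,
               payload = ev$payload,
               columns = paste(cols, collapse = ","),
               mirrored = ev$mirrored, ssr_locus = ev$ssr_locus,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

tip_genome_from_row <- function(taxon, row, col_region, ancestor, final_ids) {
  nongap <- row != "-"
  seq <- paste(row[nongap], collapse = "")
  reg_labels <- col_region[nongap]
  counts <- vapply(REGION_ORDER, function(r) sum(reg_labels == r), integer(1L))
  ends <- cumsum(counts)
  starts <- c(0L, ends[-length(ends)])
  keep <- counts > 0L
  regions <- data.frame(region = REGION_ORDER[keep],
                        start = unname(starts[keep]),
                        end = unname(ends[keep]), stringsAsFactors = FALSE)
  genes <- NULL
  if (!is.null(ancestor$genes) && nrow(ancestor$genes) > 0L) {
    cum <- cumsum(nongap)
    anc_pos <- match(seq_len(nchar(ancestor$sequence)), final_ids)
    gs <- ancestor$genes
    tip_start <- integer(nrow(gs)); tip_end <- integer(nrow(gs))
    ok <- logical(nrow(gs))
    for (i in seq_len(nrow(gs))) {
      scol <- anc_pos[gs$start[i] + 1L]
      ecol <- anc_pos[gs$end[i]]
      s0 <- cum[scol] - as.integer(nongap[scol])  # bases strictly before scol
      e0 <- cum[ecol]
      if (e0 > s0) {
        tip_start[i] <- s0; tip_end[i] <- e0; ok[i] <- TRUE
      }
    }
    if (any(ok)) {
      genes <- data.frame(name = gs$name[ok], start = tip_start[ok],
                          end = tip_end[ok], strand = gs$strand[ok],
                          is_cds = gs$is_cds[ok], stringsAsFactors = FALSE)
    }
  }
  genome_record(taxon, seq, regions = regions, genes = genes)
}

#' @export
print.plastome_simulation <- function(x, ...) {
  cat("<plastome_simulation> ", length(x$genomes), " tips, master alignment ",
      x$alignment$ncol, " columns, ", nrow(x$events), " logged events\n",
      sep = "")
  invisible(x)
}

#' Replay a truth event log
#'
#' Reconstructs every tip sequence by applying the logged events along each
#' root-to-tip path to the ancestor row, in log order. Used to verify that
#' the event log is a complete and exact account of the simulation.
#'
#' @param sim a `plastome_simulation`.
#' @return named character vector of reconstructed aligned tip rows.
#' @export
replay_event_log <- function(sim) {
  tree <- sim$tree
  ntip <- length(tree$tip.label)
  node_name <- c(tree$tip.label, tree$node.label)
  anc <- seq_chars(sim$ancestor_row)
  ev_cols <- strsplit(sim$events$columns, ",", fixed = TRUE)
  out <- character(ntip)
  names(out) <- tree$tip.label
  for (t in seq_len(ntip)) {
    path <- ancestry_path(tree, t)  # node numbers root..tip
    branches <- node_name[path[-1L]]
    row <- anc
    sel <- which(sim$events$branch %in% branches)
    # log order equals application order along the path
    for (i in sel) {
      cols <- as.integer(ev_cols[[i]])
      kind <- sim$events$kind[i]
      if (kind %in% c("deletion", "ssr_contraction")) {
        row[cols] <- "-"
      } else {
        row[cols] <- strsplit(sim$events$payload[i], "", fixed = TRUE)[[1L]]
      }
    }
    out[t] <- paste(row, collapse = "")
  }
  out
}

ancestry_path <- function(tree, tip) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  path <- tip
  node <- tip
  root <- ntip + 1L
  while (node != root) {
    node <- parent[node]
    path <- c(node, path)
  }
  path
}

#' Write a simulated dataset to disk
#'
#' Emits unaligned FASTA, aligned truth FASTA, a BED-like region table, a
#' GFF3-subset feature table (when genes are annotated), the Newick tree and
#' the TSV event log. All files round-trip losslessly through the package's
#' readers.
#'
#' @param sim a `plastome_simulation`.
#' @param out_dir output directory (created if missing).
#' @param groups optional named character vector of group labels to write as
#'   `groups.tsv`.
#' @return invisibly, a named character vector of the written paths.
#' @export
emit_dataset <- function(sim, out_dir, groups = NULL) {
  stopifnot(inherits(sim, "plastome_simulation"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(
    genomes = file.path(out_dir, "genomes.fasta"),
    alignment = file.path(out_dir, "alignment.fasta"),
    regions = file.path(out_dir, "regions.tsv"),
    tree = file.path(out_dir, "tree.nwk"),
    events = file.path(out_dir, "events.tsv")
  )
  write_fasta(vapply(sim$genomes, `[[`, character(1L), "sequence"),
              paths[["genomes"]])
  write_alignment(sim$alignment, paths[["alignment"]])
  reg <- do.call(rbind, lapply(sim$genomes, function(g) {
    cbind(taxon = g$taxon_id, g$regions)
  }))
  write_regions(reg, paths[["regions"]])
  write_tree(sim$tree, paths[["tree"]])
  write_event_table(sim$events, paths[["events"]])
  feats <- do.call(rbind, lapply(sim$genomes, function(g) {
    if (is.null(g$genes) || nrow(g$genes) == 0L) return(NULL)
    cbind(taxon = g$taxon_id, g$genes)
  }))
  if (!is.null(feats) && nrow(feats) > 0L) {
    paths[["features"]] <- file.path(out_dir, "features.gff3")
    write_features(feats, paths[["features"]])
  }
  if (!is.null(groups)) {
    paths[["groups"]] <- file.path(out_dir, "groups.tsv")
    write_groups(groups, paths[["groups"]])
  }
  invisible(paths)
}
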