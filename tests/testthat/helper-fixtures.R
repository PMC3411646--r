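# Shared fixture builders for the cotton-like 4-group design.

cotton_taxa <- function() names(default_group_labels())

# toy alignment over the 14 cotton-like taxa: all-A background with one gap
# locus spanning `span` carried by `gapped`; other taxa keep sequence there.
toy_polar_alignment <- function(gapped, span = 4:6, len = 12L) {
  taxa <- cotton_taxa()
  seqs <- setNames(rep(strrep("A", len), length(taxa)), taxa)
  for (tx in gapped) {
    ch <- strsplit(seqs[[tx]], "", fixed = TRUE)[[1L]]
    ch[span] <- "-"
    seqs[tx] <- paste(ch, collapse = "")
  }
  plastome_alignment(seqs)
}

polarize_toy <- function(gapped, span = 4:6, tree = default_species_tree()) {
  aln <- toy_polar_alignment(gapped, span)
  loci <- multi_taxon_indel_loci(aln)
  polarize_indels(loci, default_group_labels(), tree = tree)
}

# small simulated dataset reused across tests
small_sim <- function(seed = 101L, sub_rate = 5e-4, indel_rate = 1e-4,
                      slippage = 0.02, n_genes = 0L, ssr_seed_loci = NULL,
                      tree = default_species_tree()) {
  spec <- ancestral_spec(lsc_len = 4000L, ssc_len = 1000L, ir_len = 800L,
                         n_genes = n_genes, ssr_seed_loci = ssr_seed_loci,
                         rng_seed = seed)
  anc <- build_ancestral_genome(spec)
  model <- evolution_model(sub_rate = sub_rate, indel_rate = indel_rate,
                           ssr_slippage_rate = slippage, rng_seed = seed + 1L)
  evolve_along_tree(anc, tree, model)
}

sim_regions <- function(sim) {
  out <- do.call(rbind, lapply(sim$genomes, function(g) {
    cbind(taxon = g$taxon_id, g$regions)
  }))
  rownames(out) <- NULL
  out
}
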