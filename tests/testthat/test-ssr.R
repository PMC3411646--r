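test_that("perfect SSR scanning respects thresholds and maximality", {
  hits <- find_ssrs("CCAAAAAAAAGG")  # 8 x A
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif, "A")
  expect_equal(hits$length, 8L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 10L)

  expect_equal(nrow(find_ssrs("CCAAAAAAAGG")), 0L)  # 7 x A below threshold

  di <- find_ssrs("GGATATATATGG")  # (AT)4 = 8 bp
  expect_equal(nrow(di), 1L)
  expect_equal(di$motif, "AT")
  expect_equal(di$unit, 2L)
  expect_equal(di$length, 8L)
})

test_that("runs report at the smallest generating unit, partial units drop", {
  # a 10-A run is one mononucleotide locus, never an "AA" dinucleotide one
  hits <- find_ssrs("GGAAAAAAAAAAGG")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit, 1L)
  expect_equal(hits$length, 10L)

  # 9-bp AT span: trailing partial unit excluded, length 8
  tr <- find_ssrs("CCATATATATAGG")
  expect_equal(tr$length, 8L)
  expect_equal(tr$motif, "AT")

  # trinucleotide at its threshold
  tri <- find_ssrs(paste0("GG", strrep("AAT", 3), "CC"))
  expect_equal(tri$unit, 3L)
  expect_equal(tri$length, 9L)
})

test_that("threshold set B loci are a subset of set A loci", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      seq <- paste(sample(c("A", "T", "G", "C"), 5000, replace = TRUE,
                          prob = c(0.33, 0.33, 0.17, 0.17)), collapse = "")
      a <- find_ssrs(seq, ssr_thresholds("A"))
      b <- find_ssrs(seq, ssr_thresholds("B"))
      key <- function(df) paste(df$start, df$end, df$motif, df$unit)
      expect_true(all(key(b) %in% key(a)))
      expect_lte(nrow(b), nrow(a))
    }
  })
})

test_that("reverse-complement scanning maps loci to mirrored coordinates", {
  withr::with_seed(19, {
    seq <- paste(sample(c("A", "T", "G", "C"), 4000, replace = TRUE,
                        prob = c(0.32, 0.32, 0.18, 0.18)), collapse = "")
    fwd <- find_ssrs(seq)
    ch <- strsplit(seq, "")[[1]]
    rc <- paste(rev(chartr("ACGT", "TGCA", ch)), collapse = "")
    rev_hits <- find_ssrs(rc)
    expect_equal(nrow(fwd), nrow(rev_hits))
    n <- nchar(seq)
    # same loci, mirrored; a trailing partial unit is truncated at the
    # opposite end on the reverse strand, so starts may shift by < unit
    fwd <- fwd[order(fwd$start), ]
    rev_hits <- rev_hits[order(n - rev_hits$end), ]
    expect_equal(fwd$unit, rev_hits$unit)
    expect_equal(fwd$length, rev_hits$length)
    expect_true(all(abs(fwd$start - (n - rev_hits$end)) < fwd$unit))
  })
})

test_that("canonical motifs are minimal rotations without strand collapse", {
  expect_equal(canonical_motif("TA"), "AT")
  expect_equal(canonical_motif("GAA"), "AAG")
  expect_equal(canonical_motif("A"), "A")
  expect_equal(canonical_motif("CT"), "CT")  # not collapsed to AG
  expect_equal(canonical_motif(c("ATG", "TGA", "GAT")),
               rep("ATG", 3))
})

test_that("homologous loci group by column overlap and motif", {
  aln <- plastome_alignment(c(
    t1 = "GGAAAAAAAAA-GG",   # A9 at columns 3-11
    t2 = "GGAAAAAAAAAAGG",   # A10 at columns 3-12
    t3 = "GG-AGAGAGAGAGG"))  # AG repeat overlapping the same columns
  ssrs <- rbind(find_ssrs(genome_record("t1", ungapped_sequence(aln, "t1"))),
                find_ssrs(genome_record("t2", ungapped_sequence(aln, "t2"))),
                find_ssrs(genome_record("t3", ungapped_sequence(aln, "t3"))))
  grp <- ssr_locus_homology(aln, ssrs)
  a_groups <- unique(grp$group[grp$motif == "A"])
  expect_equal(length(a_groups), 1L)
  expect_equal(sum(grp$group == a_groups), 2L)
  expect_false(any(grp$group[grp$motif == "AG"] %in% a_groups))
})

test_that("polymorphism statistics apply the absence-is-zero rule", {
  groups <- data.frame(
    taxon = c("t1", "t2", "t3", "t1", "t2"),
    motif = c("A", "A", "A", "AT", "AT"),
    unit = c(1L, 1L, 1L, 2L, 2L),
    length = c(8L, 8L, 8L, 8L, 10L),
    group = c(1L, 1L, 1L, 2L, 2L))
  st <- polymorphism_stats(groups, c("t1", "t2", "t3"))
  expect_true(st$conserved["1"])
  expect_false(st$conserved["2"])   # t3 lacks the AT locus entirely
  expect_equal(st$pairwise["t1", "t2"], 1L)  # 8 vs 10 at group 2
  expect_equal(st$pairwise["t1", "t3"], 1L)  # absence counts as 0
  expect_equal(unname(diag(st$pairwise)), rep(0L, 3))
  expect_true(isSymmetric(st$pairwise))
  expect_equal(st$by_class$conserved_rate[st$by_class$unit == 1], 1)
  expect_equal(st$by_class$conserved_rate[st$by_class$unit == 2], 0)
})

test_that("short indels attribute to polymorphic SSR groups only", {
  groups <- data.frame(
    taxon = c("t1", "t2"), motif = "A", unit = 1L,
    length = c(9L, 8L), group = 1L,
    col_start = c(10L, 10L), col_end = c(18L, 17L))
  ev <- data.frame(start = c(18L, 40L), end = c(18L, 41L),
                   length = c(1L, 2L), gapped_taxon = c("b", "a"),
                   bases = c("A", "GT"), region = NA)
  att <- attribute_short_indels(ev, groups, "t1", "t2")
  expect_equal(att$n_short, 2L)
  expect_equal(att$n_attributed, 1L)
  expect_equal(att$attributed_fraction, 0.5)
  none <- attribute_short_indels(ev[0, ], groups, "t1", "t2")
  expect_true(is.nan(none$attributed_fraction))
})

test_that("slippage-only homology groups match the planted loci", {
  two_tip <- ape::read.tree(text = "(t1:1,t2:1)anc;")
  sl <- data.frame(motif = c("A", "T", "AT"), units = c(14, 13, 7),
                   region = c("LSC", "LSC", "SSC"))
  # low AT content keeps the random background free of incidental SSRs,
  # so the planted loci are the only homology groups
  spec <- ancestral_spec(lsc_len = 6000, ssc_len = 2000, ir_len = 800,
                         at_content = c(LSC = 0.4, SSC = 0.4, IR = 0.4),
                         ssr_seed_loci = sl, rng_seed = 23)
  anc <- build_ancestral_genome(spec)
  model <- evolution_model(sub_rate = 0, indel_rate = 0,
                           ssr_slippage_rate = 0.8, rng_seed = 24)
  sim <- evolve_along_tree(anc, two_tip, model)
  ssrs <- do.call(rbind, lapply(sim$genomes, find_ssrs))
  grp <- ssr_locus_homology(sim$alignment, ssrs)
  # every planted locus is recovered as one group holding both taxa
  planted_groups <- 0L
  for (i in seq_len(nrow(anc$ssr_loci))) {
    motif <- canonical_motif(anc$ssr_loci$motif[i])
    cand <- grp[grp$motif == motif, ]
    ids <- unique(cand$group)
    planted_groups <- planted_groups + length(ids)
    for (id in ids) {
      expect_setequal(cand$taxon[cand$group == id], c("t1", "t2"))
    }
  }
  expect_equal(planted_groups, nrow(anc$ssr_loci))
})
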