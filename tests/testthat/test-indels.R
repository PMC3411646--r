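test_that("gap loci split wherever the gapped set changes", {
  aln <- plastome_alignment(c(t1 = "AAAAAAAAAA",
                              t2 = "AA-----AAA",
                              t3 = "AAAA---AAA"))
  loci <- multi_taxon_indel_loci(aln)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$start, c(3L, 5L))
  expect_equal(loci$end, c(4L, 7L))
  expect_equal(loci$gapped_taxa, c("t2", "t2,t3"))

  single <- plastome_alignment(c(t1 = "AAAAAAAAA",
                                 t2 = "AA-----AA",
                                 t3 = "AAAAAAAAA"))
  l2 <- multi_taxon_indel_loci(single)
  expect_equal(nrow(l2), 1L)
  expect_equal(l2$length, 5L)
  expect_equal(l2$gapped_taxa, "t2")
  expect_true(l2$boundary_exact)

  nogap <- plastome_alignment(c(a = "ACGT", b = "ACGT"))
  expect_equal(nrow(multi_taxon_indel_loci(nogap)), 0L)
})

test_that("staged polarization implements the four-group rules", {
  groups <- default_group_labels()
  A <- names(groups)[groups == "A_diploid"]
  D <- names(groups)[groups == "D_diploid"]
  AD <- names(groups)[groups == "allotetraploid"]

  check <- function(gapped, polarity, lineage, stage) {
    p <- polarize_toy(gapped)
    expect_equal(nrow(p), 1L)
    expect_equal(p$polarity, polarity)
    expect_equal(p$lineage, lineage)
    expect_equal(p$stage, stage)
  }

  # allotetraploid stage 1, both polarities
  check(AD, "deletion", "AD", 1L)
  check(c("OUT", A, D), "insertion", "AD", 1L)
  # D lineage stages
  check(D, "deletion", "D", 1L)
  check(c("OUT", A, AD), "insertion", "D", 1L)
  check("D5", "deletion", "terminal:D5", 2L)
  check(setdiff(names(groups), "D5"), "insertion", "terminal:D5", 2L)
  # A lineage stages
  check(c(A, AD), "deletion", "A", 1L)
  check(c("OUT", D), "insertion", "A", 1L)
  check(A, "deletion", "A", 2L)
  check(c("OUT", D, AD), "insertion", "A", 2L)
  check("A1", "deletion", "terminal:A1", 3L)
  # allotetraploid stage 2 requires a clade
  check(c("AD2", "AD2k", "AD2y", "AD5"), "deletion", "AD", 2L)
  check("AD4", "deletion", "terminal:AD4", 2L)
  p <- polarize_toy(c("AD1", "AD3"))  # not a clade of the fixed tree
  expect_equal(p$polarity, "unpolarized")
  expect_equal(p$reason, "homoplasy_candidate")
  # patterns matching no rule stay unpolarized
  p2 <- polarize_toy(c("A1", "AD1", "AD2", "AD3"))
  expect_equal(p2$polarity, "unpolarized")
  expect_equal(p2$reason, "no_rule")
})

test_that("ragged shared boundaries are left unpolarized", {
  taxa <- cotton_taxa()
  seqs <- setNames(rep(strrep("A", 12), length(taxa)), taxa)
  gap_at <- function(tx, span) {
    ch <- strsplit(seqs[[tx]], "")[[1]]
    ch[span] <- "-"
    seqs[tx] <<- paste(ch, collapse = "")
  }
  gap_at("D5", 4:6)
  gap_at("D6", 4:7)
  aln <- plastome_alignment(seqs)
  loci <- multi_taxon_indel_loci(aln)
  pol <- polarize_indels(loci, default_group_labels(),
                         tree = default_species_tree())
  shared <- pol[pol$start == 4, ]
  expect_equal(shared$polarity, "unpolarized")
  expect_equal(shared$reason, "ragged_boundary")
  # the D6-only overhang is part of D6's longer maximal run: also ragged
  over <- pol[pol$start == 7, ]
  expect_equal(over$polarity, "unpolarized")
  expect_equal(over$reason, "ragged_boundary")
  # an isolated single-taxon gap with exact boundaries does polarize
  exact <- polarize_toy("D6", span = 4:7)
  expect_equal(exact$polarity, "deletion")
  expect_equal(exact$lineage, "terminal:D6")
})

test_that("flipping the outgroup never preserves stage-1 polarity", {
  groups <- default_group_labels()
  A <- names(groups)[groups == "A_diploid"]
  D <- names(groups)[groups == "D_diploid"]
  AD <- names(groups)[groups == "allotetraploid"]
  flip_of <- function(gapped) {
    if ("OUT" %in% gapped) setdiff(gapped, "OUT") else c("OUT", gapped)
  }
  stage1 <- list(D, c("OUT", A, AD),        # D lineage
                 c(A, AD), c("OUT", D),     # A lineage
                 AD, c("OUT", A, D))        # allotetraploids
  for (gapped in stage1) {
    before <- polarize_toy(gapped)
    after <- polarize_toy(flip_of(gapped))
    expect_equal(before$stage, 1L)
    expect_false(after$polarity == before$polarity)
    if (before$lineage %in% c("A", "D")) {
      # A/D-lineage stage-1 events flip polarity exactly
      expect_setequal(c(before$polarity, after$polarity),
                      c("insertion", "deletion"))
    }
  }
})

test_that("polarized events map to the branch implied by their carriers", {
  tree <- default_species_tree()
  pol <- polarize_toy(names(default_group_labels())[
    default_group_labels() == "allotetraploid"])
  asn <- assign_events_to_branches(pol, tree)
  expect_equal(asn$events$branch, "ADcrown")
  expect_equal(asn$branch_counts$n_deletions[
    asn$branch_counts$branch == "ADcrown"], 1L)

  pol2 <- polarize_toy("D5")
  expect_equal(assign_events_to_branches(pol2, tree)$events$branch, "D5")

  pol3 <- polarize_toy(c("AD2", "AD2k", "AD2y", "AD5"))
  expect_equal(assign_events_to_branches(pol3, tree)$events$branch, "AD25")

  pol4 <- polarize_toy(c("OUT", "D5", "D6"))  # A stage 1 insertion
  expect_equal(assign_events_to_branches(pol4, tree)$events$branch, "AAD")
})

test_that("pairwise indel counts agree with counts derived from loci", {
  derive_pair_events_from_loci <- function(loci, aln, a, b) {
    state <- rep(".", aln$ncol)
    for (i in seq_len(nrow(loci))) {
      g <- strsplit(loci$gapped_taxa[i], ",")[[1]]
      s <- if (a %in% g && b %in% g) "bg"
      else if (a %in% g) "a" else if (b %in% g) "b" else "."
      if (s != ".") state[loci$start[i]:loci$end[i]] <- s
    }
    st <- state[state != "bg"]  # projection removes double-gap columns
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sum(r$values %in% c("a", "b") & starts > 1L & ends < length(st))
  }
  sim <- small_sim(seed = 91, indel_rate = 4e-4)
  loci <- multi_taxon_indel_loci(sim$alignment)
  for (pair in list(c("A1", "D5"), c("AD1", "OUT"), c("AD2", "AD3"))) {
    expected <- derive_pair_events_from_loci(loci, sim$alignment,
                                             pair[1], pair[2])
    got <- nrow(extract_indels(project_pairwise(sim$alignment,
                                                pair[1], pair[2])))
    expect_equal(got, expected)
  }
})

test_that("indel size spectrum summarizes lengths", {
  sp <- indel_size_spectrum(c(1, 1, 5, 5, 5, 2))
  expect_equal(unname(sp$frac_1_to_10["1"]), 1 / 3)
  expect_equal(names(which.max(sp$counts)), "5")
  expect_equal(sp$frac_le_10, 1)
  empty <- indel_size_spectrum(integer(0))
  expect_equal(length(empty$counts), 0L)
  long <- indel_size_spectrum(c(1, 20))
  expect_equal(long$frac_le_10, 0.5)
})

test_that("tandem duplication check compares the adjacent segment", {
  expect_true(tandem_dup_check("ATGCA", flank_up = "GGATGCA"))
  expect_true(tandem_dup_check("ATGCA", flank_down = "ATGCAGG"))
  expect_false(tandem_dup_check("ATGCA", flank_up = "TTTTT",
                                flank_down = "TTTTT"))
  expect_false(tandem_dup_check("ATGCA", flank_up = "GCA"))  # short flank
})

test_that("simulated tandem insertions all pass the duplication check", {
  two_tip <- ape::read.tree(text = "(t1:1,t2:1)anc;")
  spec <- ancestral_spec(lsc_len = 20000, ssc_len = 3000, ir_len = 1500,
                         rng_seed = 3)
  anc <- build_ancestral_genome(spec)
  model <- evolution_model(sub_rate = 0, indel_rate = 3e-4,
                           tandem_dup_fraction = 1, ins_del_bias = 1e9,
                           ssr_slippage_rate = 0, rng_seed = 4)
  sim <- evolve_along_tree(anc, two_tip, model)
  ins <- sim$events[sim$events$kind == "insertion" & !sim$events$mirrored, ]
  expect_gt(nrow(ins), 10)
  m <- aln_matrix(sim$alignment)
  ok <- vapply(seq_len(nrow(ins)), function(i) {
    tx <- ins$branch[i]
    row <- m[tx, ]
    cols <- as.integer(strsplit(ins$columns[i], ",")[[1]])
    up_cols <- setdiff(which(row != "-" & seq_along(row) < min(cols)),
                       integer(0))
    flank_up <- paste(row[tail(up_cols, ins$length[i])], collapse = "")
    tandem_dup_check(ins$payload[i], flank_up = flank_up)
  }, logical(1))
  expect_true(all(ok))
})

test_that("indel ratio normalizes per lineage per million years", {
  expect_equal(indel_ratio(100, 0.5, 2)$ratio, 100)
  expect_equal(indel_ratio(0, 3, 2)$ratio, 0)
  r1 <- indel_ratio(50, 1)$ratio
  r2 <- indel_ratio(50, 2)$ratio
  r3 <- indel_ratio(50, 4)$ratio
  expect_true(r1 > r2 && r2 > r3)
  expect_error(indel_ratio(10, 0))
})
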