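test_that("substitution counting classifies bases and excludes N", {
  aln <- plastome_alignment(c(a = "ACGT", b = "ACGA"))
  v <- project_pairwise(aln, "a", "b")
  res <- count_substitutions(v)
  expect_equal(res$summary$n, 1L)
  expect_equal(res$events$pair_type, "A/T")
  expect_equal(res$events$class, "transversion")

  ident <- project_pairwise(plastome_alignment(c(a = "ACGT", b = "ACGT")),
                            "a", "b")
  res0 <- count_substitutions(ident)
  expect_equal(res0$summary$n, 0L)
  expect_true(is.nan(res0$summary$si_sv))

  withN <- project_pairwise(plastome_alignment(c(a = "ANGT", b = "ACGT")),
                            "a", "b")
  expect_equal(count_substitutions(withN)$summary$n, 0L)

  ti <- project_pairwise(plastome_alignment(c(a = "AC", b = "GT")), "a", "b")
  res2 <- count_substitutions(ti)
  expect_equal(res2$summary$si, 2L)  # A<->G and C<->T are transitions
  expect_equal(res2$summary$sv, 0L)
})

test_that("transition + transversion counts and pair types are conserved", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      aln <- random_alignment(2, 60, alphabet = c("A", "C", "G", "T"))
      v <- project_pairwise(aln, "t1", "t2")
      s <- count_substitutions(v)$summary
      expect_equal(s$si + s$sv, s$n)
      expect_equal(sum(unlist(s[, 5:10])), s$n)
    }
  })
})

test_that("indel extraction finds maximal single-taxon gap runs", {
  v <- project_pairwise(plastome_alignment(c(a = "ACGTA", b = "AC--A")),
                        "a", "b")
  ev <- extract_indels(v)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 3L)
  expect_equal(ev$end, 4L)
  expect_equal(ev$length, 2L)
  expect_equal(ev$gapped_taxon, "b")
  expect_equal(ev$bases, "GT")

  v2 <- project_pairwise(plastome_alignment(c(a = "A--C", b = "AGGC")),
                         "a", "b")
  ev2 <- extract_indels(v2)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$length, 2L)
  expect_equal(ev2$gapped_taxon, "a")

  # terminal gap runs are linearization artifacts, not events
  v3 <- project_pairwise(plastome_alignment(c(a = "--ACG-", b = "TTACGT")),
                         "a", "b")
  expect_equal(nrow(extract_indels(v3)), 0L)
})

test_that("substitution and indel counts are symmetric in the pair", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      aln <- random_alignment(2, 50)
      vab <- project_pairwise(aln, "t1", "t2")
      vba <- project_pairwise(aln, "t2", "t1")
      expect_equal(count_substitutions(vab)$summary$n,
                   count_substitutions(vba)$summary$n)
      expect_equal(nrow(extract_indels(vab)), nrow(extract_indels(vba)))
    }
  })
})

test_that("divergence percentages follow the printed-count convention", {
  expect_equal(divergence_percent(852, 161600), 100 * 852 / 161600)
  expect_lt(abs(divergence_percent(852, 161600) - 0.527), 5e-4)
  expect_lt(abs(divergence_percent(1863, 161600) - 1.153), 5e-4)
  expect_equal(divergence_percent(0, 12345), 0)
  expect_error(divergence_percent(1, 0))
})

test_that("per-region rates pool the two IR copies", {
  # constructed pair: LSC 0-999, IRb 1000-1199, SSC 1200-1499, IRa 1500-1699
  base <- strrep("A", 1700)
  ch <- strsplit(base, "")[[1]]
  ch[c(10, 20, 30, 40)] <- "C"       # 4 subs in LSC
  ch[c(1250, 1260)] <- "G"           # 2 subs in SSC
  ch[1100] <- "T"                    # 1 sub in IRb
  ch[1650] <- "T"                    # 1 sub in IRa (mirror-style)
  b <- paste(ch, collapse = "")
  aln <- plastome_alignment(c(x = base, y = b))
  regions <- data.frame(taxon = c("x", "x", "x", "x"),
                        region = c("LSC", "IRb", "SSC", "IRa"),
                        start = c(0, 1000, 1200, 1500),
                        end = c(1000, 1200, 1500, 1700))
  st <- per_region_stats(aln, regions, "x", "y")
  expect_equal(st$n_substitutions[st$region == "LSC"], 4)
  expect_equal(st$n_substitutions[st$region == "SSC"], 2)
  expect_equal(st$n_substitutions[st$region == "IR"], 1)  # (1 + 1) / 2
  expect_equal(st$length_bp[st$region == "IR"], 200)
  expect_equal(st$sub_rate_per_kb[st$region == "SSC"], 2 / 0.3)
  expect_equal(st$indel_rate_per_kb, rep(0, 3))
})

test_that("pairwise matrix equals per-pair computation and is order-stable", {
  sim <- small_sim(seed = 71, indel_rate = 3e-4)
  taxa <- c("A1", "D5", "AD1")
  m <- pairwise_matrix(sim$alignment, taxa)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      v <- project_pairwise(sim$alignment, taxa[i], taxa[j])
      expect_equal(m[i, j], nrow(extract_indels(v)))
      expect_equal(m[j, i], count_substitutions(v)$summary$n)
    }
  }
  expect_true(all(is.na(diag(m))))
  perm <- c("AD1", "A1", "D5")
  m2 <- pairwise_matrix(sim$alignment, perm)
  for (a in taxa) {
    for (b in setdiff(taxa, a)) {
      # same cell content under permutation: upper/lower depends on order,
      # so compare the pair's {indels, subs} multiset
      expect_setequal(c(m[a, b], m[b, a]), c(m2[a, b], m2[b, a]))
    }
  }
  ident <- plastome_alignment(c(p = "ACGTACGT", q = "ACGTACGT"))
  mi <- pairwise_matrix(ident)
  expect_equal(mi["p", "q"], 0L)
  expect_equal(mi["q", "p"], 0L)
})

test_that("sliding AT/divergence profile handles degenerate alignments", {
  allA <- plastome_alignment(c(a = strrep("A", 200), b = strrep("A", 200)))
  prof <- sliding_at_vs_divergence(allA, at_window = 100, div_step = 10)
  expect_true(all(prof$at_content == 1))
  expect_true(all(prof$divergence == 0))

  opp <- plastome_alignment(c(a = strrep("A", 200), b = strrep("T", 200)))
  prof2 <- sliding_at_vs_divergence(opp, at_window = 100, div_step = 10)
  expect_true(all(prof2$divergence == 1))
  expect_true(all(prof2$at_content == 1))

  expect_error(sliding_at_vs_divergence(allA, at_window = 500), "larger")
})

test_that("divergence profile correlates with substitution density", {
  # two halves with very different substitution rates
  withr::with_seed(5, {
    n <- 2000
    a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    b <- a
    hot <- 1:1000
    cold <- 1001:2000
    flip <- c(sample(hot, 150), sample(cold, 5))
    b[flip] <- vapply(b[flip], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    aln <- plastome_alignment(c(a = paste(a, collapse = ""),
                                b = paste(b, collapse = "")))
    prof <- sliding_at_vs_divergence(aln, 100, 50)
    mid <- (prof$start + prof$end) / 2
    expect_gt(mean(prof$divergence[mid < 1000]),
              mean(prof$divergence[mid > 1000]))
  })
})

test_that("pairwise divergence summary satisfies its own identities", {
  sim <- small_sim(seed = 81, indel_rate = 3e-4)
  pd <- pairwise_divergence(sim$alignment, "A1", "D6", sim_regions(sim))
  expect_equal(pd$subst_divergence_pct,
               100 * pd$n_substitutions / sim$alignment$ncol)
  expect_equal(pd$indel_divergence_pct,
               100 * pd$total_indel_length / sim$alignment$ncol)
  if (pd$total_indel_events > 0) {
    expect_equal(pd$s_i, pd$n_substitutions / pd$total_indel_events)
  }
})
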