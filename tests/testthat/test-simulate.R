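test_that("simulated genomes tile fragments exactly and are reproducible", {
  g <- simulate_genome(seed = 101)
  expect_equal(nrow(g$chrom_sizes), 2)
  # ~10,000 fragments expected for 2 x 20 Mb at 4-kb mean, within 10%
  expect_lt(abs(nrow(g$fragments) - 1e4) / 1e4, 0.1)
  for (ch in g$chrom_sizes$chrom) {
    f <- g$fragments[g$fragments$chrom == ch, ]
    expect_equal(f$start[1], 0)
    expect_equal(utils::tail(f$end, 1),
                 g$chrom_sizes$length[g$chrom_sizes$chrom == ch])
    expect_true(all(f$start[-1] == f$end[-nrow(f)]))  # adjacent, no gaps
  }
  g2 <- simulate_genome(seed = 101)
  expect_identical(g, g2)
  g3 <- simulate_genome(seed = 102)
  expect_false(identical(g$fragments$end[1], g3$fragments$end[1]))
  expect_error(simulate_genome(n_genes = 1e6, seed = 1), "cannot place")
})

test_that("planted architecture respects genome bounds and invariants", {
  g <- simulate_genome(seed = 103)
  tr <- simulate_architecture_truth(g, seed = 104)
  expect_true(all(tr$boundaries$pos > 0))
  expect_true(all(tr$boundaries$pos < 2e7))
  # boundaries strictly increasing per chromosome
  for (ch in unique(tr$boundaries$chrom)) {
    expect_true(all(diff(tr$boundaries$pos[tr$boundaries$chrom == ch]) > 0))
  }
  # compartment blocks tile each chromosome
  for (ch in g$chrom_sizes$chrom) {
    cc <- tr$compartments[tr$compartments$chrom == ch, ]
    expect_equal(cc$start[1], 0)
    expect_equal(utils::tail(cc$end, 1), 2e7)
    expect_true(all(cc$start[-1] == cc$end[-nrow(cc)]))
  }
  expect_true(all(tr$loops$bin2 > tr$loops$bin1))
  expect_true(all(tr$loops$enrichment == 5))
})

test_that("contact totals scale with depth and pairs mode conserves counts", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 5e6, n_genes = 50,
                       seed = 105)
  s1 <- simulate_contacts(g, NULL, depth = 100, replicates = 1,
                          conditions = "A", seed = 106)
  s2 <- simulate_contacts(g, NULL, depth = 200, replicates = 1,
                          conditions = "A", seed = 106)
  t1 <- matrix_total(s1$libraries$A[[1]])
  t2 <- matrix_total(s2$libraries$A[[1]])
  expect_lt(abs(t2 / t1 - 2), 0.02)
  # pairs mode: building the matrix recovers exactly n_pairs counts
  sp <- simulate_contacts(g, NULL, depth = 50, replicates = 1,
                          conditions = "A", output = "pairs",
                          n_pairs = 5000, seed = 107)
  cm <- build_matrix(sp$libraries$A[[1]], sp$binned_genome)
  expect_equal(matrix_total(cm), 5000)
  # determinism
  sp2 <- simulate_contacts(g, NULL, depth = 50, replicates = 1,
                           conditions = "A", output = "pairs",
                           n_pairs = 5000, seed = 107)
  expect_identical(sp$libraries$A[[1]], sp2$libraries$A[[1]])
})

test_that("capture truth is internally consistent", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 1e7, n_genes = 300,
                       seed = 108)
  cap <- simulate_capture(g, n_baits = 200, n_interactions = 600, seed = 109)
  tr <- cap$truth
  # spans honour the configured range up to fragment-snapping slack
  expect_true(all(tr$span >= 5e4 - 3e4 & tr$span <= 3.5e5 + 3e4))
  expect_false(any(duplicated(tr$other_id)))
  cc <- grep("^count_", names(cap$counts), value = TRUE)
  expect_equal(length(cc), 4)
  # preformed/static interactions are count-stable: |log2FC| < 0.5 for >=90%
  stab <- tr$class %in% c("preformed_activated_A", "preformed_activated_B",
                          "static")
  cnt <- cap$counts[match(paste(tr$bait_id, tr$other_id),
                          paste(cap$counts$bait_id, cap$counts$other_id)), ]
  lfc <- log2((cnt$count_A_1 + cnt$count_A_2 + 0.5) /
                (cnt$count_B_1 + cnt$count_B_2 + 0.5))
  expect_gte(mean(abs(lfc[stab]) < 0.5), 0.9)
  # rewired interactions actually change
  expect_gte(mean(abs(lfc[!stab]) > 1), 0.95)
  # planted peaks direction matches the class at the distal end
  pre_a <- tr$other_id[tr$class == "preformed_activated_A"]
  frag <- cap$fragments
  oe <- frag[match(pre_a, frag$fragment_id), ]
  hits <- overlap_query(oe[, c("chrom", "start", "end")],
                        cap$peaks[, c("chrom", "start", "end")])
  # every preformed_activated_A distal end carries at least one up_A peak
  up_a_by_end <- tapply(cap$peak_truth$planted_dir[hits$b_index] == "up_A",
                        hits$a_index, any)
  expect_equal(sum(up_a_by_end), length(pre_a))
  expect_true(all(up_a_by_end))
})

test_that("peak/expression/cage simulation plants what it claims", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 1e8, n_genes = 500,
                       min_gene_spacing_bp = 50000, seed = 110)
  classes <- tibble::tibble(gene_id = g$genes$gene_id[1:100],
                            class = rep(c("rewired_gained_A",
                                          "preformed_activated_B"), 50))
  px <- simulate_peaks_expression_cage(g, loop_classes = classes, seed = 111)
  # co-binding fraction 0.5 within binomial tolerance at 2000 peaks
  ov <- mean(overlaps_any(px$tf_b, px$tf_a))
  expect_lt(abs(ov - 0.5), 0.03)
  # enhancers do not overlap each other
  expect_equal(nrow(overlap_query(px$enhancers, px$enhancers)),
               nrow(px$enhancers))
  # planted DE tied to classes
  expect_equal(px$de_truth$de_status[1], "up_A")
  expect_equal(px$de_truth$de_status[2], "up_B")
  de <- nb_count_test(px$expression_counts, rep(c("A", "B"), each = 5),
                      type = "gene")
  planted_up_a <- px$de_truth$gene_id[px$de_truth$de_status == "up_A"]
  expect_gte(mean(de$direction[match(planted_up_a, de$unit_id)] == "up_A"),
             0.9)
  # the cage EE column is exactly the calorimetric equation
  expect_identical(px$cage$ee,
                   energy_expenditure(px$cage$vo2, px$cage$vco2))
  # TPM is a proper normalisation
  expect_equal(sum(px$expression$tpm_A * 0 + px$expression$tpm_A), 1e6,
               tolerance = 1e-6)
})
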