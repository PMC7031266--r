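mk_diff <- function(ids, p = 1, lfc = 0, dir = "ns") {
  tibble::tibble(unit_id = ids, log2fc = lfc, p = p, fdr = p, direction = dir)
}

mk_frag <- function() {
  tibble::tibble(chrom = "chr1",
                 start = c(0, 1e4, 2e4, 3e4),
                 end = c(1e4, 2e4, 3e4, 4e4),
                 fragment_id = c("b1", "d1", "d2", "d3"))
}

test_that("classification follows the rewired / preformed / static rules", {
  frag <- mk_frag()
  ints <- tibble::tibble(bait_id = "b1", other_id = c("d1", "d2", "d3"))
  idiff <- mk_diff(paste("b1", c("d1", "d2", "d3")),
                   p = c(1e-4, 0.5, 0.5), lfc = c(1, 0.1, 0))
  peaks <- tibble::tibble(peak_id = c("p1", "p2"), chrom = "chr1",
                          start = c(12000, 35000), end = c(13000, 36000))
  pdiff <- mk_diff(c("p1", "p2"), p = c(1e-5, 0.9), lfc = c(2, 0),
                   dir = c("up_A", "ns"))
  bg <- tibble::tibble(bait_id = "b1", gene_id = "gene1")
  cl <- classify_loop_dynamics(ints, idiff, peaks, pdiff, frag, bg)
  # d1: rewired wins even though an up_A peak overlaps it
  expect_equal(cl$class, c("rewired_gained_A", "static", "static"))
  expect_equal(unique(cl$linked_genes), "gene1")

  # making d1 stable turns it preformed via the up_A distal peak
  idiff2 <- mk_diff(paste("b1", c("d1", "d2", "d3")), p = c(0.4, 0.5, 0.5))
  cl2 <- classify_loop_dynamics(ints, idiff2, peaks, pdiff, frag, bg)
  expect_equal(cl2$class, c("preformed_activated_A", "static", "static"))

  # down-direction rewiring labels the B condition
  idiff3 <- mk_diff(paste("b1", c("d1", "d2", "d3")),
                    p = c(1e-5, 0.5, 0.5), lfc = c(-2, 0, 0))
  cl3 <- classify_loop_dynamics(ints, idiff3, peaks, pdiff, frag, bg)
  expect_equal(cl3$class[1], "rewired_gained_B")

  # every interaction gets exactly one class; counts partition the input
  expect_equal(sum(table(cl$class)), nrow(ints))
  expect_error(
    classify_loop_dynamics(ints, idiff[-1, ], peaks, pdiff, frag, bg),
    "without a differential record")
})

test_that("gene linkage deduplicates within class and skips unlinked loops", {
  frag <- mk_frag()
  ints <- tibble::tibble(bait_id = c("b1", "b1", "b1"),
                         other_id = c("d1", "d2", "d3"))
  idiff <- mk_diff(paste("b1", c("d1", "d2", "d3")),
                   p = c(1e-5, 1e-5, 0.5), lfc = c(1, 2, 0))
  peaks <- tibble::tibble(peak_id = "p0", chrom = "chr1",
                          start = 0, end = 1)
  pdiff <- mk_diff("p0")
  bg <- tibble::tibble(bait_id = "b1", gene_id = "gene1")
  cl <- classify_loop_dynamics(ints, idiff, peaks, pdiff, frag, bg)
  tab <- link_dynamics_to_genes(cl)
  # two rewired_gained_A loops collapse to one gene row with n_loops = 2
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_loops, 2L)
  expect_equal(tab$class, "rewired_gained_A")
  degs <- mk_diff("gene1", p = 1e-4, lfc = 1, dir = "up_A")
  tab2 <- link_dynamics_to_genes(cl, degs)
  expect_equal(tab2$de_status, "up_A")
})

test_that("classification recovers planted labels on simulated capture data", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 1e7, n_genes = 400,
                       seed = 61)
  cap <- simulate_capture(g, n_baits = 300, n_interactions = 800, seed = 62)
  kp <- paste(cap$truth$bait_id, cap$truth$other_id)
  cnt <- cap$counts[match(kp, paste(cap$counts$bait_id, cap$counts$other_id)), ]
  cc <- grep("^count_", names(cnt), value = TRUE)
  idiff <- nb_count_test(
    dplyr::bind_cols(tibble::tibble(unit_id = kp), cnt[, cc]),
    c("A", "A", "B", "B"), type = "interaction")
  pdiff <- nb_count_test(cap$peak_counts, rep(c("A", "B"), each = 3),
                         type = "peak")
  cl <- classify_loop_dynamics(
    cap$truth[, c("bait_id", "other_id")], idiff, cap$peaks, pdiff,
    cap$fragments, cap$bait_genes)
  acc <- vapply(unique(cap$truth$class), function(x) {
    mean(cl$class[cap$truth$class == x] == x)
  }, 0)
  expect_true(all(acc >= 0.9))
  expect_equal(sum(table(cl$class)), nrow(cap$truth))
})
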