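mk_universe <- function(n = 200, width = 1000, pitch = 5000) {
  tibble::tibble(chrom = "chr1",
                 start = (seq_len(n) - 1) * pitch,
                 end = (seq_len(n) - 1) * pitch + width)
}

test_that("shuffled placements preserve count, lengths and the universe", {
  uni <- mk_universe()
  set.seed(91)
  lens <- sample(c(100, 200, 400), 50, replace = TRUE)
  layout <- loopdyn:::shuffle_layout(loopdyn:::merge_intervals(uni), lens)
  for (k in 1:20) {
    placed <- loopdyn:::place_size_matched(layout)
    expect_equal(nrow(placed), 50)
    expect_equal(sort(placed$end - placed$start), sort(lens))
    # no self-overlap
    o <- order(placed$start)
    expect_true(all(placed$start[o][-1] >= placed$end[o][-50]))
    # all inside the (globalised) universe
    ug <- layout$uni_global
    k_int <- findInterval(placed$start, ug$start)
    expect_true(all(k_int >= 1 & placed$end <= ug$end[k_int]))
  }
})

test_that("total containment in a sparse reference gives the minimal p", {
  uni <- mk_universe(500)
  ref <- uni[1:5, ]                      # reference covers 1% of the universe
  query <- tibble::tibble(chrom = "chr1", start = ref$start + 100,
                          end = ref$start + 300)
  st <- shuffle_overlap_test(query, ref, uni, n_iter = 999, seed = 7)
  expect_equal(st$observed, 5)
  expect_equal(st$p_value, 1 / 1000)
})

test_that("unrelated queries are not called significant", {
  uni <- mk_universe(400)
  ref <- uni[seq(1, 400, by = 4), ]
  set.seed(92)
  p <- replicate(30, {
    pick <- sample(400, 40)
    query <- tibble::tibble(chrom = "chr1", start = uni$start[pick] + 200,
                            end = uni$start[pick] + 500)
    shuffle_overlap_test(query, ref, uni, n_iter = 199,
                         seed = sample.int(1e6, 1))$p_value
  })
  expect_gte(mean(p > 0.05), 0.9)
  expect_true(all(p >= 1 / 200 & p <= 1))
})

test_that("null empirical p-values are approximately uniform", {
  # enough queries that the overlap count is granular, so the empirical p
  # is not dominated by ties
  uni <- mk_universe(1000)
  ref <- uni[seq(1, 1000, by = 3), ]
  set.seed(93)
  p <- replicate(200, {
    pick <- sample(1000, 150)
    query <- tibble::tibble(chrom = "chr1", start = uni$start[pick] + 100,
                            end = uni$start[pick] + 400)
    shuffle_overlap_test(query, ref, uni, n_iter = 199,
                         seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("universe preconditions are enforced", {
  uni <- mk_universe(4)
  q <- tibble::tibble(chrom = "chr1", start = 0, end = 2800)
  expect_error(shuffle_overlap_test(q, uni, uni, n_iter = 10, seed = 1),
               "universe too small")
  q2 <- tibble::tibble(chrom = "chr1", start = 0, end = 1500)
  expect_error(shuffle_overlap_test(q2, uni, uni, n_iter = 10, seed = 1),
               "long enough")
})

test_that("matched-control annotation overlap finds planted enrichment", {
  uni <- mk_universe(1000)
  ann <- uni[1:250, ]                     # annotation = first quarter
  set.seed(94)
  inside <- sample(250, 120)
  outside <- sample(251:1000, 80)
  query <- tibble::tibble(chrom = "chr1",
                          start = uni$start[c(inside, outside)] + 100,
                          end = uni$start[c(inside, outside)] + 600)
  res <- matched_control_annotation_overlap(
    query, list(planted = ann, everything = uni), uni, n_controls = 60,
    seed = 11)
  everything <- res[res$annotation == "everything", ]
  expect_equal(everything$query_pct, 100)
  expect_equal(everything$control_mean_pct, 100)
  planted <- res[res$annotation == "planted", ]
  expect_equal(planted$query_pct, 60)     # 120 of 200 seeded inside
  expect_gt(planted$query_pct,
            planted$control_mean_pct + 3 * planted$control_sd_pct)
  # control percentages are stable across seeds
  res2 <- matched_control_annotation_overlap(
    query, list(planted = ann), uni, n_controls = 60, seed = 12)
  expect_lt(abs(res2$control_mean_pct - planted$control_mean_pct),
            2 * planted$control_sd_pct)
})
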