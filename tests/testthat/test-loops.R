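loops_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- simulate_genome(n_chrom = 1, chrom_length = 8e6, n_genes = 80,
                           seed = 31)
      tr <- simulate_architecture_truth(g, n_loops_per_chrom = 20, seed = 32)
      sim <- simulate_contacts(g, tr, depth = 1300, seed = 33,
                               features = c("compartments", "loops"))
      bal <- filter_and_balance(merge_replicates(sim$libraries$A))
      cache <<- list(tr = tr, bal = bal, z = loop_zscores(bal))
    }
    cache
  }
})

test_that("z-scores are standardised within distance strata", {
  fx <- loops_fixture()
  z <- fx$z
  ok <- !is.na(z$z)
  by_d <- split(z$z[ok], z$distance_bins[ok])
  mus <- vapply(by_d, mean, 0)
  sds <- vapply(by_d, stats::sd, 0)
  expect_lt(max(abs(mus)), 1e-6)
  expect_lt(max(abs(sds - 1)), 1e-6)
})

test_that("distance-determined matrices give z = 0 and sparse strata give NA", {
  bg <- binned_genome(c(chrG = 50 * 1e4), 1e4)
  n <- 50
  i <- rep.int(seq_len(n), n:1)
  j <- sequence(n:1) - 1L + i
  px <- tibble::tibble(chrom1 = "chrG", bin1 = i - 1L, chrom2 = "chrG",
                       bin2 = j - 1L, count = 200 / pmax(j - i, 1))
  cm <- loopdyn:::new_contact_matrix(px, bg)
  z <- loop_zscores(cm)
  defined <- !is.na(z$z)
  expect_true(all(abs(z$z[defined]) < 1e-12))
  # strata with < 10 pixels (d > 40) are NA
  expect_true(all(is.na(z$z[z$distance_bins > n - 10])))
})

test_that("a pixel 10 sd above its stratum mean scores z = 10", {
  bg <- binned_genome(c(chrH = 40 * 1e4), 1e4)
  n <- 40
  i <- rep.int(seq_len(n), n:1)
  j <- sequence(n:1) - 1L + i
  set.seed(34)
  cnt <- rep(10, length(i))
  d <- j - i
  # alternate counts at stratum 5 to give it spread, then spike one pixel
  sel <- which(d == 5)
  cnt[sel] <- rep(c(8, 12), length.out = length(sel))
  mu <- mean(cnt[sel]); sdv <- stats::sd(cnt[sel])
  spike <- sel[1]
  cnt[spike] <- mu + 10 * sdv
  # recompute the stratum statistics with the spike included
  mu2 <- mean(cnt[sel]); sd2 <- stats::sd(cnt[sel])
  px <- tibble::tibble(chrom1 = "chrH", bin1 = i - 1L, chrom2 = "chrH",
                       bin2 = j - 1L, count = cnt)
  z <- loop_zscores(loopdyn:::new_contact_matrix(px, bg))
  got <- z$z[z$bin1 == i[spike] - 1L & z$bin2 == j[spike] - 1L]
  expect_equal(got, (cnt[spike] - mu2) / sd2, tolerance = 1e-10)
})

test_that("loop calling thresholds, merges and respects the span filter", {
  fx <- loops_fixture()
  lc <- call_loops(fx$z)
  tl <- fx$tr$loops
  stopifnot(nrow(lc) > 0)
  tp <- vapply(seq_len(nrow(lc)), function(k) {
    any(abs(tl$bin1 - lc$bin1[k]) <= 1 & abs(tl$bin2 - lc$bin2[k]) <= 1)
  }, logical(1))
  rec <- vapply(seq_len(nrow(tl)), function(k) {
    any(abs(lc$bin1 - tl$bin1[k]) <= 1 & abs(lc$bin2 - tl$bin2[k]) <= 1)
  }, logical(1))
  expect_gte(mean(tp), 0.9)
  expect_gte(mean(rec), 0.8)
  expect_true(all(lc$zscore >= 6))
  expect_true(all(lc$span <= 1e6))
  # nothing above threshold -> empty call set
  expect_equal(nrow(call_loops(fx$z, z_min = Inf)), 0)
  # a 2-Mb span never passes the span filter even with huge z
  z2 <- fx$z
  far <- which(z2$distance_bins == 200)[1]
  z2$z[far] <- 50
  lc2 <- call_loops(z2)
  expect_false(any(lc2$bin2 - lc2$bin1 == 200))
})

test_that("APA is exactly 1 on uniform matrices and scale-invariant", {
  bg <- binned_genome(c(chrU = 120 * 1e4), 1e4)
  n <- 120
  i <- rep.int(seq_len(n), n:1)
  j <- sequence(n:1) - 1L + i
  px <- tibble::tibble(chrom1 = "chrU", bin1 = i - 1L, chrom2 = "chrU",
                       bin2 = j - 1L, count = 4)
  cm <- loopdyn:::new_contact_matrix(px, bg)
  loops <- tibble::tibble(chrom = "chrU", bin1 = c(30L, 40L), bin2 = c(70L, 90L))
  res <- apa(cm, loops)
  expect_identical(res$center_score, 1)
  expect_equal(res$n_loops_used, 2L)
  cm2 <- cm; cm2$pixels$count <- cm2$pixels$count * 17
  expect_equal(apa(cm2, loops)$center_score, res$center_score)
  # a 200-kb loop is within 300 kb of the diagonal and contributes nothing
  res2 <- apa(cm, dplyr::bind_rows(loops, tibble::tibble(
    chrom = "chrU", bin1 = 50L, bin2 = 70L)))
  expect_equal(res2$n_loops_used, 2L)
  expect_error(apa(cm, tibble::tibble(chrom = "chrU", bin1 = 10L, bin2 = 20L)),
               "no loops usable")
})

test_that("APA recovers planted enrichment within 15%", {
  fx <- loops_fixture()
  res <- apa(fx$bal, fx$tr$loops)
  expect_lt(abs(res$center_score - 5) / 5, 0.15)
  expect_gt(res$n_loops_used, 10)
})
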