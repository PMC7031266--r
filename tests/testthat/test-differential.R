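test_that("identical conditions give large p and no calls", {
  cnt <- tibble::tibble(unit_id = paste0("u", 1:50),
                        a1 = rep(40, 50), a2 = rep(60, 50),
                        b1 = rep(40, 50), b2 = rep(60, 50))
  dr <- nb_count_test(cnt, c("A", "A", "B", "B"), type = "interaction")
  expect_true(all(dr$p > 0.5))
  expect_true(all(dr$direction == "ns"))
  expect_true(all(dr$fdr >= dr$p))
})

test_that("degenerate and invalid inputs are handled", {
  cnt <- tibble::tibble(unit_id = c("z", "ok"), a1 = c(0, 10), a2 = c(0, 12),
                        b1 = c(0, 9), b2 = c(0, 11))
  dr <- nb_count_test(cnt, c("A", "A", "B", "B"))
  expect_equal(dr$p[dr$unit_id == "z"], 1)
  expect_equal(dr$direction[dr$unit_id == "z"], "ns")
  bad <- cnt; bad$a1 <- bad$a1 + 0.5
  expect_error(nb_count_test(bad, c("A", "A", "B", "B")), "non-negative integers")
  expect_error(nb_count_test(cnt, c("A", "B", "C", "C")), "exactly two")
})

# planted units embedded in a null background, so library-size
# normalization (which absorbs any global shift) is exercised realistically
planted_counts <- function(n_de, fc, n_null = 4000, base = 100, phi = 0.05) {
  n <- n_de + n_null
  mu_a <- c(rep(base * sqrt(fc), n_de), rep(base, n_null))
  mu_b <- c(rep(base / sqrt(fc), n_de), rep(base, n_null))
  tibble::tibble(
    unit_id = paste0("u", seq_len(n)),
    a1 = rnbinom(n, mu = mu_a, size = 1 / phi),
    a2 = rnbinom(n, mu = mu_a, size = 1 / phi),
    b1 = rnbinom(n, mu = mu_b, size = 1 / phi),
    b2 = rnbinom(n, mu = mu_b, size = 1 / phi))
}

test_that("a planted 4-fold change at base mean 100 is detected in >=95% of units", {
  set.seed(51)
  cnt <- planted_counts(n_de = 500, fc = 4)
  dr <- nb_count_test(cnt, c("A", "A", "B", "B"), type = "interaction")
  expect_gte(mean(dr$p[1:500] < 0.001 & dr$log2fc[1:500] > 0), 0.95)
})

test_that("power is monotone in fold change", {
  set.seed(52)
  power <- vapply(c(1.5, 2, 4), function(fc) {
    cnt <- planted_counts(n_de = 400, fc = fc, n_null = 2000)
    dr <- nb_count_test(cnt, c("A", "A", "B", "B"), type = "interaction")
    mean(dr$p[1:400] < 0.001)
  }, 0)
  expect_true(all(diff(power) >= 0))
})

test_that("direction thresholds follow the unit type", {
  # planted FC 1.35 sits between the gene (1.2) and peak (1.5) bars; with
  # 8 replicates/group it is overwhelmingly significant, so only the fold
  # change gate separates the two unit types
  set.seed(53)
  n_de <- 60; n_null <- 500; n <- n_de + n_null
  fc <- 1.35; base <- 5000; phi <- 0.005; n_rep <- 8
  mu_a <- c(rep(base * sqrt(fc), n_de), rep(base, n_null))
  mu_b <- c(rep(base / sqrt(fc), n_de), rep(base, n_null))
  cnt <- tibble::tibble(unit_id = paste0("u", seq_len(n)))
  for (r in seq_len(n_rep)) cnt[[paste0("a", r)]] <-
    rnbinom(n, mu = mu_a, size = 1 / phi)
  for (r in seq_len(n_rep)) cnt[[paste0("b", r)]] <-
    rnbinom(n, mu = mu_b, size = 1 / phi)
  cond <- rep(c("A", "B"), each = n_rep)
  peak <- nb_count_test(cnt, cond, type = "peak")
  expect_true(all(peak$direction[1:n_de] == "ns"))  # FC 1.35 < 1.5
  expect_gt(mean(peak$fdr[1:n_de] < 0.05), 0.9)     # yet significant
  gene <- nb_count_test(cnt, cond, type = "gene")
  expect_gt(mean(gene$direction[1:n_de] == "up_A"), 0.9)
})

test_that("BH adjustment matches the textbook step-up on hand-checkable vectors", {
  set.seed(54)
  for (k in 1:5) {
    p <- round(runif(20), 3)
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
  }
  # and the fdr column of the test equals BH of its p column
  cnt <- tibble::tibble(unit_id = paste0("u", 1:30),
                        a1 = rpois(30, 100), a2 = rpois(30, 100),
                        b1 = rpois(30, 120), b2 = rpois(30, 80))
  dr <- nb_count_test(cnt, c("A", "A", "B", "B"))
  expect_equal(dr$fdr, oracle_bh(dr$p))
})

test_that("null calibration: empirical FPR at p<0.001 stays below 0.003", {
  set.seed(55)
  n <- 10000
  mu <- rlnorm(n, log(80), 0.7)
  cnt <- tibble::tibble(unit_id = paste0("u", seq_len(n)),
                        a1 = rnbinom(n, mu = mu, size = 20),
                        a2 = rnbinom(n, mu = mu, size = 20),
                        b1 = rnbinom(n, mu = mu, size = 20),
                        b2 = rnbinom(n, mu = mu, size = 20))
  dr <- nb_count_test(cnt, c("A", "A", "B", "B"), type = "interaction")
  expect_lte(mean(dr$p < 0.001), 0.003)
})
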