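test_that("mann_whitney handles the textbook cases", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 0.1)  # 2 of 20 assignments as extreme
  expect_equal(mann_whitney(c(2, 2, 3), c(2, 3, 2))$p_value, 1,
               tolerance = 0.05)
  expect_equal(mann_whitney(rep(5, 4), rep(5, 6))$p_value, 1)
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("U statistic matches brute-force pair counting with midrank ties", {
  set.seed(81)
  for (k in 1:20) {
    n1 <- sample(2:20, 1); n2 <- sample(2:20, 1)
    x <- sample(1:8, n1, replace = TRUE)
    y <- sample(1:8, n2, replace = TRUE)
    u_brute <- sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(mann_whitney(x, y)$u, u_brute)
  }
})

test_that("exact enumeration is used and matches the oracle for n1+n2 <= 8", {
  set.seed(82)
  for (n1 in 1:4) {
    for (n2 in n1:(8 - n1)) {
      x <- sample(1:5, n1, replace = TRUE)
      y <- sample(1:5, n2, replace = TRUE)
      got <- mann_whitney(x, y)
      expect_equal(got$method, "exact enumeration")
      expect_equal(got$p_value, oracle_mw(x, y))
    }
  }
})

test_that("the normal approximation agrees with wilcox.test on untied data", {
  set.seed(83)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  got <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  expect_equal(got$u, unname(ref$statistic))
})

test_that("TPM bins partition at the stated edges", {
  b <- tpm_bin(c(0, 1e-9, 1, 1.0001, 10, 10.0001, 250))
  expect_equal(as.character(b),
               c("0", "(0,1]", "(0,1]", "(1,10]", "(1,10]", ">10", ">10"))
  expect_false(anyNA(tpm_bin(runif(100, 0, 100))))
})

test_that("loop counts rise with expression and recount exactly", {
  set.seed(84)
  n_gene <- 400
  tpm <- c(rep(0, 100), runif(100, 0.01, 1), runif(100, 1.01, 10),
           runif(100, 10.1, 500))
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:n_gene), tpm = tpm)
  lam <- c(rep(0.3, 100), rep(1, 100), rep(3, 100), rep(8, 100))
  n_loops <- rpois(n_gene, lam)
  gene_loops <- tibble::tibble(
    gene_id = rep(genes$gene_id, n_loops))
  res <- expression_by_loop_count(genes, gene_loops)
  expect_equal(sum(res$genes$n_loops), sum(n_loops))
  expect_equal(res$genes$n_loops, as.numeric(n_loops))
  med <- res$summary$median_loops
  expect_true(all(diff(med) > 0))
  expect_true(all(res$tests$p_value < 0.01))
  # all-identical expression collapses to a single bin and warns per skip
  flat <- tibble::tibble(gene_id = genes$gene_id, tpm = 5)
  w <- testthat::capture_warnings(expression_by_loop_count(flat, gene_loops))
  expect_true(length(w) > 0 && all(grepl("empty TPM bin", w)))
})

test_that("acetylation strata split genes and detect planted expression effects", {
  set.seed(85)
  n <- 600
  genes <- sprintf("g%03d", 1:n)
  n_loops <- sample(0:8, n, replace = TRUE)
  any_ac <- n_loops > 0 & runif(n) < 0.5
  gene_loops <- tibble::tibble(
    gene_id = rep(genes, n_loops),
    distal_ac = unlist(lapply(seq_len(n), function(k) {
      if (n_loops[k] == 0) return(logical())
      c(any_ac[k], rep(FALSE, n_loops[k] - 1))
    })))
  strata <- loop_count_strata(gene_loops, genes)
  expect_equal(nrow(strata), n)
  expect_equal(sum(table(strata$stratum)), n)
  expect_true(all(strata$stratum[strata$n_loops == 0] == "no_interaction"))
  # plant acetylation -> higher expression
  tpm <- exp(rnorm(n, log(5), 0.5)) * ifelse(strata$any_ac, 4, 1)
  res <- expression_by_strata(tibble::tibble(gene_id = genes, tpm = tpm),
                              strata)
  expect_true(all(res$tests$median_ac > res$tests$median_no_ac))
  expect_true(all(res$tests$p_value < 0.01))
})

test_that("nearest-TSS assignment respects the window and the tie rule", {
  expr <- tibble::tibble(gene_id = c("gB", "gA"), chrom = "chr1",
                         tss = c(100000, 200000))
  sites <- tibble::tibble(chrom = "chr1",
                          start = c(129750, 159750, 149750),
                          end = c(130250, 160250, 150250))
  res <- nearest_tss_assignment(sites, expr, window_bp = 5e4)
  expect_equal(res$gene_id[1], "gB")       # 30 kb away
  # site 2 centre 160000: 60 kb from gB but 40 kb from gA -> assigned gA
  expect_equal(res$gene_id[2], "gA")
  # equidistant site centre 150000 -> ties break to the smaller gene_id
  expect_equal(res$gene_id[3], "gA")
  far <- tibble::tibble(chrom = "chr1", start = 260250, end = 260750)
  expect_true(is.na(nearest_tss_assignment(far, expr, 5e4)$gene_id))
})

test_that("energy expenditure follows the calorimetric equation", {
  expect_identical(energy_expenditure(1, 0), 3.941)
  expect_identical(energy_expenditure(0, 1), 1.106)
  expect_identical(energy_expenditure(0, 0), 0)
  expect_equal(energy_expenditure(0.5, 0.5), 2.5235)
  expect_equal(energy_expenditure(c(1, 2), c(0, 1)), c(3.941, 8.988))
  expect_error(energy_expenditure(-1, 0), "non-negative")
})
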