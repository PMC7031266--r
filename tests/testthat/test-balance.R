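make_random_matrix <- function(n_bins = 200, density = 0.2, seed = 8,
                               bias = TRUE, flat = FALSE) {
  set.seed(seed)
  bg <- binned_genome(c(chrZ = n_bins * 1e4), 1e4)
  i <- rep.int(seq_len(n_bins), n_bins:1)
  j <- sequence(n_bins:1) - 1L + i
  keep <- runif(length(i)) < density
  i <- i[keep]; j <- j[keep]
  lam <- if (flat) rep(5, length(i)) else 20 / pmax(j - i, 1)
  if (bias) {
    v <- rlnorm(n_bins, 0, 0.4)
    lam <- lam * v[i] * v[j]
  }
  cnt <- rpois(length(lam), lam * 5)
  nz <- cnt > 0
  loopdyn:::new_contact_matrix(
    tibble::tibble(chrom1 = "chrZ", bin1 = i[nz] - 1L, chrom2 = "chrZ",
                   bin2 = j[nz] - 1L, count = as.numeric(cnt[nz])), bg)
}

sum_masked_counts <- function(cm, mask) {
  key <- function(ch, b) paste(ch, b)
  mk <- key(mask$chrom, mask$bin)
  px <- cm$pixels
  sum(px$count[key(px$chrom1, px$bin1) %in% mk |
                 key(px$chrom2, px$bin2) %in% mk])
}

unmasked_coverage <- function(cm) {
  cov <- bin_coverage(cm)
  key <- paste(cov$chrom, cov$bin)
  cov$coverage[!key %in% paste(cm$bin_mask$chrom, cm$bin_mask$bin)]
}

test_that("balancing equalises row sums and is idempotent", {
  cm <- make_random_matrix()
  bal <- filter_and_balance(cm)
  s <- unmasked_coverage(bal)
  expect_lt(diff(range(s)) / mean(s), 1e-6)
  expect_true(bal$balanced)
  # total preserved through correction
  expect_equal(matrix_total(bal), matrix_total(cm) -
                 sum_masked_counts(cm, bal$bin_mask), tolerance = 1e-8)
  bal2 <- filter_and_balance(bal)
  expect_lt(max(abs(bal2$pixels$count - bal$pixels$count) /
                  pmax(bal$pixels$count, 1e-12)), 1e-6)
})

test_that("a constant-row-sum matrix is unchanged up to global scale", {
  bg <- binned_genome(c(chrC = 5e4), 1e4)
  # circulant structure: every row sums to the same value
  px <- tibble::tibble(chrom1 = "chrC", bin1 = c(0:4, 0:4),
                       chrom2 = "chrC", bin2 = c(c(1:4, 0), c(2:4, 0:1)),
                       count = c(rep(2, 5), rep(3, 5)))
  cm <- loopdyn:::new_contact_matrix(px, bg)
  bal <- filter_and_balance(cm)
  ratio <- bal$pixels$count / cm$pixels$count
  expect_lt(diff(range(ratio)), 1e-8)
})

test_that("zero-coverage bins are masked", {
  bg <- binned_genome(c(chrC = 5e4), 1e4)
  set.seed(12)
  ij <- which(upper.tri(matrix(TRUE, 4, 4), diag = TRUE), arr.ind = TRUE)
  px <- tibble::tibble(chrom1 = "chrC", bin1 = ij[, 1] - 1L,
                       chrom2 = "chrC", bin2 = ij[, 2] - 1L,
                       count = rpois(nrow(ij), 20) + 1)
  cm <- loopdyn:::new_contact_matrix(px, bg)  # bin 4 has no contacts
  bal <- filter_and_balance(cm, low_cutoff = -10, high_cutoff = 10)
  expect_true(any(bal$bin_mask$bin == 4))
})

test_that("matrix correlation behaves as log1p Pearson", {
  cm <- make_random_matrix(seed = 9)
  expect_equal(matrix_correlation(cm, cm), 1)
  cm2 <- cm
  cm2$pixels$count <- 2 * cm2$pixels$count
  expect_gt(matrix_correlation(cm, cm2), 0.99)
  # matrices with independent flat noise decorrelate
  a <- make_random_matrix(n_bins = 150, density = 0.9, seed = 10,
                          bias = FALSE, flat = TRUE)
  b <- make_random_matrix(n_bins = 150, density = 0.9, seed = 11,
                          bias = FALSE, flat = TRUE)
  expect_lt(abs(matrix_correlation(a, b)), 0.1)
  expect_error(matrix_correlation(cm, filter_and_balance(cm)), "raw or two balanced")
})

test_that("expected_by_distance reproduces an exact distance function", {
  bg <- binned_genome(c(chrD = 3e5), 1e4)
  n <- 30
  i <- rep.int(seq_len(n), n:1)
  j <- sequence(n:1) - 1L + i
  f <- function(d) 100 - 3 * d
  px <- tibble::tibble(chrom1 = "chrD", bin1 = i - 1L, chrom2 = "chrD",
                       bin2 = j - 1L, count = f(j - i))
  cm <- loopdyn:::new_contact_matrix(px, bg)
  prof <- expected_by_distance(cm)
  expect_equal(prof$mean_count, f(prof$distance_bins))
  expect_equal(prof$mean_count[prof$distance_bins == 0], 100)
  expect_equal(prof$n_pixels, (n):(1))
})

test_that("planted power-law decay is recovered from simulated contacts", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 5e6, n_genes = 50, seed = 2)
  sim <- simulate_contacts(g, truth = NULL, depth = 300, replicates = 1,
                           conditions = "A", visibility_sd = 0,
                           dead_bin_fraction = 0, seed = 5)
  prof <- expected_by_distance(sim$libraries$A[[1]])
  sel <- prof$distance_bins >= 1 & prof$distance_bins <= 100 &
    prof$n_pixels >= 100
  fit <- stats::lm(log(mean_count) ~ log(distance_bins), data = prof[sel, ])
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.1)
})
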