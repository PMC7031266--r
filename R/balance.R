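#' Filter low/high-coverage bins and iteratively balance a contact matrix
#'
#' Bins whose coverage z-score falls outside `[low_cutoff, high_cutoff]`
#' (computed over bins with non-zero coverage; zero-coverage bins are always
#' masked) are removed, then the remaining matrix is corrected by iterative
#' row/column scaling (ICE) until every unmasked row sum equals the common
#' target within `tolerance` (relative). The corrected matrix keeps the same
#' grand total as the filtered input, so counts remain on a familiar scale.
#'
#' @param matrix A raw `contact_matrix`.
#' @param low_cutoff,high_cutoff Coverage z-score cutoffs. The asymmetric
#'   default (-2.5, 4) removes dead/invisible bins and coverage blow-ups
#'   while keeping bins whose coverage is genuinely depressed by local
#'   structure (e.g. domain boundaries); in practice these thresholds are
#'   chosen per dataset from the coverage histogram.
#' @param max_iter Maximum ICE iterations.
#' @param tolerance Relative row-sum deviation at convergence.
#' @return A balanced `contact_matrix` with `bin_mask` filled in.
#' @export
filter_and_balance <- function(matrix, low_cutoff = -2.5, high_cutoff = 4,
                               max_iter = 200, tolerance = 1e-8) {
  stopifnot(low_cutoff < high_cutoff, tolerance > 0)
  g <- matrix$genome
  cov <- bin_coverage(matrix)
  nz <- cov$coverage > 0
  z <- rep(NA_real_, nrow(cov))
  sd_cov <- if (sum(nz) >= 2) stats::sd(cov$coverage[nz]) else 0
  # a (nearly) constant coverage profile — e.g. an already balanced matrix —
  # carries no outlier information; skip z-filtering in that case
  if (sd_cov > 1e-6 * mean(cov$coverage[nz])) {
    z[nz] <- (cov$coverage[nz] - mean(cov$coverage[nz])) / sd_cov
  } else {
    z[nz] <- 0
  }
  masked <- !nz | z < low_cutoff | z > high_cutoff
  mask_tbl <- cov[masked, c("chrom", "bin")]

  px <- matrix$pixels
  g1 <- global_bin(g, px$chrom1, px$bin1) + 1
  g2 <- global_bin(g, px$chrom2, px$bin2) + 1
  keep <- !(masked[g1] | masked[g2])
  px <- px[keep, , drop = FALSE]
  g1 <- g1[keep]; g2 <- g2[keep]
  if (nrow(px) == 0) stop("all pixels masked during filtering", call. = FALSE)

  n <- g$n_bins
  counts <- px$count
  total0 <- sum(counts)
  unmasked <- which(!masked)
  off <- g1 != g2
  idx_all <- c(g1, g2[off])
  rowsum_of <- function(x) {
    s <- numeric(n)
    a <- rowsum(c(x, x[off]), idx_all)
    s[as.integer(rownames(a))] <- a[, 1]
    s
  }
  converged <- FALSE
  dev <- NA_real_
  for (it in seq_len(max_iter)) {
    s <- rowsum_of(counts)
    sm <- s[unmasked]
    if (any(sm == 0)) {
      # bins emptied by filtering elsewhere: mask them and drop pixels
      newly <- unmasked[sm == 0]
      masked[newly] <- TRUE
      unmasked <- which(!masked)
      keep <- !(g1 %in% newly | g2 %in% newly)
      counts <- counts[keep]; px <- px[keep, , drop = FALSE]
      g1 <- g1[keep]; g2 <- g2[keep]
      off <- g1 != g2
      idx_all <- c(g1, g2[off])
      next
    }
    b <- sm / mean(sm)
    dev <- max(abs(b - 1))
    if (dev < tolerance) { converged <- TRUE; break }
    # square-root damping keeps the symmetric update from oscillating on
    # sparse matrices
    scale <- rep(1, n)
    scale[unmasked] <- sqrt(b)
    counts <- counts / (scale[g1] * scale[g2])
  }
  if (!converged) {
    stop("iterative correction did not converge in ", max_iter,
         " iterations (last max relative row-sum deviation ",
         signif(dev, 3), ")", call. = FALSE)
  }
  counts <- counts * (total0 / sum(counts))
  px$count <- counts
  mask_tbl <- cov[masked, c("chrom", "bin")]
  new_contact_matrix(px, g, balanced = TRUE, bin_mask = mask_tbl,
                     library_total = matrix$library_total)
}

#' Correlation between two contact matrices
#'
#' Pearson correlation of `log1p(count)` over the union of bin-pairs that
#' are non-zero in either matrix (absent pixels count as zero). Used to ask
#' how similar genome organisation is across conditions.
#'
#' @param m1,m2 Two `contact_matrix` objects on the same binned genome and
#'   with the same balancing state.
#' @return A single correlation in `[-1, 1]`.
#' @export
matrix_correlation <- function(m1, m2) {
  if (!identical(m1$genome$bin_size, m2$genome$bin_size)) {
    stop("matrices have different bin sizes", call. = FALSE)
  }
  if (!identical(m1$balanced, m2$balanced)) {
    stop("compare two raw or two balanced matrices, not a mix", call. = FALSE)
  }
  key <- function(m) paste(m$pixels$chrom1, m$pixels$bin1,
                           m$pixels$chrom2, m$pixels$bin2)
  k1 <- key(m1); k2 <- key(m2)
  all_k <- union(k1, k2)
  if (length(all_k) == 0) stop("no non-zero pixels in either matrix", call. = FALSE)
  x <- numeric(length(all_k)); y <- numeric(length(all_k))
  x[match(k1, all_k)] <- m1$pixels$count
  y[match(k2, all_k)] <- m2$pixels$count
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate matrix: zero variance over shared pixel set", call. = FALSE)
  }
  stats::cor(log1p(x), log1p(y))
}

#' Mean contact count by genomic distance
#'
#' For each cis distance stratum (multiples of the bin size), the mean count
#' over *all* unmasked bin pairs at that separation — zero pixels included,
#' so the profile is a proper expected-value curve usable as an
#' observed/expected denominator and as the capture-scoring background.
#'
#' @param matrix A `contact_matrix`.
#' @param smooth If `TRUE`, enforce a non-increasing profile (monotone
#'   pool-adjacent-violators from the diagonal outwards).
#' @return Tibble (`distance_bins`, `distance_bp`, `mean_count`, `n_pixels`),
#'   one row per stratum present in the genome, of class `decay_profile`.
#' @export
expected_by_distance <- function(matrix, smooth = FALSE) {
  g <- matrix$genome
  px <- matrix$pixels
  cis <- px$chrom1 == px$chrom2
  if (!any(cis)) stop("no cis pixels", call. = FALSE)
  d <- px$bin2[cis] - px$bin1[cis]
  sums <- tapply(px$count[cis], d, sum)

  # unmasked pair counts per stratum, accumulated per chromosome
  max_d <- max(g$chrom_sizes$n_bins) - 1
  npairs <- numeric(max_d + 1)
  for (ci in seq_len(nrow(g$chrom_sizes))) {
    chrom <- g$chrom_sizes$chrom[ci]
    n <- g$chrom_sizes$n_bins[ci]
    m_bins <- masked_bins_of(matrix, chrom)
    ok <- rep(TRUE, n); ok[m_bins + 1L] <- FALSE
    idx <- which(ok)
    if (length(idx) == 0) next
    # count pairs (i, i+d) with both unmasked, vectorised over d via convolution
    v <- as.numeric(ok)
    # autocorrelation via FFT: cc[n - d] = sum_i v_i v_{i+d}
    cc <- stats::convolve(v, rev(v), type = "open")
    dmax <- n - 1
    npairs[seq_len(dmax + 1)] <- npairs[seq_len(dmax + 1)] +
      pmax(0, round(cc[n - 0:dmax]))
  }
  dist_lev <- as.integer(names(sums))
  all_d <- sort(unique(c(dist_lev, which(npairs > 0) - 1L)))
  all_d <- all_d[npairs[all_d + 1] > 0]
  mean_count <- numeric(length(all_d))
  mi <- match(all_d, dist_lev)
  mean_count[!is.na(mi)] <- as.numeric(sums[mi[!is.na(mi)]])
  mean_count <- mean_count / npairs[all_d + 1]
  if (smooth) {
    for (k in seq_along(mean_count)[-1]) {
      if (mean_count[k] > mean_count[k - 1]) mean_count[k] <- mean_count[k - 1]
    }
  }
  out <- tibble::tibble(distance_bins = all_d,
                        distance_bp = all_d * g$bin_size,
                        mean_count = mean_count,
                        n_pixels = npairs[all_d + 1])
  class(out) <- c("decay_profile", class(out))
  out
}
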