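#' A/B compartments from the leading eigenvector of the O/E correlation map
#'
#' Per chromosome: the balanced cis matrix is divided by its expected-by-
#' distance profile, the Pearson correlation matrix of the resulting
#' observed/expected columns is computed over unmasked bins, and the first
#' principal component (leading eigenvector) of that correlation matrix is
#' extracted. The eigenvector sign is arbitrary, so it is oriented with an
#' activity proxy: the sign is flipped so bins overlapping
#' `orientation_track` have positive mean PC1. Bins with `pc1 > 0` are
#' labelled `A`, the rest `B`; masked bins stay `masked`.
#'
#' @param matrix A balanced `contact_matrix` (typically at 50-kb bins).
#' @param orientation_track Interval tibble of active regions (planted
#'   active bins, gene-dense regions, or an H3K27ac-style track).
#' @param min_bins Chromosomes with fewer unmasked bins than this are fully
#'   masked with a warning.
#' @return A tibble of class `compartment_track`: one row per bin with
#'   `chrom`, `bin`, `start`, `end`, `pc1`, `label` in
#'   `{"A", "B", "masked"}`.
#' @export
compartment_pc1 <- function(matrix, orientation_track, min_bins = 20) {
  if (!matrix$balanced) {
    stop("compartment calling needs a balanced matrix", call. = FALSE)
  }
  g <- matrix$genome
  orientation_track <- validate_intervals(orientation_track,
                                          what = "orientation_track")
  out <- vector("list", nrow(g$chrom_sizes))
  for (ci in seq_len(nrow(g$chrom_sizes))) {
    chrom <- g$chrom_sizes$chrom[ci]
    n <- g$chrom_sizes$n_bins[ci]
    bins <- tibble::tibble(
      chrom = chrom, bin = seq_len(n) - 1L,
      start = (seq_len(n) - 1) * g$bin_size,
      end = pmin(seq_len(n) * g$bin_size, g$chrom_sizes$length[ci]),
      pc1 = 0, label = "masked"
    )
    m <- cis_dense(matrix, chrom)
    ok <- rep(TRUE, n); ok[masked_bins_of(matrix, chrom) + 1L] <- FALSE
    ok <- ok & rowSums(m) > 0
    if (sum(ok) < min_bins) {
      warning("chromosome ", chrom, " has fewer than ", min_bins,
              " unmasked bins; compartments masked", call. = FALSE)
      out[[ci]] <- bins
      next
    }
    exp_prof <- expected_by_distance(subset_chrom(matrix, chrom))
    e <- numeric(n)
    e[exp_prof$distance_bins + 1] <- exp_prof$mean_count
    dmat <- abs(outer(seq_len(n), seq_len(n), "-")) + 1L
    expm <- base::matrix(e[dmat], n, n)
    oe <- m[ok, ok, drop = FALSE] / expm[ok, ok, drop = FALSE]
    oe[!is.finite(oe)] <- 0
    sds <- apply(oe, 2, stats::sd)
    if (all(sds == 0)) {
      warning("chromosome ", chrom,
              " has no contact structure; compartments masked", call. = FALSE)
      out[[ci]] <- bins
      next
    }
    keep2 <- sds > 0
    cm <- suppressWarnings(stats::cor(oe[keep2, keep2, drop = FALSE]))
    cm[!is.finite(cm)] <- 0
    ev <- eigen(cm, symmetric = TRUE)
    pc1 <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0))
    idx <- which(ok)[keep2]
    bins$pc1[idx] <- pc1
    # orient: positive mean PC1 on bins overlapping the activity track
    act <- overlaps_any(bins[idx, c("chrom", "start", "end")],
                        orientation_track)
    if (any(act) && mean(pc1[act]) < 0) {
      pc1 <- -pc1
      bins$pc1[idx] <- pc1
    }
    bins$label[idx] <- ifelse(pc1 > 0, "A", "B")
    out[[ci]] <- bins
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("compartment_track", class(res))
  res
}

# single-chromosome view of a contact matrix (cis pixels only)
subset_chrom <- function(matrix, chrom) {
  g <- matrix$genome
  ci <- match(chrom, g$chrom_sizes$chrom)
  sub_g <- binned_genome(stats::setNames(g$chrom_sizes$length[ci], chrom),
                         g$bin_size)
  sel <- matrix$pixels$chrom1 == chrom & matrix$pixels$chrom2 == chrom
  new_contact_matrix(matrix$pixels[sel, , drop = FALSE], sub_g,
                     balanced = matrix$balanced,
                     bin_mask = matrix$bin_mask[matrix$bin_mask$chrom == chrom, ],
                     library_total = matrix$library_total)
}

#' Write a compartment track as bedGraph-style TSV
#' @param track A `compartment_track`.
#' @param path Output path.
#' @export
write_compartments <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "pc1", "label")], path,
                   progress = FALSE)
  invisible(path)
}
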