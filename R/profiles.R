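#' Metagene-style signal profile around region centres
#'
#' Resamples a per-bin signal track to `n_points` positions across
#' `[center - flank_bp, center + flank_bp)` for every region, and averages
#' across regions. Used for C/EBP-alpha- or H3K27ac-style metagene plots at
#' bound regions.
#'
#' @param signal Track tibble `chrom`, `start`, `end`, `value` (sorted or
#'   not; intervals are assumed non-overlapping per chromosome). Positions
#'   not covered by the track read as 0.
#' @param regions Interval tibble; profiles are taken around each region's
#'   midpoint.
#' @param flank_bp Half-window in bp.
#' @param n_points Number of sample points across the window.
#' @param chrom_sizes Optional chromosome-size table; regions whose centre
#'   lies outside the chromosome are skipped with a warning.
#' @return Object of class `signal_profile`: list with `matrix`
#'   (regions x points), `positions` (bp offsets relative to centre) and
#'   `mean_curve` (tibble `position`, `mean_value`).
#' @export
signal_profile <- function(signal, regions, flank_bp = 2000, n_points = 81,
                           chrom_sizes = NULL) {
  stopifnot(flank_bp >= 0, n_points >= 2)
  signal <- validate_intervals(signal, what = "signal")
  stopifnot("value" %in% names(signal))
  regions <- validate_intervals(regions, what = "regions")
  if (nrow(regions) == 0) stop("regions must be non-empty", call. = FALSE)
  if (inherits(chrom_sizes, "binned_genome")) chrom_sizes <- chrom_sizes$chrom_sizes
  offs <- seq(-flank_bp, flank_bp, length.out = n_points)
  centers <- (regions$start + regions$end) / 2
  max_pos <- rep(Inf, nrow(regions))
  if (!is.null(chrom_sizes)) {
    max_pos <- chrom_sizes$length[match(regions$chrom, chrom_sizes$chrom)]
    max_pos[is.na(max_pos)] <- Inf
  }
  prof <- base::matrix(NA_real_, nrow(regions), n_points)
  kept <- rep(TRUE, nrow(regions))
  for (chrom in unique(regions$chrom)) {
    tr <- signal[signal$chrom == chrom, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    ri <- which(regions$chrom == chrom)
    for (r in ri) {
      pos <- centers[r] + offs
      if (centers[r] < 0 || centers[r] >= max_pos[r]) { kept[r] <- FALSE; next }
      if (nrow(tr) == 0) { prof[r, ] <- 0; next }
      k <- findInterval(pos, tr$start)
      val <- numeric(n_points)
      inside <- k >= 1
      inside[inside] <- pos[inside] < tr$end[k[inside]]
      val[inside] <- tr$value[k[inside]]
      prof[r, ] <- val
    }
  }
  if (!all(kept)) {
    warning(sum(!kept), " region(s) with centre outside the chromosome skipped",
            call. = FALSE)
    prof <- prof[kept, , drop = FALSE]
  }
  mean_curve <- tibble::tibble(position = offs, mean_value = colMeans(prof))
  structure(list(matrix = prof, positions = offs, mean_curve = mean_curve,
                 n_regions = nrow(prof)),
            class = "signal_profile")
}

#' @export
print.signal_profile <- function(x, ...) {
  cat("<signal_profile> ", x$n_regions, " regions x ", length(x$positions),
      " points; peak mean ", signif(max(x$mean_curve$mean_value), 4), "\n",
      sep = "")
  invisible(x)
}

#' Split a peak set by co-binding with a premark set
#'
#' Partitions `sites_primary` into sites that overlap (>= 1 bp) at least
#' one `sites_premark` interval and sites that do not — e.g. splitting
#' differentially bound C/EBP-alpha sites by whether Hnf4-alpha was
#' premarked there.
#'
#' @param sites_primary,sites_premark Interval tibbles.
#' @return List with elements `with_premark` and `without_premark` (both
#'   tibbles), partitioning `sites_primary`.
#' @export
cobinding_split <- function(sites_primary, sites_premark) {
  hit <- overlaps_any(sites_primary, sites_premark)
  list(with_premark = sites_primary[hit, , drop = FALSE],
       without_premark = sites_primary[!hit, , drop = FALSE])
}
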