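#' Distance-stratified contact z-scores
#'
#' For every unmasked cis pixel (zero counts included) within `max_depth_bp`
#' of the diagonal, the z-score of its count against the mean and standard
#' deviation of all unmasked pixels in the same genomic-distance stratum.
#' Strata with fewer than `min_pixels` pixels, or zero spread, give
#' undefined (`NA`) z.
#'
#' @param matrix A balanced `contact_matrix`.
#' @param max_depth_bp Maximum genomic distance considered.
#' @param min_pixels Minimum pixels for a stratum to be scored.
#' @return Tibble of class `loop_zscores`: `chrom`, `bin1`, `bin2`,
#'   `distance_bins`, `count`, `z`. Carries the genome as attribute
#'   `genome`.
#' @export
loop_zscores <- function(matrix, max_depth_bp = 1e8, min_pixels = 10) {
  g <- matrix$genome
  max_d <- floor(max_depth_bp / g$bin_size)
  rows <- vector("list", nrow(g$chrom_sizes))
  for (ci in seq_len(nrow(g$chrom_sizes))) {
    chrom <- g$chrom_sizes$chrom[ci]
    n <- g$chrom_sizes$n_bins[ci]
    m <- cis_dense(matrix, chrom)
    ok <- rep(TRUE, n); ok[masked_bins_of(matrix, chrom) + 1L] <- FALSE
    idx <- which(ok)
    if (length(idx) < 2) next
    # enumerate unmasked pixel pairs by distance
    pr <- which(upper.tri(base::matrix(TRUE, length(idx), length(idx)), diag = TRUE),
                arr.ind = TRUE)
    i <- idx[pr[, 1]]; j <- idx[pr[, 2]]
    d <- j - i
    keep <- d <= max_d
    i <- i[keep]; j <- j[keep]; d <- d[keep]
    cnt <- m[cbind(i, j)]
    mu <- tapply(cnt, d, mean)
    sdv <- tapply(cnt, d, stats::sd)
    npx <- tapply(cnt, d, length)
    di <- match(d, as.integer(names(mu)))
    z <- (cnt - as.numeric(mu)[di]) / as.numeric(sdv)[di]
    bad <- as.numeric(npx)[di] < min_pixels | !is.finite(z)
    z[bad] <- NA_real_
    rows[[ci]] <- tibble::tibble(chrom = chrom, bin1 = i - 1L, bin2 = j - 1L,
                                 distance_bins = d, count = cnt, z = z)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "genome") <- g
  class(out) <- c("loop_zscores", class(out))
  out
}

#' Call loops from contact z-scores
#'
#' Thresholds pixels at `z >= z_min` and span `<= span_max`, then merges
#' 8-connected runs of called pixels into single loop calls anchored at the
#' maximum-z pixel of each connected component.
#'
#' @param zscores Output of [loop_zscores()].
#' @param z_min Minimum z-score (default 6).
#' @param span_max Maximum loop span in bp (default 1 Mb).
#' @return Tibble of class `loop_calls`: `chrom`, `bin1`, `bin2`, `start1`,
#'   `end1`, `start2`, `end2`, `count`, `zscore`, `span`, `n_pixels`.
#' @export
call_loops <- function(zscores, z_min = 6, span_max = 1e6) {
  g <- attr(zscores, "genome")
  bs <- g$bin_size
  hit <- !is.na(zscores$z) & zscores$z >= z_min &
    (zscores$distance_bins * bs) <= span_max
  px <- zscores[hit, , drop = FALSE]
  if (nrow(px) == 0) {
    out <- tibble::tibble(chrom = character(), bin1 = integer(),
                          bin2 = integer(), start1 = numeric(), end1 = numeric(),
                          start2 = numeric(), end2 = numeric(), count = numeric(),
                          zscore = numeric(), span = numeric(), n_pixels = integer())
    class(out) <- c("loop_calls", class(out))
    return(out)
  }
  comp <- connected_pixel_components(px$chrom, px$bin1, px$bin2)
  out <- dplyr::group_by(
    tibble::tibble(comp = comp, chrom = px$chrom, bin1 = px$bin1,
                   bin2 = px$bin2, count = px$count, z = px$z),
    .data$comp)
  out <- dplyr::summarise(
    out,
    chrom = .data$chrom[which.max(.data$z)],
    bin1 = .data$bin1[which.max(.data$z)],
    bin2 = .data$bin2[which.max(.data$z)],
    count = .data$count[which.max(.data$z)],
    zscore = max(.data$z),
    n_pixels = dplyr::n(),
    .groups = "drop")
  out <- dplyr::mutate(
    out,
    start1 = bin_start(g, .data$bin1), end1 = .data$start1 + bs,
    start2 = bin_start(g, .data$bin2), end2 = .data$start2 + bs,
    span = (.data$bin2 - .data$bin1) * bs)
  out <- out[order(match(out$chrom, g$chrom_sizes$chrom), out$bin1, out$bin2),
             c("chrom", "bin1", "bin2", "start1", "end1", "start2", "end2",
               "count", "zscore", "span", "n_pixels")]
  attr(out, "genome") <- g
  class(out) <- c("loop_calls", class(out))
  out
}

# union-find over pixels; neighbours = 8-connectivity in (bin1, bin2) space
connected_pixel_components <- function(chrom, b1, b2) {
  n <- length(chrom)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  key <- split(seq_len(n), chrom)
  for (idx in key) {
    ord <- idx[order(b1[idx], b2[idx])]
    # compare each pixel against candidates with bin1 in {b1-1, b1, b1+1}
    for (a_pos in seq_along(ord)) {
      a <- ord[a_pos]
      for (b_pos in seq_len(a_pos - 1L)) {
        b <- ord[b_pos]
        if (b1[a] - b1[b] > 1L) next
        if (abs(b2[a] - b2[b]) <= 1L) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Aggregate peak analysis
#'
#' Sums fixed-size submatrices of the contact map centred on each loop
#' pixel (21 x 21 at 10-kb bins for a +/-100-kb background window), after
#' excluding loops within `min_diag_bp` of the diagonal and loops whose
#' window leaves the chromosome. The aggregate is scaled by the mean of its
#' 4 corner pixels; the centre of the scaled aggregate is the APA score.
#'
#' @param matrix A `contact_matrix` whose bin size equals `bin_bp`.
#' @param loops A data frame with `chrom`, `bin1`, `bin2` (e.g.
#'   [call_loops()] output).
#' @param window_bp Half-width of the local background window.
#' @param bin_bp Bin size expected of the matrix.
#' @param min_diag_bp Loops closer than this to the diagonal are excluded.
#' @return Object of class `apa_result`: list with `aggregate` (the scaled
#'   submatrix), `center_score`, `corner_mean` (pre-scaling), and
#'   `n_loops_used`.
#' @export
apa <- function(matrix, loops, window_bp = 1e5, bin_bp = 1e4,
                min_diag_bp = 3e5) {
  g <- matrix$genome
  if (g$bin_size != bin_bp) {
    stop("matrix bin size (", g$bin_size, ") does not match bin_bp (",
         bin_bp, ")", call. = FALSE)
  }
  w <- as.integer(window_bp / bin_bp)
  size <- 2L * w + 1L
  min_d <- min_diag_bp / bin_bp
  agg <- base::matrix(0, size, size)
  used <- 0L
  for (chrom in unique(loops$chrom)) {
    m <- cis_dense(matrix, chrom)
    n <- nrow(m)
    sel <- loops[loops$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(sel))) {
      i <- sel$bin1[k] + 1L; j <- sel$bin2[k] + 1L
      if ((j - i) < min_d) next
      if (i - w < 1 || i + w > n || j - w < 1 || j + w > n) next
      agg <- agg + m[(i - w):(i + w), (j - w):(j + w)]
      used <- used + 1L
    }
  }
  if (used == 0L) stop("no loops usable for APA after diagonal/edge exclusion",
                       call. = FALSE)
  corners <- c(agg[1, 1], agg[1, size], agg[size, 1], agg[size, size])
  corner_mean <- mean(corners)
  if (corner_mean <= 0) stop("zero corner background in APA", call. = FALSE)
  scaled <- agg / corner_mean
  structure(list(aggregate = scaled, center_score = scaled[w + 1L, w + 1L],
                 corner_mean = corner_mean, n_loops_used = used,
                 window_bins = w),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat("<apa_result> center score ", signif(x$center_score, 4), " over ",
      x$n_loops_used, " loops\n", sep = "")
  invisible(x)
}

#' Write loop calls as BEDPE
#' @param loops `loop_calls` tibble.
#' @param path Output path.
#' @export
write_loops_bedpe <- function(loops, path) {
  df <- tibble::tibble(
    chrom1 = loops$chrom, start1 = loops$start1, end1 = loops$end1,
    chrom2 = loops$chrom, start2 = loops$start2, end2 = loops$end2,
    name = ".", score = loops$zscore, strand1 = ".", strand2 = ".",
    count = loops$count, span = loops$span)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
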