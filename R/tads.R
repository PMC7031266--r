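#' Insulation-based TAD segmentation
#'
#' Computes, for each bin and each window size, the TAD-separation score:
#' the mean balanced contact count in the diamond window spanning the `w`
#' bins upstream versus the `w` bins downstream of the bin, log2-scaled
#' relative to the chromosome mean. The per-bin score is the minimum over
#' window sizes. A bin becomes a boundary when it is a local minimum whose
#' score drops at least `delta` below the nearest flanking local maxima on
#' both sides, and when the contact depletion is statistically supported: a
#' one-sided rank-sum comparison of the diamond counts at the minimum
#' against those at the flanking maxima, multiple-testing corrected (BH)
#' across candidates, at level `comparison_p`.
#'
#' @param matrix A balanced `contact_matrix`.
#' @param window_bins Integer vector of diamond half-widths in bins.
#' @param delta Minimum score drop below both flanking maxima.
#' @param comparison_p Significance level for the boundary test.
#' @param fdr_correct Apply BH correction across candidate boundaries.
#' @param min_boundary_bins Candidate boundaries closer than this collapse
#'   to the one with the lowest score (suppresses twin minima on flat
#'   valley bottoms).
#' @return An object of class `tad_set`: list with `boundaries` (tibble
#'   `chrom`, `bin`, `start`, `end`, `score`, `p`, `fdr`), `domains`
#'   (intervals between consecutive boundaries per chromosome), and
#'   `scores` (per-bin separation score track).
#' @export
insulation_tads <- function(matrix, window_bins = c(5, 10, 20), delta = 0.1,
                            comparison_p = 0.05, fdr_correct = TRUE,
                            min_boundary_bins = 5) {
  if (!matrix$balanced) stop("TAD calling needs a balanced matrix", call. = FALSE)
  g <- matrix$genome
  score_rows <- list(); cand_rows <- list()
  for (ci in seq_len(nrow(g$chrom_sizes))) {
    chrom <- g$chrom_sizes$chrom[ci]
    n <- g$chrom_sizes$n_bins[ci]
    if (max(window_bins) * 2 + 1 > n) {
      stop("window of ", max(window_bins), " bins too large for chromosome ",
           chrom, call. = FALSE)
    }
    m <- cis_dense(matrix, chrom)
    mask <- rep(FALSE, n); mask[masked_bins_of(matrix, chrom) + 1L] <- TRUE
    sc_w <- sapply(window_bins, function(w) diamond_score(m, w, mask))
    # log2 relative to chromosome mean, per window, then min across windows
    for (k in seq_along(window_bins)) {
      mu <- mean(sc_w[, k], na.rm = TRUE)
      sc_w[, k] <- log2(sc_w[, k] / mu)
    }
    score <- apply(sc_w, 1, function(r) if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
    score_rows[[ci]] <- tibble::tibble(chrom = chrom, bin = seq_len(n) - 1L,
                                       score = score)
    mins <- local_extrema(score, minima = TRUE)
    maxs <- local_extrema(score, minima = FALSE)
    for (b in mins) {
      lmax <- maxs[maxs < b]; rmax <- maxs[maxs > b]
      if (length(lmax) == 0 || length(rmax) == 0) next
      lmax <- max(lmax); rmax <- min(rmax)
      drop_l <- score[lmax] - score[b]
      drop_r <- score[rmax] - score[b]
      if (min(drop_l, drop_r) < delta) next
      w0 <- max(window_bins)
      dmin <- diamond_values(m, b, w0, mask)
      dfl <- c(diamond_values(m, lmax, w0, mask),
               diamond_values(m, rmax, w0, mask))
      p <- if (length(dmin) >= 2 && length(dfl) >= 2) {
        suppressWarnings(stats::wilcox.test(dmin, dfl, alternative = "less",
                                            exact = FALSE)$p.value)
      } else NA_real_
      cand_rows[[length(cand_rows) + 1]] <- tibble::tibble(
        chrom = chrom, bin = b - 1L, score = score[b], p = p)
    }
  }
  cand <- dplyr::bind_rows(cand_rows)
  if (nrow(cand) > 1) {
    # collapse candidate runs closer than min_boundary_bins (same chrom)
    cand <- cand[order(cand$chrom, cand$bin), , drop = FALSE]
    grp <- cumsum(c(TRUE, cand$chrom[-1] != cand$chrom[-nrow(cand)] |
                      diff(cand$bin) >= min_boundary_bins))
    cand <- dplyr::slice_min(dplyr::group_by(cand, grp = grp),
                             order_by = .data$score, n = 1,
                             with_ties = FALSE)
    cand <- dplyr::ungroup(cand)[, setdiff(names(cand), "grp")]
  }
  if (nrow(cand) > 0) {
    cand$p[is.na(cand$p)] <- 1
    cand$fdr <- if (fdr_correct) stats::p.adjust(cand$p, "BH") else cand$p
    cand <- cand[cand$fdr <= comparison_p, , drop = FALSE]
  } else {
    cand <- tibble::tibble(chrom = character(), bin = integer(),
                           score = numeric(), p = numeric(), fdr = numeric())
  }
  cand$start <- bin_start(g, cand$bin)
  cand$end <- pmin(cand$start + g$bin_size, chrom_length(g, cand$chrom))
  boundaries <- cand[order(match(cand$chrom, g$chrom_sizes$chrom), cand$bin),
                     c("chrom", "bin", "start", "end", "score", "p", "fdr")]
  domains <- boundaries_to_domains(boundaries, g)
  structure(list(boundaries = tibble::as_tibble(boundaries),
                 domains = domains,
                 scores = dplyr::bind_rows(score_rows),
                 genome = g),
            class = "tad_set")
}

# mean contact in the w x w diamond across each bin (NA near edges/mask)
diamond_score <- function(m, w, mask) {
  n <- nrow(m)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n || mask[i]) next
    rows <- (i - w):(i - 1); cols <- (i + 1):(i + w)
    rows <- rows[!mask[rows]]; cols <- cols[!mask[cols]]
    if (length(rows) == 0 || length(cols) == 0) next
    out[i] <- mean(m[rows, cols, drop = FALSE])
  }
  out
}

diamond_values <- function(m, i, w, mask) {
  n <- nrow(m)
  rows <- (i - w):(i - 1); cols <- (i + 1):(i + w)
  rows <- rows[rows >= 1 & !mask[pmax(rows, 1)]]
  cols <- cols[cols <= n & !mask[pmin(cols, n)]]
  if (length(rows) == 0 || length(cols) == 0) return(numeric())
  as.numeric(m[rows, cols, drop = FALSE])
}

local_extrema <- function(x, minima = TRUE) {
  n <- length(x)
  if (!minima) x <- -x
  out <- integer()
  for (i in 2:(n - 1)) {
    if (is.na(x[i])) next
    l <- x[i - 1]; r <- x[i + 1]
    if ((is.na(l) || x[i] <= l) && (is.na(r) || x[i] <= r) &&
        ((!is.na(l) && x[i] < l) || (!is.na(r) && x[i] < r))) {
      out <- c(out, i)
    }
  }
  out
}

boundaries_to_domains <- function(boundaries, genome) {
  rows <- list()
  for (ci in seq_len(nrow(genome$chrom_sizes))) {
    chrom <- genome$chrom_sizes$chrom[ci]
    b <- boundaries$start[boundaries$chrom == chrom]
    if (length(b) == 0) next
    edges <- sort(unique(c(0, b, genome$chrom_sizes$length[ci])))
    rows[[ci]] <- tibble::tibble(chrom = chrom,
                                 start = edges[-length(edges)],
                                 end = edges[-1])
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
  }
  out
}

#' @export
print.tad_set <- function(x, ...) {
  cat("<tad_set> ", nrow(x$boundaries), " boundaries, ",
      nrow(x$domains), " domains\n", sep = "")
  print(x$boundaries, n = 5)
  invisible(x)
}

#' Fraction of boundaries shared between two TAD sets
#'
#' A boundary in one set is colocalized when the other set has a boundary
#' on the same chromosome within `tolerance_bp`. Reported in both
#' directions, since the two sets need not have equally many boundaries.
#'
#' @param tads_a,tads_b `tad_set` objects on the same genome.
#' @param tolerance_bp Matching tolerance in bp (defaults to one 50-kb bin).
#' @return Tibble with rows `a_in_b` and `b_in_a` and columns `direction`,
#'   `n`, `n_matched`, `fraction`.
#' @export
boundary_colocalization <- function(tads_a, tads_b, tolerance_bp = 50000) {
  ba <- tads_a$boundaries; bb <- tads_b$boundaries
  if (nrow(ba) == 0 || nrow(bb) == 0) {
    stop("empty boundary set", call. = FALSE)
  }
  match_frac <- function(x, y) {
    hit <- vapply(seq_len(nrow(x)), function(i) {
      same <- y$chrom == x$chrom[i]
      any(same & abs(y$start - x$start[i]) <= tolerance_bp)
    }, logical(1))
    c(n = nrow(x), n_matched = sum(hit), fraction = mean(hit))
  }
  ab <- match_frac(ba, bb); ba_ <- match_frac(bb, ba)
  tibble::tibble(direction = c("a_in_b", "b_in_a"),
                 n = unname(c(ab["n"], ba_["n"])),
                 n_matched = unname(c(ab["n_matched"], ba_["n_matched"])),
                 fraction = unname(c(ab["fraction"], ba_["fraction"])))
}
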