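#' Monte-Carlo size-matched shuffle overlap test
#'
#' Tests whether `query_set` overlaps `reference_set` more than expected by
#' chance, mirroring the shuffle-then-intersect strategy used to assess
#' transcription-factor colocalization within enhancer regions. The
#' observed statistic is the number of query intervals overlapping the
#' reference (>= 1 bp). In each of `n_iter` iterations a size-matched
#' random set (same number of intervals, same lengths) is placed uniformly
#' inside the `universe` intervals, without overlap among placed intervals,
#' and the statistic recomputed. The empirical p-value uses the add-one
#' estimator `(r + 1) / (n_iter + 1)` with `r` = iterations at least as
#' extreme as observed, so it is never zero.
#'
#' @param query_set,reference_set,universe Interval tibbles; `universe`
#'   (e.g. H3K27ac-defined enhancer regions) constrains placement and must
#'   total at least twice the summed query length.
#' @param n_iter Number of shuffles (default 10,000).
#' @param seed Mandatory RNG seed for reproducibility.
#' @return Object of class `shuffle_test`: list with `observed`,
#'   `p_value`, `null_counts` (length `n_iter`), `n_iter`, `n_query`.
#' @export
shuffle_overlap_test <- function(query_set, reference_set, universe,
                                 n_iter = 10000, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  query_set <- validate_intervals(query_set, what = "query_set")
  reference_set <- validate_intervals(reference_set, what = "reference_set")
  universe <- validate_intervals(universe, what = "universe")
  stopifnot(n_iter >= 1)
  uni <- merge_intervals(universe)
  lens <- query_set$end - query_set$start
  if (sum(uni$end - uni$start) < 2 * sum(lens)) {
    stop("universe too small: total length must be >= 2x summed query length",
         call. = FALSE)
  }
  layout <- shuffle_layout(uni, lens)
  ref_g <- globalise(reference_set, layout$chrom_offsets)
  ref_m <- merge_global(ref_g)
  obs <- count_overlapping(globalise(query_set, layout$chrom_offsets), ref_m)

  set.seed(seed)
  null_counts <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    placed <- place_size_matched(layout)
    null_counts[it] <- count_overlapping(placed, ref_m)
  }
  p <- (sum(null_counts >= obs) + 1) / (n_iter + 1)
  structure(list(observed = obs, p_value = p, null_counts = null_counts,
                 n_iter = n_iter, n_query = nrow(query_set)),
            class = "shuffle_test")
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat("<shuffle_test> observed ", x$observed, "/", x$n_query,
      " overlapping; empirical p = ", signif(x$p_value, 4),
      " (", x$n_iter, " iterations)\n", sep = "")
  invisible(x)
}

# ---- internal machinery -----------------------------------------------------
# All placement arithmetic happens in a single global coordinate system in
# which chromosomes are laid end to end; universe intervals keep their real
# coordinates via per-chromosome offsets, so overlap counting is exact.

merge_intervals <- function(x) {
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  out <- dplyr::group_by(x, .data$chrom)
  out <- dplyr::mutate(out,
    grp = cumsum(dplyr::lag(cummax(.data$end), default = -Inf) < .data$start))
  out <- dplyr::summarise(dplyr::group_by(out, .data$chrom, .data$grp),
                          start = min(.data$start), end = max(.data$end),
                          .groups = "drop")
  out[order(out$chrom, out$start), c("chrom", "start", "end")]
}

chromosome_offsets <- function(chroms, maxima) {
  off <- cumsum(c(0, utils::head(maxima, -1) + 1))
  stats::setNames(off, chroms)
}

globalise <- function(x, offsets) {
  o <- offsets[x$chrom]
  tibble::tibble(start = x$start + o, end = x$end + o)
}

merge_global <- function(x) {
  x <- x[order(x$start), , drop = FALSE]
  if (nrow(x) == 0) return(x)
  keep_end <- cummax(x$end)
  new_grp <- c(TRUE, x$start[-1] > keep_end[-nrow(x)])
  grp <- cumsum(new_grp)
  last <- which(c(new_grp[-1], TRUE))
  tibble::tibble(start = x$start[new_grp], end = keep_end[last])
}

count_overlapping <- function(q, ref_m) {
  if (nrow(ref_m) == 0) return(0L)
  k <- findInterval(q$start, ref_m$start)
  hit <- (k >= 1 & ifelse(k >= 1, ref_m$end[pmax(k, 1)] > q$start, FALSE)) |
    (k < nrow(ref_m) & ref_m$start[pmin(k + 1, nrow(ref_m))] < q$end)
  sum(hit)
}

# precompute everything reusable across iterations
shuffle_layout <- function(uni, lens) {
  chroms <- unique(uni$chrom)
  maxima <- vapply(chroms, function(ch) max(uni$end[uni$chrom == ch]), 0)
  offsets <- chromosome_offsets(chroms, maxima)
  ug <- globalise(uni, offsets)
  widths <- ug$end - ug$start
  ulens <- sort(unique(lens))
  per_len <- lapply(ulens, function(L) {
    w <- pmax(0, widths - L + 1)
    if (sum(w) == 0) {
      stop("universe has no interval long enough for a query of length ", L,
           call. = FALSE)
    }
    list(cum = cumsum(w), total = sum(w))
  })
  names(per_len) <- as.character(ulens)
  list(uni_global = ug, lens = lens, per_len = per_len,
       chrom_offsets = offsets)
}

# place size-matched intervals uniformly in the universe, rejecting
# self-overlap (re-draw only the conflicting intervals)
place_size_matched <- function(layout) {
  lens <- layout$lens
  n <- length(lens)
  ug <- layout$uni_global
  draw <- function(idx) {
    s <- numeric(length(idx))
    for (L in unique(lens[idx])) {
      sel <- idx[lens[idx] == L]
      pl <- layout$per_len[[as.character(L)]]
      r <- stats::runif(length(sel)) * pl$total
      j <- findInterval(r, pl$cum) + 1L
      off <- r - c(0, pl$cum)[j]
      s[match(sel, idx)] <- ug$start[j] + floor(off)
    }
    s
  }
  start <- draw(seq_len(n))
  end <- start + lens
  for (round in 1:100) {
    ord <- order(start)
    conflict_next <- start[ord][-1] < end[ord][-n]
    if (!any(conflict_next)) {
      return(tibble::tibble(start = start, end = end))
    }
    bad <- unique(ord[c(FALSE, conflict_next)])
    start[bad] <- draw(bad)
    end[bad] <- start[bad] + lens[bad]
  }
  stop("could not place size-matched intervals without self-overlap; ",
       "universe too crowded", call. = FALSE)
}

#' Annotation overlap of a region set versus matched random controls
#'
#' For the query set and `n_controls` size-matched random sets (placed in
#' `universe` exactly as in [shuffle_overlap_test()]), the percentage of
#' intervals overlapping each annotation by at least
#' `min_overlap_fraction` of their own length (the "at least 10% overlap"
#' criterion).
#'
#' @param query_set Interval tibble.
#' @param annotation_sets Named list of interval tibbles.
#' @param universe Interval tibble constraining control placement.
#' @param min_overlap_fraction Required overlap fraction of the query
#'   interval.
#' @param n_controls Number of control sets.
#' @param seed RNG seed.
#' @return Tibble of class `annotation_overlap`: `annotation`,
#'   `query_pct`, `control_mean_pct`, `control_sd_pct`, `n_controls`.
#' @export
matched_control_annotation_overlap <- function(query_set, annotation_sets,
                                               universe,
                                               min_overlap_fraction = 0.10,
                                               n_controls = 100, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  query_set <- validate_intervals(query_set, what = "query_set")
  universe <- validate_intervals(universe, what = "universe")
  stopifnot(is.list(annotation_sets), length(annotation_sets) > 0)
  if (is.null(names(annotation_sets))) {
    names(annotation_sets) <- paste0("annotation_", seq_along(annotation_sets))
  }
  uni <- merge_intervals(universe)
  lens <- query_set$end - query_set$start
  if (sum(uni$end - uni$start) < 2 * sum(lens)) {
    stop("universe too small: total length must be >= 2x summed query length",
         call. = FALSE)
  }
  layout <- shuffle_layout(uni, lens)
  pct_vs <- function(set_local) {
    vapply(annotation_sets, function(ann) {
      100 * mean(overlaps_any(set_local, ann, min_overlap_fraction))
    }, 0)
  }
  degolobalise <- function(g) {
    # map global coordinates back to (chrom, start, end)
    offs <- layout$chrom_offsets
    chrom <- names(offs)[findInterval(g$start, unname(offs))]
    o <- offs[chrom]
    tibble::tibble(chrom = chrom, start = g$start - o, end = g$end - o)
  }
  q_pct <- pct_vs(query_set)
  set.seed(seed)
  ctrl <- base::matrix(0, n_controls, length(annotation_sets))
  for (k in seq_len(n_controls)) {
    placed <- degolobalise(place_size_matched(layout))
    ctrl[k, ] <- pct_vs(placed)
  }
  out <- tibble::tibble(
    annotation = names(annotation_sets),
    query_pct = unname(q_pct),
    control_mean_pct = colMeans(ctrl),
    control_sd_pct = apply(ctrl, 2, stats::sd),
    n_controls = n_controls)
  class(out) <- c("annotation_overlap", class(out))
  out
}
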