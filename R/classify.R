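#' Classify dynamic promoter interactions
#'
#' Implements the two-category view of diet-induced promoter interaction
#' change, plus a static remainder:
#'
#' * **rewired**: the interaction frequency itself differs between
#'   conditions (`p < rewired_p` from the interaction-count test);
#'   `rewired_gained_A` / `rewired_gained_B` by direction of change.
#' * **preformed_activated**: the interaction is *not* significantly
#'   different, but at least one differential acetylation (H3K27ac-style)
#'   peak overlaps its distal (non-bait) end; the condition label follows
#'   the peak's direction.
#' * **static**: everything else.
#'
#' Rewired takes precedence; each interaction receives exactly one class.
#' When differential peaks of both directions overlap a distal end, the
#' peak with the larger absolute log2 fold change decides.
#'
#' @param interactions `capture_interactions` (or any tibble with
#'   `bait_id`, `other_id` and, via `fragments`, locatable distal ends).
#' @param interaction_diffs [nb_count_test()] result whose `unit_id` is
#'   `paste(bait_id, other_id)`; every interaction must be present.
#' @param peaks Peak interval tibble (`chrom`, `start`, `end`, `peak_id`).
#' @param peak_diffs [nb_count_test()] result for the peaks (`unit_id` =
#'   `peak_id`).
#' @param fragments Fragment map locating other ends.
#' @param bait_genes Tibble `bait_id`, `gene_id` linking baits to genes.
#' @param rewired_p Raw-p cutoff for the rewired class.
#' @param min_overlap_fraction Overlap required between distal end and
#'   peak, as a fraction of the distal fragment (0 means >= 1 bp).
#' @return Tibble of class `loop_dynamics`: interaction columns plus
#'   `class`, `interaction_p`, `interaction_log2fc`, `distal_peak_ids`,
#'   `linked_genes`.
#' @export
classify_loop_dynamics <- function(interactions, interaction_diffs, peaks,
                                   peak_diffs, fragments, bait_genes,
                                   rewired_p = 0.001,
                                   min_overlap_fraction = 0) {
  key <- paste(interactions$bait_id, interactions$other_id)
  di <- match(key, interaction_diffs$unit_id)
  if (anyNA(di)) {
    stop("interaction without a differential record: ", key[which(is.na(di))[1]],
         " (test all interactions before classifying)", call. = FALSE)
  }
  ip <- interaction_diffs$p[di]
  ifc <- interaction_diffs$log2fc[di]

  pk <- match(peaks$peak_id, peak_diffs$unit_id)
  if (anyNA(pk)) {
    stop("peak without a differential record: ",
         peaks$peak_id[which(is.na(pk))[1]], call. = FALSE)
  }
  pdir <- peak_diffs$direction[pk]
  pfc <- peak_diffs$log2fc[pk]
  diff_peaks <- peaks[pdir != "ns", , drop = FALSE]
  diff_dir <- pdir[pdir != "ns"]
  diff_fc <- pfc[pdir != "ns"]

  distal <- other_end_intervals(interactions, fragments)
  hits <- overlap_query(distal, diff_peaks, min_overlap_fraction)

  n <- nrow(interactions)
  class <- rep("static", n)
  distal_peaks <- rep("", n)
  rew <- ip < rewired_p
  class[rew] <- ifelse(ifc[rew] > 0, "rewired_gained_A", "rewired_gained_B")
  if (nrow(hits) > 0) {
    by_int <- split(hits$b_index, hits$a_index)
    for (nm in names(by_int)) {
      i <- as.integer(nm)
      js <- by_int[[nm]]
      distal_peaks[i] <- paste(diff_peaks$peak_id[js], collapse = ",")
      if (rew[i]) next
      best <- js[which.max(abs(diff_fc[js]))]
      class[i] <- ifelse(diff_dir[best] == "up_A",
                         "preformed_activated_A", "preformed_activated_B")
    }
  }
  genes <- tapply(bait_genes$gene_id, bait_genes$bait_id,
                  function(g) paste(sort(unique(g)), collapse = ","))
  linked <- as.character(genes[interactions$bait_id])
  linked[is.na(linked)] <- ""
  out <- tibble::as_tibble(interactions)
  out$class <- class
  out$interaction_p <- ip
  out$interaction_log2fc <- ifc
  out$distal_peak_ids <- distal_peaks
  out$linked_genes <- linked
  class(out) <- c("loop_dynamics", class(out))
  out
}

#' Gene-level table of loop-dynamics classes
#'
#' One row per (gene, class) over all classified interactions, deduplicated
#' within class; a gene may appear under several classes. Differential
#' expression status is attached when a DEG table is supplied.
#'
#' @param records [classify_loop_dynamics()] output.
#' @param degs Optional [nb_count_test()] gene result (`unit_id` =
#'   gene id) or any tibble with `unit_id`/`gene_id` and `direction`.
#' @param drop_static Drop the static class from the table (default keeps
#'   only dynamic classes, the objects of interest).
#' @return Tibble `gene_id`, `class`, `n_loops`, `de_status`.
#' @export
link_dynamics_to_genes <- function(records, degs = NULL, drop_static = TRUE) {
  rows <- records[records$linked_genes != "", c("class", "linked_genes")]
  if (drop_static) rows <- rows[rows$class != "static", , drop = FALSE]
  long <- tidyr::separate_rows(rows, "linked_genes", sep = ",")
  names(long)[names(long) == "linked_genes"] <- "gene_id"
  out <- dplyr::summarise(dplyr::group_by(long, .data$gene_id, .data$class),
                          n_loops = dplyr::n(), .groups = "drop")
  out$de_status <- NA_character_
  if (!is.null(degs)) {
    idc <- if ("unit_id" %in% names(degs)) "unit_id" else "gene_id"
    i <- match(out$gene_id, degs[[idc]])
    out$de_status <- ifelse(is.na(i), "ns", degs$direction[i])
  }
  out[order(out$gene_id, out$class), ]
}
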