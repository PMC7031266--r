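#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. U is computed from midrank sums (ties allowed).
#' For small samples (`n1 + n2 <= 14`) the p-value is obtained by
#' exhaustive enumeration of all group assignments of the pooled values,
#' counting assignments whose U is at least as far from the null mean
#' `n1 n2 / 2` as the observed one; this handles ties exactly. For larger
#' samples a normal approximation with tie and continuity correction is
#' used. Identical samples give p = 1.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest `n1 + n2` for exhaustive enumeration.
#' @return One-row tibble: `u`, `p_value`, `n_x`, `n_y`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney <- function(x, y, exact_max = 14) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (stats::sd(pooled) == 0 || isTRUE(all.equal(stats::var(pooled), 0))) {
    return(tibble::tibble(u = u, p_value = 1, n_x = n1, n_y = n2,
                          method = "degenerate"))
  }
  if (n1 + n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    us <- colSums(base::matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  tibble::tibble(u = u, p_value = p, n_x = n1, n_y = n2, method = method)
}

#' TPM expression categories
#'
#' The four-level expression binning used throughout the
#' expression/interaction comparisons: `TPM = 0`, `(0, 1]`, `(1, 10]`,
#' `> 10`.
#'
#' @param tpm Non-negative numeric vector.
#' @return Ordered factor with levels `"0"`, `"(0,1]"`, `"(1,10]"`,
#'   `">10"`.
#' @export
tpm_bin <- function(tpm) {
  stopifnot(all(tpm >= 0, na.rm = TRUE))
  lab <- dplyr::case_when(
    tpm == 0 ~ "0",
    tpm <= 1 ~ "(0,1]",
    tpm <= 10 ~ "(1,10]",
    TRUE ~ ">10")
  factor(lab, levels = c("0", "(0,1]", "(1,10]", ">10"), ordered = TRUE)
}

#' Interaction count per gene as a function of expression level
#'
#' Counts promoter interactions per gene (via bait-to-gene linkage), bins
#' genes by TPM category, and tests adjacent categories with
#' [mann_whitney()] on per-gene loop counts. Recovers the positive
#' association between promoter interaction number and expression.
#'
#' @param expression Tibble with `gene_id` and `tpm`.
#' @param gene_loops Tibble with `gene_id` (one row per interaction per
#'   gene), e.g. exploded from `linked_genes`; genes absent here count 0
#'   loops.
#' @return Object of class `expression_loops`: list with `genes` (per-gene
#'   tibble), `summary` (per-bin medians), `tests` (adjacent-bin p-values).
#' @export
expression_by_loop_count <- function(expression, gene_loops) {
  stopifnot(all(c("gene_id", "tpm") %in% names(expression)))
  nl <- table(gene_loops$gene_id)
  genes <- tibble::tibble(
    gene_id = expression$gene_id,
    tpm = expression$tpm,
    tpm_bin = tpm_bin(expression$tpm),
    n_loops = as.numeric(nl[expression$gene_id]))
  genes$n_loops[is.na(genes$n_loops)] <- 0
  summ <- dplyr::summarise(dplyr::group_by(genes, .data$tpm_bin),
                           n_genes = dplyr::n(),
                           median_loops = stats::median(.data$n_loops),
                           mean_loops = mean(.data$n_loops),
                           .groups = "drop")
  levs <- levels(genes$tpm_bin)
  tests <- list()
  for (k in seq_len(length(levs) - 1)) {
    a <- genes$n_loops[genes$tpm_bin == levs[k]]
    b <- genes$n_loops[genes$tpm_bin == levs[k + 1]]
    if (length(a) == 0 || length(b) == 0) {
      warning("empty TPM bin ", levs[k], " or ", levs[k + 1],
              "; test skipped", call. = FALSE)
      next
    }
    mw <- mann_whitney(a, b)
    tests[[length(tests) + 1]] <- tibble::tibble(
      bin_low = levs[k], bin_high = levs[k + 1],
      u = mw$u, p_value = mw$p_value)
  }
  structure(list(genes = genes, summary = summ,
                 tests = dplyr::bind_rows(tests)),
            class = "expression_loops")
}

#' Gene strata by loop count and distal-end acetylation
#'
#' Splits genes into the seven strata used for the enhancer-activity
#' analysis: no interaction; 1, 2-5 or >5 interactions, each with or
#' without at least one acetylated (H3K27ac-overlapping) distal end.
#'
#' @param gene_loops Tibble with `gene_id` and logical `distal_ac` (one row
#'   per interaction per gene).
#' @param all_genes Character vector of every gene (so zero-loop genes are
#'   represented).
#' @return Tibble `gene_id`, `n_loops`, `any_ac`, `stratum`.
#' @export
loop_count_strata <- function(gene_loops, all_genes) {
  agg <- dplyr::summarise(dplyr::group_by(gene_loops, .data$gene_id),
                          n_loops = dplyr::n(),
                          any_ac = any(.data$distal_ac), .groups = "drop")
  out <- tibble::tibble(gene_id = all_genes)
  i <- match(out$gene_id, agg$gene_id)
  out$n_loops <- ifelse(is.na(i), 0, agg$n_loops[i])
  out$any_ac <- ifelse(is.na(i), FALSE, agg$any_ac[i])
  band <- dplyr::case_when(
    out$n_loops == 0 ~ "0",
    out$n_loops == 1 ~ "1",
    out$n_loops <= 5 ~ "2-5",
    TRUE ~ ">5")
  out$stratum <- ifelse(band == "0", "no_interaction",
                        paste0(band, ifelse(out$any_ac, "_ac", "_no_ac")))
  out
}

#' Expression by loop-count/acetylation strata
#'
#' Within each loop-count band, compares TPM of genes whose interactions
#' have an acetylated distal end against those without, with
#' [mann_whitney()].
#'
#' @param expression Tibble `gene_id`, `tpm`.
#' @param strata [loop_count_strata()] output.
#' @return Object of class `expression_strata`: list with `genes`,
#'   `summary` (per-stratum medians), `tests` (with vs without per band).
#' @export
expression_by_strata <- function(expression, strata) {
  genes <- dplyr::inner_join(tibble::as_tibble(expression[, c("gene_id", "tpm")]),
                             strata, by = "gene_id")
  summ <- dplyr::summarise(dplyr::group_by(genes, .data$stratum),
                           n_genes = dplyr::n(),
                           median_tpm = stats::median(.data$tpm),
                           .groups = "drop")
  tests <- list()
  for (band in c("1", "2-5", ">5")) {
    a <- genes$tpm[genes$stratum == paste0(band, "_ac")]
    b <- genes$tpm[genes$stratum == paste0(band, "_no_ac")]
    if (length(a) == 0 || length(b) == 0) {
      warning("empty stratum in band ", band, "; test skipped", call. = FALSE)
      next
    }
    mw <- mann_whitney(a, b)
    tests[[length(tests) + 1]] <- tibble::tibble(
      band = band, median_ac = stats::median(a),
      median_no_ac = stats::median(b), u = mw$u, p_value = mw$p_value)
  }
  structure(list(genes = genes, summary = summ,
                 tests = dplyr::bind_rows(tests)),
            class = "expression_strata")
}

#' Assign sites to the nearest TSS within a window
#'
#' Each site (by midpoint) is assigned to the nearest TSS within
#' `+/- window_bp`; farther sites stay unassigned. Equidistant ties break
#' deterministically to the smaller `gene_id`.
#'
#' @param sites Interval tibble.
#' @param expression Tibble with `gene_id`, `chrom`, `tss`.
#' @param window_bp Assignment window (default 50 kb).
#' @return `sites` with added `gene_id` (NA when unassigned) and
#'   `tss_distance`.
#' @export
nearest_tss_assignment <- function(sites, expression, window_bp = 5e4) {
  sites <- validate_intervals(sites, what = "sites")
  mid <- (sites$start + sites$end) / 2
  gene_id <- rep(NA_character_, nrow(sites))
  dist <- rep(NA_real_, nrow(sites))
  for (chrom in unique(sites$chrom)) {
    tss <- expression[expression$chrom == chrom, , drop = FALSE]
    si <- which(sites$chrom == chrom)
    if (nrow(tss) == 0) next
    ord <- order(tss$tss, tss$gene_id)
    tss <- tss[ord, , drop = FALSE]
    for (s in si) {
      d <- abs(tss$tss - mid[s])
      dmin <- min(d)
      if (dmin > window_bp) next
      cand <- which(d <= dmin + 1e-9)
      pick <- cand[order(tss$gene_id[cand])][1]
      gene_id[s] <- tss$gene_id[pick]
      dist[s] <- dmin
    }
  }
  out <- tibble::as_tibble(sites)
  out$gene_id <- gene_id
  out$tss_distance <- dist
  out
}

#' Total energy expenditure from indirect calorimetry
#'
#' `EE (kcal/h) = 3.941 x VO2 (l/h) + 1.106 x VCO2 (l/h)` — the standard
#' open-circuit calorimetry equation used by metabolic-cage systems.
#'
#' @param vo2,vco2 Oxygen consumption and carbon dioxide production in l/h
#'   (non-negative, vectorised).
#' @return Energy expenditure in kcal/h.
#' @export
#' @examples
#' energy_expenditure(1, 0)  # 3.941
energy_expenditure <- function(vo2, vco2) {
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE)) {
    stop("VO2 and VCO2 must be non-negative", call. = FALSE)
  }
  3.941 * vo2 + 1.106 * vco2
}
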