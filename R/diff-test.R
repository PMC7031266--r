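#' Exact negative binomial test for differential counts
#'
#' A two-condition differential test for small replicate numbers
#' (typically n = 2/group): counts are library-size normalised by
#' total-count scaling to the mean library size, a single common dispersion
#' is estimated by method of moments pooled over units (floored at 0.01),
#' and each unit is tested with an exact conditional NB test: given the
#' summed normalised counts of the two conditions, the conditional
#' distribution of the condition-A sum is negative hypergeometric, and the
#' two-sided p-value is the total probability of outcomes no more likely
#' than the observed one. BH-FDR is computed across units.
#'
#' Direction calls use the convention of the downstream analyses:
#' interactions are called on raw p (`p < 0.001`), ChIP peaks on
#' `FDR < 0.05` and fold change `> 1.5`, genes on `FDR < 0.05` and fold
#' change `> 1.2`. `up_A` means higher in the first condition level.
#'
#' @param counts A data frame with a `unit_id` column and one numeric
#'   column per replicate library, or a plain numeric matrix with rownames.
#' @param condition Character/factor vector, one entry per count column,
#'   with exactly two levels; the first level is condition A.
#' @param type One of `"interaction"`, `"peak"`, `"gene"`, or `"custom"`.
#' @param alpha,fc_min Thresholds used when `type = "custom"`; `alpha` is
#'   applied to raw p when `use_fdr = FALSE`, else to FDR.
#' @param use_fdr Whether `alpha` applies to FDR (custom type only).
#' @param dispersion Optional fixed common dispersion (else MoM, floor
#'   0.01).
#' @return Tibble of class `differential_result`: `unit_id`, `log2fc`
#'   (A over B), `p`, `fdr`, `direction` in `{"up_A", "up_B", "ns"}`.
#'   Attribute `dispersion` records the dispersion used.
#' @export
nb_count_test <- function(counts, condition,
                          type = c("interaction", "peak", "gene", "custom"),
                          alpha = NULL, fc_min = NULL, use_fdr = TRUE,
                          dispersion = NULL) {
  type <- match.arg(type)
  if (is.data.frame(counts)) {
    stopifnot("unit_id" %in% names(counts))
    unit_id <- as.character(counts$unit_id)
    mat <- as.matrix(counts[, setdiff(names(counts), "unit_id"), drop = FALSE])
  } else {
    mat <- as.matrix(counts)
    unit_id <- rownames(mat)
    if (is.null(unit_id)) unit_id <- as.character(seq_len(nrow(mat)))
  }
  storage.mode(mat) <- "double"
  if (any(mat < 0) || any(mat != round(mat))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  condition <- as.character(condition)
  lev <- unique(condition)
  if (length(condition) != ncol(mat) || length(lev) != 2) {
    stop("`condition` must give exactly two conditions, one per count column",
         call. = FALSE)
  }
  a_cols <- which(condition == lev[1]); b_cols <- which(condition == lev[2])
  na <- length(a_cols); nb <- length(b_cols)

  libsize <- colSums(mat)
  if (any(libsize == 0)) stop("a library has zero total counts", call. = FALSE)
  norm <- sweep(mat, 2, mean(libsize) / libsize, `*`)

  if (is.null(dispersion)) {
    dispersion <- max(0.01, mom_common_dispersion(norm, a_cols, b_cols))
  }

  ya <- round(rowSums(norm[, a_cols, drop = FALSE]))
  yb <- round(rowSums(norm[, b_cols, drop = FALSE]))
  p <- nb_exact_p(ya, yb, size_a = na / dispersion, size_b = nb / dispersion)
  log2fc <- log2((ya / na + 0.5) / (yb / nb + 0.5))
  fdr <- stats::p.adjust(p, "BH")

  thr <- switch(type,
    interaction = list(alpha = 0.001, fc = 1, fdr = FALSE),
    peak = list(alpha = 0.05, fc = 1.5, fdr = TRUE),
    gene = list(alpha = 0.05, fc = 1.2, fdr = TRUE),
    custom = list(alpha = if (is.null(alpha)) 0.05 else alpha,
                  fc = if (is.null(fc_min)) 1 else fc_min,
                  fdr = use_fdr))
  crit <- if (thr$fdr) fdr < thr$alpha else p < thr$alpha
  crit <- crit & (2^abs(log2fc) > thr$fc | thr$fc <= 1)
  direction <- ifelse(!crit, "ns", ifelse(log2fc > 0, "up_A", "up_B"))
  out <- tibble::tibble(unit_id = unit_id, log2fc = log2fc, p = p, fdr = fdr,
                        direction = direction)
  attr(out, "dispersion") <- dispersion
  attr(out, "type") <- type
  class(out) <- c("differential_result", class(out))
  out
}

# method-of-moments common dispersion pooled over units, on the normalised
# scale: for each unit and condition with >= 2 replicates,
# phi_i = (s^2 - m) / m^2; pooled as a m^2-weighted mean so high-count
# units (where phi is identifiable) dominate.
mom_common_dispersion <- function(norm, a_cols, b_cols) {
  num <- 0; den <- 0
  for (cols in list(a_cols, b_cols)) {
    if (length(cols) < 2) next
    m <- rowMeans(norm[, cols, drop = FALSE])
    v <- apply(norm[, cols, drop = FALSE], 1, stats::var)
    ok <- m > 0
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  if (den <= 0) return(0)
  num / den
}

# exact conditional two-sided p for NB sums: given s = ya + yb, the
# conditional law of ya is negative hypergeometric with parameters
# (size_a, size_b); p = sum of conditional probabilities <= P(observed).
nb_exact_p <- function(ya, yb, size_a, size_b) {
  n <- length(ya)
  p <- numeric(n)
  s_all <- ya + yb
  for (i in seq_len(n)) {
    s <- s_all[i]
    if (s == 0) { p[i] <- 1; next }
    k <- 0:s
    logp <- lgamma(k + size_a) - lgamma(k + 1) +
      lgamma(s - k + size_b) - lgamma(s - k + 1)
    logp <- logp - max(logp)
    pr <- exp(logp); pr <- pr / sum(pr)
    p[i] <- min(1, sum(pr[pr <= pr[ya[i] + 1] * (1 + 1e-10)]))
  }
  p
}
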