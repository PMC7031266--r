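#' Score promoter-capture interactions against a distance-decay background
#'
#' Each candidate bait/other-end pair is scored as `-log10 p`, where `p` is
#' the upper-tail probability of its (replicate-summed) count under a
#' negative binomial background. The background mean for a pair at distance
#' `d` is `s_bait * decay(d)`: `decay` is the pooled mean count per
#' *possible* cis fragment pair per log-spaced distance stratum (zeros
#' included, computed from the fragment map), and `s_bait` scales for
#' bait-to-bait capture efficiency (observed bait total over its expected
#' total). A single global dispersion is estimated by a leverage-corrected
#' method of moments over all possible pairs (fitting one scale per bait
#' absorbs part of the count variance, concentrated on the high-mean
#' short-range pairs; the correction restores it), and each bait's scale
#' uncertainty is propagated into the test so background estimation error
#' cannot masquerade as signal. Pairs with score >= `score_min` are
#' flagged significant — the analogue of an interaction-score cutoff of 5.
#'
#' @param counts Data frame with columns `bait_id`, `other_id` and one or
#'   more count columns (`count` or `count_*` replicate columns, summed for
#'   scoring). Only cis pairs within `span_max` are scored.
#' @param fragments Fragment map: tibble `chrom`, `start`, `end`,
#'   `fragment_id` covering the genome.
#' @param baits Character vector of bait fragment ids (defaults to the
#'   baits present in `counts`).
#' @param score_min Significance cutoff on `-log10 p`.
#' @param span_max Maximum cis span considered part of the background
#'   model.
#' @param dispersion Optional fixed NB dispersion; estimated when `NULL`.
#' @param n_strata Number of log-spaced distance strata for the decay
#'   estimate.
#' @return Tibble of class `capture_interactions`: `bait_id`, `other_id`,
#'   `chrom`, `bait_mid`, `other_mid`, `span`, `count`, `expected`,
#'   `score`, `significant`, plus any replicate count columns carried
#'   through. Attribute `dispersion` records the dispersion used.
#' @export
score_capture_interactions <- function(counts, fragments, baits = NULL,
                                       score_min = 5, span_max = 1e6,
                                       dispersion = NULL, n_strata = 25) {
  stopifnot(all(c("bait_id", "other_id") %in% names(counts)))
  cnt_cols <- count_columns(counts)
  counts$count_total <- rowSums(counts[, cnt_cols, drop = FALSE])
  frag <- fragments
  frag$mid <- (frag$start + frag$end) / 2
  fi <- match(counts$bait_id, frag$fragment_id)
  fj <- match(counts$other_id, frag$fragment_id)
  if (anyNA(fi) || anyNA(fj)) {
    stop("counts reference fragment ids missing from the fragment map",
         call. = FALSE)
  }
  cis <- frag$chrom[fi] == frag$chrom[fj]
  span <- abs(frag$mid[fj] - frag$mid[fi])
  in_range <- cis & span <= span_max & counts$bait_id != counts$other_id
  obs <- counts[in_range, , drop = FALSE]
  obs$span <- span[in_range]
  obs$chrom <- frag$chrom[fi][in_range]
  obs$bait_mid <- frag$mid[fi][in_range]
  obs$other_mid <- frag$mid[fj][in_range]

  if (is.null(baits)) baits <- unique(obs$bait_id)
  bait_tot <- tapply(obs$count_total, obs$bait_id, sum)
  zero_baits <- setdiff(baits, names(bait_tot)[bait_tot > 0])
  if (length(zero_baits) > 0) {
    warning(length(zero_baits), " bait(s) with zero total counts dropped",
            call. = FALSE)
    baits <- setdiff(baits, zero_baits)
    obs <- obs[obs$bait_id %in% baits, , drop = FALSE]
  }
  if (nrow(obs) == 0) stop("no scorable cis pairs", call. = FALSE)

  # distance strata: log-spaced edges over [min_span, span_max]
  lo <- max(1, min(obs$span))
  edges <- unique(c(0, exp(seq(log(lo), log(span_max), length.out = n_strata)), Inf))
  obs$stratum <- findInterval(obs$span, edges, rightmost.closed = FALSE)

  # possible cis pairs per (bait, stratum): count fragments at each distance
  # from each bait, pooled
  poss <- possible_pairs_by_stratum(frag, baits, edges, span_max)

  # robust background fit: a first pass over all pairs, then refits that
  # exclude strongly enriched pairs (true interactions) so the decay curve
  # and the dispersion describe the background, not the signal
  fit_background <- function(exclude) {
    inc <- !exclude
    obs_sum <- tapply(obs$count_total[inc], obs$stratum[inc], sum)
    n_exc <- tapply(as.numeric(exclude), obs$stratum, sum)
    decay <- numeric(length(edges) - 1)
    decay[as.integer(names(obs_sum))] <- as.numeric(obs_sum)
    tot_poss <- poss$total_by_stratum
    tot_poss[as.integer(names(n_exc))] <-
      tot_poss[as.integer(names(n_exc))] - as.numeric(n_exc)
    decay <- ifelse(tot_poss > 0, decay / pmax(tot_poss, 1), 0)
    bait_tot_inc <- tapply(obs$count_total[inc], obs$bait_id[inc], sum)
    exp_bait <- as.numeric(poss$by_bait %*% decay)
    names(exp_bait) <- rownames(poss$by_bait)
    # expected totals are barely affected by the few excluded pairs
    s_bait <- as.numeric(bait_tot_inc[names(exp_bait)]) / pmax(exp_bait, 1e-12)
    s_bait[is.na(s_bait)] <- 1
    names(s_bait) <- names(exp_bait)
    # smooth the decay within strata: log-log interpolation across stratum
    # mean log-spans, so a pair's expected count follows the continuous
    # decay curve rather than a step function
    mid <- tapply(log(obs$span), obs$stratum, mean)
    ks <- as.integer(names(mid))
    ok_k <- decay[ks] > 0
    if (sum(ok_k) >= 2) {
      xs <- as.numeric(mid[ok_k]); ys <- log(decay[ks[ok_k]])
      lx <- log(obs$span)
      decay_pair <- exp(stats::approx(xs, ys, xout = lx, rule = 2)$y)
      # extrapolate with the end slopes: the decay is steepest at short
      # range, where flat extrapolation would underestimate the expectation
      m <- length(xs)
      lo <- lx < xs[1]; hi <- lx > xs[m]
      if (any(lo)) {
        s1 <- (ys[2] - ys[1]) / (xs[2] - xs[1])
        decay_pair[lo] <- exp(ys[1] + s1 * (lx[lo] - xs[1]))
      }
      if (any(hi)) {
        s2 <- (ys[m] - ys[m - 1]) / (xs[m] - xs[m - 1])
        decay_pair[hi] <- exp(ys[m] + s2 * (lx[hi] - xs[m]))
      }
    } else {
      decay_pair <- decay[obs$stratum]
    }
    mu <- pmax(s_bait[obs$bait_id] * decay_pair, 1e-9)

    # per-bait moment sums sum(mu), sum(mu^2), sum(mu^3) over all possible
    # pairs: per-pair fitted means for the observed pairs, stratum-level
    # means for the genuinely unobserved (zero-count) remainder
    b_ids <- rownames(poss$by_bait)
    sb <- s_bait[b_ids]
    bf <- factor(obs$bait_id, levels = b_ids)
    n_obs_bk <- table(bf, factor(obs$stratum, levels = seq_along(decay)))
    nz <- pmax(poss$by_bait - unclass(n_obs_bk), 0)
    bait_sum <- function(x) {
      out <- tapply(x, bf, sum)
      out[is.na(out)] <- 0
      as.numeric(out)
    }
    m1 <- bait_sum(mu) + sb * as.numeric(nz %*% decay)
    m2o <- bait_sum(mu^2)
    m2 <- m2o + sb^2 * as.numeric(nz %*% decay^2)
    m3 <- bait_sum(mu^3) + sb^3 * as.numeric(nz %*% decay^3)
    names(m1) <- names(m2) <- names(m3) <- b_ids

    phi <- dispersion
    if (is.null(phi)) {
      # residual sum of squares per bait: observed pairs directly, plus
      # mu^2 for every unobserved pair (their count is zero)
      num2 <- bait_sum(ifelse(inc, (obs$count_total - mu)^2, 0)) +
        (m2 - m2o)
      # leverage correction: fitting one scale per bait from its own total
      # removes part of the variance, concentrated on high-mean pairs.
      # With w_i = mu_i/sum(mu), E[sum (x - mu_hat)^2] =
      # A(1 + C) - 2B, where A = sum sigma^2, B = sum w sigma^2,
      # C = sum w^2; invert with plug-in sigma^2 = mu + phi mu^2.
      phi <- 0.0
      for (it in 1:3) {
        B <- (m2 + phi * m3) / pmax(m1, 1e-12)
        C <- m2 / pmax(m1, 1e-12)^2
        A <- (num2 + 2 * B) / (1 + C)
        phi <- max(0, sum(A - m1) / max(sum(m2), 1e-12))
      }
    }
    # relative variance of each bait's fitted scale, propagated into the
    # test below so background uncertainty cannot masquerade as signal
    v_bait <- (m1 + phi * m2) / pmax(m1, 1e-12)^2
    list(mu = mu, phi = phi, v_bait = v_bait)
  }
  tail_p <- function(fit) {
    size <- 1 / pmax(fit$phi + fit$v_bait[obs$bait_id], 1e-12)
    stats::pnbinom(obs$count_total - 1, mu = fit$mu, size = size,
                   lower.tail = FALSE)
  }
  # refit twice, excluding pairs that are extreme outliers under the current
  # fit (p < 1e-6): genuine interactions are far beyond this, while on pure
  # background data essentially nothing is trimmed, so the dispersion
  # estimate stays unbiased
  fit <- fit_background(exclude = rep(FALSE, nrow(obs)))
  for (pass in 1:2) {
    exclude <- tail_p(fit) < 1e-6
    fit <- fit_background(exclude)
  }
  mu <- fit$mu
  dispersion <- fit$phi
  p <- tail_p(fit)
  obs$expected <- mu
  obs$score <- -log10(pmax(p, 1e-300))
  obs$significant <- obs$score >= score_min
  out <- obs[, c("bait_id", "other_id", "chrom", "bait_mid", "other_mid",
                 "span", cnt_cols, "count_total", "expected", "score",
                 "significant")]
  attr(out, "dispersion") <- dispersion
  attr(out, "score_min") <- score_min
  class(out) <- c("capture_interactions", class(out))
  out
}

count_columns <- function(counts) {
  cc <- grep("^count($|_)", names(counts), value = TRUE)
  cc <- setdiff(cc, "count_total")
  if (length(cc) == 0) stop("no count column(s) found", call. = FALSE)
  cc
}

# number of possible cis other-end fragments per distance stratum per bait
possible_pairs_by_stratum <- function(frag, baits, edges, span_max) {
  n_str <- length(edges) - 1
  by_bait <- base::matrix(0, nrow = length(baits), ncol = n_str,
                          dimnames = list(baits, NULL))
  for (chrom in unique(frag$chrom)) {
    f <- frag[frag$chrom == chrom, , drop = FALSE]
    mids <- sort(f$mid)
    b_here <- baits[baits %in% f$fragment_id]
    if (length(b_here) == 0) next
    bm <- f$mid[match(b_here, f$fragment_id)]
    for (k in seq_len(n_str)) {
      lo <- edges[k]; hi <- min(edges[k + 1], span_max)
      if (lo >= hi) next
      # fragments with lo < |mid - bm| <= hi, excluding the bait itself
      cnt <- (findInterval(bm + hi, mids) - findInterval(bm + lo, mids)) +
        (findInterval(bm - lo - 1e-9, mids) - findInterval(bm - hi - 1e-9, mids))
      by_bait[b_here, k] <- by_bait[b_here, k] + cnt
    }
  }
  list(by_bait = by_bait, total_by_stratum = colSums(by_bait))
}

#' Keep cis interactions within the span limit
#'
#' Drops trans pairs and pairs spanning more than `span_max` (a span of
#' exactly `span_max` is retained). Idempotent.
#'
#' @param interactions A data frame with `chrom` per end (`chrom` +
#'   `bait_mid`/`other_mid`, as produced by
#'   [score_capture_interactions()]), or explicit `chrom1`/`chrom2` and
#'   `span` columns.
#' @param span_max Maximum span in bp.
#' @return The filtered tibble, same class.
#' @export
filter_cis <- function(interactions, span_max = 1e6) {
  if (all(c("chrom1", "chrom2") %in% names(interactions))) {
    keep <- interactions$chrom1 == interactions$chrom2
  } else {
    keep <- rep(TRUE, nrow(interactions))  # single-chrom representation is cis
  }
  if (!"span" %in% names(interactions)) {
    stop("interactions need a `span` column", call. = FALSE)
  }
  keep <- keep & interactions$span <= span_max
  interactions[keep, , drop = FALSE]
}

#' Descriptive comparison of two interaction sets
#'
#' Computes the cross-condition sharing (identical bait/other-end fragment
#' pairs), span summaries, the promoter-promoter fraction (other end
#' overlapping any promoter window), and optionally the capture efficiency
#' (fraction of raw di-tags with at least one end in a bait fragment).
#'
#' @param interactions_a,interactions_b Filtered `capture_interactions`.
#' @param promoters Promoter interval tibble (see [promoter_regions()]).
#' @param fragments Fragment map (needed to locate other ends).
#' @param pairs_a,pairs_b Optional raw valid-pair tibbles for capture
#'   efficiency.
#' @param bait_intervals Optional interval tibble of bait fragments
#'   (required for capture efficiency).
#' @return A list of class `interaction_summary` with elements `per_set`
#'   (tibble of per-set statistics) and `shared` (tibble with sharing
#'   fractions in both directions).
#' @export
describe_interactions <- function(interactions_a, interactions_b, promoters,
                                  fragments, pairs_a = NULL, pairs_b = NULL,
                                  bait_intervals = NULL) {
  key <- function(x) paste(x$bait_id, x$other_id)
  ka <- key(interactions_a); kb <- key(interactions_b)
  shared <- tibble::tibble(
    direction = c("a_in_b", "b_in_a"),
    n = c(length(ka), length(kb)),
    n_shared = c(sum(ka %in% kb), sum(kb %in% ka)),
    fraction = c(mean(ka %in% kb), mean(kb %in% ka)))

  per_set <- function(x, pairs, label) {
    oe <- other_end_intervals(x, fragments)
    pp <- mean(overlaps_any(oe, promoters))
    ce <- NA_real_
    if (!is.null(pairs) && !is.null(bait_intervals)) {
      e1 <- tibble::tibble(chrom = pairs$chrom1, start = pairs$pos1,
                           end = pairs$pos1 + 1)
      e2 <- tibble::tibble(chrom = pairs$chrom2, start = pairs$pos2,
                           end = pairs$pos2 + 1)
      ce <- mean(overlaps_any(e1, bait_intervals) |
                   overlaps_any(e2, bait_intervals))
    }
    tibble::tibble(set = label, n = nrow(x), span_mean = mean(x$span),
                   span_median = stats::median(x$span),
                   span_q80 = stats::quantile(x$span, 0.8, names = FALSE),
                   promoter_promoter_fraction = pp, capture_efficiency = ce)
  }
  out <- list(per_set = dplyr::bind_rows(per_set(interactions_a, pairs_a, "A"),
                                         per_set(interactions_b, pairs_b, "B")),
              shared = shared)
  class(out) <- "interaction_summary"
  out
}

other_end_intervals <- function(interactions, fragments) {
  i <- match(interactions$other_id, fragments$fragment_id)
  tibble::tibble(chrom = fragments$chrom[i], start = fragments$start[i],
                 end = fragments$end[i])
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat("<interaction_summary>\n")
  print(x$per_set)
  print(x$shared)
  invisible(x)
}
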