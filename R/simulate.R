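#' Simulate a genome scaffold: chromosomes, restriction fragments, genes
#'
#' Desk-scale genome for pipeline testing: chromosomes of fixed length,
#' restriction fragments with exponentially distributed lengths (mean
#' `fragment_mean_bp`, as for a 6-cutter) tiling each chromosome exactly,
#' and genes placed with a minimum spacing. Deterministic under `seed`.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param fragment_mean_bp Mean restriction-fragment length.
#' @param n_genes Total number of genes.
#' @param min_gene_spacing_bp Minimum TSS spacing.
#' @param seed RNG seed.
#' @return List with `chrom_sizes` (tibble), `fragments` (tibble `chrom`,
#'   `start`, `end`, `fragment_id`) and `genes` (tibble `gene_id`, `chrom`,
#'   `tss`, `strand`, `length`).
#' @export
simulate_genome <- function(n_chrom = 2, chrom_length = 2e7,
                            fragment_mean_bp = 4000, n_genes = 1500,
                            min_gene_spacing_bp = 10000, seed = 1) {
  stopifnot(n_chrom >= 1, chrom_length >= 5e6)
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  chrom_sizes <- tibble::tibble(chrom = chroms, length = chrom_length)

  frag_rows <- list()
  fid <- 0L
  for (ch in chroms) {
    pos <- 0
    starts <- numeric(0)
    # draw in blocks until the chromosome is covered
    while (pos < chrom_length) {
      lens <- pmax(500, round(stats::rexp(2000, 1 / fragment_mean_bp)))
      starts <- c(starts, pos + cumsum(c(0, lens[-length(lens)])))
      pos <- pos + sum(lens)
    }
    starts <- starts[starts < chrom_length]
    ends <- c(starts[-1], chrom_length)
    n <- length(starts)
    frag_rows[[ch]] <- tibble::tibble(
      chrom = ch, start = starts, end = ends,
      fragment_id = sprintf("%s_f%05d", ch, seq_len(n)))
  }
  fragments <- dplyr::bind_rows(frag_rows)

  per_chrom <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
  gene_rows <- list()
  g0 <- 0L
  for (k in seq_len(n_chrom)) {
    n <- per_chrom[k]
    slots <- floor((chrom_length - 2 * min_gene_spacing_bp) / min_gene_spacing_bp)
    if (n > slots) stop("cannot place ", n, " genes with spacing ",
                        min_gene_spacing_bp, call. = FALSE)
    at <- sort(sample.int(slots, n)) * min_gene_spacing_bp
    jitter <- floor(stats::runif(n, 0, min_gene_spacing_bp / 2))
    gene_rows[[k]] <- tibble::tibble(
      gene_id = sprintf("g%05d", g0 + seq_len(n)),
      chrom = chroms[k],
      tss = at + jitter,
      strand = sample(c("+", "-"), n, replace = TRUE),
      length = round(stats::runif(n, 1000, 20000)))
    g0 <- g0 + n
  }
  list(chrom_sizes = chrom_sizes, fragments = fragments,
       genes = dplyr::bind_rows(gene_rows))
}

#' Plant chromatin architecture: compartments, TAD boundaries, loops
#'
#' Boundaries are laid down first (domain sizes uniform within +/-25% of
#' `domain_mean_bp`, snapped to bins); compartment labels alternate in
#' blocks of roughly `compartment_block_bp`, switching only at planted TAD
#' boundaries (compartment transitions co-occur with domain boundaries, as
#' in real genomes, so the two structures do not create spurious extra
#' boundaries for each other). Loops connect two same-compartment anchor
#' bins at spans within `loop_span_range`, kept at least 3 bins apart from
#' one another.
#'
#' @param genome Output of [simulate_genome()].
#' @param bin_size Matrix resolution the truth is expressed at.
#' @param domain_mean_bp Mean planted TAD size.
#' @param compartment_block_bp Approximate compartment block size.
#' @param n_loops_per_chrom Planted loops per chromosome.
#' @param loop_enrichment Contact enrichment factor at loop pixels.
#' @param loop_span_range Span range (bp) for planted loops.
#' @param seed RNG seed.
#' @return List of class `architecture_truth`: `boundaries` (tibble
#'   `chrom`, `pos`), `compartments` (tibble `chrom`, `start`, `end`,
#'   `label`), `loops` (tibble `chrom`, `bin1`, `bin2`, `enrichment`),
#'   `bin_size`.
#' @export
simulate_architecture_truth <- function(genome, bin_size = 1e4,
                                        domain_mean_bp = 4e5,
                                        compartment_block_bp = 2e6,
                                        n_loops_per_chrom = 40,
                                        loop_enrichment = 5,
                                        loop_span_range = c(4.5e5, 9.5e5),
                                        seed = 1) {
  set.seed(seed)
  b_rows <- list(); c_rows <- list(); l_rows <- list()
  for (k in seq_len(nrow(genome$chrom_sizes))) {
    ch <- genome$chrom_sizes$chrom[k]
    len <- genome$chrom_sizes$length[k]
    # boundaries
    pos <- 0; bds <- numeric(0)
    while (TRUE) {
      step <- round(stats::runif(1, 0.75, 1.25) * domain_mean_bp / bin_size) * bin_size
      pos <- pos + step
      if (pos >= len - domain_mean_bp / 2) break
      bds <- c(bds, pos)
    }
    b_rows[[k]] <- tibble::tibble(chrom = ch, pos = bds)
    # compartment blocks: switch label at the boundary nearest each
    # multiple of compartment_block_bp
    switches <- vapply(seq_len(floor(len / compartment_block_bp) - 1),
                       function(m) bds[which.min(abs(bds - m * compartment_block_bp))],
                       0)
    switches <- sort(unique(switches))
    edges <- c(0, switches, len)
    labs <- rep(c("A", "B"), length.out = length(edges) - 1)
    c_rows[[k]] <- tibble::tibble(chrom = ch, start = edges[-length(edges)],
                                  end = edges[-1], label = labs)
    # loops between same-compartment anchors
    n_bins <- floor(len / bin_size)
    lab_of_bin <- labs[findInterval(seq_len(n_bins) * bin_size - bin_size / 2,
                                    edges, rightmost.closed = TRUE)]
    span_bins <- round(loop_span_range / bin_size)
    picked <- tibble::tibble(bin1 = integer(), bin2 = integer())
    guard <- 0
    while (nrow(picked) < n_loops_per_chrom && guard < 5000) {
      guard <- guard + 1
      d <- sample(span_bins[1]:span_bins[2], 1)
      b1 <- sample(15:(n_bins - d - 15), 1)
      b2 <- b1 + d
      if (lab_of_bin[b1] != lab_of_bin[b2]) next
      if (nrow(picked) > 0 &&
          any(abs(picked$bin1 - b1) <= 3 & abs(picked$bin2 - b2) <= 3)) next
      picked <- dplyr::bind_rows(picked, tibble::tibble(bin1 = b1, bin2 = b2))
    }
    l_rows[[k]] <- tibble::tibble(chrom = ch, bin1 = picked$bin1 - 1L,
                                  bin2 = picked$bin2 - 1L,
                                  enrichment = loop_enrichment)
  }
  structure(list(boundaries = dplyr::bind_rows(b_rows),
                 compartments = dplyr::bind_rows(c_rows),
                 loops = dplyr::bind_rows(l_rows),
                 bin_size = bin_size),
            class = "architecture_truth")
}

#' Simulate Hi-C contacts with planted structure
#'
#' Per-pixel cis contact intensity is
#' `depth * d^(-alpha) * f_comp * f_tad * f_loop`: a power-law distance
#' decay modulated by compartment preference (cross-compartment pixels
#' scaled by `comp_ratio`), TAD insulation (cross-domain pixels scaled by
#' `tad_ratio`) and planted loop pixels (scaled by their enrichment).
#' Replicate libraries draw negative binomial counts around the condition
#' mean (`dispersion`). The planted structure is shared between
#' conditions.
#'
#' Two output modes: `"matrix"` returns [new_contact_matrix()] objects
#' built directly from the per-pixel counts (the distributional equivalent
#' of binning the pair list, without materialising it); `"pairs"` returns
#' valid-pair tables with `n_pairs` rows each, positions uniform within
#' bins.
#'
#' @param genome Output of [simulate_genome()].
#' @param truth Output of [simulate_architecture_truth()] (or `NULL` for a
#'   structureless decay-only simulation).
#' @param bin_size Bin size (bp).
#' @param depth Intensity scale: expected count at distance 1 bin for an
#'   unmodulated pixel, per replicate.
#' @param alpha Distance-decay exponent.
#' @param tad_ratio Between/within-TAD contact ratio.
#' @param comp_ratio Cross/same-compartment contact ratio.
#' @param dispersion NB dispersion of replicate counts.
#' @param replicates Replicates per condition.
#' @param conditions Condition labels.
#' @param features Which planted features to include.
#' @param visibility_sd Log-normal sd of per-bin technical visibility; the
#'   multiplicative bin bias (mappability/GC-style) that matrix balancing
#'   is meant to remove. Zero disables it.
#' @param dead_bin_fraction Fraction of bins with near-zero visibility
#'   (0.02 of genome), emulating unmappable regions the coverage filter
#'   should mask.
#' @param output `"matrix"` or `"pairs"`.
#' @param n_pairs Pairs per replicate library (pairs mode only).
#' @param seed RNG seed.
#' @return List of class `contact_simulation`: `libraries` (nested list
#'   `[[condition]][[replicate]]` of `contact_matrix` or pair tibbles),
#'   `truth`, `genome`, and the parameters.
#' @export
simulate_contacts <- function(genome, truth = NULL, bin_size = 1e4,
                              depth = 1300, alpha = 1, tad_ratio = 0.2,
                              comp_ratio = 0.4, dispersion = 0.05,
                              replicates = 2, conditions = c("A", "B"),
                              features = c("compartments", "tads", "loops"),
                              visibility_sd = 0.3, dead_bin_fraction = 0.02,
                              output = c("matrix", "pairs"), n_pairs = NULL,
                              seed = 1) {
  output <- match.arg(output)
  set.seed(seed)
  bg <- binned_genome(stats::setNames(genome$chrom_sizes$length,
                                      genome$chrom_sizes$chrom), bin_size)
  per_chrom <- lapply(seq_len(nrow(bg$chrom_sizes)), function(ci) {
    ch <- bg$chrom_sizes$chrom[ci]
    n <- bg$chrom_sizes$n_bins[ci]
    i <- rep.int(seq_len(n), n:1)
    j <- sequence(n:1) - 1L + i
    d <- j - i
    lam <- depth * pmax(d, 1)^(-alpha)
    if (!is.null(truth)) {
      mids <- (seq_len(n) - 0.5) * bin_size
      if ("compartments" %in% features) {
        cmp <- truth$compartments[truth$compartments$chrom == ch, ]
        lab <- cmp$label[findInterval(mids, c(cmp$start, utils::tail(cmp$end, 1)),
                                      rightmost.closed = TRUE)]
        lam <- lam * ifelse(lab[i] == lab[j], 1, comp_ratio)
      }
      if ("tads" %in% features) {
        bds <- truth$boundaries$pos[truth$boundaries$chrom == ch]
        dom <- findInterval(mids, bds)
        lam <- lam * ifelse(dom[i] == dom[j], 1, tad_ratio)
      }
      if ("loops" %in% features && nrow(truth$loops) > 0) {
        lp <- truth$loops[truth$loops$chrom == ch, ]
        if (nrow(lp) > 0) {
          i0 <- lp$bin1; j0 <- lp$bin2  # 0-based
          idx <- i0 * n - i0 * (i0 - 1) / 2 + (j0 - i0) + 1
          lam[idx] <- lam[idx] * lp$enrichment
        }
      }
    }
    if (visibility_sd > 0 || dead_bin_fraction > 0) {
      v <- stats::rlnorm(n, 0, visibility_sd)
      if (dead_bin_fraction > 0) {
        dead <- sample.int(n, max(0, round(dead_bin_fraction * n)))
        v[dead] <- 0.02
      }
      lam <- lam * v[i] * v[j]
    }
    list(chrom = ch, n = n, i = i, j = j, lam = lam)
  })

  libraries <- list()
  for (cond in conditions) {
    libraries[[cond]] <- list()
    for (r in seq_len(replicates)) {
      px_rows <- lapply(per_chrom, function(pc) {
        cnt <- stats::rnbinom(length(pc$lam), mu = pc$lam, size = 1 / dispersion)
        nz <- cnt > 0
        tibble::tibble(chrom1 = pc$chrom, bin1 = pc$i[nz] - 1L,
                       chrom2 = pc$chrom, bin2 = pc$j[nz] - 1L,
                       count = as.numeric(cnt[nz]))
      })
      px <- dplyr::bind_rows(px_rows)
      if (output == "matrix") {
        libraries[[cond]][[r]] <- new_contact_matrix(px, bg)
      } else {
        if (is.null(n_pairs)) stop("`n_pairs` required for pairs output",
                                   call. = FALSE)
        w <- px$count
        pick <- sample.int(nrow(px), n_pairs, replace = TRUE, prob = w)
        libraries[[cond]][[r]] <- tibble::tibble(
          chrom1 = px$chrom1[pick],
          pos1 = bin_start(bg, px$bin1[pick]) +
            floor(stats::runif(n_pairs, 0, bin_size)),
          chrom2 = px$chrom2[pick],
          pos2 = bin_start(bg, px$bin2[pick]) +
            floor(stats::runif(n_pairs, 0, bin_size)))
      }
    }
  }
  structure(list(libraries = libraries, truth = truth, genome = genome,
                 binned_genome = bg,
                 params = list(bin_size = bin_size, depth = depth,
                               alpha = alpha, tad_ratio = tad_ratio,
                               comp_ratio = comp_ratio,
                               dispersion = dispersion, seed = seed)),
            class = "contact_simulation")
}

#' Simulate promoter-capture interaction counts with planted dynamics
#'
#' Designates bait fragments at gene TSSs and plants `n_interactions`
#' bait/other-end interactions with class labels:
#'
#' * `rewired_gained_A` / `rewired_gained_B`: interaction counts change
#'   `interaction_fc`-fold between conditions (geometric split around the
#'   enriched mean);
#' * `preformed_activated_A` / `preformed_activated_B`: equal interaction
#'   counts in both conditions, but a differential acetylation peak
#'   (`peak_fc`-fold) planted at the distal end;
#' * `static`: equal counts; half carry a non-differential distal peak.
#'
#' All planted interactions are enriched `enrichment`-fold over the
#' distance-decay background `capture_depth * bin_ref / distance`
#' (`bin_ref` = 10 kb). Every other cis bait/fragment pair within
#' `background_span_max` receives unenriched background counts (zero-count
#' pairs are omitted from the table), so interaction scoring has a full
#' background to learn from. Planted interactions use distinct distal
#' fragments, so class labels never collide on a shared distal end. Null
#' peaks are added away from distal ends.
#'
#' @param genome Output of [simulate_genome()].
#' @param n_baits Number of bait fragments (taken at the first genes).
#' @param n_interactions Planted interactions.
#' @param class_probs Named class proportions (must sum to 1).
#' @param span_range Planted interaction span range (bp).
#' @param capture_depth Background depth: expected per-replicate count for
#'   a pair at 10 kb.
#' @param enrichment Planted-over-background enrichment of interactions.
#' @param interaction_fc Between-condition fold change of rewired
#'   interactions.
#' @param peak_fc Fold change of planted differential peaks.
#' @param dispersion NB dispersion of replicate counts.
#' @param replicates Interaction replicates per condition.
#' @param peak_replicates Peak (ChIP) replicates per condition.
#' @param peak_mean Base mean reads-in-peak per replicate.
#' @param peak_width Planted peak width (bp).
#' @param background_span_max Span limit for background pairs.
#' @param n_null_peaks Additional non-differential background peaks.
#' @param seed RNG seed.
#' @return List of class `capture_simulation`: `counts` (wide tibble of
#'   interaction counts), `truth` (tibble with planted `class` per
#'   interaction), `peaks`, `peak_counts`, `peak_truth`, `bait_genes`,
#'   `baits` (fragment ids), `fragments`.
#' @export
simulate_capture <- function(genome, n_baits = 2000, n_interactions = 5000,
                             class_probs = c(rewired_gained_A = 0.05,
                                             rewired_gained_B = 0.05,
                                             preformed_activated_A = 0.10,
                                             preformed_activated_B = 0.10,
                                             static = 0.70),
                             span_range = c(5e4, 3.5e5),
                             capture_depth = 280, enrichment = 8,
                             interaction_fc = 4, peak_fc = 4,
                             dispersion = 0.02, replicates = 2,
                             peak_replicates = 3, peak_mean = 50,
                             peak_width = 1000, background_span_max = 1e6,
                             n_null_peaks = 3000, seed = 1) {
  stopifnot(abs(sum(class_probs) - 1) < 1e-8)
  set.seed(seed)
  frag <- genome$fragments
  frag$mid <- (frag$start + frag$end) / 2

  genes <- genome$genes[seq_len(min(n_baits, nrow(genome$genes))), ]
  bait_id <- vapply(seq_len(nrow(genes)), function(k) {
    f <- frag[frag$chrom == genes$chrom[k], ]
    f$fragment_id[findInterval(genes$tss[k], f$start)]
  }, "")
  bait_genes <- tibble::tibble(bait_id = bait_id, gene_id = genes$gene_id)
  bait_genes <- bait_genes[!duplicated(bait_genes$bait_id), ]
  baits <- bait_genes$bait_id

  mu0 <- function(d) capture_depth * 1e4 / pmax(d, 1e4)

  # planted interactions; oversample candidates because duplicate distal
  # fragments are discarded below
  n_cand <- 4L * n_interactions
  cls <- sample(names(class_probs), n_cand, replace = TRUE,
                prob = class_probs)
  bsel <- sample(baits, n_cand, replace = TRUE)
  bi <- match(bsel, frag$fragment_id)
  span <- stats::runif(n_cand, span_range[1], span_range[2])
  chrom_len <- chrom_len_of(genome, frag$chrom[bi])
  # pick a direction in which the planted span actually fits
  can_plus <- frag$mid[bi] + span < chrom_len - 1
  can_minus <- frag$mid[bi] - span > 1
  rnd_sign <- sample(c(-1, 1), n_cand, replace = TRUE)
  span_sign <- ifelse(can_plus & can_minus, rnd_sign,
                      ifelse(can_plus, 1, -1))
  ok <- can_plus | can_minus
  bsel <- bsel[ok]; bi <- bi[ok]; span <- span[ok]; cls <- cls[ok]
  span_sign <- span_sign[ok]; chrom_len <- chrom_len[ok]
  n_cand <- sum(ok)
  target <- frag$mid[bi] + span_sign * span
  oi <- vapply(seq_len(n_cand), function(k) {
    f_idx <- which(frag$chrom == frag$chrom[bi[k]])
    f_idx[findInterval(target[k], frag$start[f_idx])]
  }, 0L)
  planted <- tibble::tibble(
    bait_id = bsel, other_id = frag$fragment_id[oi],
    class = cls, span = abs(frag$mid[oi] - frag$mid[bi]),
    gene_id = bait_genes$gene_id[match(bsel, bait_genes$bait_id)])
  planted <- planted[planted$bait_id != planted$other_id, ]
  # one interaction per distal fragment: a shared distal end would let one
  # interaction's planted peak change another interaction's class
  planted <- planted[!duplicated(planted$other_id) &
                       !planted$other_id %in% baits, ]
  planted <- utils::head(planted, n_interactions)

  lam <- enrichment * mu0(planted$span)
  fcsq <- sqrt(interaction_fc)
  mu_a <- ifelse(planted$class == "rewired_gained_A", lam * fcsq,
                 ifelse(planted$class == "rewired_gained_B", lam / fcsq, lam))
  mu_b <- ifelse(planted$class == "rewired_gained_A", lam / fcsq,
                 ifelse(planted$class == "rewired_gained_B", lam * fcsq, lam))

  # background: every cis bait/fragment pair within background_span_max
  bg_rows <- lapply(seq_along(baits), function(k) {
    b_idx <- match(baits[k], frag$fragment_id)
    f <- which(frag$chrom == frag$chrom[b_idx])
    d <- abs(frag$mid[f] - frag$mid[b_idx])
    f <- f[d <= background_span_max & d > 0]
    tibble::tibble(bait_id = baits[k], other_id = frag$fragment_id[f],
                   span = abs(frag$mid[f] - frag$mid[b_idx]))
  })
  background <- dplyr::bind_rows(bg_rows)
  key_p <- paste(planted$bait_id, planted$other_id)
  background <- background[!paste(background$bait_id, background$other_id)
                           %in% key_p, ]
  bg_lam <- mu0(background$span)

  draw <- function(mu, n_rep) {
    base::matrix(stats::rnbinom(length(mu) * n_rep, mu = rep(mu, n_rep),
                                size = 1 / dispersion),
                 ncol = n_rep)
  }
  cnt_a_p <- draw(mu_a, replicates); cnt_b_p <- draw(mu_b, replicates)
  cnt_a_g <- draw(bg_lam, replicates); cnt_b_g <- draw(bg_lam, replicates)
  mk_counts <- function(ids, ca, cb) {
    out <- ids
    for (r in seq_len(replicates)) out[[paste0("count_A_", r)]] <- ca[, r]
    for (r in seq_len(replicates)) out[[paste0("count_B_", r)]] <- cb[, r]
    out
  }
  bg_counts <- mk_counts(background[, c("bait_id", "other_id")],
                         cnt_a_g, cnt_b_g)
  bg_counts <- bg_counts[rowSums(cnt_a_g) + rowSums(cnt_b_g) > 0, ]
  counts <- dplyr::bind_rows(
    mk_counts(planted[, c("bait_id", "other_id")], cnt_a_p, cnt_b_p),
    bg_counts)

  # peaks at distal ends
  oi_keep <- match(planted$other_id, frag$fragment_id)
  distal_mid <- frag$mid[oi_keep]
  has_peak <- planted$class %in% c("preformed_activated_A",
                                   "preformed_activated_B") |
    (planted$class == "static" & stats::runif(nrow(planted)) < 0.5)
  pk <- tibble::tibble(
    chrom = frag$chrom[oi_keep][has_peak],
    start = pmax(0, distal_mid[has_peak] - peak_width / 2),
    end = distal_mid[has_peak] + peak_width / 2,
    planted_dir = dplyr::case_when(
      planted$class[has_peak] == "preformed_activated_A" ~ "up_A",
      planted$class[has_peak] == "preformed_activated_B" ~ "up_B",
      TRUE ~ "ns"))
  # null peaks away from planted interactions
  null_chrom <- sample(genome$chrom_sizes$chrom, n_null_peaks, replace = TRUE)
  null_mid <- floor(stats::runif(n_null_peaks, peak_width,
                                 chrom_len_of(genome, null_chrom) - peak_width))
  pk <- dplyr::bind_rows(pk, tibble::tibble(
    chrom = null_chrom, start = null_mid - peak_width / 2,
    end = null_mid + peak_width / 2, planted_dir = "ns"))
  pk$peak_id <- sprintf("pk%05d", seq_len(nrow(pk)))
  pk_fcsq <- sqrt(peak_fc)
  pmu_a <- ifelse(pk$planted_dir == "up_A", peak_mean * pk_fcsq,
                  ifelse(pk$planted_dir == "up_B", peak_mean / pk_fcsq,
                         peak_mean))
  pmu_b <- ifelse(pk$planted_dir == "up_A", peak_mean / pk_fcsq,
                  ifelse(pk$planted_dir == "up_B", peak_mean * pk_fcsq,
                         peak_mean))
  pka <- draw(pmu_a, peak_replicates); pkb <- draw(pmu_b, peak_replicates)
  peak_counts <- tibble::tibble(unit_id = pk$peak_id)
  for (r in seq_len(peak_replicates)) peak_counts[[paste0("A_", r)]] <- pka[, r]
  for (r in seq_len(peak_replicates)) peak_counts[[paste0("B_", r)]] <- pkb[, r]

  structure(list(
    counts = counts,
    truth = planted,
    peaks = pk[, c("peak_id", "chrom", "start", "end")],
    peak_counts = peak_counts,
    peak_truth = pk[, c("peak_id", "planted_dir")],
    bait_genes = bait_genes,
    baits = baits,
    fragments = genome$fragments,
    n_background_pairs = nrow(background),
    params = list(capture_depth = capture_depth, enrichment = enrichment,
                  interaction_fc = interaction_fc, peak_fc = peak_fc,
                  dispersion = dispersion, seed = seed)),
    class = "capture_simulation")
}

chrom_len_of <- function(genome, chrom) {
  genome$chrom_sizes$length[match(chrom, genome$chrom_sizes$chrom)]
}

#' Simulate TF peak sets, expression and metabolic-cage tables
#'
#' Generates (i) an enhancer universe and two transcription-factor peak
#' sets with a planted co-binding fraction; (ii) per-replicate NB read
#' counts for a subset of differentially bound TF peaks; (iii) a gene
#' expression table whose planted differential expression follows the loop
#' classes when supplied (genes on A-activated loops are upregulated in
#' condition A, and symmetrically); (iv) a metabolic-cage table with group
#' offsets whose energy-expenditure column follows the calorimetric
#' equation exactly.
#'
#' @param genome Output of [simulate_genome()].
#' @param loop_classes Optional tibble `gene_id`, `class` (from the capture
#'   truth or [link_dynamics_to_genes()]).
#' @param n_enhancers,enhancer_width Enhancer universe size and width.
#' @param n_tf_peaks,tf_peak_width Peaks per TF set and their width.
#' @param cobinding_fraction Fraction of TF-B peaks planted inside TF-A
#'   peaks.
#' @param de_fc Fold change of planted DE genes.
#' @param extra_de_fraction Fraction of unlinked genes that are also DE.
#' @param expr_replicates Expression replicates per condition.
#' @param expr_mean_log,expr_sd_log Log-normal baseline expression.
#' @param dispersion NB dispersion.
#' @param cage_n_per_group,cage_n_intervals Mice per group and 27-min
#'   measurement intervals per mouse.
#' @param vo2_mean,vco2_mean Named (`A`, `B`) group mean VO2/VCO2 in l/h.
#' @param cage_sd Within-mouse interval standard deviation (l/h).
#' @param seed RNG seed.
#' @return List of class `peaks_expression_simulation` with elements
#'   `enhancers`, `tf_a`, `tf_b`, `cobinding_truth`, `tf_counts`,
#'   `tf_truth`, `expression`, `expression_counts`, `de_truth`, `cage`.
#' @export
simulate_peaks_expression_cage <- function(genome, loop_classes = NULL,
                                           n_enhancers = 5000,
                                           enhancer_width = 1000,
                                           n_tf_peaks = 2000,
                                           tf_peak_width = 500,
                                           cobinding_fraction = 0.5,
                                           de_fc = 3, extra_de_fraction = 0.1,
                                           expr_replicates = 5,
                                           expr_mean_log = log(100),
                                           expr_sd_log = 1,
                                           dispersion = 0.05,
                                           cage_n_per_group = 4,
                                           cage_n_intervals = 96,
                                           vo2_mean = c(A = 1.6, B = 1.3),
                                           vco2_mean = c(A = 1.5, B = 1.0),
                                           cage_sd = 0.08, seed = 1) {
  set.seed(seed)
  total_len <- sum(genome$chrom_sizes$length)
  # non-overlapping enhancers on a spaced grid
  pitch <- floor(total_len / n_enhancers)
  if (pitch < 2 * enhancer_width) stop("genome too small for enhancer universe",
                                       call. = FALSE)
  gpos <- (seq_len(n_enhancers) - 1) * pitch +
    floor(stats::runif(n_enhancers, 0, pitch - enhancer_width))
  enh <- global_to_chrom(genome, gpos, enhancer_width)
  enh$enhancer_id <- sprintf("e%05d", seq_len(nrow(enh)))

  # TF-A peaks inside distinct enhancers
  a_in <- sample.int(nrow(enh), n_tf_peaks)
  a_off <- floor(stats::runif(n_tf_peaks, 0, enhancer_width - tf_peak_width))
  tf_a <- tibble::tibble(chrom = enh$chrom[a_in],
                         start = enh$start[a_in] + a_off,
                         end = enh$start[a_in] + a_off + tf_peak_width,
                         name = sprintf("tfa%05d", seq_len(n_tf_peaks)))
  # TF-B: planted fraction inside TF-A peaks, rest in TF-A-free enhancers
  n_co <- round(cobinding_fraction * n_tf_peaks)
  co_src <- sample.int(n_tf_peaks, n_co)
  shift <- floor(stats::runif(n_co, -tf_peak_width / 2, tf_peak_width / 2))
  b_co <- tibble::tibble(chrom = tf_a$chrom[co_src],
                         start = pmax(0, tf_a$start[co_src] + shift),
                         end = pmax(0, tf_a$start[co_src] + shift) + tf_peak_width)
  free <- setdiff(seq_len(nrow(enh)), a_in)
  b_in <- sample(free, n_tf_peaks - n_co)
  b_off <- floor(stats::runif(n_tf_peaks - n_co, 0, enhancer_width - tf_peak_width))
  b_free <- tibble::tibble(chrom = enh$chrom[b_in],
                           start = enh$start[b_in] + b_off,
                           end = enh$start[b_in] + b_off + tf_peak_width)
  tf_b <- dplyr::bind_rows(b_co, b_free)
  tf_b$name <- sprintf("tfb%05d", seq_len(nrow(tf_b)))

  # differential binding counts for TF-B peaks: half planted differential
  n_diff <- round(nrow(tf_b) / 2)
  tf_dir <- c(sample(c("up_A", "up_B"), n_diff, replace = TRUE),
              rep("ns", nrow(tf_b) - n_diff))
  fcsq <- sqrt(4)
  tmu_a <- ifelse(tf_dir == "up_A", 50 * fcsq,
                  ifelse(tf_dir == "up_B", 50 / fcsq, 50))
  tmu_b <- ifelse(tf_dir == "up_A", 50 / fcsq,
                  ifelse(tf_dir == "up_B", 50 * fcsq, 50))
  tf_counts <- tibble::tibble(unit_id = tf_b$name)
  for (r in 1:2) tf_counts[[paste0("A_", r)]] <-
    stats::rnbinom(nrow(tf_b), mu = tmu_a, size = 1 / dispersion)
  for (r in 1:2) tf_counts[[paste0("B_", r)]] <-
    stats::rnbinom(nrow(tf_b), mu = tmu_b, size = 1 / dispersion)

  # expression with DE tied to loop classes
  genes <- genome$genes
  base <- stats::rlnorm(nrow(genes), expr_mean_log, expr_sd_log)
  de_status <- rep("ns", nrow(genes))
  if (!is.null(loop_classes)) {
    upA <- unique(loop_classes$gene_id[loop_classes$class %in%
      c("rewired_gained_A", "preformed_activated_A")])
    upB <- unique(loop_classes$gene_id[loop_classes$class %in%
      c("rewired_gained_B", "preformed_activated_B")])
    upB <- setdiff(upB, upA)
    de_status[genes$gene_id %in% upA] <- "up_A"
    de_status[genes$gene_id %in% upB] <- "up_B"
  }
  frees <- which(de_status == "ns")
  extra <- sample(frees, round(extra_de_fraction * length(frees)))
  de_status[extra] <- sample(c("up_A", "up_B"), length(extra), replace = TRUE)
  dsq <- sqrt(de_fc)
  emu_a <- ifelse(de_status == "up_A", base * dsq,
                  ifelse(de_status == "up_B", base / dsq, base))
  emu_b <- ifelse(de_status == "up_A", base / dsq,
                  ifelse(de_status == "up_B", base * dsq, base))
  expr_counts <- tibble::tibble(unit_id = genes$gene_id)
  for (r in seq_len(expr_replicates)) expr_counts[[paste0("A_", r)]] <-
    stats::rnbinom(nrow(genes), mu = emu_a, size = 1 / dispersion)
  for (r in seq_len(expr_replicates)) expr_counts[[paste0("B_", r)]] <-
    stats::rnbinom(nrow(genes), mu = emu_b, size = 1 / dispersion)
  tpm_of <- function(cols) {
    m <- rowMeans(as.matrix(expr_counts[, cols]))
    rate <- m / genes$length
    rate / sum(rate) * 1e6
  }
  expression <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, tss = genes$tss,
    strand = genes$strand, length = genes$length,
    tpm_A = tpm_of(paste0("A_", seq_len(expr_replicates))),
    tpm_B = tpm_of(paste0("B_", seq_len(expr_replicates))))

  # metabolic cage
  cage_rows <- list()
  for (cond in c("A", "B")) {
    for (m in seq_len(cage_n_per_group)) {
      vo2 <- pmax(0, stats::rnorm(cage_n_intervals, vo2_mean[[cond]], cage_sd))
      vco2 <- pmax(0, stats::rnorm(cage_n_intervals, vco2_mean[[cond]], cage_sd))
      cage_rows[[paste(cond, m)]] <- tibble::tibble(
        condition = cond, mouse = paste0(cond, m),
        interval = seq_len(cage_n_intervals), vo2 = vo2, vco2 = vco2,
        ee = energy_expenditure(vo2, vco2))
    }
  }
  structure(list(
    enhancers = enh, tf_a = tf_a, tf_b = tf_b,
    cobinding_truth = list(fraction = cobinding_fraction, n_cobound = n_co),
    tf_counts = tf_counts,
    tf_truth = tibble::tibble(name = tf_b$name, planted_dir = tf_dir),
    expression = expression, expression_counts = expr_counts,
    de_truth = tibble::tibble(gene_id = genes$gene_id, de_status = de_status),
    cage = dplyr::bind_rows(cage_rows),
    params = list(seed = seed)),
    class = "peaks_expression_simulation")
}

# map global linear positions to (chrom, start, end) intervals of width w
global_to_chrom <- function(genome, gpos, w) {
  edges <- cumsum(c(0, genome$chrom_sizes$length))
  ci <- findInterval(gpos, edges, rightmost.closed = FALSE)
  ci <- pmin(ci, nrow(genome$chrom_sizes))
  start <- gpos - edges[ci]
  len <- genome$chrom_sizes$length[ci]
  start <- pmin(start, len - w)
  tibble::tibble(chrom = genome$chrom_sizes$chrom[ci], start = start,
                 end = start + w)
}
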