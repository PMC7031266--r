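# loopdyn

Promoter-interaction dynamics from chromatin contact maps.

`loopdyn` is an R toolkit for asking how a physiological perturbation — a
diet switch, a treatment, any two-condition design — rewires the
three-dimensional regulatory genome of a tissue. It covers the full
analysis arc of a promoter-capture Hi-C study:

* **Contact matrices**: build binned matrices from valid ligation pairs,
  merge replicates, filter bins by coverage and balance by iterative
  correction (ICE), compare conditions by matrix correlation, and estimate
  the contact distance-decay curve.
* **Chromatin architecture**: A/B compartments from the leading
  eigenvector (PC1) of the observed/expected correlation map at 50-kb
  bins; TADs from a multi-window insulation (TAD-separation) score with a
  delta criterion and an FDR-corrected boundary test; cross-condition
  boundary colocalization.
* **Loops**: distance-stratified contact z-scores, loop calls at
  `z >= 6` within 1 Mb, and aggregate peak analysis (APA) with corner-pixel
  background scaling.
* **Capture interactions**: promoter-capture interaction scoring as
  `-log10 p` against a negative-binomial distance-decay background with
  per-bait scaling (significance at score >= 5), cis/1-Mb filtering, and
  descriptive comparisons (sharing, span, promoter–promoter fraction,
  capture efficiency).
* **Differential analysis & loop dynamics**: an exact negative-binomial
  count test with common method-of-moments dispersion for interactions
  (`p < 0.001`), ChIP peaks (`FDR < 0.05`, FC > 1.5) and genes
  (`FDR < 0.05`, FC > 1.2); classification of each promoter interaction as
  **rewired** (contact frequency itself changes), **preformed activated**
  (stable contact, differential H3K27ac at the distal end) or **static**;
  gene-level linkage of loop classes.
* **Integration statistics**: Mann–Whitney rank tests, TPM-binned
  expression vs. loop count, acetylation-stratified expression,
  nearest-TSS (±50 kb) assignment, Monte-Carlo size-matched shuffle
  overlap tests inside an enhancer universe, matched-control annotation
  overlap (>= 10% overlap criterion), metagene signal profiles,
  co-binding splits, and the calorimetric energy-expenditure equation
  `EE (kcal/h) = 3.941 · VO2 + 1.106 · VCO2`.
* **Synthetic data**: a first-class simulation module that plants
  compartments, TADs, loops, capture interactions with class labels,
  co-bound TF peak sets, differential expression and metabolic-cage
  records — with full ground truth, so every stage of the pipeline is
  testable without any external download.

Functions are data-frame-first and return tibbles; fitted/derived objects
have `tidy()`/`glance()` methods and `autoplot()` ggplot2 views.

## Worked example

Simulate a two-chromosome genome with planted structure, call loops, and
aggregate them:

```r
library(loopdyn)

genome <- simulate_genome(seed = 1)                    # 2 x 20 Mb, ~10k fragments
truth  <- simulate_architecture_truth(genome, seed = 2)
sim    <- simulate_contacts(genome, truth, seed = 3,
                            features = c("compartments", "loops"))

mat   <- merge_replicates(sim$libraries$A)             # merge 2 replicates
bal   <- filter_and_balance(mat)                       # mask bins + ICE
loops <- call_loops(loop_zscores(bal))                 # z >= 6, span <= 1 Mb
nrow(loops)
#> [1] 80
res <- apa(bal, loops)
res
#> <apa_result> center score 4.796 over 76 loops
```

All 80 planted loops are recovered; the APA centre score of ~4.8
reflects the planted 5-fold contact enrichment at loop pixels, read
against the corner-pixel background of the aggregated ±100-kb window
(scores sit slightly below the planted factor because the corners ride
the rising distance-decay curve).

The dynamics arm works the same way from count tables:

```r
cap   <- simulate_capture(genome, seed = 4)            # planted loop classes
sc    <- score_capture_interactions(cap$counts, cap$fragments)
idiff <- nb_count_test(..., type = "interaction")      # p < 0.001 rule
pdiff <- nb_count_test(cap$peak_counts, rep(c("A","B"), each = 3), type = "peak")
cl    <- classify_loop_dynamics(cap$truth[, 1:2], idiff, cap$peaks, pdiff,
                                cap$fragments, cap$bait_genes)
table(cl$class)
```

which recovers the planted rewired / preformed-activated / static labels
at >= 95% per-class accuracy (see `tests/testthat/test-acceptance.R`).

## Vignette

`vignettes/promoter-interaction-dynamics.Rmd` documents the models, the
numerical choices (balancing, dispersion estimation, boundary testing),
what the synthetic generator emulates — and what it deliberately does
not — and the known limitations.
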