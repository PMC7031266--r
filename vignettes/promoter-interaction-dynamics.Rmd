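---
title: "Promoter-interaction dynamics: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-interaction dynamics: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(loopdyn)
```

`loopdyn` implements a complete promoter-interaction dynamics analysis:
from binned chromatin-contact matrices through compartments, TADs and
loops, promoter-capture interaction scoring, differential testing, the
rewired-versus-preformed loop classification, and the statistics that tie
loop classes to enhancer activity and gene expression. This vignette is
the package's own account of the science: the models and their
assumptions, the tunable parameters, the numerical choices, and what the
synthetic-data module does and does not establish about real data.

## Coordinates and containers

All coordinates are 0-based half-open; BED is the native on-disk dialect
and any 1-based input must be converted at the reader boundary. Position
`p` falls in bin `floor(p / bin_size)`; bins tile each chromosome and the
last bin may be short. Contact matrices are symmetric and stored once in
upper-triangular pixel form; every operation preserves that symmetry.
Interval overlap fractions (the "at least 10% overlap" rule used for
annotation comparisons) are measured relative to the *query* interval's
length. Promoter windows are strand-symmetric `TSS ± 2 kb`, clipped at
chromosome ends — the strand is deliberately ignored because the window
definition is symmetric, and clipping is the only defensible behaviour at
contig edges.

## Matrix balancing

`filter_and_balance()` removes bins whose coverage z-score falls outside
`[low_cutoff, high_cutoff]` (default −2.5 and 4; zero-coverage bins are
always masked), then applies iterative correction: symmetric row/column
scaling until all unmasked row sums agree to within `tolerance`
(default 1e−8 relative), with square-root damping so the update does not
oscillate on sparse matrices, and a final rescale that preserves the
matrix total. In real analyses the coverage cutoffs are chosen per
dataset from the coverage histogram; the asymmetric default reflects
that low-coverage artefacts are common while coverage blow-ups are rare.
Balancing an already-balanced matrix is a no-op (coverage is constant, so
the z-filter is skipped and the scalings are identity to within
tolerance). A matrix whose sparsity pattern cannot support equal row sums
(e.g. a bin connected to a single partner) fails with a convergence error
rather than returning a half-corrected object.

## Compartments

`compartment_pc1()` follows the classical eigenvector recipe per
chromosome: divide the balanced cis matrix by its expected-by-distance
profile, take the Pearson correlation matrix of the O/E columns over
unmasked bins, and extract the leading eigenvector. The eigenvector sign
is arbitrary, so orientation is fixed by an explicit user-supplied
activity track (planted active regions in simulations; gene density or an
acetylation track on real data): the sign is flipped so bins overlapping
the track have positive mean PC1, and `A` is `pc1 > 0`. We require at
least 20 unmasked bins per chromosome — below that the correlation matrix
is too noisy to interpret and the chromosome is masked with a warning, as
is a structureless (constant) matrix.

## TAD segmentation

`insulation_tads()` computes, per bin and per window size `w` in
`{5, 10, 20}` bins, the mean balanced contact count in the diamond
spanning the `w` bins upstream versus the `w` bins downstream. Each
window's profile is log2-scaled relative to its chromosome mean, and the
per-bin TAD-separation score is the minimum over windows (the strictest
window decides). A boundary must be (i) a local minimum, (ii) at least
`delta = 0.1` below the nearest flanking local maxima on both sides,
(iii) supported by a one-sided rank-sum comparison of diamond counts at
the minimum versus the flanking maxima, BH-corrected across candidates at
`comparison_p = 0.05`, and (iv) at least `min_boundary_bins = 5` bins away
from a stronger candidate — twin minima on a flat valley bottom collapse
to the deeper one. Domains are the intervals between consecutive
boundaries. `boundary_colocalization()` reports, in both directions, the
fraction of boundaries with a partner within `tolerance_bp` (default one
50-kb bin; the tolerance is a genuine free parameter with no canonical
value).

## Loops and APA

`loop_zscores()` standardises every unmasked cis pixel (zeros included)
against the mean and standard deviation of its genomic-distance stratum,
up to `max_depth_bp = 1e8`; strata with fewer than 10 pixels are
undefined. `call_loops()` keeps pixels with `z >= 6` and span `<= 1 Mb`
and merges 8-connected runs of called pixels into one call anchored at
the maximum-z pixel — adjacent super-threshold pixels are one loop, not
several. `apa()` sums fixed 21 × 21 submatrices (10-kb bins, ±100-kb
background) centred on loop pixels, excluding loops within 300 kb of the
diagonal and loops whose window leaves the chromosome, and scales the
aggregate by the mean of its four corner pixels; the centre of the scaled
aggregate is the APA score. Note an intrinsic property of this
definition: because two corners sit at larger and one at smaller genomic
distance than the centre, the corner mean rides the convex decay curve
and the score systematically underestimates the true enrichment for
loops close to the exclusion limit (about −20% at 350 kb span, −5% at
650 kb). This is a property of the statistic, not of the implementation.

## Capture interaction scoring

`score_capture_interactions()` scores each bait/other-end pair as
`-log10` of the upper-tail probability of its replicate-summed count
under a negative-binomial background; score >= 5 is called significant.
The background has three estimated components:

* a pooled **distance-decay** curve: mean count per *possible* cis
  fragment pair (zeros included, counted from the fragment map) in 25
  log-spaced distance strata, smoothed by log-log interpolation across
  stratum means so a pair's expected count follows the continuous curve
  rather than a step function — without this, pairs at the short edge of
  each stratum are anti-conservative;
* a per-bait **scaling factor** (observed over expected bait total)
  absorbing bait-to-bait capture efficiency;
* a single **dispersion**, by a leverage-corrected method of moments over
  all possible pairs. Fitting one scale per bait from its own total
  absorbs part of the count variance — concentrated on the high-mean
  short-range pairs that dominate the moment sums, biasing the naive
  estimate low by several percent — so the estimator inverts the exact
  expectation of the residual sum of squares under the scale fit
  (`E[RSS] = A(1 + Σw²) − 2Σwσ²` with `w` the bait's mean weights),
  with a plug-in iteration. Each bait's scale uncertainty is additionally
  propagated into the test (`size = 1/(φ + v_bait)`), so background
  estimation error cannot masquerade as signal. The fit is made twice
  more after excluding pairs that are extreme outliers under the current
  fit (p < 1e−6): genuine interactions are far beyond that threshold,
  while on pure background essentially nothing is trimmed, so signal does
  not inflate the dispersion and the null tail is not clipped. The
  calibration contract — a per-pair null rate at score >= 5 of at most
  1.2e−5 — is enforced by simulation in the test suite.

This scorer is a deliberately minimal background model: it keeps the
fixed score-5 threshold semantics while omitting the heavier machinery of
full capture-interaction callers (compound background distributions,
multiple-window p-value weighting). Trans pairs and spans above 1 Mb are
removed by `filter_cis()` (a span of exactly 1 Mb is kept); interaction
identity across conditions is exact fragment-pair identity.

## Differential testing and loop classes

`nb_count_test()` is an exact conditional negative-binomial test built
for n = 2 replicates per group, where per-unit dispersion estimation is
hopeless: counts are library-size normalised by total-count scaling, a
single common dispersion is estimated by method of moments pooled over
units (weighted towards high-count units, floored at 0.01), and, given
the summed normalised counts of the two conditions, the condition-A sum
follows a negative hypergeometric law whose parameters depend only on the
replicate numbers and the common dispersion. The two-sided p-value is the
total conditional probability of outcomes no more likely than the
observed one. The dispersion floor deliberately caps sensitivity: with
two replicates, fold changes below roughly 1.5 cannot reach extreme
significance, which is the intended behaviour for this design. Direction
calls follow the unit type: interactions on raw `p < 0.001`; ChIP peaks
on `FDR < 0.05` and fold change > 1.5; genes on `FDR < 0.05` and fold
change > 1.2.

`classify_loop_dynamics()` then assigns each tested interaction exactly
one label. *Rewired* (`p < 0.001` on interaction counts, gained in A or
B by sign) takes precedence. Otherwise, if at least one differential
acetylation peak overlaps the distal (non-bait) fragment, the interaction
is *preformed activated* in the peak's direction — when peaks of both
directions overlap one distal end, the larger |log2FC| decides, a
tie-break the two-category definition leaves open. Everything else is
*static*. Classification requires a differential record for every
interaction (a missing record is an error, not a silent `ns`), and the
classes partition the input by construction.

## Integration statistics

`mann_whitney()` computes U from midrank sums. For `n1 + n2 <= 14` the
p-value comes from exhaustive enumeration of all group assignments,
counting assignments whose U is at least as far from `n1·n2/2` as
observed — this is exact under ties, which the usual exact algorithms do
not handle; beyond that, a normal approximation with tie and continuity
correction takes over (at 15+ observations the two differ negligibly,
and enumeration cost grows combinatorially). Tests are two-sided.

TPM bins are `{0}`, `(0,1]`, `(1,10]`, `>10` — zero expression is its own
category and interval edges are right-closed, the natural reading of
"0–1, 1–10, >10" given that exact zeros are meaningful in RNA-seq.
Gene strata for the enhancer-activity analysis are
`{no interaction; 1; 2–5; >5} × {with/without acetylated distal end}`,
where "with" means at least one interaction whose distal end overlaps an
acetylation peak. Nearest-TSS assignment uses site midpoints, a ±50-kb
window, and breaks exact ties to the smaller gene id so results are
reproducible.

`shuffle_overlap_test()` places size-matched random interval sets
uniformly within a universe (each interval wholly inside one universe
interval, no overlap among placed intervals, conflicts re-drawn), and
reports the add-one empirical p-value `(r + 1)/(n_iter + 1)` — never
zero, and bounded below by `1/(n_iter + 1)`. The universe must total at
least twice the summed query length, otherwise placement is refused.
`matched_control_annotation_overlap()` reuses the same placement engine
to compare a query set's annotation overlap percentages (>= 10% of the
query interval) against the mean ± sd of size-matched random controls.

Energy expenditure is the standard open-circuit calorimetry equation,
`EE = 3.941·VO2 + 1.106·VCO2` (kcal/h, inputs in l/h). Weight
normalisation of cage data is left to the caller: there is no canonical
formula, and the package does not invent one.

## The synthetic-data module

The generator is first-class, tested code, and its defaults define the
study conditions every recovery guarantee is stated under: a desk-scale
genome of 2 × 20 Mb with ~4-kb restriction fragments, 10-kb matrix bins
(50 kb for compartments), two conditions × two replicates, ~2,000 baits
and ~5,000 planted capture interactions.

Contact intensity per cis pixel is
`depth · d^(−α) · f_comp · f_tad · f_loop · v_i · v_j` with α = 1,
cross-compartment factor 0.4, between-TAD factor 0.2, loop enrichment 5,
and a per-bin technical visibility bias `v` (log-normal, sd 0.3, plus 2%
dead bins) — the multiplicative bias ICE exists to remove; without it a
coverage filter would mask exactly the biologically depleted boundary
bins. Compartment blocks (~2 Mb) switch labels only at planted TAD
boundaries, as in real genomes. Replicate counts are negative binomial
(dispersion 0.05) around the condition mean. The default depth
(`depth = 1300`, the per-pixel intensity scale at one bin) was fixed by
z-score arithmetic: at loop spans, between-TAD pixel means of ~3–4 per
merged matrix give planted 5× pixels an expected z of 8–10, comfortably
above the z = 6 calling threshold; it corresponds to roughly 10 million
cis contacts per chromosome per replicate — an explicit scale-down from
billion-read studies. Planted loops span 450–950 kb so their APA windows
clear the 300-kb diagonal exclusion with a flat local background; each
recovery experiment plants only the structure under test (TAD corner
pixels legitimately exceed z = 6, so a mixed simulation would conflate
domain corners with loops). `simulate_contacts()` can emit valid-pair
tables (the pipeline's input format) or the binned counts directly; the
two are distributionally identical, and the direct form is used at depth
so that tens of millions of pair rows are never materialised.

Capture counts follow `capture_depth · 10 kb / d` per replicate
(default 280 at 10 kb), with planted interactions enriched 8-fold,
rewired classes split 4-fold between conditions, and preformed classes
given equal counts plus a 4-fold differential acetylation peak at their
(unique) distal fragment. Interaction and peak replicate dispersion
defaults to 0.02: with two replicates, the spread of a log2 fold-change
is bounded below by the replicate dispersion alone, and 0.02 is what
keeps stable classes stable (|log2FC| < 0.5 in >  90% of preformed
loops); Hi-C contact replicates keep the rougher 0.05.

What passing these tests shows — and what it does not. The simulations
establish that each estimator recovers what its own model plants, at
realistic depth and noise, and that the thresholds are calibrated under
the stated null. They do not establish robustness to what real tissue
adds: domain hierarchy and nested/overlapping TADs, copy-number and
mappability structure beyond a log-normal bias, restriction-site
sequence effects, condition-dependent compartment shifts, or the
CHiCAGO-class technical-noise component of capture counts. Real-data
headline figures (interaction totals, sharing percentages, boundary
colocalization near 90%) are depth- and genome-dependent and are not
reproduced at desk scale.

## Problem sizes and determinism

All simulations are deterministic given `seed` (R's default Mersenne
Twister; one seed at the top of each generator). The shipped tests run
the full recovery suite at the default configuration — two 20-Mb
chromosomes, one condition's merged matrix per experiment, ~0.9–1.1
million null capture pairs for calibration, 10,000-unit null panels for
the count test, and a 10,000-iteration shuffle — sizes chosen so the
whole suite completes in minutes while leaving the guarantees
statistically meaningful.

## Known limitations

* The exact NB test assumes a common dispersion; strongly
  unit-dependent dispersion would miscalibrate extreme tails.
* The capture background assumes one global dispersion and a smooth
  pooled decay; bait-specific decay shapes are absorbed only through the
  scalar bait factor.
* The insulation caller reports a flat boundary set, not a domain
  hierarchy.
* `matrix_correlation()` is Pearson on log1p over the union of non-zero
  pixels; there is no canonical definition, and values are not comparable
  across tools that stratify by distance.
* Compartment orientation requires an activity track; without one the
  A/B sign would be arbitrary.
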