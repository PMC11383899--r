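---
title: "Methods: migration calling, secretome screening and signature scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: migration calling, secretome screening and signature scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chemoscreen` turns three kinds of raw material — per-well
flow-cytometry event tables from transwell migration assays, NPX
secretome panels with limits of detection, and bulk expression matrices
with response labels — into three results: migration-induction calls,
a ranked list of candidate chemokines, and signature-level response
comparisons. This vignette documents the models, the parameters that
matter, the numerical conventions, and what the synthetic-data
generator does and does not establish.

## Migration quantification and induction calling

A transwell well yields flow-cytometry event counts per immune subset
plus events from a known spike of counting beads. The absolute
migrated count is `events * beads_added / bead_events`; a well with no
bead events is unquantifiable and is an error, not a zero. Counts are
carried as reals throughout — rounding only happens at display time.

Donor QC and calling follow two fixed decision rules:

* **Donor inclusion** (per donor x subset): keep the donor when
  migration toward the chemokine-mix positive control is at least 2.5x
  migration toward the medium-only negative control. The boundary is
  included because the exclusion rule is "ratio *less than* 2.5". A
  zero negative-control mean with positive migration is the limit of
  the rule and is included; a donor with zero migration toward both
  controls carries no information and is excluded with a warning.
* **Induction** (per attractant x subset): induced when the mean
  migrated count strictly exceeds the negative-control mean plus two
  *sample* standard deviations (n−1 denominator — control replicates
  are small samples, so the unbiased-variance form is the defensible
  choice) of the negative-control replicates. With zero control SD the
  rule degenerates to a strict mean comparison, which is the behavior
  we want for noise-free fixtures.

Both multipliers (`ratio_cutoff = 2.5`, `sd_mult = 2`) are exposed as
arguments.

**Pooling order.** Donors differ systematically in migratory capacity,
so normalization to the positive control happens *within* donor (each
donor's own positive-control mean defines 100%) before pooling. Each
donor is likewise compared against their own negative-control
replicates. With `donor_pooling = "mean"` (default) donor-level means,
thresholds and normalized percents are averaged per attractant x
subset; `"separate"` emits one row per donor for designs where the
replicates should stay visible. Neither order is canonical for this
assay family; both are supported rather than asserted.

When every donor fails QC for an attractant x subset the call is
emitted with `n_replicates = 0` and `induced = NA` — absent, not
false — so downstream tabulations see the missingness.

## The from-scratch nonparametric layer

All tests share one two-sided exact convention: the p-value is the
null probability of outcomes at least as extreme as observed in
|statistic − null mean|. This is the GraphPad-style two-sided
definition; the tests report magnitude, not direction.

* **Fisher 2x2**: full enumeration over tables with the observed
  margins; a table counts as "as extreme" when its hypergeometric
  point probability is at most the observed one within a relative
  tolerance of 1e−12 (guarding against ties in probability being
  broken by floating-point noise).
* **Mann–Whitney**: exact by enumeration of all C(n+m, n) group
  assignments when the data are untied and either both groups have at
  most `exact_threshold = 8` observations or
  `choose(n + m, min(n, m)) <= 20000`. The second clause makes
  unbalanced designs such as 3-vs-13 exact — enumeration cost depends
  on the *smaller* group, not the larger — which matters for the
  responder comparison below. Otherwise: midranks, tie-corrected
  variance, 0.5 continuity correction.
* **Wilcoxon signed-rank**: zero differences dropped before ranking
  (the standard convention); magnitude ties take midranks; exact over
  all 2^n sign patterns for up to `exact_threshold = 12` nonzero
  differences. All-zero differences are a defined degenerate result
  (p = 1, flagged) rather than an error, so batch screens over many
  proteins do not abort on a constant column. The normal
  approximation's worst-case deviation from the exact distribution at
  n = 13–15 is a little above 0.01 (the null is supported on only 2^n
  atoms); the test suite documents 0.015 as the honest bound there.
* **Kruskal–Wallis / Friedman**: tie-corrected H and Q with chi-square
  references on k−1 degrees of freedom; Friedman additionally
  enumerates all (k!)^n within-row rank permutations when
  `n * k <= 12`. A fully tied data set makes the tie correction vanish;
  the defined result is statistic 0, p = 1, degenerate flag.
* **Dunn post hoc**: rank-based z comparisons after either omnibus
  test. Each two-sided p is multiplied by the number of comparisons
  *actually requested*, capped at 1 — figures in this assay family
  typically compare selected pairs, not all pairs — and passing all
  pairs recovers the conventional family.
* **BH FDR**: the step-up formula, with the multiplier computed as
  `m/j` before the product so that `q >= p` holds in floating point
  exactly, not just in exact arithmetic.

Every exact path is validated in the test suite against independent
brute-force enumeration oracles, and against base R's `fisher.test`,
`kruskal.test`, `friedman.test`, `cor.test` and `p.adjust` where those
implement the same convention.

## Secretome representation and the presence contrast

NPX is a relative log2 abundance: comparable across samples within a
protein, never between proteins, and no cross-protein statistic is
offered. Below-LOD values are stored as reported but flagged; analyses
substitute the per-protein LOD value (the common NPX convention), with
`half_lod` (LOD − 1 on the log2 scale) as the alternative policy. A
missing LOD table means every value is treated as detected, with a
warning — detection semantics should fail loudly, not silently.

"Detected in the TME" means above LOD in at least one TME sample
(`min_detected_samples = 1`, configurable): detection counts are not
operationally standardized across studies, so the liberal reading is
the default and the threshold is a dial.

The **presence contrast** encodes the stroma-derivation argument: a
protein that no cell line secretes but that most tumor cultures do
must come from the non-tumor compartment. `passes` requires below-LOD
in *all* cell-line profiles and detection in a *strict* majority
(fraction > 0.5) of TME profiles; exactly half does not pass.

## The correlation screen and candidate rule

Migration is correlated with NPX on **absolute counts** (not
normalized percents), averaged per sample across replicates and
donors, using Pearson correlation with a t-distribution p on n−2
degrees of freedom. BH correction is applied within one subset's
protein family (the per-subset display convention); a global family is
available by flag. Significance is q < 0.05 by default; because
figure legends in this literature often conflate starred p-values with
corrected values, `use_unadjusted = TRUE` reproduces the other
reading. The positive-direction requirement (r > 0) applies at
selection, not at screening, so the screen table remains a complete
description of both directions.

Constant migration or protein columns yield flagged degenerate
records excluded from the BH family rather than errors.

## Signature scoring

Scores are cohort Z-scores: each gene is z-scored across samples
(sample SD), and a sample's signature score is the mean z over
signature genes present in the matrix. This is the most common reading
of "signature Z-score" axes; a `score_method` switch is reserved for
alternatives. Zero-variance genes contribute z = 0, absent genes are
dropped with `n_genes_used` reporting how many were used, and by
construction each signature's scores average to zero over the cohort
(asserted to 1e−9). Composite signatures resolve to duplicate-free
unions of their components, recursively. The responder comparison
(3 MPR vs 13 NPR by default) uses the exact rank-sum test — with 560
possible assignments the smallest attainable two-sided p is
2/560 ≈ 0.0036, worth knowing when interpreting "significant" at such
cohort sizes.

## The synthetic-data generator

The generator exists because raw data of this kind are typically not
depositable. Its *fixed* design parameters mirror the emulated study:
11 cell lines of which 3 HPV-positive, 28 TME-conditioned media, 2
PBMC donors per medium with duplicate test wells, a 92-protein panel
with 4 planted stroma-only chemokines (named CCL7, CCL8, CCL13, CXCL5
after their real-world counterparts), and a 16-sample expression
cohort with 3 responders.

The invented parts, and why they look the way they do:

* **Latent secretion** is log-normal. The four planted chemokines
  share a per-tumor stromal-activity factor (`stromal_sdlog = 0.8`)
  times idiosyncratic log-normal variation (`chemokine_sdlog = 0.4`
  around a median of 8 units): chemokines secreted by a common
  stromal compartment should co-vary across tumors, and that shared
  variation is what makes each of the four individually detectable in
  a 28-sample correlation screen. Cell lines secrete none of them.
  24 panel proteins are "silent" everywhere, so roughly 65–70 of 92
  proteins come out detected in the TME.
* **NPX** = per-protein baseline + log2(1 + secretion) + Gaussian
  assay noise (`npx_noise_sd = 0.3` log2 units). The per-protein LOD
  sits at the `lod_quantile = 0.9999` quantile of the baseline noise
  distribution, i.e. baseline + ~3.7 SD: with 44 cell-line x planted
  observations per simulation, a laxer quantile would let single
  noise excursions above LOD defeat the all-cell-lines-below
  requirement in a nontrivial fraction of runs, which is an artifact
  of the flag being strict rather than anything biological.
* **Counts** are negative binomial (`count_dispersion = 0.02`, i.e.
  size 50 — modest overdispersion beyond Poisson, as flow counts
  show) with mean
  `baseline_subset x donor_effect x (1 + sum_p w_p,subset x s_p)`.
  Chemokine weights are nonzero only for cDC1 (0.12) and cDC2 (0.18):
  T cells do not respond, reproducing the central negative finding
  this design is built around. Donor effects are multiplicative
  log-normal (`donor_sdlog = 0.25`) per donor x subset, emulating the
  PBMC donor variability that motivates the QC rule.
* **Control wells**: 4 negative and 4 positive wells per donor versus
  2 test wells per attractant. Controls anchor every threshold and
  every normalization on the plate, and a 2-SD threshold estimated
  from only two replicates is dominated by SD estimation noise
  (raising the false-call rate several-fold), so running more control
  wells than test wells is both the realistic plate layout and the
  statistically sound one.
* **Expression**: standard-normal genes; responders get a +1 SD shift
  on all genes of the "up" signatures (chemokine, DC, myCAF, iCAF)
  and none on the "flat" ones (eCAF, pericyte).
* **Determinism**: one master seed; sub-generators use offsets +1
  (secretome), +2 (migration), +3 (expression), so re-simulating one
  layer never perturbs another.

**What passing tests show — and do not.** The generator produces
clean, correctly specified data: log-normal secretion, negative
binomial counts, Gaussian NPX noise, no batch effects, no plate
effects, no missing wells, LODs that are exactly what the generative
model says they are. Recovery and calibration results on it
demonstrate that the *pipeline logic* is correct and well calibrated
under its own assumptions. They do not demonstrate robustness to the
things real data add: plate-to-plate LOD variation, non-monotone
dose-response, donors whose responsiveness differs per subset in
correlated ways, or chemokines secreted by tumor cells themselves
(which the presence contrast is structurally blind to).

## Problem sizes and runtime choices

The test suite runs the full generate–call–screen–select loop over
100 seeds for recovery and 100 for null calibration, 200 expression
cohorts for signature power, 1,000 random vectors for the BH oracle,
and 5,000 null draws for Pearson calibration — sizes chosen so the
whole suite completes in a few minutes while leaving the binomial
noise on estimated rates well inside the asserted margins.
`scripts/acceptance.R` recomputes the same quantities from scratch at
the same sizes.

## Known limitations

* The presence contrast cannot nominate chemokines that tumor cells
  also secrete; it is a stroma-derivation filter, not a relevance
  filter.
* Pearson correlation on counts is sensitive to heavy tails;
  the screen deliberately matches the conventional analysis rather
  than a rank-based alternative, and the two can disagree on
  borderline proteins.
* With 3 responders the rank-sum test's discreteness means "p < 0.05"
  is nearly the extreme of its attainable range; signature results at
  such sizes are screening evidence, not confirmation.
* The Dunn adjustment multiplies by the number of comparisons
  requested; users comparing many post-hoc pairs should request all
  pairs to get the conventional, more conservative family.
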