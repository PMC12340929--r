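---
title: "Methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cortexpheno` implements the statistics used to phenotype a heterozygous
mutant mouse cortex across five data modalities — single-nucleus/pseudobulk
transcriptomics, co-expression modules, slice calcium imaging, sleep
hypnograms, and design-based stereology — together with synthetic-data
generators that produce every input with recorded ground truth. This
vignette explains each model, its tunable parameters, the numerical
choices, and the reasoning behind design decisions that were genuinely
open. It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## Pseudobulk differential expression

Nucleus-level counts are aggregated to sample-level pseudobulk within one
cell population (`aggregate_pseudobulk()`); the sample, not the nucleus,
is the experimental unit. The DE engine (`de_test()`) is deliberately
simple and fully transparent:

1. counts → counts-per-million (CPM) → `log2(CPM + 1)`. The pseudocount
   of 1 bounds the logFC of genes with zero counts.
2. Expression filter: a gene is tested if CPM ≥ 1 in at least half the
   samples of either genotype group. (A fixed-count rule such as "CPM ≥ 1
   in ≥ 6 samples" does not transfer across populations whose pseudobulk
   sample count varies, so a proportional rule is used.)
3. Group test. Without a batch factor this is the Welch two-sample *t*
   between genotypes on the log2 values, and logFC is the HET − WT
   difference of group means. With a batch factor, each gene is fit by
   ordinary least squares on genotype + batch and the genotype
   coefficient's *t* (with *n − p* residual df) is used; logFC is the
   batch-adjusted genotype effect. The two-stage alternative — subtract
   the batch fit, then run Welch on the adjusted values — ignores the
   degrees of freedom consumed by the batch estimate and is measurably
   anticonservative in simulation (its null p-values fail a uniformity
   check that the package's own invariants require), which is why the
   one-stage OLS *t* is used whenever batch is modeled.
4. Benjamini–Hochberg adjustment within the population; `baseMean` is
   the mean CPM across all samples of the contrast.

This engine is a documented stand-in for shrinkage-based DE packages:
dispersion shrinkage is intentionally out of scope, and every downstream
stage (`de_burden()`, `dem_test()`) accepts any table with columns
`gene, logFC, pval, padj, baseMean`, so externally produced results can
be plugged in unchanged.

## DE burden and its permutation test

Burden is the percentage of significant genes among expressed genes:

* the expression floor is the minimum `baseMean` among genes with raw
  p < 0.05 (`min_expression_threshold()`; 0 if no such gene);
* burden = 100 · #{significant ∧ baseMean ≥ floor} / #{baseMean ≥ floor},
  with adjusted p < 0.05 as the default significance rule. Both the
  floor rule (raw p) and the numerator rule are exposed as configuration.

`burden_permutation_test()` permutes sample-level genotype labels —
within batch when one is present, since batch-confounded relabelings are
not exchangeable — and reruns the entire pipeline per permutation,
including the expression floor (freeze it with `freeze_threshold = TRUE`
if desired). With 5 vs 5 samples only 252 distinct assignments exist, so
the implementation enumerates them exhaustively whenever their number is
at most `n_iter` and reports the exact p-value (the share of
assignments, observed included, whose burden reaches the observed one);
otherwise it draws `n_iter` Monte-Carlo permutations and uses the
add-one estimator, which cannot return 0. The statistic is direction-free,
so the test is two-sided by construction and invariant to swapping the
genotype labels.

**Discreteness caveat.** Under a global null the BH-based numerator is
almost always zero (BH rejects anything with probability ≈ α at most),
so the burden statistic is massively tied at 0 and the exact test is
conservative — in the package's own calibration suite its rejection rate
sits well below the nominal 0.05. The calibration property is therefore
asserted on the raw-p numerator rule, whose near-continuous statistic
makes the exact permutation p essentially uniform, while the BH rule is
asserted *valid* (never anticonservative). Both assertions run on 200
null datasets of 2,000 genes at 5 vs 5 samples.

## Co-expression module statistics

`module_score()` is binned-control scoring: genes are placed in `n_bins`
(default 24) quantile bins of mean expression, each module gene draws
`n_controls` (default 100) control genes from its own bin (module genes
excluded; draws independent across module genes), and the score is the
mean module expression minus the mean control expression per unit. The
defaults are the conventional ones for this family of scores; matching
on expression removes the depth/abundance component, making the score 0
in expectation for an unstructured module and invariant to adding a
constant to all genes of a unit. The control draw is deterministic given
`seed`.

`annotate_clusters()` assigns each cluster the argmax-scoring marker
module; exact ties are broken lexicographically by module name — a
deterministic, documented rule — and flagged rather than hidden.

`dem_test()` compares a module's member-gene logFC distribution with the
reserved "grey" (unassigned-gene) module. The source procedure is
described as comparing *medians* with a *t*-test; a t-test compares
means, so the package runs a Welch two-sample *t* on the logFC
distributions and reports both medians for display; a one-sample variant
(module logFC against the grey median as a constant) is available behind
`one_sample = TRUE`. Bonferroni correction is applied over all
module × population comparisons actually performed in the call — the
most conservative defensible universe, matching a "significant in at
least one population" reading. Direction is the sign of the median
difference.

## Sex demultiplexing and proportions

Sex is called per nucleus from marker counts: male if the summed
Y-marker count (defaults Ddx3y, Uty, Eif2s3y, Kdm5d) reaches 1 with at
most 0 Xist counts; female if Xist reaches 1 with zero Y signal;
otherwise unknown. The thresholds are explicit package defaults (the
published tool's internal values are not available); they are strict on
purpose — with ambient contamination the `unknown` class absorbs
ambiguity rather than mislabeling. Genotype is then a pure lookup from
the pool design (each pool holds one male and one female of opposite
genotype), leaving unknown-sex nuclei unassigned.

Cell-type proportions are modeled untransformed by OLS on
genotype + sex + batch (`proportion_model()`), reporting two-sided *t*
p-values with *n − p* df and no cross-cell-type correction by default
(per-type p-values are what the source analyses report); a logit
transform is offered for boundary-heavy data.

## Calcium traces and microcircuit correlation

The trace pipeline is: neuropil subtraction (elementwise), zero-phase
FIR lowpass, ΔF/F, event detection, binary raster.

* **Filter**: linear-phase FIR designed with a Kaiser window to a
  passband edge of 0.5 and stopband edge of 0.65 *normalized to
  Nyquist* (so 2.5/3.25 Hz at 10 Hz sampling — the cited design call's
  convention), 25 dB stopband attenuation, applied forward–backward.
* **Baseline**: F0 is the 20th percentile of the full corrected trace
  (the source does not define F0); a rolling-percentile variant exists
  for drifting recordings. σ is the SD of the ΔF/F trace.
* **Events**: candidate onsets are one-frame ΔF/F increases > 2.5σ; an
  event extends from onset until ΔF/F first drops below 0.5σ (the
  source never defines the event end; a return-toward-baseline rule
  bounded away from noise was chosen, and the multiplier is
  configurable); overlapping candidates merge. An event is kept iff its
  peak reaches 8σ and its summed ΔF/F reaches 200σ (interpreted as
  σ·frames at the native frame rate — the published units are
  ambiguous). A flat trace yields zero events.

`depth_bin_correlation()` computes the Pearson (φ) correlation between
the binary rows of every neuron pair in a slice and averages by the
depth bins of the pair (default eight 75 µm bins from the pial surface);
the matrix is symmetric by construction, zero-variance rows are skipped
pairwise, and out-of-range neurons are excluded and counted.
`slice_group_compare()` averages all defined bin pairs per slice
(within-bin diagonal included — whether the source excluded it is
unstated) and the "superficial" rows (bin upper edge ≤ 300 µm, i.e.
neuron 1 superficial, matching the figure-legend definition; an
either-neuron reading can be had by symmetry of the matrix), then runs
Student *t*-tests across slices.

The generator (`sim_calcium_traces()`) draws per-frame Bernoulli event
trains — private events plus shared latent events accepted with
depth-dependent probability — convolves them with a single-exponential
kernel (τ default 0.6 s, mimicking a fast indicator; the source has no
generative model, so this is a stand-in with recorded truth) and adds
white noise and a neuropil component. Because the truth raster is an
i.i.d. Bernoulli frame process, the expected pair correlation has a
closed form (`expected_pair_correlation()`), which is what the
correlation stage is validated against. Depths are uniform on
[0, 600] µm so all eight bins are populated.

## Sleep architecture

Hypnograms are contiguous epochs over {Wake, NREM, REM} tiling exactly
24 h, ZT0 = lights-on. `hourly_state_seconds()` apportions epochs to
hours by exact interval overlap (an 86,400-point rasterization oracle is
used only in tests); row sums are exactly 3600 s. `phase_summary()`
reports per state × phase (light ZT0–12, dark ZT12–24) the total
seconds and the sample SD (n − 1; the source does not state the
denominator) of the 12 hourly values. `sleep_genotype_compare()` runs
unpaired Welch-corrected *t*-tests per state × phase × metric with no
multiple-testing correction, matching the raw-p reporting convention;
seconds are used throughout. All statistics are invariant to epoch
refinement. The generator is a first-order Markov chain at 10 s epochs
whose transition matrix switches at ZT12; the default light/dark
matrices were chosen once to mimic a nocturnal rodent (sleep-dominated
light phase, wake-dominated dark phase, REM entered only from NREM).

## Design-based stereology

* **Cavalieri** (`cavalieri_volume()`): V = d · ΣA over systematically
  spaced profile planes with uniform random start; point-counting mode
  uses V = d · (a/p) · ΣP. The estimator is unbiased for any region and
  exact for a prism whose height is a multiple of d.
* **Optical fractionator** (`optical_fractionator_count()`):
  N = ΣQ⁻ · (1/ssf)(1/asf)(1/tsf) with ssf = t/d, asf = frame/grid area,
  tsf = h/t̄. The unique counting point is the topmost z of the soma
  sphere — a nucleolus surrogate, since the synthetic tissue does not
  model nucleoli separately. Counting frames respect exclusion edges
  (left and lower forbidden), the dissector sits g µm inside the
  section, and t̄ is the site-weighted mean measured thickness (equal to
  nominal thickness in synthetic sections). Grid rotation by a random
  angle is available but off by default: unbiasedness for uniform
  tissue needs only the random translation.
* **Nucleator** (`nucleator_volume()`): v = (4π/3) · mean(l³) over
  isotropic rays from the reference point; exact on spheres, unbiased
  for any star-shaped profile.

The unbiasedness suite uses a 10,000-soma block of 1000 × 1000 × 300 µm
with a fractionator spec of 50 × 50 µm frames on a 100 × 100 µm grid,
h = 10 µm, guard 2 µm, t = 20 µm, d = 40 µm. These fractions (ssf 1/2,
asf 1/4, tsf 1/2) were chosen once so the expected raw count E[Q⁻] is in
the hundreds, which an empirical CE below 0.15 requires (Poisson CV
≈ 1/√E[Q⁻]); a production microscopy spec such as 18 × 18 × 10 µm frames
on a 480 × 480 µm grid samples a fraction ≈ 3·10⁻⁵ of the block and is
exercised separately as arithmetic on the derived fractions. Gundersen
CE formulas are not implemented; the empirical CE over replicates is
reported instead.

## Synthetic-data conditions and seed discipline

One global seed fans out to named child streams
(`child_seed(seed, key)`, a string-hash/Lehmer composition kept inside
32-bit range), so adding a generator never shifts another's stream, and
every generator is bit-identical under a fixed seed. The count
generator matches the study design: 5 vs 5 samples, two batches,
alternating sex, negative binomial with variance μ + μ²·dispersion
(dispersion → 0 giving the Poisson limit), baseline abundances
log-normal around ~32 CPM, library sizes 4–6 × 10⁵. Gene means use a
constant normalizing denominator so planted logFCs appear exactly in
the count means. Nuclei pools mirror the two-pool, opposite-genotype
design; marker dropout is Bernoulli per count.

What the generators do *not* emulate: ambient RNA, doublets, UMI
saturation, mitochondrial contamination, movie segmentation artifacts,
EEG scoring noise, tissue shrinkage and lost caps in sectioning.
Passing tests therefore demonstrate correctness of the statistics under
their stated models, not robustness to those real-data pathologies.

## Problem sizes used by the test and acceptance suites

Calibration: 200 null datasets × 252 exhaustive permutations at
2,000 genes; DEM recovery: 100 simulations of an 80-gene +0.5 logFC
module; calcium: 36,000-frame (1 h at 10 Hz) simulations; stereology:
200 random-start replicates; demultiplexing: 4,000 nuclei at dropout
0.2. These sizes reproduce the study's stated design conditions where
the source states them and otherwise were fixed once at values that give
the Monte-Carlo precision each assertion needs.

## Known limitations

* The DE engine does not shrink dispersions; at pseudobulk sample sizes
  its per-gene power is below that of shrinkage engines, which is why
  every downstream stage accepts external DE tables.
* The exact burden permutation p is conservative for heavily tied
  statistics (see above).
* `proportion_model()` treats proportions as unconstrained responses;
  compositional dependence between cell types is not modeled.
* The calcium event detector is threshold-based; no spike inference or
  deconvolution is attempted beyond the three-rule criterion.
* Stereology assumes perfectly registered, shrinkage-free synthetic
  sections; `t̄` equals nominal thickness by construction.
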