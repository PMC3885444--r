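---
title: "Methods: comparing the biological impact of a branded and a generic complex drug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing the biological impact of a branded and a generic complex drug}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A glatiramoid is a stochastic copolymer: no chemical assay fully
characterises it, and no pharmacodynamic marker exists. What can be
measured is its biological impact — the transcriptional response of
immune cells activated by it. `glatcomp` compares two drug products
(a branded medicine and a generic) against a manufacturing reference
standard and a vehicle (medium) control on a probe × sample matrix of
log2 expression intensities, and asks whether the generic is (i) as
*consistent* across production batches and (ii) *biologically equivalent*
in the genes and immune cell types it modulates.

All analyses assume background-corrected intensities on the log2 scale
(a `--log2-input auto` policy transforms linear input when the matrix
maximum exceeds 50), quantile-normalised so each array shares one
distribution, and chip-batch-adjusted (empirical-Bayes location/scale
adjustment with treatment protected as covariate). Analyses are
probe-level; probes map to genes only for enrichment.

# Batch-consistency suite

**Activation filter.** Variability in medium-only samples is assay noise;
variability induced by activation is the biology of interest. A probe
enters the analysis when a one-sided variance F-test finds it
significantly more variable under either drug arm than under medium
(union over arms, raw p < α = 0.05). Both this filter and the
directional GA-vs-generic counts use one-sided tests — the scientific
question ("more variable than") is directional — and no multiplicity
correction, because the output is a descriptive count compared between
arms, not a discovery list. The filter is applied first and the
directional comparison restricted to filtered probes.

Two subtleties are worth knowing. The two filter arms share the medium
variance estimate, so their false-positive events are positively
correlated and the union rate on null data sits between α and the
independence rate 1 − (1 − α)². And because the same sample variances feed
the filter and the directional tests, null probes selected through the
small generic arm (n = 11, so a noisy variance estimate) re-use their
inflated estimate in the directional test: even on exchangeable data the
directional counts are asymmetric. The subsampling sensitivity analysis
(below) is the pipeline's control for exactly this effect, and group
variances are computed on unmerged technical replicates except where
noted.

**Tolerance method.** Process-capability thinking applied to expression:
the acceptable window per probe is the inclusive `[min, max]` of
reference-standard expression (inclusive because a sample *at* the
observed extreme is within the observed range). Probes are the top 1000
by |log2 fold change| of reference standard vs medium, after an
expression floor of 6.00 log2 units on the mean of whichever group is
higher (reference standard for up-probes, medium for down-probes) —
low-intensity probes are noise-dominated and would contaminate the panel.
The per-product percentages of samples within tolerance, sorted
ascending with a stable probe-ID tie-break, give the
"probes failing a given specification" curve.

**Variance ratio.** `r = s²_generic / s²_GA` per probe (denominator
n − 1), ranked descending with probe-ID tie-break; a zero GA variance
yields an `Inf` sentinel, sorted first and flagged rather than silently
dropped.

**Coefficient of variation.** `CV = sd / mean` of log2 intensity per
probe within a product, after averaging technical replicates (merging is
an explicit stage flag, default off elsewhere, because only the CV and
sensitivity analyses are defined on biological replicates). A mean ≤ 0
leaves the CV undefined and flagged.

**Subsampling sensitivity.** Ten random draws of 11 GA samples (matching
the generic group size, after replicate merging) re-run the filter and
the directional counts; a two-sided paired t-test on the per-draw count
differences summarises the result. Draw seeds are derived substreams of
the user seed and recorded in the output. Constant differences are
degenerate (t undefined): p = 1 if all zero, else 0, with a flag.

# Differential expression and consensus

Five tests per probe, each BH-adjusted: one-way fixed-effects ANOVA;
a moderated linear fit; Welch t (pooled available by flag — with unequal
group sizes and possibly unequal variances Welch is the safer default);
signal-to-noise ratio `(μ₁−μ₂)/(σ₁+σ₂)` with each class sd floored at
`max(0.2·|μ|, 0.2)` and two-sided significance by class-label permutation
(1000 permutations by default, exhaustive enumeration when ≤ 10,000
distinct splits, add-one smoothing otherwise); and Wilcoxon rank-sum
(exact when the combined n ≤ 20 without ties, normal approximation with
continuity correction otherwise).

The moderated fit shrinks per-probe residual variances toward a common
prior: `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`, with `d₀, s₀²` estimated
by method of moments on the log residual variances (Newton inversion of
the trigamma function), and the contrast tested on `d₀ + d_g` df. The
default contrast is the medium-adjusted effect
`(GA − generic) − (generic − medium)` on group-mean coefficients — note
it weights the generic arm twice; the conventional
`(GA − medium) − (generic − medium) = GA − generic` is available via
`contrast = "conventional"`.

A probe is a **consensus** finding when all four parametric q-values are
≤ 0.05 *and* every signed statistic (fold change, t, SNR, moderated
effect) points the same way. Wilcoxon-only lists are kept separate; they
feed the pathway over-representation analysis. Note a resolution
constraint: a permutation p cannot fall below 1/(B + 1), so with few true
positives among many probes the SNR q-value is floored at roughly
`m / (B·k)` for k discoveries — raise `n_perm` when the discovery set is
small relative to the probe count.

# Condition patterns

For the six unordered pairs of the four conditions, two-group one-way
ANOVA p-values (identically pooled two-sided t, F = t²) are computed per
probe, and probes are matched against significance masks, e.g.
*up-only-generic*: the three generic-containing pairs significant
(p < α), the other three not (p > α; p = α matches neither, read
strictly from the "less than"/"greater than" definitions), plus a
direction predicate mean(generic) > mean(medium). Raw p-values are used
(an optional BH mode exists, default off) — the method is a pattern
classifier, not a discovery procedure. The four built-in templates
(up/down-only-generic, up/down-GA-and-reference-standard-only) use the
general rule: pairs crossing the affected/unaffected boundary must be
significant, pairs within either side must not.

Because the three SIG pairs of a template share the affected condition's
samples, their p-values are strongly positively dependent: on null data
the joint match rate exceeds the product of marginal rates severalfold.
The test suite checks the match count against a wide band around the
independence reference for this reason. The three NS constraints also cap
attainable sensitivity near (1 − α)³ ≈ 0.86 even at large effect sizes.

# Enrichment

**GSEA.** Genes are ranked by SNR (probe scores collapsed to genes by the
maximum-|score| probe, the desktop-tool convention), and a weighted
Kolmogorov–Smirnov running sum scores each set: hits advance by
|score|^p (p = 1) normalised over hits, misses retreat by 1/(N − N_hit);
ES is the signed maximum deviation, with an exact-magnitude tie resolved
toward the positive extremum for determinism. NES normalises by the mean
|ES| of same-sign permutations; nominal p is the same-sign permutation
tail (add-one smoothed); FDR q is the GSEA-style ratio of same-sign tail
fractions of pooled normalised permutation scores, capped at 1.
Permutation is over gene sets by default — the study's class sizes
(11–34) are small and unbalanced, which makes phenotype permutation
coarse; phenotype permutation is available by flag.

**Over-representation.** Upper-tail hypergeometric p with a minimum
overlap of 3 genes applied *before* BH adjustment (sets that cannot
meaningfully overlap should not dilute the correction).

**Cell types.** A reference compendium (gene × cell-type mean
expression, user-supplied, ImmGen-like) yields margin specificity scores
`spec(g,c) = mean(g,c) − max_{c'≠c} mean(g,c')` — at most one positive
entry per gene. For each cell type the reference set is
`{g : spec(g,c) > τ}` (τ = 1.0 log2 units) and the query is tested
hypergeometrically, BH across cell types. A score-sum reading (the summed
specificity of the query, with an optional permutation test) is reported
descriptively: a hypergeometric test applies to counts, not sums, so the
count-based test is primary. The margin score is this package's
formulation of cell-type specificity; other compendium-specific scores
can be emulated by supplying a transformed reference.

# Synthetic studies and what they show

`simulate_study()` emulates the real design: 22 reference-standard, 34 GA
(30 product batches), 11 generic (5 batches), 8 medium samples (the
medium count is this package's choice; the design leaves it open),
randomised over 18 chip batches. Expression is Gaussian on the log2
scale — baseline N(7, 1.5²), chip-batch effects N(0, 0.3²) per
probe × batch, residual sd 0.5, all in log2 units, chosen once as
realistic bead-array magnitudes — plus planted structure with recorded
ground truth: shared activation effects (±1.0 on 5 % of probes, with an
extra 0.3-sd activation-variability component in activated arms), a
variance-inflated generic subset (sd × γ, default γ = 2, i.e. a 4-fold
variance ratio, on 100 probes), generic-only and GA-and-RS-only shift
sets (±1.0 = two residual sd, 50 probes each), optional technical
replicates, and an optional t-distributed noise flag for robustness
checks. Companion generators plant disjoint cell-type signatures
(margin 3, entry noise 0.3) and gene-set collections with decoys.

Recovery tests isolate what they measure: the variance-inflation checks
run a configuration with only the inflation planted (no batch structure,
no activation sets), since each additional variance component — and
notably the scale part of the empirical-Bayes batch adjustment, which
partially renormalises per-batch spread — attenuates the measured ratio
below γ². At the pinned conditions (γ² = 4 on 100 of 10,000 probes,
n = 11 vs 34) the sampling distribution puts roughly 60 % of planted
probes in the ranking's top 100: planted ratios are 4·F(10, 33) against
9,900 F(10, 33) nulls whose top tail crosses the planted bulk. The
pattern-sensitivity and cell-type checks use the same isolation
principle. Test and acceptance problem sizes (10,000-probe null studies
× 3 seeds; 5-seed recovery runs at 2,000–10,000 probes) are the
package's chosen balance between statistical resolution and suite
runtime.

Passing these tests shows the machinery is correct and calibrated under
the generative model. It does not show robustness to what the generator
omits: probe-level intensity-dependent noise, correlated probe blocks,
non-Gaussian heavy tails (unless enabled), batch–treatment confounding,
or annotation error. Conclusions on real data still require the
pipeline's own diagnostics (PCA screen, CV plots, sensitivity analysis).

# Numerical conventions

* Quantile normalisation: ties receive the mean of the implicated
  order-statistic means (average-rank convention).
* Batch adjustment: `simple` (per-batch mean-centering of
  covariate-adjusted residuals) preserves each probe's grand mean exactly;
  the empirical-Bayes method recenters on pooled estimates and preserves
  it only approximately. A single batch returns the input unchanged; a
  singleton batch is an error advising merge or exclusion.
* PCA outlier screen: first two PCs of probe-centred data (no scaling,
  preserving intensity structure); each axis is centred on its median and
  scaled by its MAD before the k·sd radius test (default k = 4), because
  mean/sd standardisation lets a lone outlier mask itself (its distance
  is bounded by √n). Flagged samples are reported, never auto-removed.
* Degenerate inputs are flagged, not dropped: zero-variance F-test
  denominators (p = 1 if both degenerate, 0 otherwise), zero GA variance
  in ratios (`Inf` sentinel first), CV at non-positive means (NA),
  constant sensitivity differences (p ∈ {0, 1}), kernel densities of
  constant data (bandwidth floor 10⁻³).
* All rankings break ties by probe ID for bit-reproducibility; every
  randomised stage takes an explicit seed and the pipeline manifest
  records parameters and content hashes of all outputs.
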