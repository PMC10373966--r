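---
title: "senscreen: models, simulators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{senscreen: models, simulators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senscreen)
```

This vignette is the package's own account of its science: the models and
procedures it implements, what the synthetic-data generators do and do not
emulate, the numerical conventions, and the design decisions taken where
more than one reasonable choice existed.

# The two readouts

The package targets screens in which senescence — and its reversal by a
treatment — is read out two ways.

**Optically**, through a nucleocytoplasmic-compartmentalization (NCC)
reporter: a nuclear-localized mCherry paired with a nuclear-export eGFP.
In a healthy cell the channels are spatially anti-correlated (mCherry in
the nucleus, eGFP in the cytoplasm); when compartmentalization
deteriorates, nuclear mCherry leaks into cytoplasmic puncta that sit in
the eGFP-rich cytoplasm, and the per-cell Pearson correlation of the two
channels rises. The per-cell correlation, aggregated as mean ± SD per
condition, is the screen statistic; the Z-factor
`1 - 3(sd_pos + sd_neg)/|mean_pos - mean_neg|` summarizes whether the
separation between positive and negative controls is wide enough,
relative to noise, for a large-scale screen (values near 1: robust;
values at or below 0: unusable).

**Transcriptomically**, through bulk RNA-seq contrasts between quiescent,
senescent, and treated senescent samples: a senescence signature, the
fraction of it a treatment reverses, pathway-level enrichment, a
transcriptomic age, and signature-to-signature association.

# Synthetic data: what is emulated, and what is not

## Reporter fields

`simulate_ncc_field()` builds each cell as a concentric disk/annulus pair:
a nuclear disk carrying uniform mCherry and a cytoplasmic annulus carrying
uniform eGFP. A configurable `mislocalization_fraction` *f* of each cell's
total mCherry mass is relocated into isotropic 2-D Gaussian puncta
(sigma = `puncta_radius`, truncated at 3 sigma, clipped to the annulus and
renormalized), and an `egfp_nuclear_leak` fraction of eGFP mass is placed
in the nucleus. A constant background and clipped additive Gaussian noise
complete the image.

The bookkeeping is exact by construction: per-cell total mCherry is
conserved across *f* (signal is moved, never created), and at `f = 0`,
`noise_sd = 0` the cytoplasm holds exactly zero mCherry above background.
The tests lean on these identities.

The geometry is deliberately schematic. Real fibroblasts are not annuli;
there is no illumination gradient, no out-of-focus light, no cell-to-cell
intensity variation, no touching cells at the default density. Passing
tests on these fields therefore validate the *quantification machinery* —
mask accounting, correlation support, conservation, monotonicity of the
readout in *f* — not the segmentation of real micrographs, which is out of
scope. Puncta centers are rejection-sampled with a minimum separation of
`4*sigma + 2` pixels so that distinct puncta stay resolvable by
connected-component counting; crowded annuli may realize fewer puncta than
requested, and the per-cell truth table records the realized count.

## Count matrices

`simulate_counts()` draws `counts[g, s] ~ NB(mu = p[g, group] * L[s],
size = 1/phi)`: each group has per-gene expected expression proportions,
library sizes `L` are log-uniform over `library_size_range` (to exercise
normalization), and `phi` is a common dispersion, so marginally
`Var = mu + phi * mu^2`. Baseline log2 expression is uniform on [3, 9].
Senescence-responsive genes are shifted by ±`senescence_log2fc` in
senescent groups; in treated groups (labels `"senescent+<treatment>"`) a
`reversal_fraction` of them returns to the quiescent mean. Age genes get
log2 expression linear in age with slopes `~ Normal(0, age_slope_sd)`
(units: log2 expression per year), anchored at the mid-range age.

What this does not model: per-gene dispersion trends, outlier counts,
batch effects, correlated gene modules, or compositional shifts beyond the
planted effects. The type-I calibration and recovery results below are
therefore statements about the engine under clean NB sampling.

# Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `mislocalization_fraction` | 0.3 | mid-range phenotype; the demo uses 0 vs 0.8 for quiescent vs senescent conditions |
| `senescence_log2fc` | 2 | matches the signature fold-change threshold scale (FC > 2); the demo pipeline uses 2.5 |
| `dispersion` (phi) | 0.1 | typical bulk RNA-seq biological CV (~0.3) |
| `samples_per_group` | 6 | power analysis, below |
| `library_size_range` | 5e5–2e6 | a 4-fold spread to make normalization do real work |
| `n_age_genes`, `age_slope_sd` | 0, 0.02 | a 70-year age range at slope SD 0.02 spans ~1.4 log2 units, a realistic weak-per-gene/strong-in-aggregate clock signal |
| signature cutoffs | `p_adj < 0.01`, FC > 2 | the senescence-signature convention |
| reversal cutoff | `p_adj < 0.05` | the treatment-effect convention |
| GSEA `n_perm` | 5000 | permutation resolution `p >= 1/5001`; tests and the demo use fewer for speed |
| clock `l1_ratio` | 0.5 | balanced elastic net; penalty grid log-spaced over six decades, 5-fold CV |

**Replicates: a power-analysis choice.** The DE engine is an unmoderated
per-gene Welch *t* (see below). To call a planted `log2FC = 2–2.5` gene at
the BH-effective per-gene level (~1e-3 with a few hundred discoveries
among 2000 genes), with log-scale residual SD ≈ 0.55, the closed-form
two-sample power is ≈ 0.22 at n = 3, ≈ 0.65 at n = 4 and ≈ 0.99 at n = 6
(`power.t.test(n, delta = 2.5, sd = 0.55, sig.level = 1e-3)`). The
generator therefore defaults to six replicates per group, where signature
recovery and the reversal-fraction statistic are well determined.
Three-replicate designs are realistic for sequencing studies but depend on
variance-moderated engines (empirical-Bayes dispersion shrinkage) for
their power; with this package's transparent engine they leave planted
effects under-detected, which would confound tests of the *procedure* with
tests of *power*.

# The DE engine and its substitution

The canonical engine for this design is an NB GLM with dispersion
shrinkage (DESeq2-style). This package deliberately substitutes a simpler,
fully transparent chain — median-of-ratios size factors,
`log2(normalized + 1)`, per-gene Welch *t*, BH — because the claims the
package makes are about the *signature, reversal, enrichment, clock and
association procedures downstream of any DE engine*, and a transparent
engine makes every number reproducible by hand. The engine sits behind the
`de_test()` interface so a moderated engine can be swapped in without
touching anything downstream. Consequences to keep in mind: no dispersion
shrinkage (hence the replicate choice above), and a mildly conservative
null (the measured type-I rate at n = 3 is ~3.5% at nominal 5%,
within the calibration band but below it in expectation, as is typical
for small-sample *t* tests on discrete counts).

Other conventions: genes with zero counts in all samples are dropped
(their logFC is undefined); the pseudocount is 1 on normalized counts;
"FC > 2" is applied directionally (`log2fc > 1` for up, `< -1` for down);
both-groups-constant genes get `p = 1` when equal and `p = 0` when
different; `t` tests default to the Welch form with a `var_equal` flag
for the pooled (Student) form.

**Reversal classification.** For a senescence-upregulated gene, the
treatment contrast (treated vs senescent) classifies it *reversed* if
significantly decreased, *exacerbated* if significantly increased,
*unchanged* otherwise — significance alone is not enough; the direction
must oppose the senescence change. This direction-aware rule is an
interpretation (the alternative counts any significant change), chosen
because "reversal" is a directional claim; the three classes partition the
signature by construction, and `reversed_pct` is rounded to one decimal to
match the precision at which such percentages are conventionally reported.

# Pre-ranked GSEA conventions

- **Ranking metric.** `-log10(p) * sgn(logFC)`, descending. The literal
  form `log10(p) * sgn(logFC)` (which puts the most significant
  upregulated genes at the *bottom*) is available behind a
  `literal_sign` flag; the default follows the universal convention that
  significant upregulated genes rank first. `p = 0` is clamped to the
  smallest positive double, with a clamp count recorded. Score ties break
  lexicographically by gene id, so rankings are deterministic.
- **Enrichment score.** Weighted Kolmogorov–Smirnov running sum, weight
  exponent 1: hits add `|score|/sum_set|score|`, misses subtract
  `1/(N - K)`; ES is the signed maximal deviation. The implementation
  evaluates only hit boundaries (the running sum is piecewise linear
  between hits); it is tested for exact agreement against a full
  prefix-sum enumeration and against the reference implementation of the
  same statistic in fgsea. When positive and negative deviations tie in
  magnitude, the positive peak is reported. If all set scores are zero,
  hits fall back to equal weights `1/K`.
- **Null.** Gene-label permutations: size-matched random sets drawn from
  the ranked universe, shared across gene sets of equal size. The p-value
  is the add-one estimator restricted to same-sign permutation scores,
  `p = (1 + #{|ES_perm| >= |ES_obs|, same sign}) / (1 + n_same_sign)`, so
  `p >= 1/(1 + n_perm)` always; `NES = ES / mean(|ES_perm|, same sign)`.
  This is the simple permutation estimator, labelled as such — no
  multilevel/adaptive refinement. Sets smaller than 2 after intersection
  with the universe are dropped with a warning.

# The transcriptomic clock

The published clocks this workflow emulates apply fixed coefficient
vectors; those coefficients are not public, so the package ships a
*trainer* and treats clock application — preprocessing, imputation,
centering, group statistics — as the procedure of record. That is the
central substitution in the package.

- Preprocessing is fixed as `log2(median-of-ratios-normalized + 1)`
  followed by per-gene z-scaling; in application mode the *training*
  means/SDs are used, and genes with zero training SD are excluded from
  the model (logged).
- Missing clock genes are imputed with their training averages — i.e.
  `z = 0`, contributing nothing beyond the intercept; the imputation
  count is reported. A sample missing every clock gene predicts exactly
  the intercept.
- Training is `glmnet::cv.glmnet` with `alpha = 0.5`, lambda grid
  `10^seq(1, -5)` (60 points), 5-fold CV with a seeded fold assignment;
  the model stores everything needed for standalone application and
  serializes to a single JSON document.
- ΔtAge centers predicted ages on the *median* of the quiescent controls
  (exactly zero for the control median; idempotent; invariant to global
  shifts), and group comparisons are independent *t*-tests BH-adjusted
  across pairs.

The trainer targets chronological age in years; lifespan-adjusted
biological-age variants are out of scope.

# Signature association

Pairs of signatures are correlated by Spearman's rho over the union of
each signature's `top_n = 300` lowest-p genes (ties in p broken by gene
id), dropping genes absent from either signature (the per-pair `n_used`
is reported); p-values come from the *t*-approximation with average ranks
for ties. The matrix is BH-adjusted over its upper triangle; the diagonal
is `rho = 1, p_adj = 0` by convention and excluded from the adjustment.

# NCC quantification conventions

- **Correlation support.** Pearson r is computed per cell over the union
  of that cell's nucleus and cytoplasm pixels, on raw intensities (no
  thresholded-Pearson or Manders variants), and aggregated as mean ± SD
  per condition. Per-field or whole-image correlation would mask
  cell-level heterogeneity; per-compartment correlation would discard the
  nuclear/cytoplasmic contrast that carries the signal.
- **Segmentation.** Otsu threshold on the smoothed (sigma 2 px) mCherry
  channel for nuclei, distance-transform watershed (tolerance 3) to split
  touching nuclei, minimum nucleus area 50 px, then Voronoi-style
  propagation of cell territories over the combined-channel Otsu
  foreground; cytoplasm = territory minus nucleus. These defaults are
  tuned to the simulator's scale (nuclei of radius 8–12 px). Known
  limitation: nuclei are detected from mCherry, which is nuclear *by
  construction* only in compartmentalized cells; at high mislocalization
  the channel is punctate and the detector over-segments. Quantification
  of strongly senescent fields should use ground-truth or
  externally-supplied masks (`truth_segmentation()`, the pipeline's
  `segmentation: "truth"` default); `segment_field()` is validated on
  low-mislocalization fields.
- Zero-variance cell regions are flagged and excluded from aggregates
  rather than erroring. Pixel coordinates are 0-based `(row, col)`;
  line profiles interpolate bilinearly and report positions in pixels
  along the segment. Puncta counting applies a white top-hat (disc brush,
  9 px) before thresholding; components below `min_area` are discarded.
- Images are stored as floating-point matrices and written to 16-bit TIFF
  by linear scaling (the scale factor is returned and recorded), so
  round-trips are invertible to within one quantization step.

# Seeding and reproducibility

Every simulator takes an explicit integer seed and evaluates inside a
scope that restores the caller's RNG state. Multi-stage runs derive
per-stage seeds from one master seed by the fixed rule
`derive_seed(seed, stream) = (seed + 7919 * stream) mod (2^31 - 160)`,
with stable stream indices per stage — so re-running a pipeline with the
same config and seed is numerically identical, and disabling one stage
never changes another's numbers. Identical configs give bit-identical
fields and count matrices.

# Problem sizes used by the tests

The test and acceptance suites run the machinery at deliberately modest
sizes, chosen so each property is determined well beyond its tolerance:
type-I calibration at 50 replicates x 2000 genes (100,000 null tests,
Monte-Carlo SE ~0.07 points); clock recovery on ten cohorts of 200
samples x 1000 genes (300 age genes, slope SD 0.02) with a 25% holdout;
colocalization monotonicity over ten seeds x ten cells per fraction;
oracle sweeps of 1000 (BH) and 200 (enrichment score) random instances;
and the full demo pipeline at 2000 genes, six replicates per group, and
two imaging conditions of two fields each. These sizes are the package's
validation design, not limits of the implementation.

# Known limitations

- The DE engine trades power at small n for transparency; use more
  replicates or swap in a moderated engine for n = 3 designs.
- The image simulator's schematic geometry means segmentation accuracy
  results do not transfer to real micrographs.
- Proportion-based count simulation means strong planted shifts slightly
  perturb all other genes' effective proportions (compositional
  coupling), as in real sequencing.
- The GSEA p-value estimator is bounded below by `1/(1 + n_perm)`;
  strongly enriched sets saturate at that floor rather than yielding
  vanishing p-values.
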