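---
title: "ProteoVasc: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ProteoVasc: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and where the design was genuinely open and a choice had to be
made.

# The data model

A `ProteoSet` is a `SummarizedExperiment` holding one `abundance` assay
(proteins × samples) with explicit missingness (`NA`; a raw intensity of 0
means "not quantified" and is converted to `NA` during sum scaling, never
carried as a number). The sample manifest lives in `colData`: multiplex
batch, a logical GIS flag for pooled-standard channels, diagnosis group,
ordinal neuropathology scores (CAA 0–3, CERAD, Braak), continuous and binary
imaging traits (WMH burden, microbleeds, infarcts), and nuisance covariates
(age in years, post-mortem interval in hours, sex, *APOE4* dose 0–2,
endothelial cell proportion in [0, 1]).

A `scaleTag` slot tracks the processing state and only moves forward:
`raw → sum_scaled → log2 → tampor_corrected → regressed`. Each stage checks
its precondition, so a matrix cannot, say, be batch-corrected twice or
log-transformed before scaling.

# Preprocessing

**Sum scaling.** Each sample's present intensities are divided by the
sample's intensity total and multiplied by the maximum total across samples,
equalizing loading. Note that this already removes any *sample-level*
multiplicative distortion — including whole-sample batch offsets — which is
why the batch-correction contract below is exercised on unscaled log2
intensities.

**Missingness filter.** Proteins with `>= maxMissingFrac` missing samples
are removed; the default 0.5 uses a *strict* inequality (a protein missing
in exactly half the samples is removed). The threshold is a parameter
because published analyses vary (some retain at > 30% non-missing).

**PCA outlier flagging.** Samples whose score on any of the first 2
principal components exceeds 4 standard deviations of that component's
scores (strict `>`) are flagged. The rule is deliberately conservative and
single-pass (no iterative re-fitting); removal is a separate explicit subset
so the analyst sees what is dropped. Missing values are imputed by the
protein mean for the decomposition only and never written back.

# TAMPOR batch correction

Multiplexed batches are tied together by a pooled global internal standard
(GIS) run as a channel in every batch. In log2 space the correction is:

1. **Ratio step.** For protein *g*, sample *s* in batch *b*:
   `R_gs = log2(x_gs) − D_gb`, where `D_gb` is the median log2 value over the
   batch's GIS channels (`useAllNonGIS = FALSE`, the default) or over all
   non-GIS samples of the batch (`useAllNonGIS = TRUE`, for designs without
   a usable GIS). Missing denominators propagate; a protein missing in *all*
   denominator samples of any batch is dropped with a warning rather than
   imputed.
2. **Two-way median polish.** Alternately subtract each protein row's median
   (over the denominator-defining samples) and each sample column's median
   until `max(|row medians|, |col medians|) < tol` (default 1e-8 log2 units)
   or 250 iterations. Convergence is verified on the current state *before*
   any further subtraction, so the returned matrix itself satisfies the
   centering contract, and a second application is a no-op (idempotence is
   exact, not approximate).

Everything is additive in log2, equivalent to a multiplicative ratio polish
but numerically stable, invariant to global additive constants, and with
the standard midpoint convention for even-count medians. On GIS-ratio data
the polish typically converges immediately (two iterations on the synthetic
reference conditions — the iteration count is always exposed in the
`TamporState`). GIS channels are corrected alongside but dropped from the
output by default; nothing downstream uses them.

The correction removes batch structure only up to the GIS channel's own
measurement noise: the denominator's error is shared by every sample in the
batch, leaving a residual batch-constant per protein on the order of the
GIS technical noise. This floor is visible in the variance-explained
diagnostics and is inherent to ratio-based correction, not a defect of the
polish.

# Bootstrap covariate regression

For each protein, log2 abundance is modelled by OLS on the covariates to
remove (age, PMI, cell proportion, one-hot-encoded batch by default) plus
any *protected* terms (e.g. diagnosis), which are estimated but never
subtracted. The model is refit on 1000 resamples of samples with
replacement; the **median** bootstrap coefficient of each removed covariate
is subtracted times the *centered* covariate, preserving each protein's
grand mean. The median across resamples is robust to influential samples —
the reason for bootstrapping rather than a single fit. (The source method's
description of this step reads "median estimated coefficient of variation";
subtracting a coefficient of variation times a trait is dimensionally
incoherent, so the package implements the median estimated *coefficient*.)
With `nBootstrap = 1` and resampling disabled the procedure reduces exactly
to OLS residualization, which the tests verify.

`varianceExplained()` reports the marginal single-factor R² per protein — a
deliberately simple stand-in for a full mixed-model variance partition,
because its only role is before/after diagnostics. The raw R² of a B-level
factor has a finite-sample floor of about `(B − 1)/(n − 1)` even on
factor-free data; `adjusted = TRUE` applies the degrees-of-freedom
correction (clipped at 0), which is unbiased near zero, and is what the
package's own correction-contract checks use.

# The signed co-expression network

**Correlation.** Biweight midcorrelation with `u = (x − med)/(9·MAD)`
(unscaled MAD) and Tukey weights `(1 − u²)² · 1{|u| < 1}`. Missing values:
each vector's median and MAD come from its own observed entries, and
cross-products run over pairwise-complete observations — a vectorizable
policy that coincides with the textbook formula on complete data. A
zero-MAD vector cannot be biweighted, so any pair involving one falls back
to Pearson and is flagged; pairs with fewer than 4 complete observations
are `NA` and flagged.

**Adjacency and TOM.** Signed soft-thresholding
`a_ij = ((1 + cor_ij)/2)^β` with β = 8 preserves the sign of co-expression
(anticorrelated proteins get near-zero adjacency rather than high
adjacency). Topological overlap uses the `mean` connectivity denominator by
default (`min` available). Undefined correlations become zero adjacency with
a flag rather than poisoning the matrix.

**Module detection.** Average-linkage clustering of `1 − TOM`, then a
static cut at the fraction `q = 0.99 − 0.02·deepSplit` of the merge-height
*range* (`h₀ = min + q·(max − min)`, plus a 1e-12 epsilon so degenerate
trees with all-equal heights stay in one cluster). deepSplit ∈ {0..4}
(default 3) maps higher values to lower cuts and hence finer splits. The
range-fraction cut was chosen over a quantile-of-heights cut deliberately:
in a realistic proteome most merges are among background (non-module)
proteins near the top of the tree, so any rule that always leaves a fixed
*fraction of merges* uncut either lumps planted modules or promotes
background clumps; a rule anchored to the height scale is robust to how
many background proteins surround the modules. Branches smaller than
`minModuleSize = 10` dissolve into the unassigned pool. The PAM stage then
offers each unassigned protein to the module with the smallest average
`1 − TOM` dissimilarity, accepting only if that beats its average
dissimilarity to the unassigned pool and, with `pamRespectsDendro = TRUE`,
only among modules present in the smallest enclosing dendrogram cluster
that contains any assigned protein. This simplified cut is not
label-identical to the reference dynamic hybrid algorithm; the package's
acceptance surface is planted-module recovery, which its own tests measure.

**Eigenproteins.** Each module member is z-scored across samples (per-protein
mean imputation inside the decomposition only); the eigenprotein is the
first right-singular vector of the member × sample matrix, scaled to unit
variance and sign-oriented so its bicor with the module's mean z-profile is
nonnegative. `varExplained` is the leading squared singular value over the
total.

**Refinement.** Modules whose eigenproteins cluster below dissimilarity
`1 − cor = 0.07` (average linkage) merge, repeatedly, keeping the smallest
module id. Then membership is swept by three rules until a fixed point (cap
30 sweeps), with eigenproteins and kMEs recomputed after every sweep:
grey out proteins whose best kME is below 0.30; assign grey proteins whose
best kME clears 0.30; move assigned proteins whose kME to their own module
trails the best kME by more than 0.10. `auditReassignmentRules()` re-checks
the fixed point from scratch, and final modules are renumbered by
nonincreasing size (ties broken by the smaller original label, for
determinism).

# Trait association

Module-level: bicor of each eigenprotein with each numeric-coded trait,
p-values from the Student-t transform `t = r·sqrt((n − 2)/(1 − r²))`
(p floored at 1e-300). Protein-level group comparisons: Welch t-test
(unequal variances — the safer default where a plain two-sample t was
reported) or one-way ANOVA with Tukey HSD; Tukey p-values below 10^−8.5 are
replaced by Bonferroni-corrected pooled-variance pairwise p-values, which
remain numerically meaningful far into the tail where the studentized-range
CDF saturates.

Proteome-wide scans fit `outcome ~ protein + covariates` per protein — the
protein is the exposure, the pathology the outcome. Continuous outcomes use
OLS; binary outcomes logistic regression; the 0–3 ordinal severity a
proportional-odds model (cumulative logits, common slope, maximum
likelihood). Protein abundances are standardized within the complete cases
for the ordinal and logistic fits, so betas are per-SD of abundance;
non-converging or separated fits are flagged and excluded from the adjusted
ranking (`m` counts only fitted proteins, and the Bonferroni cutoff
`0.05/m` is reported explicitly). Missing outcome or covariate values drop
the sample for that scan only, with `n_used` recorded.

# Permutation module enrichment

Given per-gene p-values from any scan, the module statistic is the mean of
`−log10 p` over the module's genes. The null redraws gene sets of the same
size, without replacement, from the background of all genes that carry both
a statistic and a label — *including* unassigned genes, since they were
measured and could have been drawn into a module. `Z = (T − mean T*)/sd T*`
and the one-sided exact p is the permutation estimator `(b + 1)/(m + 1)`;
when `choose(N, k) ≤ 10 · nPerm` the subsets are enumerated exhaustively and
the same estimator is applied over the enumeration. The `−log10` transform
makes larger statistics more significant, so positive Z means enrichment —
matching the sign convention of the figures this statistic feeds (`raw_p`
and effect-signed variants are provided; under `raw_p` the direction
inverts, which the documentation flags). Degenerate nulls (zero variance)
return Z = NA and p = 1 with a flag rather than erroring, so pathological
inputs don't halt a pipeline. The finite-population correction of the
`permp` estimator is not reimplemented; the plain `(b + 1)/(m + 1)` is
conservative.

Gene-set overlap (cell-type markers, ontologies via GMT) uses the one-sided
Fisher exact test — the hypergeometric upper tail at the observed overlap —
with the sample odds ratio `ad/bc` (`Inf` allowed) and BH adjustment across
the full module × set grid.

# Module preservation

Reference-defined modules are evaluated in a test dataset through four
statistics computed with bicor throughout: mean within-module |correlation|
and mean |kME| in the test data (density), and the correlations of
intramodular connectivity and of the correlation entries themselves between
reference and test (connectivity). Permutation nulls redraw size-matched
gene sets from the shared genes; `Zdensity` and `Zconnectivity` are medians
of their pairs, `Zsummary` their average, with the standard thresholds
(≥ 1.96 preserved, ≥ 10 highly preserved, inclusive). This is a reduced,
documented statistic set rather than the full published battery; the
package validates it by the planted-structure ordering (self-preservation
≫ 10, destroyed structure < 1.96) rather than by agreement with a specific
implementation. Modules with fewer than 5 shared genes are skipped;
zero-variance null statistics are dropped from the medians with a flag.

# The synthetic-data generator

`simulateProteomics()` draws from the model

```
log2 x_gs = base_g + λ_g · f_{m(g),s} + b_{batch(s)} [+ b_{g,batch(s)}] + Σ_c β_gc z_cs + ε_gs
```

with per-module latent factors `f` standardized to exactly zero mean and
unit variance, loadings `λ ~ N(1, 0.2²)` truncated to `|λ| ≥ 0.1` (so
planted membership is always recoverable in principle), residual noise
`ε ~ N(0, 0.8²)` log2 units, per-batch offsets `b ~ N(0, 0.4²)` (or fixed
values), base abundances uniform on [14, 20] log2 units, and centered
covariate effects. Intensities are `2^log2x`, so negatives are impossible by
construction. A cell goes missing with probability
`plogis(steepness · (midpoint − log2 x))` — missingness concentrates at low
abundance (MNAR), as in real reporter-ion data; the defaults (steepness 1,
midpoint 11) give roughly 1–2% missingness. GIS channels are the
within-batch per-protein mean of the non-GIS intensities plus technical
noise of 0.08 log2 units (≈ 5–6% CV): a pooled standard averages away
biological variation, so its noise is technical-only and fixed in absolute
terms rather than scaled to the biological `noise_sd` — this is also what
keeps the ratio-denominator noise floor below the batch-correction
contract. Traits come from designated module factors: the 0–3 severity
trait through a proportional-odds model with equally spaced cutpoints
(−1.2, 0, 1.2; near-balanced categories at zero effect), binary lesions
through a logistic link, and the continuous imaging burden as
`5 + β·f + N(0,1)` floored at zero. Identical seeds give bit-identical
output.

**Reference study conditions.** Six modules of 50 proteins in a
1000-protein proteome, 120 biological samples over 7 batches with one GIS
channel each, CAA (β = 0.8, ordinal) on module 1, microbleeds/infarcts
(β = 0.8/0.5, logistic) on module 2, WMH (β = 0.5, linear) on module 3.
`noise_sd = 0.8` puts planted within-module bicor near 0.6 — typical of
strong co-expression modules. The background pool is deliberately large
(70% of proteins): per-sample summary statistics — intensity totals in sum
scaling, column medians in the polish — must be dominated by non-module
signal for those operations to behave as they do on real proteomes, where
any single module is a small fraction of total intensity. With a
module-dominated toy proteome those statistics become mixtures of the
planted factors and contaminate every profile; that is an artifact of the
emulation, not a property of the method. An optional `batch_protein_sd`
adds protein-specific batch distortions (zero by default), which is what
makes batch correction observable downstream of sum scaling — pure
sample-level offsets are already absorbed by the scaling step.

**What the generator does not emulate:** peptide-level quantification and
roll-up, isotopic interference and ratio compression, correlated
missingness across proteins in a spectrum, non-Gaussian heavy-tailed
biological variation, or covariate–module confounding. Passing tests on
this generator therefore demonstrate the pipeline's statistical contracts
(recovery, calibration, invariances) under a clean factor model — not
robustness to every artifact of real acquisition.

# Numerical choices and degenerate inputs

* TAMPOR tolerance 1e-8 log2 units; convergence is checked before
  subtraction so the output matrix itself is centered to tolerance.
* bicor p-values use the Student-t transform with `n − 2` df; p-values are
  floored at 1e-300 so `−log10 p` stays finite.
* Correlations are clamped to [−1, 1] after floating-point round-off; the
  self-correlation diagonal is set to exactly 1 for non-constant vectors.
* Eigenprotein sign ties (zero bicor with the mean profile) fall back to
  the inner product's sign.
* Module renumbering breaks size ties by the smaller original label;
  `max.col(ties.method = "first")` makes kME argmax deterministic.
* Ordinal fits require 3+ observed outcome levels; logistic fits 2; fits
  that fail, warn, or separate are flagged, not dropped silently.
* Zero-variance permutation nulls (enrichment and preservation) are
  reported as degenerate rather than raising errors.
* The pipeline derives per-stage seeds as small fixed offsets from the root
  seed so stages can be re-run in isolation deterministically.

# Problem sizes used by the test suite

The tests validate contracts at sizes chosen to finish in minutes on one
CPU: oracle equivalence on 20 randomized instances per statistic; exhaustive
versus Monte-Carlo enumeration on backgrounds of ≤ 12 genes; the full
pipeline and enrichment on the reference conditions above (one seed, 1000
bootstrap resamples, 10,000 permutations); scan calibration on 2000 null
fits per model at n = 300 and sign recovery on 200 planted fits per model
at |β| = 0.5; preservation ordering on three seeds at 200 permutations; and
byte-identical reruns of the full pipeline at reduced permutation counts
(determinism is independent of the number of permutations).

# Known limitations

* The tree cut is a documented simplification of the dynamic hybrid
  algorithm; module *boundaries* can differ from the reference
  implementation even when module *recovery* is excellent.
* The preservation statistic set is reduced (four statistics, not the full
  published battery); Zsummary magnitudes are therefore not directly
  comparable to other implementations, though the classification thresholds
  are the standard ones.
* Ratio-based batch correction cannot remove batch variance below the GIS
  channel's technical-noise floor.
* `varianceExplained()` is a marginal diagnostic; correlated factors will
  double-count shared variance.
* The bootstrap regression assumes covariates are observed for all samples
  (complete-case per protein only in the abundance, not the design).
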