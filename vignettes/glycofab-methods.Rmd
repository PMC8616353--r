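---
title: "Models and methods behind glycofab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glycofab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycofab)
```

glycofab analyzes cohorts of N- and O-glycomes measured by LC-MS of
released glycans, with myeloid leukemia cell-line panels as the motivating
use case. This vignette explains the models each stage implements, why the
defaults are what they are, what the synthetic cohort generator does and
does not emulate, and the numerical choices that matter.

## The glycan model

Glycans are named by monosaccharide composition: `H` hexose, `N`
N-acetylhexosamine, `F` fucose (deoxyhexose), `S` N-acetylneuraminic acid,
`P` phosphorylation, `Su` sulfation, each token carrying a positive count,
with an optional single lowercase suffix distinguishing structural isomers
of one composition by elution order (`H5N4S2a` elutes before `H5N4S2b`).
The suffix is purely ordinal; no structural meaning is read into the
letter. Parsing is strict — unknown or duplicated tokens and non-positive
counts are errors that name the offending token — and formatting a parsed
name reproduces it exactly.

`alditol_mass()` returns the neutral monoisotopic mass of the *reduced*
glycan (the alditol), the analyte form after borohydride reduction in
porous graphitized carbon workflows: the sum of dehydrated residue masses
(Hex 162.052824, HexNAc 203.079373, dHex 146.057909, NeuAc 291.095417,
HPO~3~ 79.966331, SO~3~ 79.956815 Da) plus the reduced terminus
(H~2~O + H~2~, 20.026215 Da). It supports plausibility checks of m/z
columns in quantification exports; no isotope-pattern computation is done.

### Type classification

When no curated annotation is available, `classify_by_composition()`
assigns the glycan type from composition alone:

* class N — *paucimannose* iff HexNAc = 2, Hex ≤ 3, Fuc ≤ 1, NeuAc = 0;
  *oligomannose* iff HexNAc = 2, 4 ≤ Hex ≤ 9, no Fuc/NeuAc; *hybrid* iff
  HexNAc = 3 and Hex ≥ 4; *complex* otherwise.
* class O — *core 1* iff HexNAc = 1, else *core 2*. Cores 3 and 4 are not
  modelled; they are not observed in the leukemia cell-line panels this
  package targets.

Two conventions deserve mention because the field is not fully
standardized. First, H4N2 (Man4) is classified oligomannose: the
paucimannose/oligomannose boundary is drawn at three hexoses with an
optional single core fucose, the common glycobiology convention for
"truncated" paucimannosidic species. Second, phosphorylated
Hex~x~HexNAc~2~ species remain oligomannose — phosphorylation is a derived
trait layered on the oligomannose family, not a fifth type, mirroring how
phospho-oligomannose mass traces are presented alongside oligomannose in
chromatogram annotations.

Curated annotations (established from MS² evidence) always override the
composition-based default. `validate_annotation()` returns *all*
inconsistencies of a record — linkage counts that do not sum to the NeuAc
count, fucose position counts inconsistent with the composition, bisection
or antennae on O-glycans, epitope flags without their structural
prerequisites — and reports disagreement with a decisive composition-based
type as a warning-level violation rather than an error, because the
curator may know better than the composition.

## The trait engine

A trait definition is a pure predicate over the curated record plus three
choices: numerator weighting, denominator set, and output form. The value
of a percentage trait in a sample is

$$\mathrm{trait} = 100 \cdot
  \frac{\sum_{g \in \text{carriers}} a_g}
       {\sum_{g \in \text{denominator}} a_g}$$

with $a_g$ the fractional abundance. Defaults:

* **Weight = presence.** A glycan carrying two α2,3-linked sialic acids
  counts once. Count weighting (abundance × occurrence count) is available
  per definition because conventions differ for multiply-sialylated
  glycans, but the default panel reads as fractional abundances of carrier
  glycans.
* **Denominator = within-class total.** All default percentages are "% of
  N-glycans" or "% of O-glycans". `complex_only` and `complex_hybrid`
  denominators are selectable per call, since several quantities commonly
  quoted for complex-type features (e.g. the share of tri/tetra-antennary
  structures or of sialylated glycans) are only meaningful relative to
  complex(+hybrid) glycans — relative to the class total they would be
  bounded by the complex-type share itself.
* **Antennarity** is the abundance of glycans with ≥ 3 antennae, not an
  abundance-weighted mean antenna count.
* **Sialic acids of undetermined linkage** count toward total sialylation
  but toward no linkage-specific trait; for heavily branched
  multisialylated species the linkage often cannot be assigned.
* **(s)Le^x/a^ on N-glycans** pools sialylated and neutral
  antennary-fucosylated forms into one composite trait; on O-glycans,
  Le^x/a^ and sLe^x/a^ remain separate traits.

The N-glycan type percentages close to 100 within each sample by
construction, as do core 1 + core 2 for O-glycans; this closure is a
tested invariant. Ratio traits (core1:core2) return `NA` on an empty
denominator rather than raising.

## Quantification QC and normalization

Records are kept iff the retention time matches, the isotope dot product
is ≥ 0.85 and the signal-to-noise ratio is ≥ 6 — both thresholds
inclusive, both configurable. Kept areas are normalized to fractional
abundances per glycan class (N and O independently), so the analysis is
invariant to per-sample loading and instrument response. Because
fractional abundances are ill-defined over a partially rejected glycan
set, the pipeline renormalizes over the kept glycans per sample.

Missing cells of the percent-scale matrix are imputed with the constant
0.01 — a pseudo-abundance standing for "below quantification" — *after*
normalization and before any multivariate statistics, and the matrix is
not renormalized afterward. Observed cells are never touched; the
imputation mask is returned alongside.

Replicate precision is the per-glycan relative standard deviation
(sample standard deviation over mean, n−1 convention; the convention is a
deliberate choice since both appear in practice) across replicate rows,
averaged over glycans with mean fractional abundance ≥ 1% — low-abundance
glycans would dominate the average with ratio noise. Technical versus
biological precision is the same computation grouped by different
replicate labels.

## Statistics

**PCA.** Features are mean-centered and unit-variance scaled by default
(Pareto and no scaling are selectable for sensitivity analyses), then
decomposed by SVD. Loading signs are fixed so each loading vector's
largest-magnitude element is positive, making outputs reproducible across
platforms. The Hotelling T² statistic over the retained $A$ components,
$T^2_i = \sum_a t_{ia}^2/\lambda_a$, is compared with the limit
$\frac{A(n-1)(n+1)}{n(n-A)} F_{1-\alpha;A,n-A}$ at $\alpha = 0.05$ to flag
samples outside the 95% confidence ellipse. The pipeline fits the PCA on
glycan fractional abundances and derived traits jointly, so both appear in
the loading space.

**Trait–gene correlation.** Pearson r over shared samples with the exact
t-transform p-value, two-sided, and the conventional `*` (p ≤ 0.05) /
`***` (p ≤ 0.001) tiers on raw p-values. A Benjamini–Hochberg column is
emitted for reference but the tiers deliberately use raw p-values, since
screening-stage glycomics reports are conventionally presented that way;
users needing strict error control should use the `p_adj` column.

**Regularized CCA.** Both blocks are standardized; the canonical
eigenproblem is solved with $C_{xx} + \lambda_1 I$ and
$C_{yy} + \lambda_2 I$ in place of the within-block correlation matrices
(ridge regularization), keeping the problem well-posed when features
outnumber samples. Weights are normalized to unit variate variance under
the regularized metric; with $\lambda = 0$ on well-conditioned data the
canonical correlations agree with classical CCA (tested against the
QR-based `stats::cancor` to 10⁻⁶, and against `mixOmics::rcc` for ridge
penalties). The default $\lambda_1 = \lambda_2 = 0.1$ with $K = 2$
components is a mild, stable choice for trait-block/TF-block sizes around
25 × 10 at 20–200 samples; `tune_rcca()` offers a leave-one-out grid
search maximizing the held-out first canonical correlation when a
data-driven penalty is wanted. The cross-block similarity
$\mathrm{sim}(i,j) = \sum_{d \le K} \mathrm{cor}(X_i, Z_d)\,
\mathrm{cor}(Y_j, Z_d)$, with $Z_d$ the average of the d-th X- and
Y-variates, is reported **unclipped**: for $K > 1$ its magnitude can
exceed 1, and heatmap color scales should saturate at ±1.

**Hierarchical ordering.** Rows and columns of the similarity map are
ordered by agglomerative clustering with Euclidean distance and complete
linkage. Inputs are pre-sorted by label so tied merges resolve
deterministically; a permuted input yields the same leaf order.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be validated against
known ground truth without access to instrument data. Per FAB class it
fits a mean glycan-weight vector: starting from a baseline profile over
the packaged 52-glycan library (oligomannose-dominated N-glycome,
core-1-leaning O-glycome, as typical for myeloid cell lines), iterative
proportional fitting rescales trait-member glycans until the class means
hit a trait effect table; the defaults encode the contrasts characteristic
of FAB subtypes — high paucimannose, hybrid and Lewis-antigen levels in
the monocytic classes, high bisection, branching, sialylation, core 1 and
α2,8-sialylation in the erythroid class, strong phosphorylation in M3,
α2,8-sialylation absent from M2/M3 — with per-class values anchored to
published cell-line panels where available. The default effect table is
mutually consistent; IPF converges below 10⁻⁸ percentage points, and an
infeasible table (type targets not closing to 100, or a positive target
with no carrier glycan) is rejected before sampling. Residuals above 0.5
percentage points would be recorded in the ground truth and warned about.

Samples are drawn from class-specific Dirichlet distributions
(concentration 200 by default; within-class standard deviation of a
15%-abundance glycan ≈ 1.6 percentage points, a realistic between-line
spread within a subtype), independently for N- and O-glycans, so class-wise
closure holds exactly. Areas are the fractions times a log-normal total
area; QC metrics are drawn in the passing range with a configured fraction
of records re-drawn as failures (low idotp, low S/N, or retention-time
mismatch, chosen uniformly), and a configured fraction of records is
dropped as missing. One designated sample is emitted in technical
triplicate; the replicate log-noise default (σ = 0.07) is calibrated so
the realized triplicate average RSD of glycans ≥ 1% lands near 7.8%, the
precision reported for this type of workflow (the calibration accounts for
renormalization and the small-n bias of the sample standard deviation).

Expression of a linked gene is generated as
$\mu + \sigma\,(r\,z(t) + \sqrt{1-r^2}\,\varepsilon)$ with $z(t)$ the
standardized realized driving trait, so the planted correlation holds by
construction up to sampling error $\approx (1-r^2)/\sqrt{n}$; the default
panel plants GST links (e.g. a 0.96 ST8SIA6 → α2,8-sialylation link) and
TF links of both signs, plus unlinked background genes. The default
21-sample cohort mimics a realistic cell-line panel; statistical recovery
checks run at n ≈ 200 (34 per class) because at n = 21 the sampling error
of a correlation estimate (± ~0.2 for moderate r) would make quantitative
assertions vacuous.

What the generator does **not** emulate: chromatography and spectra
(retention times, isotope patterns — idotp and S/N are drawn, not
computed), glycan misannotation, batch effects and count noise in
expression (the emulated expression resource is already log-scale), and
biological covariance between traits beyond what the class structure
induces. Passing recovery tests therefore demonstrates the correctness of
the statistical machinery on data with the declared structure, not
robustness to all failure modes of real LC-MS data.

Recovery is scored by `score_recovery()`: sign agreement and absolute
error of estimated versus planted correlations, sign recovery of planted
links in the rCCA similarity map, mean silhouette of the FAB labels on the
first two PCA score dimensions, and per-class trait-mean error. Silhouette
summaries over seeded replicates use the mean across seeds; note the
standard silhouette statistic is slightly negative under exchangeable
(null) labels with small groups, which is why null-cohort checks compare
the mean against a band around zero rather than expecting exactly zero.

## Numerical choices and degenerate inputs

* Constant features: z-scoring sets them to zero with a warning; the
  pipeline drops them from the rCCA block (a constant column has no
  defined correlation).
* Zero denominators: ratio traits return `NA`; an all-zero sample-class in
  normalization is an error naming the sample.
* Matrix inverses in the rCCA use symmetric eigendecompositions with
  eigenvalues floored at machine epsilon; canonical correlations are
  clipped to [0, 1].
* All randomness flows from the single config seed; nothing reads the
  system clock.
* Determinism: identical seeds give byte-identical cohorts; identical
  inputs give identical pipeline results.

## Problem sizes

The shipped tests and the acceptance script use 21-sample cohorts for
end-to-end demonstrations (matching a realistic cell-line panel), 200
samples for stochastic recovery checks, 1,000 replicates for p-value
uniformity, and 20 seeds for class-separation summaries — sizes chosen so
the full suite exercises every claim at meaningful power while remaining
desk-scale.

## Known limitations

* Trait inference requires curated annotations; beyond the default type
  classifier, no structural traits are guessed from composition alone.
* The rCCA penalty default is a pragmatic choice, not an optimum; results
  for small sample sizes can be sensitive to it, which is why the
  similarity map should be read for sign structure rather than magnitude.
* Core 3/4 O-glycans, MS² fragment evidence, retention-time prediction and
  topology encodings (GlycoCT/WURCS) are out of scope.
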