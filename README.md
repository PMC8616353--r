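# glycofab

Integrated N- and O-glycomics trait analysis for leukemia cell-line
cohorts.

Glycomics experiments on cell lines — typically porous graphitized carbon
LC-MS of released, reduced glycans — report one fractional abundance per
glycan per sample. The biology, however, lives in *derived traits*:
structural features shared across many glycans, such as the four N-glycan
types (oligomannose, paucimannose, hybrid, complex), O-glycan cores 1 and
2, sialylation split by linkage (α2,3 / α2,6 / α2,8), core and antennary
fucosylation, bisection, branching, and tumor-associated antigens like the
(sialyl) Lewis x/a epitopes that mediate E-selectin binding. glycofab turns
glycan-level quantification into that trait panel and integrates it with
transcriptomics, so that cohorts of myeloid leukemia cell lines can be
compared across FAB (French-American-British) subtypes and linked to the
glycosyltransferases (GSTs) and hematopoietic transcription factors (TFs)
that plausibly drive their glycan phenotype.

The package covers, as tested R functions:

* **Glycan model** — parsing of composition shorthand (`H5N4F1S2a`: hexose,
  HexNAc, fucose, NeuAc, phosphate `P`, sulfate `Su`, plus an isomer
  letter), monoisotopic alditol masses, composition-based glycan-type
  classification, and validation of curated structural annotations. A
  curated library of 52 N-/O-glycan records ships with the package.
* **Trait engine** — a 26-trait panel (12 N, 14 O). A percentage trait is
  `100 · Σ abundance(carriers) / Σ abundance(denominator set)`, by default
  over the within-class total; the core1:core2 ratio is the one ratio
  trait.
* **Quantification QC** — record filtering at the standard thresholds
  (retention-time match, isotope dot product ≥ 0.85, S/N ≥ 6, inclusive),
  total-area normalization per glycan class, constant imputation of missing
  values (0.01), replicate RSD, and per-feature z-transformation.
* **Statistics** — PCA (unit-variance scaling) with the Hotelling T²
  95% limit `T²ₗᵢₘ = A(n−1)(n+1)/(n(n−A)) · F₀.₉₅(A, n−A)`; Pearson
  trait–gene correlation with `t = r√((n−2)/(1−r²))` p-values and the
  `*` / `***` tiers; regularized CCA solving the canonical eigenproblem
  with `Cxx + λ₁I`, `Cyy + λ₂I` (ridge regularization) and a clustered
  cross-block similarity map `sim(i,j) = Σ_d cor(Xᵢ, Z_d)·cor(Yⱼ, Z_d)`.
* **Synthetic cohorts** — a seeded generator that draws FAB-structured
  glycan profiles from class-specific Dirichlet distributions (class means
  fitted to a trait effect table by iterative proportional fitting) and
  plants gene–trait correlations of known size, so every stage of the
  pipeline can be scored against ground truth.

## Worked example

```r
library(glycofab)

# parse and mass-check a composition
rec <- parse_glycan_name("H5N4F1S2a")
rec$composition
#> <glycan composition> H5N4F1S2
sprintf("alditol mass: %.4f Da", alditol_mass(rec$composition))
#> "alditol mass: 2370.8566 Da"

# simulate a 21-sample cohort and run the full analysis
sim <- simulate_cohort(cohort_config(seed = 1))
res <- run_pipeline(sim$quant, builtin_glycan_library(),
                    sim$expression, sim$metadata)
res
#> <glycofab pipeline result>
#>   QC: 1108 kept, 29 rejected
#>   samples: 21, glycans: 52, traits: 26
#>   replicate RSD: 6.7%
#> <PCA> 21 samples, 2 retained components (uv scaling)
#>   explained variance: 32.4%, 11.6%
#>   Hotelling T2 95% limit: 7.768 (21 of 21 samples inside)
#>   rCCA: rho = 0.972, 0.951 (lambda = 0.1/0.1, K = 2)

round(res$group_means[c("M5", "M6"),
                      c("N_paucimannose", "N_bisection", "O_sia_a28")], 1)
#>    N_paucimannose N_bisection O_sia_a28
#> M5           17.2         0.4       0.7
#> M6            6.5         4.2       3.5

# recovery of the planted ground truth
rec <- score_recovery(sim$truth, res$correlations, res$pca,
                      res$traits, res$rcca)
subset(res$correlations, gene == "ST8SIA6" & trait == "O_sia_a28")
#>        trait    gene         r            p  n tier        p_adj
#> 26 O_sia_a28 ST8SIA6 0.9666565 1.069466e-12 21  *** 6.117345e-10
```

Reading the output: of the 1137 simulated quantification records, 29 fail
the QC criteria and are dropped with a per-record reason. After
normalization, the monocytic M5 group shows the expected high paucimannose
and low bisection relative to the erythroid M6 group, and α2,8-sialylated
O-glycans are enriched in M6. The planted ST8SIA6 → α2,8-sialylation link
(target r = 0.96) is estimated at r = 0.967 with a `***` tier. All 21
samples fall inside the Hotelling T² 95% ellipse of the 2-component PCA.

See `vignettes/glycofab-methods.Rmd` for the underlying models, parameter
choices and limitations.

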