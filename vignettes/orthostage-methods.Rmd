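---
title: "orthostage: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthostage: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
procedures, why each parameter has the default it has, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## The comparative problem

Two species support their offspring with different organs: a
marsupial-like query species with a short-lived yolk-sac placenta (an
avascular and a vascularised compartment) followed by a long, complex
lactation, and a eutherian-like reference species that does most fetal
support through its placenta. All datasets arrive as gene-by-sample
tables: 3'-tag counts (one read per transcript, so no length
normalisation is ever applied), or microarray intensities for the
reference developmental series. The analyses must therefore survive two
hostile facts: the platforms' scales are incomparable, and cross-species
comparison is only defined on one-to-one orthologs.

## Presence calling: the 1%-of-mean rule

Replicates of a dataset are averaged per gene; a gene is *expressed* when
its mean is at least `fraction` (default 0.01) of the dataset's grand
mean over genes. Design points:

* **The mean is per dataset**, not global across datasets: each table is
  processed independently, and the threshold then scales with library
  size, making the partition invariant to global rescaling. This is
  verified as a property (1000 random profiles in the test suite).
* **Equality survives.** "Below threshold" excludes, so a value exactly
  at the threshold is expressed (`>=`, not `>`).
* **All-zero profiles** call every gene not-expressed, with a warning:
  `0 >= 0` would technically pass, but presence on zero evidence is
  meaningless.
* **Cell fractions** (basal/luminal mammary) are combined by the per-gene
  *mean*, not the sum, keeping the combined profile on the same scale as
  single-fraction datasets. Because calling is scale-invariant, sum
  versus mean changes nothing downstream; the mean is chosen for
  interpretability.
* **Missing values are errors**, never imputed: every downstream step is
  presence- or rank-based, and silent imputation would corrupt ranks.

## Differential expression: `nb_wald_simple`

A two-group negative-binomial pipeline implemented from first principles
and deliberately simplified; results carry a `method = "nb_wald_simple"`
attribute so downstream users know what they are getting.

1. **Size factors** by median-of-ratios: for sample *j*, the median over
   genes positive in every sample of `k_gj / geomean_g`, then centred to
   geometric mean 1. The even-count median midpoint is taken on the log
   scale (the midpoint of two ratios is their geometric mean), matching
   the reference implementation of this estimator. If no gene is positive
   in all samples the function stops — a pseudo-reference fallback is
   intentionally not implemented.
2. **Dispersion** by method of moments under `Var = mu + alpha mu^2`:
   `alpha = max(0, (s^2 - mu)/mu^2)` on normalised counts within each
   group, combined across the two groups weighted by degrees of freedom,
   floored at 1e-8 so the Wald weights stay defined. No shrinkage toward
   a mean-dispersion trend: with the pooling designs this package targets
   (4 + 6 samples), moment estimates are noisy but unbiased enough for
   the downstream use (set membership, not effect estimation).
3. **Wald test**: per gene, an NB log-link GLM with intercept, group
   indicator and `log(size factor)` offset at fixed dispersion, fitted by
   iteratively reweighted least squares (closed-form 2x2 solves,
   vectorised across genes; convergence at 1e-10 on the coefficients,
   max 60 iterations; coefficients clamped to |beta| <= 30 to keep
   separation cases finite). `z = beta/SE` from expected Fisher
   information, two-sided normal p-values (the large-sample reference),
   `log2FC = beta / ln 2`, positive when the second factor level is
   higher. All-zero genes are flagged and given `p = 1`, `lfc = 0`.
4. **BH adjustment** via the standard step-up (delegated to
   `stats::p.adjust`; an independent brute-force step-up oracle checks it
   in the tests).

Omitted on purpose: dispersion-trend and fold-change shrinkage, Cook's
outlier handling, independent filtering, multi-factor designs. The
package's contribution is the comparative machinery around DE, and a
transparent stage is easier to reason about than a re-implementation
chasing parity with a mature estimator.

Calibration, measured by the test suite: under a complete NB null (2000
genes, 5 + 5 samples, dispersion 0.2) the raw type-I rate at 0.05 stays
within [0.025, 0.10] and the BH-selected fraction stays below 0.07;
planted 4-fold changes are recovered with the correct sign in >= 95% of
significant genes.

## Stage mapping: rank, then correlate

The common universe is computed **once per matrix**: genes called
expressed in *every* compared dataset (query placenta, reference series,
control organ), bridged through the one-to-one ortholog map. Per-cell
universes would make the correlations incomparable across the grid.
Within the universe each profile is ranked highest-first with average
ranks on ties, and every query-reference pair is scored by Pearson
correlation of the rank vectors — the tie-safe Spearman. The
`1 - 6*sum(d^2)/(n(n^2-1))` shortcut is deliberately avoided: it is
biased under ties, and ties are guaranteed here (zero counts).

Ranking is the entire cross-platform strategy: any strictly monotone
transform of either side's values (log, affine, saturating) leaves every
rank, hence every cell of the matrix, bit-identical. The test suite
asserts exactly that, with random monotone transforms.

The **control organ** column answers "is this conservation
placenta-specific or just species-specific?": for each query timepoint we
report `min(reference rho) - max(control rho)` and require it positive
(strictly — a tie counts as failure). Best-stage assignment is the argmax
over reference columns, ties broken toward the earliest stage and
flagged; real-data correlations essentially never tie exactly, but
determinism requires a rule.

Genes of the second species lacking an ortholog are dropped from
cross-species operations and counted in an `n_unmappable` attribute
rather than treated as absent: absence of mapping is not evidence of
absence of expression. The one-to-one restriction on the map is a
modelling choice the user should be aware of; multi-mapping orthology
must be resolved upstream, before the map is read.

## Stage-partition enrichment and convergence screens

The reference species' placenta-specific program, split into early
(pre-midgestation) and late genes, is crossed against presence of the
query ortholog into a 2x2 table; a Pearson chi-square (1 df) tests
whether the query placenta is biased toward the early program. The Yates
continuity correction is off by default — the uncorrected form is the
classical Pearson statistic and with the program sizes involved (hundreds
of genes) the correction is immaterial — but is exposed behind a flag,
and both variants are reported by the pipeline.

The convergence screens are pure set logic over called presence:

* shared co-option: `(placenta_A & placenta_B & organ_A) \ organ_B`;
* reference-placenta-only: `(placenta_B & organ_A) \ (placenta_A | organ_B)`.

Results are reported in query-species identifiers with the reference
ortholog attached. Control screens substitute the organ slots (liver,
testis) into the *identical* formula to estimate by-chance counts.
Over-representation of screen hits in annotation sets uses the one-sided
hypergeometric tail with BH across sets; the default universe is the
union of all expressed sets entering the screen, which is configurable.
No attempt is made to reproduce any web service's composite enrichment
score, and no GO-graph propagation is done.

## What the synthetic generator emulates

`sim_config()` defaults encode the study design end to end: 5000 ortholog
pairs; a query placenta with 4 avascular-compartment and 6
vascularised-compartment samples over days 21/23/25 (4 early vs 6 late);
query mammary timepoints; an eight-stage reference microarray series;
reference placenta/mammary-fractions/liver/testis/heart tag-count
datasets. Planted structure: 300-gene organ programs; a 340-gene early
and 70-gene late placenta-specific program of which the query expresses
90 and 10 ortholog subsets; a 77-gene co-opted set (both placentas plus
query mammary, silent in reference mammary); a 108-gene
reference-placenta-only set; 200 planted 4-fold DE genes per contrast.

Numerical choices, chosen once as plausible study conditions:

* **Baselines** are log-normal, `meanlog = log(50)`, `sdlog = 0.8` —
  roughly a 100-fold active dynamic range. Together with
  `organ_effect_sd = 0.8` (per-gene, per-organ log effects shared across
  species, making organs transcriptionally distinct), the lower tail of
  active expression stays clear of the 1% presence threshold, so organ
  membership is crisp by design: organ effects perturb *ranks*, presence
  is carried by the planted on/off structure.
* **Silenced means 0.1% of the gene's active mean**, not structural
  zero, so the 1% rule's boundary behaviour stays exercised — a silenced
  gene with a high baseline can brush the threshold, which is exactly the
  boundary case worth testing.
* **NB dispersion** uniform in 0.05–0.5, the range typical of bulk
  tag-count data; library sizes log-normal around 1e6 with CV 0.2.
* **The reference series decorrelates by a random walk** on the log
  scale, step sd 0.4 per stage, so adjacent stages are more
  rank-correlated than distant ones; early-program genes are active only
  before the midgestation boundary, late-program genes only from it on.
  Microarray intensities are an affine-log transform (offset 4, scale
  1.2 per log2 unit, Gaussian noise sd 0.25) of the underlying means —
  a deliberately distorted, floor-inflated scale that forces the
  rank-based pipeline to prove platform invariance (note the floor means
  a naive 1%-of-mean call on intensities calls everything expressed;
  presence information in the intersection comes from the tag-count
  datasets, which is faithful to how mixed-platform comparisons behave).
* **Query timepoints** deviate from their planted reference stage by
  per-gene effects of sd 0.3; the default planted stage is e10.5 for all
  three timepoints.
* **Determinism**: every sample draws from its own RNG stream derived by
  hashing the master seed with the sample's identity, so any dataset can
  be regenerated in isolation, replicates are reproducible individually,
  and the whole study is a pure function of `(seed, config)`.

What the generator does **not** emulate: read-level artefacts (no
sequences, no alignment or region-calling noise), multi-mapping
orthology, correlated gene programs beyond the planted block structure,
batch effects, and compositional distortions between sample groups.
Passing the planted-recovery tests therefore shows the *pipeline logic*
is sound under realistic noise — it does not certify performance on real
GEO/ENCODE data, where ortholog resolution and annotation quality
dominate.

## Problem sizes in the test suite

The suite runs the full study at its native size (5000 genes) where the
claim depends on it — stage recovery and control contrasts over 20 seeded
studies, co-option precision/recall over 20 studies, DE calibration at
2000 genes — and uses a scaled-down configuration (1500 genes,
proportionally smaller programs) for structural end-to-end checks where
only the plumbing is under test. Property checks (set-logic oracle
equivalence, BH and hypergeometric brute-force agreement, caller
invariants) run on hundreds to a thousand random instances.

## Known limitations

* The DE stage is intentionally simple; with fewer than ~3 replicates
  per group its moment dispersion estimates are crude, and its Wald
  p-values are mildly anticonservative at n = 5 + 5 (measured type-I
  ~0.06–0.09 at nominal 0.05). Treat its gene lists as screen inputs,
  not as publication-grade DE calls.
* The presence threshold is a single global fraction per dataset; genes
  hovering at the boundary can flip between datasets, which puts a floor
  on the attainable precision of presence-based screens (visible in the
  planted-recovery numbers, which sit near 0.95 rather than 1.0).
* Spearman on thousands of shared genes yields very tight correlation
  estimates, so small rho differences between adjacent stages can be
  "decisive"; the package reports the full matrix and margins rather
  than only the argmax so users can judge flatness themselves.
* One-to-one orthology discards lineage-specific duplications, which are
  exactly the genes most likely to be interesting in co-option stories;
  the unmappable tallies make the loss visible but do not recover it.
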