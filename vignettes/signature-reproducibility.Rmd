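---
title: "Benchmarking signature reproducibility in perturbation compendia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking signature reproducibility in perturbation compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrepro)
```

## The evaluation this package performs

Connectivity-map-style resources answer queries of the form "which
compounds induce a transcriptional state similar to this signature?". The
usefulness of the answer rests on three layers of reproducibility, which
this package measures on corpora where the truth is known:

1. **Within-dataset**: do replicate differential-expression (DE) profiles
   of the same condition — compound × concentration (µM) × cell line ×
   treatment duration (h) — agree with each other?
2. **Cross-dataset**: do two compendia ("platform A" and "platform B")
   agree for harmonized conditions?
3. **Retrieval**: does a query signature derived from one compendium
   retrieve its own compound from the other, and how does that degrade
   with cross-platform concordance?

A fourth, explanatory layer models *why* agreement varies: its
dependence on DE strength, on sample-level expression reproducibility,
and on compound dose and cell-line responsiveness.

## The generative model

`corpus_spec()` fixes the corpus design; `generate_ground_truth()` and
`simulate_corpus()` realize it. For gene $g$, sample $s$ on plate $p$:

$$
x_{gs} = b_g + u_p + \underbrace{f(d)\,\rho_{c\ell}\,\theta_{g}^{(c\ell)}
+ \delta_{g}^{(c\ell)}}_{\text{treatment samples only}} + \varepsilon_{gs}
$$

- $b_g$: per-gene baseline, drawn once per corpus from Uniform(4, 12) on
  the log2 scale. The downstream metrics are rank-based within profiles,
  so results are invariant to the baseline's distribution; a broad
  uniform is the simplest non-degenerate choice.
- $u_p$: scalar plate offset, $N(0, \texttt{plate\_effect\_sd}^2)$,
  shared by every gene on the plate. Because each treatment group is
  paired with a control group from the *same* plate pool, $u_p$ cancels
  exactly in fold changes — which is precisely why plate-matching of
  controls is enforced.
- $\theta^{(c\ell)}$: sparse effect vector of compound $c$ in cell line
  $\ell$; each gene is nonzero with probability `frac_de_genes` (default
  0.15) and nonzero effects are $N(0, \texttt{effect\_scale}^2)$ (default
  SD 2 log2 units, so a substantial minority of planted effects clear the
  ±1 fold-change cutoff at saturating dose — weak conditions are part of
  the design, not a defect).
- $f(d) = d^h/(\mathrm{EC50}^h + d^h)$: Hill dose–response (computed on
  the log scale for numerical stability). The underlying empirical
  phenomenon is a saturating dose-dependent rise in DE strength; the Hill
  form expresses it with a single interpretable midpoint (EC50, drawn
  from $10^{U(-0.5,1)}$ µM) and slope ($h \sim U(1,2)$), the standard
  pharmacological parameterization.
- $\rho_{c\ell} \in [0,1]$: cell-line responsiveness (default
  $U(0.25, 1)$); 0 means the cell line does not respond at any dose.
- $\delta^{(c\ell)}$: fixed per-(compound, cell line) platform
  distortion, $N(0, \texttt{platform\_noise\_sd}^2)$ per gene, drawn
  independently per platform and added to every treatment sample. It is a
  *systematic* artefact: unlike per-sample noise it does not average out
  with more samples, which is what makes two platforms disagree even at
  full effect-vector concordance.
- $\varepsilon_{gs}$: per-sample noise, $N(0, \texttt{sample\_noise\_sd}^2)$.

Platform B's effect vectors are
$\theta_B = \rho\,\theta_A + \sqrt{1-\rho^2}\,\eta$ with $\eta$ an
independent draw of the same sparse marginal, so their expected Pearson
correlation with $\theta_A$ is exactly `concordance_rho`. The random
draws do not depend on $\rho$: corpora generated at different
concordance levels under one seed share $\theta_A$ and $\eta$, so a
$\rho$-sweep varies concordance and nothing else.

A single master seed expands into named substreams (ground truth, each
platform, each subsampling step), so any stage can be regenerated
independently and two runs with the same configuration are byte-identical.

### What the generator does not emulate

No bead-array detection physics, no landmark-based inference of
non-landmark genes (landmarks are a flag, not a measurement model), no
count-level mean–variance relationship, no compound-class structure
(effect vectors are mutually independent), and no batch drift over time.
Passing tests therefore demonstrate that the *statistics and benchmarks
are computed correctly* and that they recover planted structure; they do
not certify how any real compendium will score.

## Statistical conventions

- **Spearman correlation** is Pearson on average ranks. Constant vectors
  have undefined rank correlation and yield `NA` (excluded and counted in
  summaries) rather than a fabricated 0.
- **Ternary Jaccard** counts same-direction DE calls over any-DE calls;
  two all-zero vectors score 0, because "nothing is DE in either" must
  not be confused with "the same genes are DE". Thresholds: ±1.0 on log2
  fold change; moderated z-scores are first de-standardized by
  $\sqrt{n}$ and cut at ±2.0. Values exactly at a cutoff count as DE, so
  counts are reproducible.
- **Signatures**: per-direction lists are ordered by descending
  magnitude; ties at a truncation boundary break lexicographically by
  gene id; a gene with value exactly 0 never enters a top-k list. The
  query-size contract (10–150 per direction) disqualifies — with a
  recorded reason — rather than pads.
- **Moderated z-scores** are computed as mean difference over pooled
  standard error with a variance floor of 0.01 (guarding near-constant
  genes in small groups). This is a deliberately plain moderation; no
  replicate-weighting scheme is applied.
- **Group pairing**: each treatment replicate group is paired with the
  largest control group sharing its plate pool (ties: lexicographic
  label), both subsampled with a seeded uniform draw to a common size in
  [2, 20].
- **Enrichment scoring** is the unweighted two-sided KS running sum; the
  up/down combination zeroes on sign conflict, otherwise
  $(ES_{up} - ES_{down})/2$. Compound-level aggregation over a compound's
  profiles is the maximum score (median available). Rank ties use
  competition ranking with lexicographic tie-break. This engine is the
  package's own documented scorer; all benchmark claims in this package
  are claims about it.
- **Decile success** uses $\lceil 0.1 K \rceil$ computed from the ranked
  universe size $K$, so it is meaningful for any corpus size.
- **Meta-rankings**: rank product is the geometric mean of ranks; the
  percentile ordering uses the 75th percentile with linear interpolation
  (quantile type 7). Both operate on ranks, not scores.

## The explanatory models

The regression of within-dataset agreement is
$\hat{Y}_i = B_1 X_{1i} + B_2 X_{2i} + B_3 X_{3i}$ with $Y$ the
condition's maximal pairwise DE correlation, $X_1$ the lesser DE-gene
count of the pair achieving that maximum (the "limiting profile"), and
$X_2, X_3$ the in-replicate (min-of-maxima) and cross-replicate
(max-of-cross-pairs) sample-level agreements *of that same pair*. All
four variables are z-scored before an OLS fit, so the coefficients are
standardized; an intercept is retained for numerical stability (it is ~0
after z-scoring). `simulate_regression_data()` plants chosen standardized
coefficients exactly — unit-variance response, a common predictor
correlation solved analytically so the population $R^2$ hits its target —
which is what makes coefficient-recovery tests sharp.

For dose trends, pooled pairwise agreement values within a condition
share profiles and are not independent, so the asymptotic p-value of the
rank-correlation trend test is anti-conservative. `dose_trend()` therefore
offers a condition-level permutation test (`n_perm`): concentration labels
are permuted across conditions, keeping each condition's pairs together,
giving a calibrated two-sided p. The eligibility filters (≥3 replicate
profiles per condition, ≥3 distinct concentrations per compound) follow
the standard practice of not inferring dose trends from degenerate
designs.

## Problem sizes and defaults

The default corpus is 1,000 genes (200 landmarks), 20 compounds × 4
concentrations (0.08–10 µM) × 2 cell lines × 6 h, 3 replicate groups per
condition and 4 samples per group, with `sample_noise_sd` 0.5,
`platform_noise_sd` 0.25, `plate_effect_sd` 0.3 and `concordance_rho`
0.7 — a deliberately mid-noise regime in which agreement statistics are
neither saturated nor pure noise. The test suite uses smaller corpora
(150–500 genes, 3–20 compounds) chosen so each property is expressed with
margin: e.g. the concordance sweep uses 10 compounds × 2 cell lines at
400 genes, and the dose-recovery analysis uses an 8-point dose curve
spanning EC50 ($10^{-1.5}$–$10^{2}$ µM, EC50 = 1 µM) with 4 replicate
profiles, i.e. 48 replicate pairs per compound — a standard design for a
dose–response characterization.

## Degenerate inputs and edge behaviour

Conditions without a plate-matched control, groups below the minimum
size, signatures outside the size contract, harmonization misses, and
constant-vector correlations are all reported as values or exclusion
tables, never silent drops and never exceptions mid-pipeline. Empty
ternary pairs score 0 by definition. Top-k signatures disqualify when
fewer than k strictly signed genes exist (no padding). Probe collapsing
drops multi-gene probes before selection, and thresholds are applied
after collapsing.

## Known limitations

- The enrichment engine is a stand-in family member, not a re-derivation
  of any production scoring service; absolute scores are not comparable
  to externally published connectivity values.
- The moderated z-score is a plain pooled-SE statistic; corpora built
  with weighted replicate aggregation will differ in the tails.
- Harmonization with a concentration tolerance uses corpus A as the
  reference denominator; the relation is therefore not symmetric in the
  two corpora.
- The regression is associative; no causal reading of its coefficients is
  intended.
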