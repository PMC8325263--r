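---
title: "Mapping heterotic QTLs and predicting hybrid performance in triple testcross populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping heterotic QTLs and predicting hybrid performance in triple testcross populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttcqtl)
```

## The design and the genetic model

A triple testcross (TTC) crosses every line of a recombinant-inbred base
population to three testers: the two parental inbreds (P1, P2) and their F1.
For line *i* the three testcross family means are denoted H1 (vs P1), H2
(vs P2) and H3 (vs the F1). Three linear transformations carry separable
genetic signal:

* **Z1 = (H1 + H2) / 2** — *augmented additive* effects `a* = a − 0.5 Σ da`
  (the additive effect minus half the sum of dominance-by-additive
  interactions with the genetic background);
* **Z2 = H1 − H2** — *augmented dominance* effects
  `d* = d − 0.5 Σ aa`;
* **Z3 = H1 + H2 − 2 H3** — purely epistatic signal; in expectation Z3 is
  identically zero for every line when no digenic epistasis segregates.

The underlying per-plant genotypic value is the standard two-locus model:
`mu + Σ(a_i x_i + d_i z_i) + Σ coef · w_ij` with `x ∈ {+1, 0, −1}` counting
the P1 allele, `z` the heterozygosity indicator and `w` one of
`x_i x_j` (aa), `x_i z_j` (ad), `z_i x_j` (da), `z_i z_j` (dd). Mid-parent
heterosis is `MPH(%) = (F1 − MP)/MP × 100`; in this parameterization
`MPH ∝ Σd + Σdd − Σaa`, so *negative* aa interactions contribute
*positively* to heterosis.

QTLs detected in Z1 are classified by the dominance ratio `|d*/a*|`:
additive below 0.2, partially dominant to 0.8, dominant to 1.2,
overdominant above.

## What the simulator emulates — and what it does not

`sim_ttc()` generates the whole experiment from a genetic map, a QTL
architecture and a trial design:

* **RIL genomes** follow the Haldane (no crossover interference) model: an
  F2, `intermating_rounds` rounds of random mating (default 4, the
  conventional count for intermated B73×Mo17-style populations; the true
  number for any given population is rarely published), then idealized
  fixation by gamete doubling. Lines are fully homozygous — residual
  heterozygosity is not modelled. Intermating expands the realized map
  mechanically; the input map is never rescaled.
* **The default map** has 10 chromosomes × 163 evenly spaced markers over
  694 cM each (1630 markers, 6940 cM, mean interval 4.28 cM), emulating a
  dense intermated-RIL linkage map.
* **Testcrosses**: TC(B) and TC(M) genotypes are deterministic given the
  line (A→A/H, B→H/B); TC(F) families segregate, so each family plot is the
  mean of `plants_per_family` individually simulated progenies (default 8,
  one field row) — finite-family sampling is the realistic noise source for
  Z3.
* **The trial** is a randomized complete block design with 3 blocks.
  Parents and F1 are replicated `tester_replicates = 10` times per block
  (each block column carries the three testers), lines and testcross
  families once. Residuals are Gaussian and homoscedastic per trait; block
  effects are additive constants — exactly the model the downstream BLUE
  step assumes.
* **Preset architectures** for four seedling biomass traits (leaf length,
  leaf width, leaf area, seedling dry weight) put mid-parent heterosis
  below 50% for the leaf traits and near 150% for dry weight, mixing
  additive, dominance, and aa/dd/da epistatic effects; a `"polygenic"`
  preset (40 purely additive loci) backs the genomic-prediction
  experiments. When no residual SD is given it is calibrated so the
  entry-mean heritability of the testcross hybrids hits `h2_target`
  (default 0.25; seedling traits are weakly heritable, with reported
  values of roughly 0.1–0.45).

Not emulated: crossover interference, segregation distortion or selection
during line development, non-Gaussian or heteroscedastic noise, spatial
field trends, and shared plot effects between traits (traits are simulated
independently, so genetic correlations between traits arise only through
shared loci). Passing tests on these simulations therefore validate the
estimators under their own assumptions; they cannot certify behaviour under
field artefacts the generator does not produce.

## Phenotype aggregation

`compute_blues()` fits the two-way fixed-effects model
`value = genotype + block` per trait and reports each genotype's marginal
mean. With the balanced complete design this equals the plain mean across
blocks, and with missing plots it is the least-squares solution; a mixed
model would differ only in unbalanced data, which is why the dependency-free
fixed-effects route was chosen. Since all four traits are strictly
positive, a non-positive mid-parent value in `mph()` is treated as an
error, never a NaN.

## One-dimensional scans

`scan1d()` approximates inclusive composite interval mapping (ICIM) as:

1. **Background selection** — forward–backward stepwise regression of the
   response on all marker codes (`select_background()`), with entry
   p-value `p_enter = 0.001` and removal at `2 × p_enter`. The stringent
   "probability 0.001" is read as the stepwise inclusion probability; the
   genome-wide significance level is a separate knob (`alpha`, default
   0.05) because the two play different roles.
2. **Walking the genome** in 1-cM steps on conditional expected codes:
   between markers the code is `P(A|flanks) − P(B|flanks)` for an
   idealized homozygous line under Haldane recombination; missing flanks
   fall back to the single informative flank or to the marginal 0.
3. **Adjusting the response** by the joint background coefficients while
   excluding background markers within ±10 cM of the test position — this
   preserves ICIM's protection against the tested QTL's own effect being
   absorbed by nearby cofactors. A full EM mixture likelihood is
   unnecessary because RIL marker classes are nearly complete; the
   regression on expected codes (Haley–Knott style) is exact in the
   noise-free limit, as the recovery tests verify.
4. **LOD and effects** — `LOD = (n/2) log10(RSS0/RSS1)`. Effect
   conventions are fixed by exact noise-free recovery of simulated truth:
   `a* = 2 β(Z1)`, `d* = −β(Z2)`, `da = 2 β(Z3)` under ±1 coding, so a
   positive `a*` means the P1 allele increases the trait. The `da` sign
   convention is the simulator-oracle one; published tables cannot pin it
   down without raw data.

Permutation thresholds shuffle the response across lines (1000 permutations
by default), re-run the whole scan — including background reselection — and
take the empirical 95% quantile (type-7) of the genome-wide maximum LOD.
Each permutation uses a named sub-seed of the master seed, so thresholds
are reproducible and parallelizable. Peaks above threshold are merged
within 20 cM (higher LOD wins, ties to the left), reported with nearest
flanking markers, a 1-LOD support interval, and
`R² = 100 (1 − RSS1/RSS0)` from the single-QTL fit on the adjusted
response.

## Two-dimensional scans

`pair_scan()` tests every admissible position pair on a 5-cM grid for an
interaction between the conditional codes, comparing the full model
(`µ + background + x_i + x_j + x_i x_j`) against the reduced model without
the interaction. Within-chromosome pairs closer than 20 cM are excluded to
avoid collinearity, and pairs whose codes correlate above 0.95 are skipped.
Background cofactors come from the corresponding 1D stepwise selection,
dropping markers within 10 cM of either test locus. Interactions found in
H3 are interpreted as additive×additive, in Z3 as dominance×dominance. The
interaction R² uses the total phenotypic variance of the response as
denominator (the natural "phenotypic variation explained" reading). The
default permutation count for 2D thresholds is 200 (configurable to 1000):
the grid×permutation cost grows quadratically and the threshold's
Monte-Carlo SE at 200 permutations is already a small fraction of a LOD.

## GCA/SCA GBLUP

The prediction model is
`y = µ + Z_M g_M + Z_P g_P + Z_S s + e` with
`g_M ~ N(0, G_M σ²_GCA^M)`, `g_P ~ N(0, G_P σ²_GCA^P)`,
`s ~ N(0, G_S σ²_SCA)`. Marker matrices are encoded +1/0/−1, missing
values mean-imputed per marker, each column centered and standardized by
its population SD (divisor *n*; zero-variance columns dropped and the
marker count decremented, so kinships are bit-reproducible);
`G = W W'/N` and `G_S` is the elementwise product of the hybrid-level
maternal and paternal matrices. With only two testers `G_P` is the
degenerate 2×2 case — accepted as-is (that *is* the design), with a
warning and no shrinkage.

Variance components are estimated by REML with average-information updates
and an EM fallback whenever an AI step would leave the parameter space or
decrease the restricted likelihood; non-negativity is enforced by boundary
projection, and convergence requires a relative log-likelihood change
below 1e-8 (cap 200 iterations). Heritabilities follow
`h² = (σ²_GCA^M + σ²_GCA^P) / (σ²_GCA^M + σ²_GCA^P + σ²_SCA + σ²_R)` and
`H²` adds `σ²_SCA` to the numerator; a block variance, when fitted, stays
out of the denominator. Prediction is BLUP through the mixed-model
equations at the REML estimates, with kernels always spanning all hybrids
and only phenotypes masked.

The default response is the per-hybrid BLUE across blocks
(`response = "blues"`); `response = "plots"` keeps plot-level records with
a random block effect, covering both readings of a "block-aware" model.
The 2D-spline spatial adjustment used by some field analyses is out of
scope; independent row/column effects could stand in for it, and the
block-only model is the one that performed best in the motivating study
anyway. Cross-validation is five-fold with 80/20 splits; fold assignments
derive from per-run sub-seeds, folds are as equal as possible
(49/49/49/49/48 for 244 hybrids), the Pearson correlation between observed
and predicted validation values is the accuracy, and the summary SD is
taken across all fold-runs (the across-runs alternative is obtainable from
the tidy per-fold table).

`marker_subset_experiment()` rebuilds kinships for random subsets of given
sizes (with repeats) or for groups defined by a maximum marker missing
rate. `qtl_augmented_experiment()` compares a baseline using only markers
outside all QTL-defining intervals against an augmented model that adds
the QTL flanking markers either to the kinships or as fixed covariates —
published tables do not say which route "fitting marker-enclosed QTLs"
took, so both are provided. Identical fold splits make the comparison
paired.

## Numerical choices and degenerate inputs

* Monomorphic scan positions get LOD 0 and undefined effects; an
  all-missing genotype column is dropped with a warning.
* `R²` ratios are clipped away from 1 by 1e-15 before logs.
* A constant response short-circuits REML to all-zero components; the
  residual variance is floored at 1e-10 of the response variance so V
  stays invertible while genetic components may be pinned at exactly 0.
* Gene-mode intervals are half-open with the boundary in the upper class;
  `a* = 0` with `d* ≠ 0` is an infinite dominance ratio, hence
  overdominant; both zero is undefined (NA with a warning).
* LOD ties in peak calling resolve to the leftmost position.

## Problem sizes used by the test suite

The default test and acceptance runs keep full-scale dimensions where the
property under test depends on them (122 lines, 244 hybrids, three blocks,
the 1630-marker map for prediction experiments) and use compact maps
(2 chromosomes × 6 markers) with 200-permutation thresholds where only
calibration is at stake — the type-I error of a permutation threshold does
not depend on map size, and 500 null datasets at 200 permutations pin the
rejection rate to ±2%. Scan calibration, single-QTL recovery (200
datasets), and the prediction property suite (100 cross-validation runs at
heritability 0.5, a seven-point marker-number curve) are all exercised at
those sizes.

## Known limitations

* The Haldane idealization is used both to simulate and to compute
  conditional codes; real intermated-RIL genomes show interference and
  map expansion heterogeneity the package does not model.
* With two testers the paternal relationship matrix is rank-deficient and
  the GCA/SCA split between `σ²_GCA^P` and `σ²_SCA` is weakly identified;
  sums of components (and predictions) are stable, the individual split
  less so.
* The 1D scan is a regression approximation to ICIM, not a reimplementation
  of any specific software; LOD values agree in the well-separated-QTL
  regimes the tests cover but need not match other tools decimal-for-
  decimal.
* Single-dataset "null" prediction accuracies retain the dataset's chance
  genotype–phenotype association across folds; null calibration must
  average over independent permutations, as the tests do.
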