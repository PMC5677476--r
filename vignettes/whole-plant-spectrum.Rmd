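---
title: "Testing the whole-plant economic spectrum with traitaxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the whole-plant economic spectrum with traitaxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitaxes)
```

## The question

The whole-plant economic spectrum hypothesis predicts that leaf, stem and
fine-root economic traits covary along a single fast–slow axis across
species, and that this axis predicts relative growth rate. Empirical
support is mixed: studies in standardized growing conditions tend to find
tight multi-organ coordination, while field studies often do not. One
candidate explanation is intraspecific trait variation: if organs within a
species respond to an environmental gradient in *opposite* directions
(leaves get cheaper in shade while wood and roots get denser), then
sampling species haphazardly across environments mixes those divergent
displacements into the interspecific comparison and can weaken or erase a
correlation that is real within any single environment. Convergent
responses, by contrast, leave interspecific correlations intact or even
strengthen them.

`traitaxes` implements that whole argument as a reusable, testable
pipeline: trait derivation from raw organ measurements, growth rates from
repeated stem measurements, phylogenetically corrected ordination,
bivariate trait and trait–growth analyses on raw species means and on
independent contrasts, meta-analysis of site-level correlations, paired
environment comparisons, and a resampling null that quantifies the mixing
mechanism directly. A synthetic-data module generates studies with the
same structure, so every stage is testable without any external data.

## The data model

The canonical trait set is seven tissue traits spanning three organs:

| trait | meaning | unit |
|-------|---------|------|
| LMA | leaf mass per area | g/m² |
| LTD | leaf tissue density (dry mass / fresh volume) | mg/mm³ |
| LDMC | leaf dry matter content (dry / fresh mass) | fraction |
| WD | wood density (dry mass / fresh cylinder volume) | mg/mm³ |
| WDMC | wood dry matter content | fraction |
| RTD | fine-root tissue density | mg/mm³ |
| RDMC | fine-root dry matter content | fraction |

All derivations are simple ratios of raw organ measurements
(`derive_leaf_traits()`, `derive_wood_traits()`, `derive_root_traits()`);
wood volume uses a cylinder with an elliptical cross-section built from
the two orthogonal caliper diameters, since stem segments are rarely
perfectly circular. Analyses run at the species level: unweighted means
over individuals per environment, held in a `trait_table` with explicit
`NA` for missing cells and replicate counts retained.

Relative growth rate comes from two censuses of stem height and diameter:

RGR = (ln(d₂²h₂) − ln(d₁²h₁)) / (t₂ − t₁)

d²h is a standard proxy linearly related to above-ground mass, and the
length units cancel, leaving 1/year. Because many wild individuals are
suppressed by neighbours, the per-species 95th percentile of RGR (RGR95,
linear interpolation between order statistics) serves as a
maximum-realized-growth measure; records with negative growth are dropped
before summarizing (the computed d²h change for juveniles, the diameter
increment for mature trees whose heights are estimated allometrically —
`apply_height_allometry()` provides a pluggable power law
h = a·d^b·adj for that case).

## Phylogenetic machinery

Species are not independent observations, so every interspecific analysis
has a tree-corrected twin.

**Independent contrasts.** `compute_pics()` implements the pruning
algorithm: at each internal node the standardized contrast is
(x₁ − x₂)/√(b₁ + b₂), the node receives the precision-weighted average of
its daughters, and its parent branch is extended by b₁b₂/(b₁ + b₂). The
implementation is cross-checked in the test suite against `ape::pic` on
random trees. Contrast regressions are forced through the origin with
positivized x contrasts (`sma_fit_origin()`), the standard contrast
convention; sign flips of whole contrast pairs leave every statistic
invariant, which the tests assert.

**Phylogenetically corrected PCA.** `phylo_pca()` performs eigenanalysis
of the *evolutionary* correlation matrix: with phylogenetic covariance C
(shared path lengths, `phylo_vcv()`), the GLS ancestral mean is
a = (1′C⁻¹1)⁻¹1′C⁻¹X and the evolutionary covariance
R = (X − 1a)′C⁻¹(X − 1a)/(n − 1), standardized to unit diagonal in the
default correlation mode (covariance mode sits behind a flag). On a star
tree with equal depths this reduces exactly to ordinary correlation PCA,
and the through-origin PIC correlation equals the GLS evolutionary
correlation to machine precision — both identities are acceptance checks.
The implementation agrees with `phytools::phyl.pca` to 1e-15 in the test
suite; phytools is used only as an independent oracle, never as the
implementation.

**Integration and dimensionality.** Two scalar summaries of the
eigenvalues λ₁…λ_N of the correlation-matrix eigenanalysis:

* the phenotypic integration index Var(λ) = Σ(λᵢ − 1)²/N, which is 0 for
  uncorrelated traits and N − 1 when one axis carries everything; for an
  equicorrelated matrix it is exactly (N − 1)ρ², an identity the
  acceptance suite asserts for N = 7 at ρ ∈ {0, 0.3, 0.5, 1};
* Kaiser dimensionality, the number of eigenvalues strictly greater
  than 1 (the mean eigenvalue of a correlation matrix). One axis supports
  a whole-plant spectrum; two or more reject it.

## Site-level meta-analysis

Wild growth data come from many sites differing in climate and species
composition, so trait–growth correlations are computed per site
(`site_correlations()`, requiring at least four species so the Fisher-z
variance 1/(n − 3) exists) and pooled with site as a random effect
(`dl_random_effects_pool()`), using the DerSimonian–Laird τ² estimator via
`metafor` — the conventional default of the meta-analysis tooling this
kind of study uses; REML is available behind the `method` argument. A
two-site hand computation (Q = 2.6667, τ² = 0.05, pooled z = 0.45,
pooled r ≈ 0.4219) is frozen in the acceptance suite.

## The environment-mixing resampling null

`resample_mixed_environments()` is the heart of the masking test. Given a
greenhouse (standardized environment) and a field trait table over the
same species, each of B replicate datasets draws, per species, *both*
traits of the pair from one environment chosen by a fair coin — one coin
per species per replicate, because a real specimen's phenotype comes from
a single environment (an independent-coin mode exists for sensitivity
analysis only). The squared Pearson correlation of each replicate is
compared with the observed R² among species in the greenhouse: a
quantile position (fraction of simulated R² ≤ observed, "≤" so an
observed maximum sits at exactly 1.0) at or above 0.95 says that mixing
environments weakens this trait pair — the divergent-response signature.
Positions well below 0.95 (often near 0) say mixing leaves the pair
intact or strengthens it — the convergent signature.

Two numerical points deserve care:

* **Degenerate spread.** If the two tables are identical, every replicate
  equals the observed value; the result is flagged degenerate and never
  reported as exceeding.
* **Calibration.** Under genuinely exchangeable environments the
  procedure should flag ~5% of datasets. Exchangeability here means both
  tables are iid noisy copies of a common latent species mean; then the
  observed table is just one coin pattern among 2^S exchangeable
  patterns, so its quantile position is uniform and the exceedance rate
  calibrates to the nominal 5%. Note that "field = greenhouse + noise"
  with a *noise-free* greenhouse is **not** exchangeable: the clean
  baseline is privileged, mixing can only attenuate, and the exceedance
  rate is far above 5% even with zero mean shift. The acceptance suite
  therefore calibrates with symmetric noisy copies (noise 0.25
  interspecific SD; the symmetry argument holds at any noise level).

## The synthetic-data generator

The generator (`synthetic_config()`, `generate_study()`) emulates the
structure of a temperate-tree common-garden-plus-field study and defines
the package's study conditions:

* **Phylogeny**: a pure-birth (Yule) tree rescaled to unit depth, 56
  species by default, tips `sp001…`.
* **Species means**: correlated Brownian motion — a matrix-normal draw
  with row covariance C and column covariance D·R·D, where R is the
  evolutionary correlation (default equicorrelation 0.8: a strong single
  fast–slow axis) and D holds per-trait root rates. Root states and
  rates are set so tip values span realistic ranges (LMA ~50–230 g/m²,
  WD ~0.26–0.74 mg/mm³, RTD ~0.06–0.54 mg/mm³, dry-matter fractions well
  inside (0, 1)).
* **Reaction norms**: per-species displacements
  Normal(mean_shift, shift_sd²) per trait, divergent by default (LMA
  −30 g/m², about one interspecific SD, downward; WD and RTD +0.08
  mg/mm³, one SD, upward — the shade response). Displacements can be
  correlated across traits (`shift_correlation`); the
  `exposure_shift_spec()` constructor builds the rank-1 case of a latent
  per-species environment exposure that moves LMA opposite to the tissue
  densities. That correlated, divergent structure — not mere per-trait
  noise, which can only flatten the spectrum — is what raises the field
  group's dimensionality above one while the greenhouse stays
  one-dimensional. Tissue traits are floored at 2% of the greenhouse
  value and fractions capped below 1, so additive shifts cannot produce
  impossible measurements.
* **Individuals**: 9 replicates per species by default with
  mean-preserving multiplicative lognormal noise (CV 0.15, a plausible
  magnitude for tissue-trait measurement given none is reported for this
  kind of protocol). Raw organ measurements are back-constructed so the
  `derive_*` functions recover the noisy trait values exactly —
  the derivation layer is exercised end-to-end, and with CV = 0 the
  round trip is exact to 1e-9.
* **Growth**: species' true RGR is baseline + slope × standardized
  composite trait score (slope −0.4/SD: dense-tissue species grow
  slower). Final dimensions are solved from the RGR formula
  (isometric log increment RGR·Δt/3), so `compute_rgr()` recovers the
  injected rate exactly. Field individuals are additionally suppressed
  by a one-sided half-normal term (SD 1.0/yr) — suppression only ever
  lowers growth, which is precisely why RGR95 is a sensible
  maximum-realized-growth filter; with it, RGR95 averages ~1.6–2× the
  mean RGR and some individuals shrink and get filtered, as in real
  field data. Field records are spread over 3 sites with 0.6 occupancy.

## Running the pipeline

```r
library(traitaxes)
res <- run_pipeline(synthetic_config(seed = 1), b_reps = 10000,
                    output_dir = "reports")
print(res)
```

`run_pipeline()` chains every stage, logs species counts per analysis,
and `write_reports()` emits stable-named CSVs, a JSON summary of every
headline statistic and the run log. A study bundle written with
`write_study_bundle()` (Newick tree, individuals and growth CSVs) is a
complete input: `run_pipeline(input_dir = ...)` reproduces the in-memory
results, and `--skip-growth` (or `skip_growth = TRUE`) degrades cleanly
when growth records are absent. A thin command-line wrapper lives in
`inst/scripts/run_pipeline.R`.

## Numerical choices and conventions

* Percentiles use linear interpolation between order statistics (R type
  7), the common scientific-software default.
* SMA significance is the two-tailed test of r = 0; the SMA slope
  magnitude is s_y/s_x and does not shrink with r, so a slope test would
  be meaningless at r = 0. A relationship is *reported* (flagged
  `both_significant`) only when raw and PIC analyses are both significant
  at α = 0.05.
* The Wilcoxon signed-rank test drops zero differences, average-ranks
  ties, and enumerates the exact two-tailed distribution by dynamic
  programming over doubled ranks for n ≤ 25 (ties included); above that a
  normal approximation with continuity and tie corrections takes over,
  agreeing with the exact path to < 0.01 at the boundary.
* Polytomies are resolved into zero-length bifurcations at parse time; a
  zero-sum contrast denominator is an *error*, never a silent epsilon.
  Eigenvalues are clipped to 0 only within −1e-10 of numerical noise.
* Species matching between tree and tables is exact and case-sensitive;
  mismatches are reported, never fuzzy-matched. Complete-case filtering
  is per analysis, so different analyses may use different species
  counts, each reported alongside its result.
* Traits enter analyses untransformed by default; whether to log-transform
  is left to the user since the ratios involved are already
  scale-standardized.

## What the synthetic tests do and do not show

The generator produces Gaussian interspecific variation, exactly
Brownian evolution, balanced replicate numbers, and reaction norms that
are linear displacements — real data have skewed trait distributions,
non-Brownian evolution, unbalanced sampling and ontogenetic drift, none
of which the tests exercise. Passing the suite shows the *machinery* is
correct (exact identities, hand-computed oracles, parameter recovery
under the assumed model) and that the masking mechanism behaves as the
theory predicts under those assumptions; it does not validate the
biological hypothesis on any real flora.

One limitation deserves emphasis: GLS estimators weight contrasts by
inverse branch length, so iid measurement error on species means is
amplified without bound as terminal branches shrink. Pure-birth trees
contain occasional near-zero cherries, and with replicate-level noise the
evolutionary correlation matrix can be visibly corrupted even when
ordinary sample correlations are barely attenuated. The dimensionality
contrast (one greenhouse axis vs. two or more field axes) is therefore
demonstrated on species means; with noisy replicates on an unfavourable
tree the phylogenetic ordination of any package — this one, or the
standard tools it cross-checks against — becomes unstable. Real studies
mitigate this with trees whose shallowest splits are ancient relative to
measurement error; users with very recent radiations should treat
phylogenetic eigenstructure with caution.

## Problem sizes used by the tests

Module tests run at 3–56 species with 10–300 Monte-Carlo replicates; the
acceptance suite uses the full 56-species study conditions with 100
outer replicates per recovery rate and B = 1000 resampling replicates
(B = 10000 in the pipeline run of the acceptance script, matching the
canonical replicate count for the mixing null). These sizes give
recovery rates with ±2–5% Monte-Carlo resolution, which is sufficient
for the ≥80%, ≥95% and 5 ± 3% assertions they feed.
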