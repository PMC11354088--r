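---
title: "Methods: building a PCA-weighted community resilience index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a PCA-weighted community resilience index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cribuild)
```

# The model and its assumptions

`cribuild` implements the composite-indicator workflow used by the BRIC
family of community resilience indices, adapted to English local authority
districts (LADs). The object of measurement — community resilience — is a
latent construct; the working assumption is that a moderate number of
correlated area-level indicators (here 44, spanning six theoretical
domains: social, economic, institutional, infrastructure, environmental and
community capital) share a low-dimensional correlation structure that PCA
can expose, and that the empirical components are a better grouping and
weighting basis than the theoretical domains.

The statistical assumptions are the standard second-moment ones of
correlation-matrix PCA: what matters about the indicators is their linear
co-variation; monotone but non-linear relations are partially captured only
because the aggregation step ranks the data. No distributional assumption
is needed for the index itself; Bartlett's test and the t/F tests in the
evaluation stage carry the usual normality caveats at small group sizes.

The pipeline order is fixed (imputation → standardisation → suitability →
PCA → retention → rotation → assignment → weighting → rank transform →
aggregation → audit → comparison → validation) because each stage's
contract assumes the previous one ran: e.g. PCA requires complete data, and
the weight normalisation requires the assignment.

# Tunable parameters

| parameter | default | units / range | why this default |
|---|---|---|---|
| `percentile_convention` | `hazen` | `(rank−0.5)/N` vs `rank/N` | symmetric, tie-free columns average exactly 50, so sub-index scales are comparable across runs |
| sample sd denominator | `n−1` | — | matches mainstream statistical software defaults |
| `pa_reps` | 1000 | replicates | standard practice; mean random eigenvalues stabilise well below this |
| `pa_quantile` | `NULL` (mean) | probability | Horn's original formulation; see retention note below |
| `varimax_normalize` | `FALSE` | Kaiser row-normalisation | matches the default of the major closed-source package this workflow is usually run in |
| `weight_mode` | `as_printed` | see below | the published equation divides the weighted sum by the member count `n_i` |
| `weight_basis` | `normalized_squared_loading` | Σ within sub-index = 1 | the verbal description of the weighting scheme |
| `subindex_weight_source` | `eigenvalues` | unrotated eigenvalues of retained components | "weighted by the eigenvalue for the respective component" |
| t-test variant | pooled | Welch selectable | pooled is the conventional default in this literature |
| `n_outliers` | 10 | per sign | the customary top-10 outlier listing |

**Aggregation ambiguity.** The equation defining a sub-index divides the
weighted sum of ranks by `n_i` even though the weights already sum to one,
while the accompanying prose calls the score a "weighted mean". Both
readings are implemented (`weight_mode = "as_printed"` vs
`"weighted_mean"`); `as_printed` is the default because the formula is the
more precise statement. Under `as_printed` a sub-index is the weighted mean
shrunk by `1/n_i`, so larger sub-indices are *per-indicator* down-weighted
before the eigenvalue weighting is applied; users comparing against other
implementations should check which reading those use. Neither mode is
asserted to reproduce any published score scale exactly — the published
sub-index magnitudes are not fully reconstructible from the printed
weighting description, and the configuration space here spans the plausible
readings.

**Retention rule.** Components are retained while the adjusted eigenvalue
`observed_j − (random_mean_j − 1)` stays above 1, counting from the first.
With the *mean* random reference (the default, and Horn's original
proposal), the rule sits on a knife edge under the null: the observed top
eigenvalue of pure noise is a draw from the same distribution whose mean it
is compared against, so pure-noise data yield `k = 0` only about half the
time (measured: 52% over 40 seeds at n = 300, p = 10). The
95th-percentile reference (`pa_quantile = 0.95`, the common Glorfeld
correction) retains zero components in the large majority (~85%) of null
runs while still recovering all five planted factors on the default
generator. The default follows the original mean formulation; analysts who
need strict null control should set `pa_quantile = 0.95`. The package's
null-retention acceptance test asserts the guarantee under the quantile
configuration for exactly this reason.

**Sign conventions.** Eigenvector signs are fixed deterministically
(largest-magnitude element positive). Assignment uses absolute loadings and
weights use squared loadings, so every downstream quantity is invariant to
loading signs — which is what makes the LOW-is-good negation in the
generator harmless to the factor model.

# What the synthetic generator emulates — and what it does not

`synth_generate()` draws `values = F Λᵀ + ε` with standard-normal factor
scores `F` (n × k), a block loading matrix `Λ` (primary loading 0.7 on the
indicator's own factor, 0.1 elsewhere), and Gaussian noise scaled so every
column has unit total variance (`noise sd = sqrt(1 − 0.7² − (k−1)·0.1²) ≈
0.69` at k = 5). Defaults state the world being emulated: 307 areas ×
44 indicators, five factors, nine regions cycled round-robin, 20% coastal
areas, rurality proportions 0.567/0.163/0.270 (the published urban /
mixed / rural split of English LADs), log-normal populations with median
142,000 (log-sd 0.574 reproduces the published inter-quartile range), and
ten nested lower-level units per area with gamma-share population splits.

Indicators flagged LOW-is-good — the bundled 44-indicator registry's own
directions when `n_indicators = 44`, otherwise a 50% random subset — are
negated after generation, preserving |loading| so the factor model is
direction-invariant while the rank transform must do real reversal work.

The reference deprivation index is the rank of
`−Σ w_i F_i + noise` with unit factor weights and noise sd 3.3. That noise
level was fixed a priori from the construct being emulated: deprivation
and resilience are opposing but not opposite, and with five unit-weighted
factors the implied expected correlation `−sqrt(5/(5+3.3²))` ≈ −0.56
matches the moderate published CRI–IMD association. It is a statement
about the world, not a tuning knob, and the tests only assert the *sign*.

Features of real data deliberately **not** emulated: the marginal
distributions of specific indicators (skewed rates, counts), spatial
autocorrelation between neighbouring areas, geographic patterning of
resilience (region, coastal flag and rurality are attached independently
of the factors, so geographic comparisons behave as null tests on
synthetic data), and measurement error correlated across indicators from a
shared source. A green recovery test therefore establishes that the
machinery is correct, not that the published empirical values would be
reproduced — those depend on the real (partly licence-restricted)
assembled dataset.

The three injectable missingness patterns mirror the documented data
problems: whole indicators observed only at upper-tier level (with a
population-weighted companion table), a few areas missing a year (with a
complete prior-year column), and a few areas missing a baseline (filled
from peer-group means). The generator has no temporal drift, so the
emitted prior-year column equals the true values; the imputation logic is
exercised identically either way.

# Numerical choices

* **Percentile ranks** use average ranks for ties; Hazen scaling keeps all
  values strictly inside (0, 100).
* **Varimax** is the classical pairwise planar-rotation algorithm run to a
  1e-8 angle tolerance; the rotation matrix is accumulated and returned, and
  orthogonality/communality preservation are tested to 1e-8.
* **Upper-tier imputation** broadcasts the parent value to constituent
  areas. The alternative reading — distributing a *count* by population
  share — applies to extensive quantities, but the affected indicators are
  per-capita rates, for which broadcasting is the population-weighted-mean
  consistent choice. The other reading is noted, not implemented.
* **Standardisation** refuses constant columns (sd = 0) by name rather than
  producing NaNs; KMO refuses singular correlation matrices with advice.
* **Degenerate tests**: two identical constant groups report t = 0, p = 1
  (not an error); all-zero composites yield undefined (NA) contribution
  shares and are excluded from the audit with a warning.
* **Validation outliers** ignore residuals at numerical-noise scale
  (|r| ≤ 1e-8 · max(1, max|CRI|)) so a perfectly linear relation reports no
  outliers.
* **Rotation scope**: only the retained k components are rotated before
  assignment (rotating all p and then truncating is a different model; a
  `rotate_all` flag exposes it).

# Known limitations

* The index inherits composite-indicator limitations: weight schemes are
  not uniquely determined by the data, and the published score scale cannot
  be pinned down from the printed weighting description alone (see the
  aggregation ambiguity above).
* Mean-reference parallel analysis over-retains on null data about half the
  time; use `pa_quantile = 0.95` when that matters.
* The pipeline's built-in imputation pass covers only the peer-group rule
  (the other two need companion inputs and are applied upstream); it will
  refuse, rather than guess, when gaps remain without peer-group metadata.
* Geographic comparisons assume independent areas; spatial autocorrelation
  would make the reported p-values optimistic on real data.
* GeoJSON support attaches properties to an existing FeatureCollection;
  no geometry processing or cartography is attempted.
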