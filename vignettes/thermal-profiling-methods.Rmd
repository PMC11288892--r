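---
title: "Methods: thermal stability profiling from LiP-MS data"
author: "thermolip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal stability profiling from LiP-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermolip)
```

## The measurement and the model

Limited proteolysis coupled to mass spectrometry (LiP-MS) probes protein
structure in native lysates: a brief digestion with the sequence-unspecific
proteinase K cleaves flexible and solvent-accessible regions, and the
abundance of the resulting peptides reports local structural state.
Applied across a temperature gradient (ten incubation temperatures,
37-76 °C, two replicates per condition), peptide intensities trace thermal
unfolding: fully tryptic (FT) peptides of a folded region decay as the
protein unfolds, while half-tryptic (HT) peptides — which carry a
proteinase K cleavage site — show the flipped profile, appearing as their
parent region becomes accessible.

To quantify how a co-solute (an osmolyte such as TMAO, betaine or
trehalose) changes thermal stability, each peptide is measured under a
control and an osmolyte condition and the two thermal profiles are
compared.  A genuine stabilization shifts the unfolding transition to
higher temperature; the analysis turns that shift into a signed score with
units of °C × scaled intensity, which for an ideal rigid shift of a full
transition equals the shift itself.

The pipeline is:

1. **Scaling.** Per peptide, intensities are min-max scaled to [0, 1]
   *pooled across both conditions and all replicates*.  Pooling is
   essential: scaling each condition separately would erase exactly the
   between-condition differences the score integrates.  Scaling also
   removes differences in absolute protease activity between samples,
   which is why the differential-abundance analyses that run on
   *nonscaled* data (binding, aggregation) use more stringent cutoffs.
   A peptide enters fitting only if it is quantified at ≥ 8 of the 10
   gradient temperatures in each condition (replicate mean); fewer
   observations leave a squared-exponential GP under-determined.
   Zero intensities are treated as missing, since a DIA zero almost
   always means "not quantified" and downstream operations use a log
   scale.
2. **Profile learning.** One exact Gaussian process per peptide and
   condition, with a constant mean, squared exponential kernel
   $k(t,t') = \sigma_f^2 \exp(-(t-t')^2 / 2\ell^2)$ and Gaussian
   likelihood.  All replicate observations are fed to the GP unaveraged.
   Hyperparameters $(c, \sigma_f^2, \ell, \sigma_n^2)$ maximise the exact
   marginal likelihood (L-BFGS-B with analytic gradients; convergence or
   the iteration cap of 1000, restart from a long lengthscale on
   failure, after which the peptide is flagged unfit).
   Initialisation: $c = \bar y$, $\sigma_f^2 = \mathrm{var}(y)$,
   $\ell = 10$ °C, $\sigma_n^2 = 0.1\,\mathrm{var}(y)$; restart at
   $\ell = 30$ °C.  A lengthscale floor of 1 °C prevents the kernel from
   chasing replicate noise between gradient points (spacing 3.5-4.9 °C).
   A pooled-condition (joint) fit is available as a diagnostic
   (`joint_diagnostic`): the marginal-likelihood gain of separate fits
   over the joint fit indexes how strongly the two conditions differ,
   but plays no role in the score.
3. **Confidence bands.** Curves are evaluated on a dense scoring grid
   (37-76 °C, 0.5 °C steps) with a band of mean ± 2 posterior standard
   deviations.  The band is the posterior of the *observation*
   distribution — latent variance plus the learned noise variance — not
   the latent function alone.  This is the band the Gaussian likelihood
   implies, and it is what calibrates the non-overlap test: with
   latent-only bands the replicate-split null (below) separates at
   ~16% of peptides, an order of magnitude above the intended false
   discovery rate, while the predictive band brings it to ~1%.
   `include_noise = FALSE` exposes the latent band.
4. **Shape groups.** The fitted control profiles, evaluated on a
   20-point grid (37-75 °C in 2 °C steps), are clustered into k = 20
   fuzzy clusters by entropy-regularised fuzzy k-means (entropy degree
   p = 2): memberships update as $u_{im} \propto \exp(-d_{im}^2/p)$,
   centroids as membership-weighted means.  Clusters are grouped by
   their centroid's endpoints: *nonmonotonous* when
   |end − start| < 0.5 (scaled units), otherwise *increasing* or
   *decreasing*; a peptide's group probability sums its memberships over
   each group's clusters.  Pointwise-median cluster profiles are
   available as the representative via `representative = "median"`.
5. **Scoring.** Maximal runs of grid points where the two bands are
   disjoint become non-overlap intervals; the signed area
   $\sum (m_\text{osm} - m_\text{ctl})\,\Delta T$ over such an interval
   (zero elsewhere) is a spacing-weighted Riemann sum, so scores are
   stable under grid refinement (< 2% change when the step is halved).
   Intervals are classified by midpoint: below 44.4 °C *binding* (a
   native-state change before unfolding), above 68.6 °C *aggregation*,
   else *stabilization* — the boundaries are the 3rd and 8th gradient
   temperatures, matching the temperature subsets the binding and
   aggregation differential analyses use; both are configurable.  The
   peptide score is the stabilization-class interval of maximal |area|,
   sign-corrected by shape group (+1 decreasing, −1 increasing, so a
   rightward shift is always positive).  For nonmonotonous peptides the
   sign follows the local slope of the control curve over the interval —
   a locally decreasing segment behaves like a decreasing profile.
6. **Rollup.** Peptides of different lengths overlap; to avoid double
   counting, peptide scores are first projected to residues: at each
   covered position, the mean of covering scores decides the direction
   and the residue score is the weighted 0.75 quantile (stabilized) or
   0.25 quantile (destabilized) of the covering peptide scores, weighted
   by goodness of fit.  Protein scores repeat the same weighted-quantile
   summarisation over residue scores with the positions' mean fit
   weights.  The fit weight is $w = 1/(\varepsilon + RSS_\text{ctl} +
   RSS_\text{osm})$ with $\varepsilon = 10^{-3}$: the residual sum of
   squares is the fit metric where larger means worse, and inverse
   weighting is the only reading under which better fits count more.
   A protein with nonzero score is called stabilized or destabilized by
   the score's sign.

## The weighted quantile

The rollup quantile is the inverse weighted empirical CDF: after sorting,
the q-quantile is the smallest value whose cumulative weight reaches
$qW$ (the weighted analogue of the type-1 sample quantile).  Two
properties motivate this estimator over an interpolating one.  First it
is exactly invariant under splitting any weight into parts at the same
value, so expanding rational weights into unit repetitions reproduces it
exactly — which makes it directly testable against a brute-force oracle.
Second, the quantile of a mostly-zero score set is *exactly* zero until
the quantile crosses the nonzero mass: a single spurious peptide cannot
drag a protein score off zero, which is what keeps the protein-level
false-positive rate at the few-percent level.  An interpolating variant
was measured at roughly twice the intended protein-level FDR on the same
null.

## FDR calibration on replicate-split nulls

Because "score ≠ 0" is a geometric event rather than a p-value, the
false discovery rate is calibrated empirically: a control-only experiment
with four replicates is split into two pseudo-conditions of two
replicates ({1,2} vs {3,4}) and pushed through the full pipeline; any
nonzero stabilization score is a false positive.  `estimate_null_fdr()`
reports the nonzero fraction at peptide and protein level, and
`sweep_quantile()` scans symmetric rollup pairs (q, 1−q) for
q ∈ {0.5, 0.55, …, 1} to find the least conservative quantile achieving a
target FDR (default 5%); the default 0.75/0.25 pair meets it under the
simulated design below.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical structure the analysis relies
on: the 10-point 37-76 °C gradient, two (or four, for nulls) replicates,
overlapping FT peptides with nested HT peptides, three profile archetypes,
osmolyte-induced rightward midpoint shifts shared by a protein's
peptides (with per-domain overrides possible through per-protein specs),
multiplicative lognormal noise, and missingness at random.  Profiles
follow a two-state transition $f(T; T_m)$ with
$\Delta H_m = 300\ \mathrm{kJ/mol}$, which spans 3-4 gradient steps —
the shape class the experiment was designed to resolve.  Archetypes:
*unfolder* $f$, *aggregator* $1-f$, and *nonmonotonous* implemented as
full decay-then-recovery $f(T;T_m) + 1 - f(T;\min(T_m+10, 66))$
(resolubilisation-like).  The recovery is complete within the gradient
so the profile's endpoints remain comparable — the defining feature of
the nonmonotonous group; a partial recovery would be geometrically
closer to an unfolder than to its own group after scaling.  HT peptides
receive the mirrored profile $1-p$ with an independent amplitude:
flipped shape, not equal magnitude.  Default noise is
$\sigma = 0.05$ (sdlog) with 2% missingness and log-uniform amplitudes
over $10^5$-$10^7$.

The generator does *not* emulate: peptide-specific unfolding
cooperativity, correlated (batch or retention-time) noise,
intensity-dependent missingness, chromatography or search-engine
effects, or proteins whose domains melt independently unless specified.
Passing tests therefore demonstrate that the pipeline is calibrated and
sensitive under the idealised design — not that real data meet those
assumptions.

Simulated study conditions used by the test suite and the acceptance
script: the null uses 200 proteins × 8 FT peptides at σ = 0.05 with
four replicates (~1,600 peptides per run, averaged over 3 seeds);
recovery uses 100 proteins shifted by ΔTm = 3 °C against 100 unshifted.
Under these conditions the peptide-level null FDR is below 5%
(typically < 1%), the protein-level FDR at 0.75/0.25 is at or below 5%,
sensitivity at 3 °C is ≥ 0.9 and specificity ≥ 0.95.

## Clustering: why features are standardized

The entropy degree p acts as an absolute temperature on squared
Euclidean distances.  On min-max-scaled 20-point profiles, the total
between-profile variance (~1.5-4) is smaller than the maximal entropy
bonus $p\log k = 6$, and the exact optimum of the entropy-regularised
objective then *collapses all centroids into blended copies* — the
memberships spread across duplicated centroids at no distance cost while
harvesting the entropy reward.  Standardizing the feature columns before
clustering (the conventional fuzzy-clustering workflow) enlarges the
distances relative to p and restores meaningful clusters; centroids are
back-transformed to intensity units because the endpoint grouping rule
(|end − start| < 0.5) is stated in those units.  `standardize = FALSE`
reproduces the raw-space behaviour.

## Companion analyses

**Differential abundance** (`differential_abundance()`): Welch or
moderated t-tests on log2 intensities pooled over a temperature subset,
BH-corrected; presets follow the analysis conventions — *binding*: first
two temperatures (37, 40.5 °C), adjusted p < 0.01 and |log2 FC| > 1.5 on
nonscaled data; *aggregation* (LiP): last two temperatures, p < 0.05,
|log2 FC| > 1; *TPP aggregation*: last three gradient temperatures
(68.6, 72.5, 76 °C); *protease activity*: moderated t, p < 0.05,
|log2 FC| > 1.  A protein is flagged as soon as one proteotypic peptide
changes significantly.  Pooling the subset into one test per unit is the
default; a per-temperature mode (BH across both dimensions) is behind
`per_temperature`.  The moderated t shrinks per-unit variances toward a
method-of-moments prior on log variances
($\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, $t$ with $d_0 + d$
degrees of freedom), falling back to Welch below 10 units.

**TPP** (`tpp_analysis()`): soluble-fraction abundances scaled to the
37 °C value are processed exactly like single-peptide LiP profiles (GP
fit + band non-overlap scoring), without any rollup.  The profile's sign
group is read off the fitted control curve with the same endpoint rule
used for clusters — with one profile per protein there is nothing to
cluster.  Proteins are *nonprecipitators* when the mean scaled abundance
at the top temperature exceeds 0.5 (strict); LiP/TPP agreement is
reported over shared precipitators only.

**DSF** (`fit_two_state()`): min-max-scaled fluorescence is fitted to the
two-state unfolding model with linear baselines,
$$S(T) = \frac{(S_f + m_f T) + (S_u + m_u T)\,e^{x}}{1 + e^{x}},
\qquad x = \frac{\Delta H_m}{RT}\cdot\frac{T - T_m}{T_m},$$
with $T$ in kelvin internally (I/O in °C; offset 273.15) and
$R = 8.314$ J K⁻¹ mol⁻¹ fixed.  The model is evaluated through the
logistic function, so the exponential cannot overflow.  Levenberg-
Marquardt least squares with: $T_m$ initialised from the derivative peak,
$\Delta H_m = 200$ kJ/mol, baselines from linear fits of the outer 15% of
points; bounds keep $T_m$ inside the data range and $\Delta H_m$ in
[10, 2000] kJ/mol; three jittered starts before reporting failure.
Replicates are fitted jointly with shared parameters (a per-replicate
fit is simply a per-replicate call).  `derivative_tm()` smooths with a
centred 5-point moving average and reports all |dS/dT| maxima with
prominence ≥ 0.05 scaled units per °C — two maxima flag two-transition
(two-domain) melting.

**Spearman panel correlation** (`spearman_randomization()`): per protein,
the Spearman correlation between its score vector across osmolytes and
the across-protein mean vector, the latter computed leave-one-out: with
many proteins this equals the plain mean, but it removes the
$1/\sqrt{n}$ self-correlation bias that would otherwise shift the
permutation null on small panels.  The null shuffles each protein's
vector across conditions independently (1,000 repetitions by default).

**Sequence features** (`sequence_features()`): length, residue and
group percentages, Kyte-Doolittle GRAVY, aliphatic index, maximal
Eisenberg hydrophobic moment (window 11, 100° helix turn), and
charge/pI by Henderson-Hasselbalch bisection with the EMBOSS pKa set
(documented in the source; swap by editing one table).
`compare_feature_groups()` does per-feature Welch t-tests with BH
correction, reporting test-minus-control mean differences.

## Numerical choices and degenerate inputs

* GP: Cholesky with a 1e-10 jitter; signal and noise variances floored
  at 1e-10/1e-8; optimizer tolerance `factr = 1e8`.  Constant peptides
  (no intensity range) are excluded from fitting with a flag.
* Non-overlap runs are maximal consecutive-point runs; a run's class
  comes from its midpoint; ties in |area| resolve to the first maximal
  interval.
* Residue positions with mean exactly 0 take the stabilized (0.75)
  branch; with all-zero covering scores every quantile is 0 anyway.
* `weighted_quantile` rejects nonpositive weights; a single distinct
  value returns itself for every q.
* Flat-profile flag: strict |log2(max/min)| < 0.5 on raw replicate-mean
  intensities (positive means required) — used as the in situ signature
  of intrinsic disorder, not as a fitting filter.
* Gradient top-temperature inconsistencies in the source protocols
  (68.6 vs 68.8 °C) are resolved to the gradient's own 68.6 °C
  everywhere.

## Known limitations

* The GP assumes homoscedastic noise per peptide-condition; multiplicative
  noise on scaled profiles is mildly heteroscedastic, which the
  calibration absorbs but a heavy-tailed likelihood would model better.
* With k = 20 fixed, panels much smaller than ~40 profiles reduce k
  automatically (k < n is enforced); grouping then rests on fewer
  centroids.
* The binder-scaling denominator uses the asymmetric 0.7/0.25 quantile
  pair exactly as specified for cross-osmolyte comparability; it is not
  robust to panels whose significant scores are nearly tied (the
  denominator may vanish, which is an error).
* Domain tests require ≥ 2 domains with ≥ 3 peptides each and use plain
  t/ANOVA on peptide scores, ignoring peptide-length weighting.

## A worked example

```{r example, eval = FALSE}
specs <- sim_protein_specs(20, delta_tm = c(rep(4, 10), rep(0, 10)),
                           n_peptides = 8L)
ds <- simulate_lip_experiment(specs, sim_noise_model(sigma = 0.05), seed = 42)
fit <- lip_stability(ds, "control", "osmolyte", seed = 1)
summary(fit)
head(coef(fit))          # protein-level stabilization scores
plot(fit)                # strongest-scoring peptide, both conditions

nds <- simulate_null_experiment(specs, seed = 43)
estimate_null_fdr(nds, seed = 1)
```
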