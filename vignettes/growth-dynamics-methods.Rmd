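---
title: "Methods: longitudinal growth dynamics and drought-adaptation analysis"
author: "growthdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal growth dynamics and drought-adaptation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthdyn)
```

# The setting

High-throughput phenotyping platforms image every plant of a trial daily
and reduce each image to numeric traits: a voxel-based biovolume proxy
for shoot biomass (`EBv`), architectural traits (plant height `PHg`,
caliper length `CLe`, surface coverage `SCov`, solidity `Sol`), and
physiological color/fluorescence traits (`Y2G`, `B2G`, `FI`). The
experimental design this package targets is a maize-style greenhouse
trial: a cohort of inbred genotypes grown under a control (`C`), a mild
nitrogen limitation (`N`), a progressive water limitation (`W`), and
their combination (`NW`), with several replicate plants per genotype
and treatment, imaged on an almost-daily grid of days after
transplanting (DAT). Water stress is initiated at DAT 9, soil water
declines to its minimum at DAT 22 (maximum stress), and pots are
rewatered from DAT 23 to the end at DAT 35. One imaging day (DAT 30)
is lost, so the time grid is irregular: every time-aware computation in
the package uses true day distances, never consecutive indices.

The canonical data container is the replicate-level long table
(`TraitTable`): one row per (genotype, treatment, replicate, DAT,
trait). Genotype-by-day matrices used by the clustering and covariance
modules are derived views (`wideMatrix()`); missing cells there are
flagged `NA` and never imputed. Keeping the long table canonical
preserves the replicate-level information that the per-day ANOVA and
the variance decomposition require.

# Growth metrics

*Relative growth rate.* `RGR = (ln W2 - ln W1) / (T2 - T1)` in day^-1,
computed per consecutive grid interval; the interval spanning the lost
imaging day uses a two-day denominator. RGR is invariant to a
multiplicative rescaling of the trajectory, which is why the arbitrary
voxel unit of the biovolume proxy is harmless.

*Coefficient of variation.* Per day and treatment,
`CV = 100 sd/mean` (sample sd) across the genotype means — one value
per treatment per day summarizing how heterogeneous the cohort is. A
replicate-level variant (across all plants) is available.

*Water-use efficiency.* Biomass gained per gram of water applied over a
phase, by default the stress phase DAT 2–22 and the recovery phase
DAT 22–35. The irrigation schedule is not part of the data model; the
caller (or the simulation config) supplies the grams applied.

*Decline metrics.* Under progressive drought the biomass trajectory
peaks a few days before maximum stress, then shrinks (wilting, leaf
rolling) into the trough at DAT 22. `declineMetrics()` finds the peak
in a search window (default DAT 19–21; ties break to the earliest day,
the conservative choice that maximizes the decline duration) and
reports the days of decline and the percent drop from peak to trough.
A trajectory still rising into the trough day scores a 0% decline.

# Drought-adaptive capabilities

Three per-genotype indices are ratios of the stress-treatment biomass
increment to the control increment over anchored windows: tolerance
`DTO` over stress build-up (DAT 9 to 22), recovery `DRC` after
rewatering (DAT 23 to 35), and adaptability `DAD` over the whole cycle
(DAT 9 to 35). They are computed on replicate-averaged genotype-mean
curves, one value per genotype, and are invariant to a common
rescaling of both curves. A non-positive control increment makes the
corresponding ratio undefined; the package reports it as missing with
a classed warning naming the window (clipping would bias the
correlation analyses; a `strict` mode raises an error instead).
Pearson correlations among the three indices, and between the indices
and any trait at chosen days (default DAT 22 and 35), use the
t-transform on n − 2 df for p-values, with conventional significance
stars.

# Temporal clustering

Genotype-mean biomass trajectories are clustered with fuzzy c-means
(standard alternating optimization of
\(J = \sum_i \sum_k u_{ik}^m \lVert x_i - v_k \rVert^2\)). Design
choices, each exposed as an argument:

* **Raw profiles by default.** The biologically meaningful separation
  in this design is by trajectory *level* (plant size); a z-score
  option is deliberately absent — callers can standardize the matrix
  themselves for shape-based clustering.
* **Fuzzifier m = 2**, the common default when nothing is known about
  membership softness.
* **20 seeded random restarts**, memberships initialized from a uniform
  Dirichlet; the lowest final objective wins. FCM is prone to local
  optima; restarts are cheap at cohort size 20.
* **Canonical labels.** Clusters are relabeled by descending mean
  trajectory level, so cluster "A" is always the larger-biomass group.
* **Convergence** when the maximum absolute membership change falls
  below `tol` (1e-6); a profile coinciding with a center receives crisp
  membership there.

The number of clusters is chosen by a majority vote of six validity
indices — partition coefficient (max), modified partition coefficient
(max), partition entropy (min), Xie–Beni (min), Fukuyama–Sugeno (min),
and the fuzzy silhouette (max; crisp silhouettes weighted by the
margin between the two largest memberships). Each index votes for its
optimal candidate; ties break toward the smallest c (parsimony).
Candidates that produce an empty hard cluster are excluded from the
vote with a warning. The index list itself is a package choice: the
majority-rule idea only prescribes voting, not the electorate, so the
six most widely used fuzzy indices were fixed once and documented.

Two cluster summaries follow the clustering: `typicalCurves()` — the
per-cluster mean polyline over DAT 19–23, the window from the last
pre-stress peak to the day after maximum stress — and
`clusterDiffProfile()` — a per-day Welch t-test between the two hard
clusters on genotype means, reported as −log10(p), so values above
about 1.3 mark days of significant separation.

# Per-day longitudinal statistics

*Treatment tests and onset.* Each imaging day is tested separately
with the linear model `value ~ treatment + replicate` on the
genotype-replicate observations, followed by Tukey's HSD over all
treatment pairs (studentized range on the residual df). Days are *not*
adjusted across the grid — each day's family is its own test, which is
stated in the output headers. The onset of a treatment effect is the
first day starting a run of at least `k` consecutive significant days;
all maximal runs are reported. With `k = 1` a single noisy day can
fire the onset; `k = 2` is the recommended persistence when the grid
is long.

*Variance decomposition.* Per day, the Gaussian mixed model
`value = replicate (fixed) + genotype + treatment +
genotype:treatment + error` with the last three random is fitted by
REML. The estimator is a Fisher-scoring iteration on the REML score
equations with the analytic information matrix and an active-set
nonnegativity constraint. Scoring converges quadratically, so on a
balanced layout the estimates agree with the closed-form
expected-mean-squares (EMS) estimators — exported separately as
`varianceComponentsEMS()` for cross-checking — to numerical precision
whenever the EMS solution is interior. (A generic derivative-free
mixed-model optimizer locates the same optimum only to about 1e-5 in
variance units; the analytic iteration was written precisely to make
the balanced-case equivalence checkable at machine precision. When an
EMS component is negative, REML's boundary solution legitimately
differs from naive truncation.) Percentages are of the four-component
total and sum to 100.

*Covariance structures.* For a subjects-by-days response matrix with a
saturated mean (one mean per day), five within-subject covariance
models are fitted by maximum likelihood and compared by
`BIC = -2 logL + p log(n_subjects)`, with p counting covariance
parameters only (the saturated mean is common to all candidates, so
its dimension cancels in comparisons):

| structure | form | parameters |
|---|---|---|
| `UN` (uniform / compound symmetry) | \(\sigma^2[(1-\rho)I + \rho J]\) | 2 |
| `POWER` | \(\sigma^2 \rho^{|t_i-t_j|}\) | 2 |
| `HETPOWER` | \(\sigma_i\sigma_j \rho^{|t_i-t_j|}\) | T + 1 |
| `ANTE` (first-order antedependence) | \(\sigma_i\sigma_j \prod_{k=i}^{j-1}\rho_k\) | 2T − 1 |
| `US` (unstructured) | free SPD | T(T+1)/2 |

Note the naming trap: in this menu `UN` means *uniform*, not the
common "unstructured" abbreviation — `US` is the unstructured model.
The power-family correlations use actual day distances, so the lost
imaging day contributes a distance of 2. `US` and `ANTE` have
closed-form ML solutions (the divisor-n sample covariance; matching
the sample variances and adjacent-day correlations, the decomposable
chain-model property). The others are optimized numerically
(Nelder-Mead then BFGS on transformed parameters: log variances, a
bounded logistic link for correlations — \((-1/(T-1), 1)\) for
compound symmetry, \((-1, 1)\) for the power family) so every proposal
is positive definite by construction. BIC uses the number of subjects
as the sample size, the usual mixed-model convention; alternatives
exist, which is why it is documented here. Genotype-mean profiles are
the default "subjects" (20 for the default cohort); on the full
33-day grid `US` and `ANTE` are then over-parameterized, so the
pipeline thins the grid (default every 4th day) and the fitter warns
whenever parameters rival subjects.

*Correlation dynamics.* Per day and treatment, the Pearson correlation
across genotype means between a trait and the biomass proxy, together
with the exact two-sided p = 0.05 critical value
\(r^* = t_{0.975,\,n-2}/\sqrt{t_{0.975,\,n-2}^2 + n - 2}\) for the
realized n; days where a trait is constant are flagged degenerate
rather than erroring.

# The synthetic cohort

No data accompany the reference design, so the package ships a
generator whose defaults *are* the emulated study conditions:
20 genotypes x 4 treatments x 8 replicates x the 33-day grid. Biomass
is multiplicative:

\[ \mathrm{EBv}_{gijt} = L_g(t)\; N(t)\; S_g(t)\; \mathrm{Syn}(t)\; \varepsilon, \]

with \(L_g\) a genotype-specific logistic curve, \(N\) a mild nitrogen
penalty ramping in late (9% asymptotically, logistic ramp centered at
DAT 25 — the nitrogen effect in such trials is chronic and appears
after the drought effect), \(S_g\) the water-stress factor, a small
multiplicative synergy penalty in `NW`, and lognormal observation
noise with CV 10% (multiplicative, because the trait's dispersion is
scale-dependent). The stress factor declines smoothly from 1 at onset
(DAT 9) to \(1-\delta_g\) at the trough (DAT 22) as a power ramp
\(S = 1 - \delta_g\,((t-9)/13)^q\) with \(q = 3\), then relaxes
exponentially, \(1 - \delta_g e^{-\gamma_g (t-22)}\), after
rewatering. The ramp shape matters: the decline must be *steepest at
the trough* (progressive soil drying toward the wilting point) for the
observed biomass to turn down into DAT 22 while the underlying
logistic is still growing. A shape with a flat trough (e.g. a cosine
half-wave) provably cannot produce a biomass minimum at the
maximum-stress day under a still-growing logistic, which is why the
power ramp was adopted.

Two latent genotype groups mirror the reference cohort's structure:
group A (12 genotypes) is larger but slower
(K = 12000 voxels, r = 0.32 day^-1, t0 = 17) and dips deeper on
average (mean delta 0.55); group B (8 genotypes) is smaller, faster
(K = 7000, r = 0.40, t0 = 19) and dips less (mean 0.50). Genotype
dispersions: K lognormal CV 8%, r sd 0.02, t0 sd 0.5, delta sd 0.12
(chosen to match the reported spread of tolerance indices, roughly
0.2–0.73), recovery rate gamma ~ N(0.10, 0.03) day^-1 truncated
positive. The weighted mean dip (~0.53) reproduces the reported
maximum biomass reduction of about 53% at DAT 22; the group
timing/shape parameters reproduce the qualitative typical-curve
dynamics (group A peaking a day earlier and declining more than B).
Secondary traits are links of the noise-free biomass and the
instantaneous stress intensity \(1-S_g(t)\): height ~ EBv^(1/3),
caliper length ~ EBv^0.4, canopy traits saturating in biomass with a
post-trough boost for small-plant genotypes, color ratios linear in
stress intensity, fluorescence increasing with stress after onset.
Irrigation is a constant per-day schedule per treatment (control 150,
water-stressed 70 g day^-1) — real schedules are dynamic, but a
constant rate is sufficient to make WUE well defined. The biovolume
unit is an arbitrary voxel scale; every downstream statistic is either
scale-invariant or reported in ratio/percent form.

What the generator deliberately does *not* emulate: soil-water-balance
physics (each genotype's stress is parameterized directly rather than
emerging from pot water dynamics and plant size, so the reported
negative correlation between soil water content and plant size has no
analog here); spatial/greenhouse-position effects; phenology
differences in imaging; and any genetic relatedness among genotypes.
One structural consequence of the prescribed exponential-relaxation
recovery: the recovery increment is mechanically proportional to the
dip depth, so recovery capability couples negatively to tolerance in
the default cohort and the reference study's dominance of the
recovery–adaptability correlation over the tolerance–adaptability one
is *not* reproduced there. The property does hold — and is tested —
under a dedicated construction in which only the recovery rate varies
across genotypes. Passing tests on this cohort therefore demonstrate
the *statistical machinery* (formula correctness, parameter and
structure recovery, cluster recoverability, onset timing), not
biological realism of any particular dataset.

# Numerical choices and degenerate inputs

* Fuzzy memberships: rows renormalized by construction each iteration;
  the winning restart's objective trace is stored and is
  non-increasing (guaranteed by alternating minimization and asserted
  in tests). A cluster abandoned by every profile keeps its previous
  center rather than producing NaN.
* Covariance optimization: initialized from sample moments
  (adjacent-day correlations power-scaled by the minimum spacing);
  Cholesky failures inside the likelihood return a penalty value
  rather than erroring, and optimizer non-convergence is carried in
  the fit object and excluded by the BIC selector.
* REML: scoring tolerance 1e-10 on the score norm, step-halving when a
  step would cross zero, components pinned at zero only when their
  boundary score is negative (the KKT condition).
* Undefined statistics (zero-variance correlations, non-positive
  control increments, empty clusters) are reported as flagged missing
  values or classed conditions — never silently clipped.
* Validation errors are classed conditions
  (`growthdyn_duplicate_key`, `growthdyn_missing_column`, ...) with
  machine-readable payloads (offending keys, row numbers, fields).

# Problem sizes in the checks

The test suite sizes its simulations to what the properties need: the
formula oracles use 1000 random inputs; clustering internals 100
random data sets plus 100 separable cohorts for the majority rule;
covariance-structure selection 50 replicates per generating structure
at T = 8, n = 100; the variance-component recovery 200 balanced
replicates of the 20 x 4 x 8 layout at components (25, 4, 9, 16);
onset timing 100 replicates of an engineered 3-sigma divergence at
DAT 15 with a persistence of 2 days (with single-day persistence, a
32-day grid fires a false early onset in almost half of replicates —
the expected family-level behavior, not a defect); and the Tukey
family error 1000 one-day null simulations. The full pipeline on the
default cohort runs in about a minute and is byte-reproducible under
a fixed seed.

# Known limitations

* The per-day mixed model treats genotype means as exchangeable
  subjects; no kinship or spatial structure is modeled.
* Covariance fitting assumes complete profiles (genotype means at
  every retained day); subjects with missing cells are dropped by the
  pipeline rather than handled by EM.
* The treatment factor has only four levels, so its variance component
  is estimated with 3 df and is intrinsically noisy; this is a
  property of the design, not the estimator.
* Recovery indices can exceed 1 when the control has little growth
  headroom left after rewatering while stressed plants rebound
  (compensatory growth); they are reported as-is, not capped.
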