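# growthdyn

Longitudinal analysis of image-derived plant phenotypes under drought
and nitrogen stress, for quantitative geneticists and phenomics groups
working with daily trait trajectories from automated greenhouse
platforms (a biovolume biomass proxy `EBv` plus architectural and
color traits, recorded per genotype × treatment × replicate × day).

The package implements the full analysis chain for a
control / nitrogen / water / combined-stress (`C`/`N`/`W`/`NW`) design
imaged on an irregular day grid (DAT 2–35 with DAT 30 missing):

* **Growth dynamics** — relative growth rate
  `RGR = (ln W2 − ln W1)/(T2 − T1)` per imaging interval (true day
  distances across the grid gap), per-day coefficient of variation
  across genotypes, water-use efficiency per stress/recovery phase,
  and decline timing/magnitude around maximum stress.
* **Drought-adaptive capabilities** — per-genotype tolerance,
  recovery, and adaptability as ratios of stress to control biomass
  increments over anchored windows:
  `DTO = ΔEBv_W(9→22)/ΔEBv_C(9→22)`,
  `DRC = ΔEBv_W(23→35)/ΔEBv_C(23→35)`,
  `DAD = ΔEBv_W(9→35)/ΔEBv_C(9→35)`,
  with their inter-correlations and trait associations at DAT 22/35.
* **Temporal clustering** — hand-implemented fuzzy c-means on
  genotype-mean trajectories, cluster number chosen by a majority vote
  of six validity indices, per-cluster typical curves over DAT 19–23,
  and per-day −log10(p) differential profiles between clusters.
* **Per-day longitudinal statistics** — treatment ANOVA with Tukey HSD
  and onset-of-significance detection, REML variance decomposition
  (genotype / treatment / interaction random, replicate fixed; Fisher
  scoring with an expected-mean-squares cross-check), and ML fitting +
  BIC comparison of five repeated-measures covariance structures
  (uniform, power, heterogeneous power, first-order antedependence,
  unstructured).
* **A synthetic cohort generator** — replicate-level logistic growth
  with a genotype-specific stress dip troughing at DAT 22 and
  post-rewatering recovery, two latent genotype groups, and
  stress-responsive secondary traits, so the whole pipeline is
  testable without access to platform data. Ground-truth parameters
  are exposed for recovery tests.

## Worked example

```r
library(growthdyn)

cfg <- simulationConfig(seed = 42)   # 20 genotypes x C/N/W/NW x 8 replicates
tb  <- simulateExperiment(cfg)
tb
#> TraitTable: 168960 records | 20 genotypes x 4 treatments x 8 traits
#>   day grid: DAT 2..35 (33 days, irregular)
#>   missing values: 0

cs <- genotypeMeans(tb, "EBv")
W  <- wideMatrix(cs, "W"); C <- wideMatrix(cs, "C")
round(100 * (1 - mean(W[, "DAT22"]) / mean(C[, "DAT22"])), 1)
#> [1] 51
```

Water stress cuts mean biomass by ~51% at the maximum-stress day
(DAT 22) in this cohort. Clustering the stressed trajectories:

```r
vr <- selectCMajority(W, cRange = 2:6, seed = 42)
vr
#> ValidityReport: candidates c = 2, 3, 4, 5, 6; selected c = 2
#>   votes: pc->2, mpc->2, pe->2, xb->2, fs->4, fsil->2
selectedPartition(vr)
#> FuzzyPartition: 20 profiles, c = 2, m = 2, objective = 3.42469e+08
#>   hard cluster sizes: A=12, B=8
```

Five of six validity indices vote for two temporal patterns; the hard
labels split the cohort 12/8 and exactly recover the generator's
latent groups (adjusted Rand index 1). The drought indices, one row
per genotype (`dto` near 0 = growth collapsed under stress; 1 = grew
like the control):

```r
head(capabilityTable(tb, "W",
                     waterStress   = waterApplied(cfg, "W", 2, 22),
                     waterRecovery = waterApplied(cfg, "W", 22, 35)), 3)
#>   genotype treatment       dto      drc       dad wueStress wueRecovery
#> 1      G01         W 0.3188053 2.600095 0.7730719  2.744909    8.024216
#> 2      G02         W 0.1633101 3.047385 0.7503109  1.507416    7.802330
#> 3      G03         W 0.4444582 2.477111 0.8321611  3.908285    6.754041

onsetSeries(tb, "EBv", c("W", "C"), k = 2)$onsetDat
#> [1] 18
```

The water-stress effect on biomass becomes (and stays) significant
from DAT 18 in this cohort. Covariance-structure selection recovers a
generating power (continuous-time AR(1)) structure from simulated
repeated measures, with the lost-day gap counted as a two-day
distance:

```r
times <- c(1:4, 6:9)
Y <- simulateRepeatedMeasures(100,
       covarianceMatrix("POWER", c(sigma2 = 1, rho = 0.8), times),
       seed = 42)
sel <- selectStructureBIC(fitAllCovarianceStructures(Y, times))
sel$table
#>   structure    logLik nParams      bic convergence
#> 1     POWER -777.6170       2 1564.444           0
#> 2  HETPOWER -774.2986       9 1590.044           0
#> 3      ANTE -773.1078      15 1615.293           0
#> 4        US -762.8015      36 1691.389           0
#> 5        UN -921.2322       2 1851.675           0
round(sel$best@params, 3)
#> sigma2    rho
#>  1.009  0.818
```

`runPipeline(outDir, simulationConfig(), seed = 7)` chains all stages
(simulate → metrics → indices → cluster → varcomp → covstruct →
correlate → onset) into ~17 CSV/JSON outputs, each stamped with the
config hash and seed, byte-reproducible under a fixed seed. A thin
command-line wrapper lives at `inst/scripts/growthdyn.R`.

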