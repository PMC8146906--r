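#' Configuration for the synthetic greenhouse experiment
#'
#' Defines the study conditions the generator emulates: 20 genotypes in
#' two latent groups (12 large/slow "A", 8 small/fast "B"), four
#' treatments (control C, nitrogen stress N, water stress W, combined
#' NW), 8 replicate plants, and the irregular 33-day imaging grid
#' (DAT 2..35 without 30). Biomass follows a logistic curve modulated by
#' a water-stress factor that declines smoothly from stress onset
#' (DAT 9) to its trough at maximum stress (DAT 22) and relaxes after
#' rewatering, and by a mild late-ramping nitrogen penalty.
#' Units of the biovolume proxy (EBv) are arbitrary voxels: the source
#' platform's absolute scale is not published, and every downstream
#' statistic is scale-invariant or unit-carrying.
#'
#' @param nGenotypes number of genotypes (default 20).
#' @param treatments treatment codes to generate.
#' @param nReplicates replicate plants per genotype x treatment (default 8).
#' @param datGrid integer imaging-day grid.
#' @param groupSizes named counts of the latent groups, summing to
#'   `nGenotypes`.
#' @param groupParams per-group logistic parameters: asymptote `K`
#'   (voxels), rate `r` (day^-1), inflection day `t0`. Group B is smaller
#'   (lower `K`) but faster-growing (higher `r`).
#' @param dispersions genotype-level spread of the logistic parameters:
#'   lognormal CV for `K`, normal SDs for `r` and `t0`.
#' @param stress water-stress dip parameters: onset and trough days,
#'   per-group mean dip depth `deltaMean` (fraction of biomass lost at the
#'   trough, in [0,1)), its SD, and the recovery rate `gammaMean`
#'   (day^-1) with SD. Group B dips less deeply than group A.
#' @param nitrogen mild multiplicative penalty `nu` ramping in around day
#'   `rampMid` with logistic width `rampScale` (applies in N and NW).
#' @param synergy extra multiplicative penalty in NW, proportional to the
#'   instantaneous stress intensity (NW falls below W after the trough).
#' @param noiseCV lognormal coefficient of variation of one observation
#'   (multiplicative measurement + micro-environment error).
#' @param waterPerDay named grams of water applied per day per treatment
#'   (constant schedule; supports water-use efficiency).
#' @param linkNoiseCV lognormal CV of the secondary-trait link noise.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return A validated `SimulationConfig` (classed list).
#' @export
simulationConfig <- function(nGenotypes = 20L,
                             treatments = c("C", "N", "W", "NW"),
                             nReplicates = 8L,
                             datGrid = defaultDatGrid(),
                             groupSizes = c(A = 12L, B = 8L),
                             groupParams = list(
                               A = list(K = 12000, r = 0.32, t0 = 17),
                               B = list(K = 7000,  r = 0.40, t0 = 19)),
                             dispersions = list(Kcv = 0.08, rSd = 0.02,
                                                t0Sd = 0.5),
                             stress = list(onsetDat = 9, troughDat = 22,
                                           deltaMean = c(A = 0.55, B = 0.50),
                                           deltaSd = 0.12, rampExponent = 3,
                                           gammaMean = 0.10, gammaSd = 0.03),
                             nitrogen = list(nu = 0.09, rampMid = 25,
                                             rampScale = 3),
                             synergy = 0.05,
                             noiseCV = 0.10,
                             waterPerDay = c(C = 150, N = 150, W = 70, NW = 70),
                             linkNoiseCV = 0.05,
                             seed = 1L) {
  cfg <- list(nGenotypes = as.integer(nGenotypes), treatments = treatments,
              nReplicates = as.integer(nReplicates),
              datGrid = as.integer(datGrid), groupSizes = groupSizes,
              groupParams = groupParams, dispersions = dispersions,
              stress = stress, nitrogen = nitrogen, synergy = synergy,
              noiseCV = noiseCV, waterPerDay = waterPerDay,
              linkNoiseCV = linkNoiseCV, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

validateSimulationConfig <- function(cfg) {
  errs <- character()
  chk <- function(ok, field, why)
    if (!isTRUE(ok)) errs <<- c(errs, sprintf("%s: %s", field, why))
  chk(cfg$nGenotypes >= 2, "nGenotypes", "must be >= 2")
  chk(all(cfg$treatments %in% TREATMENT_LEVELS), "treatments",
      "must be within C, N, W, NW")
  chk(cfg$nReplicates >= 1, "nReplicates", "must be >= 1")
  chk(length(cfg$datGrid) >= 2 && all(diff(cfg$datGrid) > 0), "datGrid",
      "must be strictly increasing with >= 2 days")
  chk(sum(cfg$groupSizes) == cfg$nGenotypes, "groupSizes",
      "must sum to nGenotypes")
  chk(all(names(cfg$groupSizes) %in% names(cfg$groupParams)), "groupParams",
      "must provide parameters for every group")
  chk(all(vapply(cfg$groupParams, function(g) g$K > 0 && g$r > 0, TRUE)),
      "groupParams", "K and r must be > 0")
  chk(all(cfg$stress$deltaMean >= 0 & cfg$stress$deltaMean < 1),
      "stress$deltaMean", "must lie in [0, 1)")
  chk(cfg$stress$gammaMean > 0, "stress$gammaMean", "must be > 0")
  chk(cfg$stress$onsetDat < cfg$stress$troughDat, "stress",
      "onsetDat must precede troughDat")
  chk(cfg$noiseCV >= 0, "noiseCV", "must be >= 0")
  chk(all(cfg$waterPerDay[cfg$treatments] > 0), "waterPerDay",
      "must be > 0 for every generated treatment")
  if (length(errs))
    stop(gdCondition("growthdyn_invalid_config",
                     paste(errs, collapse = "; "), fields = errs))
  invisible(TRUE)
}

#' Logistic biomass curve
#'
#' @param t day (vectorized).
#' @param K asymptote (voxels).
#' @param r growth rate (day^-1).
#' @param t0 inflection day.
#' @return `K / (1 + exp(-r (t - t0)))`.
#' @export
logisticSize <- function(t, K, r, t0) K / (1 + exp(-r * (t - t0)))

#' Water-stress factor over time
#'
#' Multiplicative biomass factor of the drought treatment: 1 before
#' stress onset, a smooth accelerating decline to `1 - delta` at the
#' trough day (maximum stress), then exponential relaxation back toward
#' 1 at rate `gamma` after rewatering:
#' \deqn{S(t) = 1 - \delta \left(\frac{t - t_{on}}{t_{tr} - t_{on}}\right)^{q}
#'   \quad (t_{on} < t \le t_{tr}); \qquad
#'   S(t) = 1 - \delta e^{-\gamma (t - t_{tr})} \quad (t > t_{tr}).}
#' The ramp exponent `q > 1` makes the decline flat at onset (soil water
#' is still ample) and steepest at the trough, mirroring progressive
#' soil drying toward the wilting point; the steep final decline lets
#' the stressed biomass turn down into the trough day even while the
#' underlying logistic is still growing.
#'
#' @param t day (vectorized; `delta` and `gamma` recycle against it).
#' @param delta dip depth at the trough, in [0, 1).
#' @param gamma recovery rate after rewatering (day^-1).
#' @param onset stress-onset day (default 9).
#' @param trough maximum-stress day (default 22).
#' @param q ramp exponent (default 3).
#' @return Numeric vector of factors in (0, 1].
#' @export
stressFactor <- function(t, delta, gamma, onset = 9, trough = 22, q = 3) {
  n <- max(length(t), length(delta), length(gamma))
  t <- rep_len(t, n)
  delta <- rep_len(delta, n)
  gamma <- rep_len(gamma, n)
  s <- rep(1, n)
  mid <- t > onset & t <= trough
  s[mid] <- 1 - delta[mid] * ((t[mid] - onset) / (trough - onset))^q
  late <- t > trough
  s[late] <- 1 - delta[late] * exp(-gamma[late] * (t[late] - trough))
  s
}

nitrogenFactor <- function(t, nitrogen)
  1 - nitrogen$nu * stats::plogis((t - nitrogen$rampMid) / nitrogen$rampScale)

withSimSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

drawGenotypeParams <- function(cfg) {
  ids <- sprintf("G%02d", seq_len(cfg$nGenotypes))
  groups <- rep(names(cfg$groupSizes), times = cfg$groupSizes)
  disp <- cfg$dispersions
  sdlK <- sqrt(log(1 + disp$Kcv^2))
  K <- r <- t0 <- delta <- gamma <- numeric(cfg$nGenotypes)
  for (i in seq_len(cfg$nGenotypes)) {
    gp <- cfg$groupParams[[groups[i]]]
    K[i] <- gp$K * exp(stats::rnorm(1, 0, sdlK))
    r[i] <- max(0.05, stats::rnorm(1, gp$r, disp$rSd))
    t0[i] <- stats::rnorm(1, gp$t0, disp$t0Sd)
    delta[i] <- min(0.95, max(0, stats::rnorm(
      1, cfg$stress$deltaMean[[groups[i]]], cfg$stress$deltaSd)))
    gamma[i] <- min(1, max(0.02, stats::rnorm(
      1, cfg$stress$gammaMean, cfg$stress$gammaSd)))
  }
  data.frame(genotype = ids, group = groups, K = K, r = r, t0 = t0,
             delta = delta, gamma = gamma, stringsAsFactors = FALSE)
}

#' Latent genotype parameters behind a simulated experiment
#'
#' Returns exactly the per-genotype parameters (group label, logistic
#' `K`, `r`, `t0`, dip depth `delta`, recovery rate `gamma`) that
#' [simulateExperiment()] uses under the same config, enabling
#' parameter-recovery tests. Determinism is guaranteed: the parameters
#' are the first draws from the seeded stream.
#'
#' @param config a [simulationConfig()].
#' @return data.frame with one row per genotype.
#' @export
groundTruth <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSimSeed(config$seed, drawGenotypeParams(config))
}

#' Simulate a replicate-level multi-treatment phenotyping experiment
#'
#' Generates the full long-format trait table. The biovolume proxy for
#' genotype g, treatment j, replicate i, day t is
#' `EBv = L_g(t) * N(t) * S_g(t) * Syn(t) * eps`, where `L_g` is the
#' genotype's logistic curve, `N` the nitrogen penalty (1 in C and W),
#' `S_g` the water-stress factor (1 in C and N; see [stressFactor()]),
#' `Syn` a small extra NW synergy penalty, and `eps` lognormal
#' multiplicative noise with the configured CV (mean 1). Secondary traits
#' are deterministic links of the noise-free biomass and the
#' instantaneous stress intensity `1 - S_g(t)`, each with its own link
#' noise: height `PHg ~ EBv^(1/3)`, caliper length `CLe ~ EBv^0.4`,
#' surface coverage `SCov` and solidity `Sol` saturating in biomass with
#' a post-trough boost for small-plant genotypes, color ratios `Y2G` and
#' `B2G` increasing linearly in stress intensity, and fluorescence `FI`
#' increasing with stress after onset.
#'
#' @param config a [simulationConfig()].
#' @param traits which traits to emit (default all eight).
#' @return A [TraitTable-class].
#' @export
simulateExperiment <- function(config,
                               traits = c("EBv", "PHg", "CLe", "SCov",
                                          "Sol", "Y2G", "B2G", "FI")) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSimSeed(config$seed, {
    par <- drawGenotypeParams(config)
    grid <- expand.grid(dat = config$datGrid,
                        replicate = seq_len(config$nReplicates),
                        genotype = par$genotype,
                        treatment = config$treatments,
                        stringsAsFactors = FALSE)
    gi <- match(grid$genotype, par$genotype)
    L <- logisticSize(grid$dat, par$K[gi], par$r[gi], par$t0[gi])
    S <- rep(1, nrow(grid))
    wet <- grid$treatment %in% c("W", "NW")
    S[wet] <- stressFactor(grid$dat[wet], par$delta[gi[wet]],
                           par$gamma[gi[wet]],
                           config$stress$onsetDat, config$stress$troughDat,
                           config$stress$rampExponent)
    Nf <- rep(1, nrow(grid))
    nit <- grid$treatment %in% c("N", "NW")
    Nf[nit] <- nitrogenFactor(grid$dat[nit], config$nitrogen)
    syn <- rep(1, nrow(grid))
    nw <- grid$treatment == "NW"
    syn[nw] <- 1 - config$synergy * (1 - S[nw])
    mu <- L * S * Nf * syn
    stressIntensity <- 1 - S

    lnNoise <- function(cv, n = nrow(grid)) {
      if (cv <= 0) return(rep(1, n))
      sdl <- sqrt(log(1 + cv^2))
      exp(stats::rnorm(n, -sdl^2 / 2, sdl))
    }
    ## small-plant indicator in [0,1]: boosts canopy traits after rewatering
    small <- 1 / (1 + (par$K[gi] / 9000)^2)
    boost <- 1 + 0.25 * small * as.numeric(wet &
                                           grid$dat > config$stress$troughDat)
    cvL <- config$linkNoiseCV
    vals <- list(
      EBv  = mu * lnNoise(config$noiseCV),
      PHg  = 2.0 * mu^(1 / 3) * lnNoise(cvL),
      CLe  = 1.5 * mu^0.4 * lnNoise(cvL),
      SCov = 900 * mu / (mu + 3000) * boost * lnNoise(cvL),
      Sol  = pmin(0.99, (0.30 + 0.50 * mu / (mu + 3000)) * boost *
                         lnNoise(cvL / 2)),
      Y2G  = 0.25 + 0.50 * stressIntensity +
             stats::rnorm(nrow(grid), 0, 0.02 * (cvL > 0)),
      B2G  = 0.12 + 0.30 * stressIntensity +
             stats::rnorm(nrow(grid), 0, 0.015 * (cvL > 0)),
      FI   = 100 * (1 + 0.8 * stressIntensity) * lnNoise(cvL))
    out <- do.call(rbind, lapply(traits, function(tr)
      data.frame(genotype = grid$genotype, treatment = grid$treatment,
                 replicate = grid$replicate, dat = grid$dat, trait = tr,
                 value = vals[[tr]], stringsAsFactors = FALSE)))
    traitTable(out, grid = config$datGrid)
  })
}

#' Noise-free expected biomass trajectory of one genotype
#'
#' The generator's closed-form mean curve (no observation noise), used as
#' an analytic oracle for decline and index computations.
#'
#' @param config a [simulationConfig()].
#' @param params one row of [groundTruth()].
#' @param treatment treatment code.
#' @param dats days at which to evaluate (default the config grid).
#' @return Numeric vector of expected biovolumes.
#' @export
expectedBiomass <- function(config, params, treatment,
                            dats = config$datGrid) {
  L <- logisticSize(dats, params$K, params$r, params$t0)
  S <- if (treatment %in% c("W", "NW"))
    stressFactor(dats, params$delta, params$gamma,
                 config$stress$onsetDat, config$stress$troughDat,
                 config$stress$rampExponent)
  else rep(1, length(dats))
  Nf <- if (treatment %in% c("N", "NW")) nitrogenFactor(dats, config$nitrogen)
  else rep(1, length(dats))
  syn <- if (treatment == "NW") 1 - config$synergy * (1 - S) else rep(1, length(dats))
  L * S * Nf * syn
}

#' Water applied between two days under the configured schedule
#'
#' The irrigation schedule is a constant per-day amount per treatment, so
#' the water applied over a phase is `rate * (to - from)` grams.
#'
#' @param config a [simulationConfig()].
#' @param treatment treatment code.
#' @param from,to phase boundary days.
#' @return Grams of water applied.
#' @export
waterApplied <- function(config, treatment, from, to) {
  stopifnot(to > from, treatment %in% names(config$waterPerDay))
  unname(config$waterPerDay[treatment]) * (to - from)
}
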