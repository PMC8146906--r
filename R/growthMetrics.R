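#' Relative growth rate between two biomass measurements
#'
#' `RGR = (ln W2 - ln W1) / (T2 - T1)` in day^-1 (natural logarithm).
#'
#' @param w1,w2 biomass (e.g. biovolume voxels) at times `t1`, `t2`; must
#'   be positive.
#' @param t1,t2 days, with `t2 > t1`.
#' @return RGR in day^-1 (vectorized).
#' @export
relativeGrowthRate <- function(w1, w2, t1, t2) {
  if (any(w1 <= 0 | w2 <= 0))
    stop(gdCondition("growthdyn_nonpositive_biomass",
                     "biomass values must be > 0"))
  if (any(t2 <= t1))
    stop(gdCondition("growthdyn_bad_interval", "t2 must exceed t1"))
  (log(w2) - log(w1)) / (t2 - t1)
}

#' Per-interval relative growth rate along a growth curve
#'
#' Applies the RGR formula to each consecutive pair of imaging days. The
#' denominator is the true day distance, so the interval spanning a lost
#' imaging day (e.g. DAT 29 to 31) uses a two-day interval.
#'
#' @param curve a [GrowthCurve-class] with positive means.
#' @return data.frame with `datFrom`, `datTo`, `rgr` (day^-1); one row per
#'   consecutive interval.
#' @export
rgrSeries <- function(curve) {
  stopifnot(is(curve, "GrowthCurve"))
  d <- curve@dats
  w <- curve@means
  if (length(d) < 2)
    stop(gdCondition("growthdyn_bad_interval", "curve has fewer than 2 days"))
  if (any(w <= 0))
    stop(gdCondition("growthdyn_nonpositive_biomass", sprintf(
      "non-positive means at interval index(es): %s",
      paste(which(w <= 0), collapse = ", "))))
  k <- seq_len(length(d) - 1)
  data.frame(datFrom = d[k], datTo = d[k + 1],
             rgr = relativeGrowthRate(w[k], w[k + 1], d[k], d[k + 1]))
}

#' Coefficient of variation of a trait across genotypes over time
#'
#' Per imaging day, `CV = 100 * sd / mean` over the genotype means of the
#' trait in one treatment (sample standard deviation, n-1 divisor). The
#' genotype-mean level matches one CV point per treatment per day for the
#' cohort; `level = "replicate"` instead computes the CV across all
#' individual plants.
#'
#' @param table a [TraitTable-class].
#' @param trait trait name.
#' @param treatment treatment code.
#' @param level `"genotype"` (default, CV across genotype means) or
#'   `"replicate"` (CV across plants).
#' @return data.frame with `dat`, `cv` (percent), `n`.
#' @export
cvSeries <- function(table, trait, treatment,
                     level = c("genotype", "replicate")) {
  level <- match.arg(level)
  cs <- genotypeMeans(table, trait)
  if (level == "genotype") {
    d <- cs@data[cs@data$treatment == treatment & cs@data$n >= 1, ]
    valCol <- "mean"
  } else {
    d <- table@data[table@data$trait == trait &
                    table@data$treatment == treatment &
                    !is.na(table@data$value), ]
    valCol <- "value"
  }
  res <- do.call(rbind, lapply(split(d, d$dat), function(s) {
    v <- s[[valCol]]
    if (length(v) < 2)
      stop(gdCondition("growthdyn_too_few", sprintf(
        "need >= 2 values at DAT %d", s$dat[1])))
    m <- mean(v)
    if (m == 0)
      stop(gdCondition("growthdyn_zero_mean", sprintf(
        "zero mean at DAT %d", s$dat[1])))
    data.frame(dat = s$dat[1], cv = 100 * stats::sd(v) / m, n = length(v))
  }))
  res <- res[order(res$dat), ]
  rownames(res) <- NULL
  res
}

#' Water-use efficiency of a growth phase
#'
#' Biomass gained per gram of water applied over the phase:
#' `(EBv_end - EBv_start) / water`, in voxels per gram. Default phase
#' bounds follow the reference design: stress DAT 2 to 22, recovery
#' DAT 22 to 35.
#'
#' @param curve a [GrowthCurve-class].
#' @param water grams of water applied during the phase (> 0).
#' @param phase `"stress"` or `"recovery"` (selects the default bounds).
#' @param bounds integer pair of phase boundary days; both must be on the
#'   curve.
#' @return WUE in voxels per gram.
#' @export
wue <- function(curve, water, phase = c("stress", "recovery"),
                bounds = if (match.arg(phase) == "stress") c(2L, 22L)
                         else c(22L, 35L)) {
  phase <- match.arg(phase)
  stopifnot(is(curve, "GrowthCurve"), water > 0)
  if (!all(bounds %in% curve@dats))
    stop(gdCondition("growthdyn_off_grid", sprintf(
      "phase bound(s) not on the curve grid: %s",
      paste(setdiff(bounds, curve@dats), collapse = ", "))))
  w <- curve@means[match(bounds, curve@dats)]
  (w[2] - w[1]) / water
}

#' Timing and magnitude of the stress-induced biomass decline
#'
#' Locates the pre-stress growth peak within a search window (default
#' DAT 19..21, ties broken toward the earliest day) and measures the
#' decline into the maximum-stress day (default DAT 22):
#' `daysOfDecline = troughDat - peakDat` and
#' `pctDecline = 100 (EBv_peak - EBv_trough) / EBv_peak`. A curve still
#' rising into the trough day gets `pctDecline = 0`.
#'
#' @param curve a [GrowthCurve-class] of a stress treatment (W or NW).
#' @param window integer days searched for the peak (default 19:21).
#' @param troughDat the declared maximum-stress day (default 22).
#' @return data.frame row with `genotype`, `treatment`, `peakDat`,
#'   `daysOfDecline`, `pctDecline`.
#' @export
declineMetrics <- function(curve, window = 19:21, troughDat = 22L) {
  stopifnot(is(curve, "GrowthCurve"))
  if (!curve@treatment %in% c("W", "NW"))
    warning("decline metrics are defined for stress treatments (W, NW)")
  if (!troughDat %in% curve@dats)
    stop(gdCondition("growthdyn_off_grid",
                     sprintf("trough day %d not on the curve grid", troughDat)))
  win <- intersect(window, curve@dats)
  if (!length(win))
    stop(gdCondition("growthdyn_off_grid",
                     "search window has no days on the curve grid"))
  wv <- curve@means[match(win, curve@dats)]
  peakDat <- win[which.max(wv)]          # which.max: earliest tie wins
  peak <- max(wv)
  trough <- curve@means[match(troughDat, curve@dats)]
  data.frame(genotype = curve@genotypeId, treatment = curve@treatment,
             peakDat = peakDat,
             daysOfDecline = as.integer(troughDat - peakDat),
             pctDecline = max(0, 100 * (peak - trough) / peak))
}

#' Decline metrics for every genotype of a treatment
#'
#' @param table a [TraitTable-class].
#' @param treatment stress treatment (W or NW).
#' @param trait trait name (default "EBv").
#' @inheritParams declineMetrics
#' @return data.frame with one row per genotype.
#' @export
declineTable <- function(table, treatment, trait = "EBv", window = 19:21,
                         troughDat = 22L) {
  cs <- genotypeMeans(table, trait)
  out <- do.call(rbind, lapply(genotypeIds(table), function(g)
    declineMetrics(getCurve(cs, g, treatment), window, troughDat)))
  rownames(out) <- NULL
  out
}
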