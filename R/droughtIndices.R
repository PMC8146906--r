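#' Drought tolerance, recovery, and adaptability of one genotype
#'
#' Ratios of the stress-treatment biomass increment to the control
#' increment over three windows anchored at the experiment's milestone
#' days (stress initiation 9, maximum stress 22, start of rewatering 23,
#' harvest 35):
#' \itemize{
#'   \item tolerance  `DTO = (W_22 - W_9)  / (C_22 - C_9)`
#'   \item recovery   `DRC = (W_35 - W_23) / (C_35 - C_23)`
#'   \item adaptability `DAD = (W_35 - W_9) / (C_35 - C_9)`
#' }
#' Identical stress and control trajectories give all three ratios = 1.
#' A non-positive control increment leaves the corresponding score
#' undefined: it is reported as `NA` with a classed warning naming the
#' window (never clipped), or raised as an error with `strict = TRUE`.
#'
#' @param stressCurve,controlCurve [GrowthCurve-class] objects of the
#'   same genotype in a stress treatment (W/NW) and the control.
#' @param anchors named days `start`, `maxStress`, `rewater`, `end`; all
#'   must be on both curves.
#' @param strict raise an error (instead of `NA` + warning) on an
#'   undefined score.
#' @return data.frame row with `genotype`, `treatment`, `dto`, `drc`,
#'   `dad`.
#' @export
capabilityScores <- function(stressCurve, controlCurve,
                             anchors = c(start = 9L, maxStress = 22L,
                                         rewater = 23L, end = 35L),
                             strict = FALSE) {
  stopifnot(is(stressCurve, "GrowthCurve"), is(controlCurve, "GrowthCurve"))
  for (cv in list(stressCurve, controlCurve)) {
    off <- setdiff(anchors, cv@dats)
    if (length(off))
      stop(gdCondition("growthdyn_off_grid", sprintf(
        "anchor day(s) not on curve %s/%s: %s", cv@genotypeId, cv@treatment,
        paste(off, collapse = ", "))))
  }
  at <- function(curve, day) curve@means[match(day, curve@dats)]
  win <- list(dto = c(anchors[["start"]], anchors[["maxStress"]]),
              drc = c(anchors[["rewater"]], anchors[["end"]]),
              dad = c(anchors[["start"]], anchors[["end"]]))
  score <- function(nm) {
    b <- win[[nm]]
    ctrl <- at(controlCurve, b[2]) - at(controlCurve, b[1])
    strs <- at(stressCurve, b[2]) - at(stressCurve, b[1])
    if (!is.na(ctrl) && ctrl <= 0) {
      msg <- sprintf("undefined %s: control increment <= 0 in window DAT %d-%d",
                     toupper(nm), b[1], b[2])
      if (strict)
        stop(gdCondition("growthdyn_undefined_score", msg, window = nm))
      warning(warningCondition(msg,
                               class = c("growthdyn_undefined_score",
                                         "growthdyn_warning")))
      return(NA_real_)
    }
    strs / ctrl
  }
  data.frame(genotype = stressCurve@genotypeId,
             treatment = stressCurve@treatment,
             dto = score("dto"), drc = score("drc"), dad = score("dad"))
}

#' Capability scores and water-use efficiency for a whole cohort
#'
#' Computes DTO/DRC/DAD on replicate-averaged genotype-mean curves (one
#' value per genotype, as the indices are reported per line) plus
#' stress- and recovery-phase WUE when a water schedule is supplied.
#'
#' @param table a [TraitTable-class] containing the stress treatment and
#'   the control.
#' @param treatment stress treatment, `"W"` or `"NW"`.
#' @param trait trait name (default `"EBv"`).
#' @param waterStress,waterRecovery grams of water applied in the stress
#'   (DAT 2-22) and recovery (DAT 22-35) phases of `treatment`; `NA`
#'   skips the WUE columns.
#' @param anchors,strict passed to [capabilityScores()].
#' @return data.frame with one row per genotype: `genotype`, `treatment`,
#'   `dto`, `drc`, `dad`, `wueStress`, `wueRecovery`.
#' @export
capabilityTable <- function(table, treatment = "W", trait = "EBv",
                            waterStress = NA, waterRecovery = NA,
                            anchors = c(start = 9L, maxStress = 22L,
                                        rewater = 23L, end = 35L),
                            strict = FALSE) {
  stopifnot(treatment %in% c("W", "NW"))
  cs <- genotypeMeans(table, trait)
  rows <- lapply(genotypeIds(table), function(g) {
    sc <- capabilityScores(getCurve(cs, g, treatment),
                           getCurve(cs, g, "C"), anchors, strict)
    sc$wueStress <- if (is.na(waterStress)) NA_real_ else
      wue(getCurve(cs, g, treatment), waterStress, "stress")
    sc$wueRecovery <- if (is.na(waterRecovery)) NA_real_ else
      wue(getCurve(cs, g, treatment), waterRecovery, "recovery")
    sc
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

corWithP <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) return(c(r = NA_real_, p = NA_real_, n = n))
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x[ok], y[ok])
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  c(r = r, p = p, n = n)
}

#' Correlations among the drought-adaptive capabilities
#'
#' Pearson correlations (with two-sided p-values from the t transform on
#' n-2 df) among DTO, DRC, and DAD across genotypes. Undefined
#' correlations (a constant or all-missing score) are `NA` and flagged.
#'
#' @param scores data.frame from [capabilityTable()] (columns `dto`,
#'   `drc`, `dad`).
#' @return list with `r` (3x3 matrix, unit diagonal), `p` (3x3), `n`,
#'   and `flagged` (character vector of undefined pairs).
#' @export
capabilityCorrelations <- function(scores) {
  idx <- c("dto", "drc", "dad")
  stopifnot(all(idx %in% names(scores)))
  if (sum(stats::complete.cases(scores[, idx])) < 3)
    stop(gdCondition("growthdyn_too_few",
                     "need >= 3 genotypes with defined scores"))
  r <- p <- matrix(NA_real_, 3, 3, dimnames = list(toupper(idx), toupper(idx)))
  diag(r) <- 1
  diag(p) <- 0
  flagged <- character()
  for (i in 1:2) for (j in (i + 1):3) {
    cp <- corWithP(scores[[idx[i]]], scores[[idx[j]]])
    if (is.na(cp["r"]))
      flagged <- c(flagged, sprintf("%s-%s", toupper(idx[i]), toupper(idx[j])))
    r[i, j] <- r[j, i] <- cp[["r"]]
    p[i, j] <- p[j, i] <- cp[["p"]]
  }
  list(r = r, p = p, n = sum(stats::complete.cases(scores[, idx])),
       flagged = flagged)
}

significanceStars <- function(p)
  ifelse(is.na(p), "", ifelse(p <= 0.001, "***",
                       ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", ""))))

#' Correlations between traits and drought-adaptive capabilities
#'
#' Pearson correlation of genotype trait means at selected days (default
#' maximum stress DAT 22 and post-recovery DAT 35) with the DTO/DRC/DAD
#' scores, with conventional significance stars
#' (`*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001).
#'
#' @param table a [TraitTable-class].
#' @param scores data.frame from [capabilityTable()].
#' @param traits trait names to correlate.
#' @param dats days at which trait means are taken (default `c(22, 35)`).
#' @param treatment treatment in which trait means are measured (defaults
#'   to the scores' stress treatment).
#' @return data.frame with `trait`, `dat`, `index`, `r`, `p`, `stars`,
#'   `n`.
#' @export
traitCapabilityTable <- function(table, scores, traits = traitNames(table),
                                 dats = c(22L, 35L),
                                 treatment = scores$treatment[1]) {
  missing <- character()
  rows <- list()
  for (tr in traits) {
    cs <- genotypeMeans(table, tr)
    d <- cs@data[cs@data$treatment == treatment, ]
    for (day in dats) {
      dd <- d[d$dat == day & d$n >= 1, ]
      if (!nrow(dd)) { missing <- c(missing, sprintf("%s@DAT%d", tr, day)); next }
      v <- dd$mean[match(scores$genotype, dd$genotype)]
      for (ix in c("dto", "drc", "dad")) {
        cp <- corWithP(v, scores[[ix]])
        rows[[length(rows) + 1L]] <-
          data.frame(trait = tr, dat = day, index = toupper(ix),
                     r = cp[["r"]], p = cp[["p"]],
                     stars = significanceStars(cp[["p"]]), n = cp[["n"]])
      }
    }
  }
  if (length(missing))
    stop(gdCondition("growthdyn_missing_trait_day", sprintf(
      "missing trait/day combination(s): %s", paste(missing, collapse = ", "))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
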