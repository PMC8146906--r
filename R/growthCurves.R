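#' GrowthCurve: one genotype-by-treatment mean trajectory
#'
#' Replicate-averaged trajectory of one trait for one genotype in one
#' treatment, on the (possibly irregular) imaging-day grid. Days at which
#' no replicate was observed are dropped from the curve, so `dats` may be
#' a subset of the experiment grid.
#'
#' @slot genotypeId character genotype identifier.
#' @slot treatment one of C/N/W/NW.
#' @slot dats strictly increasing integer imaging days.
#' @slot means numeric replicate means, same length as `dats`.
#' @slot nPerPoint integer count of non-missing replicates per day (>= 1).
#' @export
setClass("GrowthCurve",
  representation(genotypeId = "character", treatment = "character",
                 dats = "integer", means = "numeric", nPerPoint = "integer"),
  validity = function(object) {
    if (length(object@dats) != length(object@means) ||
        length(object@dats) != length(object@nPerPoint))
      return("dats, means and nPerPoint must have equal length")
    if (length(object@dats) && any(diff(object@dats) <= 0L))
      return("dats must be strictly increasing")
    if (any(object@nPerPoint < 1L))
      return("nPerPoint must be >= 1")
    TRUE
  }
)

setMethod("show", "GrowthCurve", function(object) {
  cat(sprintf("GrowthCurve %s/%s: %d days (DAT %d..%d)\n",
              object@genotypeId, object@treatment, length(object@dats),
              min(object@dats), max(object@dats)))
})

#' GrowthCurveSet: all genotype-by-treatment mean trajectories of a trait
#'
#' @slot trait the trait name.
#' @slot grid the experiment's imaging-day grid.
#' @slot data data.frame with columns `genotype, treatment, dat, mean, n`;
#'   `mean` is `NA` with `n = 0` where no replicate was observed.
#' @export
setClass("GrowthCurveSet",
  representation(trait = "character", grid = "integer", data = "data.frame"))

setMethod("show", "GrowthCurveSet", function(object) {
  cat(sprintf("GrowthCurveSet '%s': %d genotypes x %d treatments, %d days\n",
              object@trait, length(unique(object@data$genotype)),
              length(unique(object@data$treatment)), length(object@grid)))
})

#' Replicate-averaged growth curves per genotype and treatment
#'
#' Averages the replicates of `trait` at each imaging day, producing one
#' mean trajectory per (genotype, treatment). `n` counts the non-missing
#' replicates entering each mean. The result is invariant to the row
#' order of the input table.
#'
#' @param table a [TraitTable-class].
#' @param trait trait name present in `table`.
#' @return A [GrowthCurveSet-class].
#' @export
genotypeMeans <- function(table, trait) {
  stopifnot(is(table, "TraitTable"))
  d <- table@data[table@data$trait == trait, , drop = FALSE]
  if (!nrow(d))
    stop(gdCondition("growthdyn_unknown_trait",
                     sprintf("trait '%s' not present in table", trait)))
  grp <- paste(d$genotype, d$treatment, d$dat, sep = "\r")
  obs <- !is.na(d$value)
  sums <- rowsum(ifelse(obs, d$value, 0), grp)
  cnts <- rowsum(as.numeric(obs), grp)
  parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  ag2 <- data.frame(genotype = parts[, 1], treatment = parts[, 2],
                    dat = as.integer(parts[, 3]),
                    mean = ifelse(cnts[, 1] > 0, sums[, 1] / cnts[, 1], NA_real_),
                    n = as.integer(cnts[, 1]))
  ag2 <- ag2[order(ag2$genotype, ag2$treatment, ag2$dat), ]
  rownames(ag2) <- NULL
  new("GrowthCurveSet", trait = trait, grid = table@grid, data = ag2)
}

#' Extract one GrowthCurve from a GrowthCurveSet
#'
#' Days with no observed replicate (`n = 0`) are dropped.
#'
#' @param curves a [GrowthCurveSet-class].
#' @param genotype,treatment identifiers of the curve to extract.
#' @return A [GrowthCurve-class].
#' @export
getCurve <- function(curves, genotype, treatment) {
  stopifnot(is(curves, "GrowthCurveSet"))
  d <- curves@data
  d <- d[d$genotype == genotype & d$treatment == treatment & d$n >= 1L, ,
         drop = FALSE]
  if (!nrow(d))
    stop(gdCondition("growthdyn_unknown_curve",
                     sprintf("no curve for %s/%s", genotype, treatment)))
  new("GrowthCurve", genotypeId = genotype, treatment = treatment,
      dats = as.integer(d$dat), means = d$mean, nPerPoint = as.integer(d$n))
}

#' Build a GrowthCurve directly from vectors
#'
#' @param genotype,treatment curve identifiers.
#' @param dats integer imaging days.
#' @param means numeric values per day.
#' @param n replicate counts per day (default 1).
#' @return A [GrowthCurve-class].
#' @export
growthCurve <- function(genotype, treatment, dats, means,
                        n = rep(1L, length(dats))) {
  new("GrowthCurve", genotypeId = as.character(genotype),
      treatment = as.character(treatment), dats = as.integer(dats),
      means = as.numeric(means), nPerPoint = as.integer(n))
}

#' Genotype-by-day profile matrix for one treatment
#'
#' Derived wide view used by the clustering and covariance modules: rows
#' are genotypes in sorted order, columns the imaging-day grid. Cells with
#' no observed replicate are `NA` (flagged, never imputed).
#'
#' @param curves a [GrowthCurveSet-class].
#' @param treatment treatment whose profiles to extract.
#' @return Numeric matrix with genotype rownames and `DAT<d>` colnames.
#' @export
wideMatrix <- function(curves, treatment) {
  stopifnot(is(curves, "GrowthCurveSet"))
  d <- curves@data[curves@data$treatment == treatment, , drop = FALSE]
  if (!nrow(d))
    stop(gdCondition("growthdyn_unknown_curve",
                     sprintf("no curves for treatment %s", treatment)))
  offgrid <- setdiff(unique(d$dat), curves@grid)
  if (length(offgrid))
    stop(gdCondition("growthdyn_grid_mismatch",
                     sprintf("days off the declared grid: %s",
                             paste(offgrid, collapse = ", "))))
  gts <- sort(unique(d$genotype))
  m <- matrix(NA_real_, length(gts), length(curves@grid),
              dimnames = list(gts, paste0("DAT", curves@grid)))
  m[cbind(match(d$genotype, gts), match(d$dat, curves@grid))] <-
    ifelse(d$n >= 1L, d$mean, NA_real_)
  m
}

#' Rebuild a GrowthCurveSet from a profile matrix
#'
#' Inverse of [wideMatrix()] (round-trip exact up to `NA` cells); used
#' when a caller supplies profiles rather than a raw table.
#'
#' @param m genotype-by-day numeric matrix with genotype rownames.
#' @param treatment treatment label for all rows.
#' @param dats integer days for the columns (default parsed from
#'   `colnames(m)`).
#' @param trait trait label (default "EBv").
#' @return A [GrowthCurveSet-class].
#' @export
curvesFromMatrix <- function(m, treatment,
                             dats = as.integer(sub("^DAT", "", colnames(m))),
                             trait = "EBv") {
  stopifnot(is.matrix(m), length(dats) == ncol(m))
  d <- data.frame(
    genotype = rep(rownames(m), times = ncol(m)),
    treatment = treatment,
    dat = rep(as.integer(dats), each = nrow(m)),
    mean = as.vector(m),
    n = ifelse(is.na(as.vector(m)), 0L, 1L))
  d <- d[order(d$genotype, d$treatment, d$dat), ]
  rownames(d) <- NULL
  new("GrowthCurveSet", trait = trait, grid = sort(as.integer(dats)), data = d)
}
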