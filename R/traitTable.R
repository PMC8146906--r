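#' @import methods
#' @importFrom stats aggregate
NULL

## Treatment codes: C control, N nitrogen stress, W water stress,
## NW combined nitrogen + water stress.
TREATMENT_LEVELS <- c("C", "N", "W", "NW")

## Traits that measure a physical size and must therefore be positive.
SIZE_TRAITS <- c("EBv", "PHg", "CLe", "SCov")

#' Default imaging-day grid
#'
#' Imaging days (days after transplanting, DAT) 2 through 35 with DAT 30
#' absent: the reference experimental design lost one imaging day, so the
#' grid is irregular and all time-aware computations must use true day
#' distances rather than consecutive indices.
#'
#' @return Integer vector of imaging days.
#' @export
defaultDatGrid <- function() setdiff(2L:35L, 30L)

gdCondition <- function(class, msg, ...) {
  structure(
    class = c(class, "growthdyn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
}

#' TraitTable: replicate-level long-format phenotype observations
#'
#' The canonical container of the package: one row per
#' (genotype, treatment, replicate, DAT, trait) with a numeric value.
#' Wide genotype-by-day matrices are derived views
#' (see [wideMatrix()]); the long table preserves the replicate-level
#' information required by per-day ANOVA and variance-component
#' decomposition. Explicitly missing observations are `NA` values on a
#' present row; a (genotype, treatment, trait) combination must cover the
#' full declared day grid.
#'
#' @slot data data.frame with columns `genotype` (character), `treatment`
#'   (one of C/N/W/NW), `replicate` (positive integer), `dat` (integer day
#'   after transplanting), `trait` (character), `value` (numeric, `NA`
#'   allowed for explicitly missing observations).
#' @slot grid strictly increasing integer vector of retained imaging days.
#' @export
setClass("TraitTable",
  representation(data = "data.frame", grid = "integer"),
  validity = function(object) {
    d <- object@data
    errs <- character()
    need <- c("genotype", "treatment", "replicate", "dat", "trait", "value")
    miss <- setdiff(need, names(d))
    if (length(miss))
      return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    if (length(object@grid) == 0L || any(diff(object@grid) <= 0L))
      errs <- c(errs, "grid must be non-empty and strictly increasing")
    bad <- setdiff(unique(d$treatment), TREATMENT_LEVELS)
    if (length(bad))
      errs <- c(errs, sprintf("unknown treatment level(s): %s",
                              paste(bad, collapse = ", ")))
    if (any(d$replicate < 1L | d$replicate != round(d$replicate)))
      errs <- c(errs, "replicate must be a positive integer")
    offgrid <- setdiff(unique(d$dat), object@grid)
    if (length(offgrid))
      errs <- c(errs, sprintf("dat value(s) off the declared grid: %s",
                              paste(offgrid, collapse = ", ")))
    key <- paste(d$genotype, d$treatment, d$replicate, d$dat, d$trait,
                 sep = "|")
    if (anyDuplicated(key))
      errs <- c(errs, sprintf("duplicate key(s): %s",
                              paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
                                    collapse = "; ")))
    sz <- d$trait %in% SIZE_TRAITS & !is.na(d$value)
    if (any(d$value[sz] <= 0))
      errs <- c(errs, "size-type traits (EBv, PHg, CLe, SCov) must be > 0")
    if (any(!is.na(d$value) & !is.finite(d$value)))
      errs <- c(errs, "trait values must be finite or NA")
    ## completeness: each (genotype, treatment, trait) covers the full grid
    combo <- unique(d[, c("genotype", "treatment", "trait")])
    cnt <- aggregate(dat ~ genotype + treatment + trait, data = d,
                     FUN = function(x) length(unique(x)))
    short <- cnt[cnt$dat < length(object@grid), , drop = FALSE]
    if (nrow(short))
      errs <- c(errs, sprintf(
        "incomplete day coverage (gaps must be NA rows, not absent): e.g. %s/%s/%s",
        short$genotype[1], short$treatment[1], short$trait[1]))
    if (length(errs)) paste(errs, collapse = "; ") else TRUE
  }
)

#' Construct a TraitTable
#'
#' @param data data.frame with columns
#'   `genotype,treatment,replicate,dat,trait,value`.
#' @param grid integer day grid the observations must lie on; defaults to
#'   the days present in `data`.
#' @return A validated [TraitTable-class] object.
#' @export
traitTable <- function(data, grid = sort(unique(as.integer(data$dat)))) {
  data$genotype <- as.character(data$genotype)
  data$treatment <- as.character(data$treatment)
  data$replicate <- as.integer(data$replicate)
  data$dat <- as.integer(data$dat)
  data$trait <- as.character(data$trait)
  data$value <- as.numeric(data$value)
  rownames(data) <- NULL
  new("TraitTable", data = data[, c("genotype", "treatment", "replicate",
                                    "dat", "trait", "value")],
      grid = as.integer(grid))
}

#' @describeIn TraitTable-class number of observation rows
#' @param x,object a `TraitTable`
#' @export
setMethod("length", "TraitTable", function(x) nrow(x@data))

setMethod("show", "TraitTable", function(object) {
  d <- object@data
  cat(sprintf("TraitTable: %d records | %d genotypes x %d treatments x %d traits\n",
              nrow(d), length(unique(d$genotype)),
              length(unique(d$treatment)), length(unique(d$trait))))
  cat(sprintf("  day grid: DAT %d..%d (%d days%s)\n",
              min(object@grid), max(object@grid), length(object@grid),
              if (length(setdiff(seq(min(object@grid), max(object@grid)),
                                 object@grid))) ", irregular" else ""))
  cat(sprintf("  missing values: %d\n", sum(is.na(d$value))))
})

#' Accessors for TraitTable
#'
#' `datGrid` returns the declared imaging-day grid, `traitNames` the traits
#' present, `genotypeIds` the genotype identifiers, `treatmentLevels` the
#' treatments present, and `traitData` the underlying long data.frame.
#'
#' @param x a [TraitTable-class]
#' @return See individual descriptions.
#' @export
datGrid <- function(x) x@grid

#' @rdname datGrid
#' @export
traitNames <- function(x) sort(unique(x@data$trait))

#' @rdname datGrid
#' @export
genotypeIds <- function(x) sort(unique(x@data$genotype))

#' @rdname datGrid
#' @export
treatmentLevels <- function(x) intersect(TREATMENT_LEVELS, unique(x@data$treatment))

#' @rdname datGrid
#' @export
traitData <- function(x) x@data

#' Read a long-format phenotype CSV into a TraitTable
#'
#' The canonical file format is a UTF-8 CSV with header
#' `genotype,treatment,replicate,dat,trait,value` and `.` as the decimal
#' separator. Lines starting with `#` (pipeline provenance headers) are
#' skipped. A `schema` mapping allows reading files whose columns are
#' named differently.
#'
#' @param path path to the CSV file.
#' @param schema named character vector mapping canonical names to the
#'   file's column names, e.g. `c(genotype = "line_id")`; unmapped columns
#'   keep the canonical name.
#' @return A validated [TraitTable-class].
#' @export
readTraitTable <- function(path, schema = character()) {
  if (!file.exists(path))
    stop(gdCondition("growthdyn_missing_file", sprintf("file not found: %s", path)))
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  canon <- c("genotype", "treatment", "replicate", "dat", "trait", "value")
  src <- canon
  names(src) <- canon
  src[names(schema)] <- schema
  miss <- src[!src %in% names(d)]
  if (length(miss))
    stop(gdCondition("growthdyn_missing_column",
                     sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
                     columns = unname(miss)))
  d <- d[, src]
  names(d) <- canon
  num <- suppressWarnings(as.numeric(d$value))
  badRows <- which(!is.na(d$value) & d$value != "" & is.na(num))
  if (length(badRows))
    stop(gdCondition("growthdyn_parse_error",
                     sprintf("non-numeric value(s) at data row(s): %s",
                             paste(badRows, collapse = ", ")),
                     rows = badRows))
  d$value <- num
  key <- paste(d$genotype, d$treatment, d$replicate, d$dat, d$trait, sep = "|")
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stop(gdCondition("growthdyn_duplicate_key",
                     sprintf("duplicate observation key(s): %s",
                             paste(dup, collapse = "; ")),
                     keys = dup))
  traitTable(d)
}

#' Write a TraitTable to the canonical CSV format
#'
#' @param x a [TraitTable-class]
#' @param path output file path.
#' @param header optional character vector of provenance lines written as
#'   `#`-prefixed comments before the CSV header.
#' @return `path`, invisibly.
#' @export
writeTraitTable <- function(x, path, header = NULL) {
  stopifnot(is(x, "TraitTable"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(x@data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Emit a JSON schema describing a TraitTable
#'
#' Writes the trait list, treatments, and day grid as a small JSON
#' document alongside pipeline outputs, so downstream consumers can
#' validate inputs without parsing the data itself.
#'
#' @param x a [TraitTable-class]
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
writeTraitSchema <- function(x, path) {
  jsonlite::write_json(
    list(columns = c("genotype", "treatment", "replicate", "dat", "trait", "value"),
         treatments = treatmentLevels(x),
         traits = traitNames(x),
         dat_grid = datGrid(x),
         size_traits = intersect(SIZE_TRAITS, traitNames(x))),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
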