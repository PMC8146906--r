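PIPELINE_STAGES <- c("simulate", "metrics", "indices", "cluster",
                     "varcomp", "covstruct", "correlate", "onset")

configHash <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

writeStageCsv <- function(df, path, hdr) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# growthdyn ", hdr), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full growth-dynamics pipeline
#'
#' Orchestrates simulate -> metrics -> indices -> cluster -> varcomp ->
#' covstruct -> correlate -> onset on one trait table, writing one CSV
#' per result plus a JSON run manifest (tool version, config hash, seed,
#' per-file md5 digests, timestamps). Re-running with the same config
#' and seed reproduces byte-identical CSVs; every CSV carries a comment
#' header with the config hash and seed. A stage whose input is missing
#' stops with an error naming the missing stage.
#'
#' @param outDir output directory (created if needed).
#' @param config a [simulationConfig()]; also the source of water
#'   amounts for WUE.
#' @param seed seed for every stochastic stage (defaults to
#'   `config$seed`; overrides it for the simulation).
#' @param stages subset of pipeline stages to run, in any order.
#' @param table optional [TraitTable-class] input; required when the
#'   `simulate` stage is not run.
#' @param trait primary trait for clustering/statistics (default "EBv").
#' @param clusterTreatment treatment whose temporal profiles are
#'   clustered (default "W").
#' @param cRange,m,restarts fuzzy clustering options (see
#'   [selectCMajority()]).
#' @param thin keep every `thin`-th imaging day for covariance-structure
#'   fitting (the full 33-day grid is over-parameterized for a
#'   20-subject cohort; default 4 keeps 9 days).
#' @param varcompDats days for the variance decomposition (default the
#'   full grid).
#' @param onsetContrasts list of treatment contrasts for onset detection.
#' @return The manifest (list), invisibly; all outputs on disk.
#' @export
runPipeline <- function(outDir, config = simulationConfig(),
                        seed = config$seed,
                        stages = PIPELINE_STAGES, table = NULL,
                        trait = "EBv", clusterTreatment = "W",
                        cRange = 2:6, m = 2, restarts = 20L, thin = 4L,
                        varcompDats = NULL,
                        onsetContrasts = list(c("W", "C"), c("N", "C"),
                                              c("NW", "C"))) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- as.integer(seed)
  hash <- configHash(config)
  hdr <- sprintf("config=%s seed=%d", hash, config$seed)
  outputs <- character()
  keep <- function(path) outputs <<- c(outputs, path)
  t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  needTable <- function(stage) {
    if (is.null(table))
      stop(gdCondition("growthdyn_missing_stage", sprintf(
        "stage '%s' requires a trait table: run stage 'simulate' first or supply `table`",
        stage), stage = "simulate"))
    table
  }

  if ("simulate" %in% stages) {
    table <- simulateExperiment(config)
    keep(writeTraitTable(table, file.path(outDir, "table.csv"),
                         header = paste("growthdyn", hdr)))
    keep(writeStageCsv(groundTruth(config),
                       file.path(outDir, "ground_truth.csv"), hdr))
    keep(writeTraitSchema(table, file.path(outDir, "schema.json")))
  }

  curves <- NULL
  getCurves <- function(stage) {
    if (is.null(curves)) curves <<- genotypeMeans(needTable(stage), trait)
    curves
  }

  if ("metrics" %in% stages) {
    tb <- needTable("metrics")
    cs <- getCurves("metrics")
    rgr <- do.call(rbind, lapply(split(cs@data, list(cs@data$genotype,
                                                     cs@data$treatment),
                                       drop = TRUE), function(s) {
      cv <- getCurve(cs, s$genotype[1], s$treatment[1])
      cbind(genotype = s$genotype[1], treatment = s$treatment[1],
            rgrSeries(cv))
    }))
    rownames(rgr) <- NULL
    keep(writeStageCsv(rgr, file.path(outDir, "rgr.csv"), hdr))
    cv <- do.call(rbind, lapply(treatmentLevels(tb), function(tr)
      cbind(treatment = tr, cvSeries(tb, trait, tr))))
    keep(writeStageCsv(cv, file.path(outDir, "cv.csv"), hdr))
    wtr <- intersect(c("W", "NW"), treatmentLevels(tb))
    wueTab <- do.call(rbind, lapply(wtr, function(tr) {
      do.call(rbind, lapply(genotypeIds(tb), function(g) {
        cv <- getCurve(cs, g, tr)
        data.frame(genotype = g, treatment = tr,
                   wueStress = wue(cv, waterApplied(config, tr, 2, 22),
                                   "stress"),
                   wueRecovery = wue(cv, waterApplied(config, tr, 22, 35),
                                     "recovery"))
      }))
    }))
    keep(writeStageCsv(wueTab, file.path(outDir, "wue.csv"), hdr))
    dec <- do.call(rbind, lapply(wtr, function(tr) declineTable(tb, tr, trait)))
    keep(writeStageCsv(dec, file.path(outDir, "decline.csv"), hdr))
  }

  scores <- NULL
  if ("indices" %in% stages) {
    tb <- needTable("indices")
    wtr <- intersect(c("W", "NW"), treatmentLevels(tb))
    scores <- do.call(rbind, lapply(wtr, function(tr)
      capabilityTable(tb, tr, trait,
                      waterStress = waterApplied(config, tr, 2, 22),
                      waterRecovery = waterApplied(config, tr, 22, 35))))
    keep(writeStageCsv(scores, file.path(outDir, "scores.csv"), hdr))
    ccor <- do.call(rbind, lapply(wtr, function(tr) {
      cc <- capabilityCorrelations(scores[scores$treatment == tr, ])
      idx <- which(upper.tri(cc$r), arr.ind = TRUE)
      data.frame(treatment = tr,
                 pair = paste(rownames(cc$r)[idx[, 1]],
                              colnames(cc$r)[idx[, 2]], sep = "-"),
                 r = cc$r[idx], p = cc$p[idx], n = cc$n)
    }))
    keep(writeStageCsv(ccor, file.path(outDir, "capability_correlations.csv"),
                       hdr))
  }

  if ("cluster" %in% stages) {
    tb <- needTable("cluster")
    profiles <- wideMatrix(getCurves("cluster"), clusterTreatment)
    if (anyNA(profiles))
      stop(gdCondition("growthdyn_missing_cells",
                       "profiles contain missing cells; cannot cluster"))
    vrep <- selectCMajority(profiles, cRange = cRange, m = m,
                           seed = config$seed, restarts = restarts)
    part <- selectedPartition(vrep)
    mem <- data.frame(genotype = rownames(profiles),
                      cluster = LETTERS[hardLabels(part)],
                      membershipMatrix(part), check.names = FALSE)
    keep(writeStageCsv(mem, file.path(outDir, "membership.csv"), hdr))
    val <- data.frame(c = vrep@cValues, vrep@indexValues,
                      votes = vapply(vrep@cValues, function(cc)
                        sum(vrep@votes == cc), 0L),
                      selected = vrep@cValues == vrep@selectedC)
    keep(writeStageCsv(val, file.path(outDir, "validity.csv"), hdr))
    keep(writeStageCsv(typicalCurves(part),
                       file.path(outDir, "typical_curves.csv"), hdr))
    if (selectedC(vrep) == 2L)
      keep(writeStageCsv(clusterDiffProfile(part, tb, trait,
                                            clusterTreatment),
                         file.path(outDir, "diffprofile.csv"), hdr))
  }

  if ("varcomp" %in% stages) {
    tb <- needTable("varcomp")
    dats <- if (is.null(varcompDats)) datGrid(tb) else varcompDats
    keep(writeStageCsv(varianceComponentsSeries(tb, trait, dats),
                       file.path(outDir, "varcomp.csv"), hdr))
  }

  if ("covstruct" %in% stages) {
    tb <- needTable("covstruct")
    cs <- getCurves("covstruct")
    grid <- datGrid(tb)
    sub <- grid[seq(1, length(grid), by = thin)]
    bic <- do.call(rbind, lapply(treatmentLevels(tb), function(tr) {
      Y <- wideMatrix(cs, tr)[, paste0("DAT", sub), drop = FALSE]
      Y <- Y[stats::complete.cases(Y), , drop = FALSE]
      sel <- selectStructureBIC(fitAllCovarianceStructures(Y, sub))
      cbind(treatment = tr, sel$table,
            best = sel$table$structure == sel$structure)
    }))
    keep(writeStageCsv(bic, file.path(outDir, "bic.csv"), hdr))
  }

  if ("correlate" %in% stages) {
    tb <- needTable("correlate")
    others <- setdiff(traitNames(tb), trait)
    corTab <- do.call(rbind, lapply(others, function(tr)
      cbind(traitX = tr, traitY = trait,
            correlationSeries(tb, tr, trait, clusterTreatment))))
    keep(writeStageCsv(corTab, file.path(outDir, "correlation.csv"), hdr))
  }

  if ("onset" %in% stages) {
    tb <- needTable("onset")
    onsTab <- do.call(rbind, lapply(onsetContrasts, function(ct) {
      if (!all(ct %in% treatmentLevels(tb))) return(NULL)
      do.call(rbind, lapply(traitNames(tb), function(tr) {
        os <- onsetSeries(tb, tr, ct)
        data.frame(trait = tr, contrast = paste(ct, collapse = "-"),
                   onsetDat = os$onsetDat,
                   runs = paste(sprintf("%d..%d", os$runs$startDat,
                                        os$runs$endDat), collapse = ";"))
      }))
    }))
    keep(writeStageCsv(onsTab, file.path(outDir, "onset.csv"), hdr))
  }

  manifest <- list(
    tool = "growthdyn",
    version = as.character(utils::packageVersion("growthdyn")),
    configHash = hash, seed = config$seed, stages = stages,
    started = t0, finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
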