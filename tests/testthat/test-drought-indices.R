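mkCurve <- function(vals, treatment = "W",
                    dats = c(2L, 9L, 22L, 23L, 35L), genotype = "G01")
  growthCurve(genotype, treatment, dats, vals)

test_that("capability scores: identity, proportional, and scaling cases", {
  ctrl <- mkCurve(c(10, 20, 120, 130, 220), "C")
  ## identical trajectories give all ratios 1
  sc <- capabilityScores(mkCurve(c(10, 20, 120, 130, 220)), ctrl)
  expect_equal(unlist(sc[, c("dto", "drc", "dad")]), c(1, 1, 1),
               ignore_attr = TRUE)
  ## stress increments exactly half of control's
  half <- mkCurve(c(10, 20, 70, 75, 120))   # 9->22: 50 vs 100; 23->35: 45 vs 90
  sc2 <- capabilityScores(half, ctrl)
  expect_equal(unlist(sc2[, c("dto", "drc", "dad")]), c(0.5, 0.5, 0.5),
               ignore_attr = TRUE)
  ## common multiplicative rescaling of both curves changes nothing
  sc3 <- capabilityScores(mkCurve(5.5 * c(10, 20, 70, 75, 120)),
                          mkCurve(5.5 * c(10, 20, 120, 130, 220), "C"))
  expect_equal(sc3[, c("dto", "drc", "dad")], sc2[, c("dto", "drc", "dad")],
               tolerance = 1e-12)
})

test_that("undefined scores are reported missing (or raised when strict)", {
  ctrl <- mkCurve(c(10, 20, 120, 130, 100), "C")   # control shrinks 23->35
  strs <- mkCurve(c(10, 15, 60, 65, 90))
  expect_warning(sc <- capabilityScores(strs, ctrl),
                 class = "growthdyn_undefined_score")
  expect_true(is.na(sc$drc))
  expect_false(is.na(sc$dto))
  err <- tryCatch(capabilityScores(strs, ctrl, strict = TRUE),
                  error = identity)
  expect_s3_class(err, "growthdyn_undefined_score")
  expect_match(conditionMessage(err), "DAT 23-35")
  ## anchor day off the curve grid
  expect_classed_error(
    capabilityScores(growthCurve("G01", "W", c(2L, 9L, 22L, 35L),
                                 c(1, 2, 3, 4)), ctrl),
    "growthdyn_off_grid")
})

test_that("adaptability is a weighted mean of tolerance and recovery when
           control increments are proportional across windows", {
  set.seed(8)
  for (i in 1:20) {
    incC <- runif(2, 10, 100)              # control 9->22 and 23->35
    dto <- runif(1, 0.1, 1.2)
    drc <- runif(1, 0.1, 1.2)
    jump <- runif(2, 0, 5)                 # shared 22->23 step
    ctrl <- mkCurve(c(5, 10, 10 + incC[1], 10 + incC[1] + jump[1],
                      10 + incC[1] + jump[1] + incC[2]), "C")
    strs <- mkCurve(c(5, 10, 10 + dto * incC[1], 10 + dto * incC[1] + jump[2],
                      10 + dto * incC[1] + jump[2] + drc * incC[2]))
    sc <- capabilityScores(strs, ctrl)
    dadTrue <- (dto * incC[1] + jump[2] + drc * incC[2]) /
      (incC[1] + jump[1] + incC[2])
    expect_equal(sc$dad, dadTrue, tolerance = 1e-10)
    expect_equal(sc$dto, dto, tolerance = 1e-10)
    expect_equal(sc$drc, drc, tolerance = 1e-10)
  }
  ## with a shared rewatering step the bound holds exactly
  ctrl <- mkCurve(c(5, 10, 60, 62, 112), "C")
  strs <- mkCurve(c(5, 10, 20, 22, 67))    # dto 0.2, drc 0.9
  sc <- capabilityScores(strs, ctrl)
  expect_true(sc$dad > sc$dto && sc$dad < sc$drc)
})

test_that("tolerance ranking recovers the latent dip depth", {
  ## with a common growth-curve shape, ranking by tolerance reproduces the
  ## ranking by 1 - delta exactly
  cfg <- simulationConfig(seed = 6L, noiseCV = 0, linkNoiseCV = 0,
                          groupSizes = c(A = 20L),
                          groupParams = list(A = list(K = 12000, r = 0.32,
                                                      t0 = 17)),
                          dispersions = list(Kcv = 0.08, rSd = 0, t0Sd = 0),
                          stress = list(onsetDat = 9, troughDat = 22,
                                        deltaMean = c(A = 0.5), deltaSd = 0.12,
                                        rampExponent = 3, gammaMean = 0.1,
                                        gammaSd = 0.03))
  tb <- simulateExperiment(cfg, traits = "EBv")
  gt <- groundTruth(cfg)
  scores <- capabilityTable(tb, "W")
  expect_identical(order(scores$dto), order(-gt$delta))
  ## with genotype-specific growth curves the association stays very strong
  cfg2 <- simulationConfig(seed = 6L, noiseCV = 0, linkNoiseCV = 0)
  sc2 <- capabilityTable(simulateExperiment(cfg2, traits = "EBv"), "W")
  expect_lt(cor(sc2$dto, groundTruth(cfg2)$delta, method = "spearman"), -0.9)
})

test_that("capability correlations: exact, degenerate, and flagged cases", {
  sc <- data.frame(genotype = sprintf("G%02d", 1:6), treatment = "W",
                   dto = c(1, 2, 3, 4, 5, 6) / 10,
                   drc = c(2, 1, 4, 3, 6, 5) / 10)
  sc$dad <- sc$drc
  cc <- capabilityCorrelations(sc)
  expect_equal(cc$r["DRC", "DAD"], 1)
  expect_true(isSymmetric(cc$r))
  expect_equal(diag(cc$r), c(DTO = 1, DRC = 1, DAD = 1))
  ## p-values match the closed t-transform (cross-check with cor.test)
  ct <- cor.test(sc$dto, sc$drc)
  expect_equal(cc$p["DTO", "DRC"], ct$p.value, tolerance = 1e-12)

  sc$dto <- 0.5                            # constant column
  cc2 <- capabilityCorrelations(sc)
  expect_true(all(is.na(cc2$r["DTO", c("DRC", "DAD")])))
  expect_true(any(grepl("DTO", cc2$flagged)))
  expect_classed_error(capabilityCorrelations(sc[1:2, ]), "growthdyn_too_few")
})

test_that("when only recovery rate varies, adaptability tracks recovery
           more than tolerance", {
  cfg <- simulationConfig(
    seed = 9L, noiseCV = 0, linkNoiseCV = 0,
    groupSizes = c(A = 20L),
    groupParams = list(A = list(K = 12000, r = 0.32, t0 = 17)),
    dispersions = list(Kcv = 0.08, rSd = 0.005, t0Sd = 0.1),
    stress = list(onsetDat = 9, troughDat = 22,
                  deltaMean = c(A = 0.5), deltaSd = 0,
                  rampExponent = 3, gammaMean = 0.10, gammaSd = 0.04))
  tb <- simulateExperiment(cfg, traits = "EBv")
  scores <- capabilityTable(tb, "W")
  cc <- capabilityCorrelations(scores)
  expect_gt(abs(cc$r["DAD", "DRC"]), abs(cc$r["DAD", "DTO"]))
})

test_that("trait-capability correlations: exact and directional cases", {
  cfg <- simulationConfig(seed = 5L)
  tb <- simulateExperiment(cfg, traits = "EBv")
  scores <- capabilityTable(tb, "W")
  ## a trait constructed equal to dto correlates perfectly at both days
  d <- traitData(tb)
  x <- d[d$trait == "EBv" & d$replicate == 1L, ]
  x$trait <- "XDT"
  x$value <- scores$dto[match(x$genotype, scores$genotype)]
  tb2 <- traitTable(rbind(d, x), grid = datGrid(tb))
  tc <- traitCapabilityTable(tb2, scores, traits = "XDT")
  expect_equal(tc$r[tc$index == "DTO"], c(1, 1), tolerance = 1e-12)
  expect_true(all(tc$stars[tc$index == "DTO"] == "***"))
  ## biomass at maximum stress relates positively to tolerance
  ## (direction check: lines that keep more biomass at the trough are the
  ## ones whose stress dip was shallow)
  te <- traitCapabilityTable(tb, scores, traits = "EBv")
  r22 <- te[te$dat == 22 & te$index == "DTO", ]
  expect_gt(r22$r, 0)
  ## missing trait/day combinations are listed
  expect_classed_error(
    traitCapabilityTable(tb, scores, traits = "EBv", dats = c(22L, 99L)),
    "growthdyn_missing_trait_day")
})

test_that("independent noise traits are rarely called significant", {
  cfg <- simulationConfig(seed = 12L)
  tb <- simulateExperiment(cfg, traits = "EBv")
  scores <- capabilityTable(tb, "W")
  d <- traitData(tb)
  base <- d[d$trait == "EBv" & d$replicate == 1L & d$treatment == "W", ]
  set.seed(99)
  noise <- do.call(rbind, lapply(1:100, function(i) {
    x <- base
    x$trait <- sprintf("N%03d", i)
    x$value <- rnorm(length(unique(x$genotype)))[match(
      x$genotype, unique(x$genotype))] + 10
    x
  }))
  tbN <- traitTable(rbind(d, noise), grid = datGrid(tb))
  tc <- traitCapabilityTable(tbN, scores, traits = sprintf("N%03d", 1:100),
                             dats = 22L)
  fracSig <- mean(tc$p[tc$index == "DTO"] <= 0.05)
  expect_lte(fracSig, 0.10)
})
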