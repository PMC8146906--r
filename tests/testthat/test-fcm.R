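test_that("single-cluster solution is the mean profile in closed form", {
  set.seed(1)
  x <- matrix(rnorm(60), 12, 5)
  p <- fcm(x, 1)
  expect_equal(as.vector(clusterCenters(p)), colMeans(x))
  expect_equal(p@objective, sum(sweep(x, 2, colMeans(x))^2), tolerance = 1e-10)
  expect_equal(hardLabels(p), rep(1L, 12))
})

test_that("well-separated clouds are recovered crisply and canonically", {
  sp <- separatedProfiles(3)
  p <- fcm(sp$x, 2, seed = 5)
  expect_equal(mclust::adjustedRandIndex(hardLabels(p), sp$truth), 1)
  expect_gt(min(apply(membershipMatrix(p), 1, max)), 0.95)
  ## canonical labels: cluster "A" (label 1) is the higher-level cloud
  expect_gt(mean(clusterCenters(p)[1, ]), mean(clusterCenters(p)[2, ]))
  expect_equal(unname(clusterLabels(p)[sp$truth == 2][1]), "A")
  ## determinism under a fixed seed
  p2 <- fcm(sp$x, 2, seed = 5)
  expect_identical(membershipMatrix(p), membershipMatrix(p2))
})

test_that("membership rows normalize and the objective never increases", {
  set.seed(7)
  for (i in 1:10) {
    x <- matrix(rnorm(40 * 6, sd = runif(1, 0.5, 3)), 40, 6)
    p <- fcm(x, sample(2:4, 1), seed = i, restarts = 3)
    expect_true(all(abs(rowSums(membershipMatrix(p)) - 1) < 1e-9))
    expect_true(all(diff(p@objectiveTrace) <= 1e-8 * max(1, p@objectiveTrace[1])))
  }
})

test_that("a profile coinciding with a center takes membership one", {
  x <- rbind(matrix(0, 5, 3), matrix(10, 5, 3)) +
    rbind(matrix(0, 5, 3), 0 * matrix(1, 5, 3))
  ## duplicate profiles are flagged but clustered
  p <- fcm(x + rnorm(30, sd = 1e-12), 2, seed = 1)
  expect_gt(min(apply(membershipMatrix(p), 1, max)), 1 - 1e-6)
  pd <- fcm(x, 3, seed = 1)
  expect_true(length(pd@flagged) > 0)
})

test_that("objective and centers agree with an independent implementation", {
  skip_if_not_installed("e1071")
  sp <- separatedProfiles(11, nPer = 10, gap = 8, spread = 1.5)
  ours <- fcm(sp$x, 2, m = 2, seed = 3, restarts = 10)
  set.seed(3)
  ref <- e1071::cmeans(sp$x, 2, m = 2, iter.max = 500)
  ## same global optimum: objective within relative 1e-5, centers aligned
  refObj <- sum(ref$membership^2 * as.matrix(stats::dist(
    rbind(sp$x, ref$centers)))[1:20, 21:22]^2)
  expect_equal(ours@objective, refObj, tolerance = 1e-4)
  ord <- order(-rowMeans(ref$centers))
  expect_equal(unname(clusterCenters(ours)), unname(ref$centers[ord, ]),
               tolerance = 1e-3)
  ## partition coefficient / entropy match the reference formulas
  vi <- validityIndices(ours)
  expect_equal(unname(vi["pc"]), sum(ours@membership^2) / 20, tolerance = 1e-12)
  fcPc <- e1071::fclustIndex(ref, sp$x, index = "partition.coefficient")
  fcPe <- e1071::fclustIndex(ref, sp$x, index = "partition.entropy")
  expect_equal(unname(vi["pc"]), unname(as.numeric(fcPc)), tolerance = 1e-4)
  expect_equal(unname(vi["pe"]), unname(as.numeric(fcPe)), tolerance = 1e-4)
})

test_that("majority rule picks two clusters for two separated groups", {
  sp <- separatedProfiles(21, nPer = 10, T = 6, gap = 30)
  vr <- selectCMajority(sp$x, 2:6, seed = 2, restarts = 5)
  expect_equal(selectedC(vr), 2L)
  expect_gte(sum(vr@votes == 2L), 4L)
  expect_s4_class(selectedPartition(vr), "FuzzyPartition")
  ## partition coefficient decreases with c on a single spherical cloud
  set.seed(31)
  cloud <- matrix(rnorm(40 * 5), 40, 5)
  vr2 <- selectCMajority(cloud, 2:5, seed = 4, restarts = 5)
  pcs <- vr2@indexValues[, "pc"]
  expect_true(all(diff(pcs) < 0))
  expect_error(selectCMajority(cloud, c(1, 3)), "cRange")
})

test_that("typical curves average hard members over the stress window", {
  x <- rbind(c(10, 10, 10, 8, 9), c(12, 12, 12, 10, 11),
             c(30, 30, 30, 28, 29))
  colnames(x) <- paste0("DAT", 19:23)
  rownames(x) <- c("G01", "G02", "G03")
  p <- fcm(x, 2, seed = 1)
  tc <- typicalCurves(p)
  a <- tc[tc$cluster == "A", ]             # the big singleton
  b <- tc[tc$cluster == "B", ]
  expect_equal(a$mean, c(30, 30, 30, 28, 29))   # one member: identity
  expect_equal(b$mean, c(11, 11, 11, 9, 10))    # two members: arithmetic mean
  expect_equal(unique(tc$dat), 19:23)
  expect_classed_error(typicalCurves(p, window = 24:28), "growthdyn_off_grid")
})

test_that("group-specific peak days show up in the typical curves", {
  cfg <- simulationConfig(
    seed = 3L, noiseCV = 0, linkNoiseCV = 0,
    groupParams = list(A = list(K = 12000, r = 0.40, t0 = 17.5),
                       B = list(K = 7000, r = 0.60, t0 = 18.6)),
    dispersions = list(Kcv = 0.05, rSd = 0.005, t0Sd = 0.1),
    stress = list(onsetDat = 9, troughDat = 22,
                  deltaMean = c(A = 0.55, B = 0.48), deltaSd = 0,
                  rampExponent = 3, gammaMean = 0.03, gammaSd = 0))
  tb <- simulateExperiment(cfg, traits = "EBv")
  prof <- wideMatrix(genotypeMeans(tb, "EBv"), "W")
  p <- fcm(prof, 2, seed = 1)
  tc <- typicalCurves(p)
  peak <- vapply(split(tc, tc$cluster), function(s) s$dat[which.max(s$mean)],
                 0L)
  expect_equal(peak[["A"]], 20L)
  expect_equal(peak[["B"]], 21L)
})

test_that("differential profile separates shifted clusters and ignores
           within-cluster labeling", {
  cfg <- simulationConfig(seed = 8L)
  tb <- simulateExperiment(cfg, traits = "EBv")
  prof <- wideMatrix(genotypeMeans(tb, "EBv"), "W")
  p <- fcm(prof, 2, seed = 1)
  dp <- clusterDiffProfile(p, tb, "EBv", "W")
  expect_equal(dp$dat, datGrid(tb))
  expect_equal(dp$negLog10P, -log10(dp$p))
  ## the two latent size groups differ strongly on every day
  expect_gt(min(dp$negLog10P), 3)
  ## permuting profiles within clusters leaves the profile unchanged
  set.seed(2)
  ord <- c(sample(which(hardLabels(p) == 1L)), sample(which(hardLabels(p) == 2L)))
  p2 <- fcm(prof[ord, ], 2, seed = 1)
  dp2 <- clusterDiffProfile(p2, tb, "EBv", "W")
  expect_equal(dp2$negLog10P, dp$negLog10P, tolerance = 1e-8)
  expect_classed_error(clusterDiffProfile(fcm(prof, 3, seed = 1), tb, "EBv", "W"),
                       "growthdyn_invalid_config")
})
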