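times8 <- c(1:4, 6:9)     # gapped grid: true distances matter

test_that("covariance builders honor their parameterizations and distances", {
  un <- covarianceMatrix("UN", c(sigma2 = 2, rho = 0.4), times8)
  expect_equal(diag(un), rep(2, 8))
  expect_equal(un[1, 5], 0.8)                     # same covariance at any lag
  pw <- covarianceMatrix("POWER", c(sigma2 = 1, rho = 0.8), c(1, 3))
  expect_equal(pw[1, 2], 0.8^2)                   # gap counts as distance 2
  hp <- covarianceMatrix("HETPOWER",
                         c(sigma1 = 1, sigma2 = 2, sigma3 = 3, rho = 0.5),
                         1:3)
  expect_equal(diag(hp), c(1, 4, 9), ignore_attr = TRUE)
  expect_equal(hp[1, 3], 1 * 3 * 0.25)
  an <- covarianceMatrix("ANTE", c(sigma1 = 1, sigma2 = 2, sigma3 = 1,
                                   rho1 = 0.9, rho2 = 0.5), 1:3)
  expect_equal(an[1, 3], 1 * 1 * 0.9 * 0.5)       # lagged = product of adjacents
  ## all five are symmetric positive definite for admissible parameters
  for (S in list(un, covarianceMatrix("POWER", c(sigma2 = 1, rho = -0.6), times8),
                 covarianceMatrix("HETPOWER",
                                  c(stats::setNames(1:8 / 2, paste0("sigma", 1:8)),
                                    rho = 0.7), times8),
                 covarianceMatrix("ANTE",
                                  c(stats::setNames(rep(1.5, 8), paste0("sigma", 1:8)),
                                    stats::setNames(rep(c(0.3, 0.9), len = 7),
                                                    paste0("rho", 1:7))), times8))) {
    expect_true(isSymmetric(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("unstructured ML fit is the sample covariance with its closed-form
           likelihood", {
  Sig <- diag(8) + 0.5
  Y <- simulateRepeatedMeasures(60, Sig, seed = 2)
  f <- fitCovarianceStructure(Y, times8, "US")
  S <- crossprod(sweep(Y, 2, colMeans(Y))) / 60
  expect_equal(fittedCovariance(f), S, tolerance = 1e-10, ignore_attr = TRUE)
  llClosed <- -60 / 2 * (8 * log(2 * pi) + determinant(S)$modulus[1] + 8)
  expect_equal(f@logLik, llClosed, tolerance = 1e-8)
  expect_equal(f@nParams, 36L)
})

test_that("antedependence matches sample variances and adjacent correlations", {
  Sig <- covarianceMatrix("ANTE",
                          c(stats::setNames(seq(1, 2.4, by = 0.2), paste0("sigma", 1:8)),
                            stats::setNames(rep(c(0.4, 0.85), len = 7),
                                            paste0("rho", 1:7))), times8)
  Y <- simulateRepeatedMeasures(80, Sig, seed = 3)
  f <- fitCovarianceStructure(Y, times8, "ANTE")
  S <- crossprod(sweep(Y, 2, colMeans(Y))) / 80
  expect_equal(diag(fittedCovariance(f)), diag(S), tolerance = 1e-10,
               ignore_attr = TRUE)
  R <- stats::cov2cor(S)
  Rf <- stats::cov2cor(fittedCovariance(f))
  expect_equal(diag(Rf[-8, -1]), diag(R[-8, -1]), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(f@nParams, 15L)
})

test_that("equal-parameter antedependence collapses to power: likelihoods
           coincide when the sample covariance is exactly a power matrix", {
  P <- covarianceMatrix("POWER", c(sigma2 = 1.3, rho = 0.75), 1:8)
  Y <- simulateRepeatedMeasures(120, P, seed = 4)
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(Yc) / 120
  Y2 <- Yc %*% t(t(chol(P)) %*% solve(t(chol(S))))   # force S == P exactly
  fits <- fitAllCovarianceStructures(Y2, 1:8)
  expect_equal(fits$ANTE@logLik, fits$POWER@logLik, tolerance = 1e-6)
  expect_equal(fits$US@logLik, fits$POWER@logLik, tolerance = 1e-6)
  ## the 2-parameter power model wins on BIC
  expect_equal(selectStructureBIC(fits)$structure, "POWER")
})

test_that("the saturated model bounds every structured likelihood", {
  set.seed(5)
  for (i in 1:5) {
    Y <- matrix(rnorm(50 * 8), 50) %*% matrix(runif(64, -0.3, 0.7), 8)
    fits <- suppressWarnings(fitAllCovarianceStructures(Y, times8))
    for (s in c("UN", "POWER", "HETPOWER", "ANTE"))
      expect_lte(fits[[s]]@logLik, fits$US@logLik + 1e-6)
  }
})

test_that("likelihoods agree with the mixed-model reference implementation", {
  skip_if_not_installed("nlme")
  P <- covarianceMatrix("POWER", c(sigma2 = 1, rho = 0.8), times8)
  Y <- simulateRepeatedMeasures(50, P, seed = 6)
  df <- data.frame(y = as.vector(t(Y)), time = rep(times8, 50),
                   id = rep(seq_len(50), each = 8))
  g <- nlme::gls(y ~ factor(time), data = df,
                 correlation = nlme::corCAR1(form = ~ time | id),
                 method = "ML")
  f <- fitCovarianceStructure(Y, times8, "POWER")
  expect_equal(f@logLik, as.numeric(stats::logLik(g)), tolerance = 1e-4)

  H <- covarianceMatrix("HETPOWER",
                        c(stats::setNames(seq(0.8, 2.2, len = 8), paste0("sigma", 1:8)),
                          rho = 0.7), times8)
  Yh <- simulateRepeatedMeasures(50, H, seed = 7)
  dfh <- data.frame(y = as.vector(t(Yh)), time = rep(times8, 50),
                    id = rep(seq_len(50), each = 8))
  gh <- nlme::gls(y ~ factor(time), data = dfh,
                  correlation = nlme::corCAR1(form = ~ time | id),
                  weights = nlme::varIdent(form = ~ 1 | factor(time)),
                  method = "ML")
  fh <- fitCovarianceStructure(Yh, times8, "HETPOWER")
  expect_equal(fh@logLik, as.numeric(stats::logLik(gh)), tolerance = 1e-3)
})

test_that("BIC ordering is location-invariant and picks the smallest value", {
  P <- covarianceMatrix("POWER", c(sigma2 = 1, rho = 0.6), times8)
  Y <- simulateRepeatedMeasures(40, P, seed = 8)
  f1 <- fitAllCovarianceStructures(Y, times8, c("UN", "POWER", "ANTE"))
  f2 <- fitAllCovarianceStructures(Y + 100, times8, c("UN", "POWER", "ANTE"))
  b1 <- vapply(f1, bicValue, 0)
  b2 <- vapply(f2, bicValue, 0)
  expect_equal(b1, b2, tolerance = 1e-6)
  sel <- selectStructureBIC(f1)
  expect_equal(sel$structure, sel$table$structure[1])
  expect_equal(min(sel$table$bic), bicValue(sel$best))
  ## advisory when parameters rival subjects
  expect_warning(fitCovarianceStructure(Y[1:10, ], times8, "US"),
                 "estimates unreliable")
})
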