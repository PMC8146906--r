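COV_STRUCTURES <- c("UN", "POWER", "HETPOWER", "ANTE", "US")

## rho^d for integer day distances, valid for rho in (-1, 1)
powRho <- function(rho, D) {
  out <- sign(rho)^D * abs(rho)^D
  out[D == 0] <- 1
  out
}

#' Build a repeated-measures covariance matrix
#'
#' Parameterizations of the five structures, using actual day distances
#' (a lost imaging day yields a distance of 2, not 1):
#' \itemize{
#'   \item `UN` (uniform / compound symmetry): `sigma2 [(1-rho) I + rho J]`,
#'     2 parameters. Note: in this menu "UN" is uniform, not the common
#'     "unstructured" abbreviation.
#'   \item `POWER`: `sigma2 * rho^|t_i - t_j|`, 2 parameters.
#'   \item `HETPOWER`: `sigma_i sigma_j rho^|t_i - t_j|`, T + 1 parameters.
#'   \item `ANTE` (first-order antedependence):
#'     `sigma_i sigma_j prod_{k=i}^{j-1} rho_k`, 2T - 1 parameters.
#'   \item `US` (unstructured): any symmetric positive definite matrix,
#'     T(T+1)/2 parameters (supply the lower triangle row-wise).
#' }
#'
#' @param structure one of `"UN"`, `"POWER"`, `"HETPOWER"`, `"ANTE"`,
#'   `"US"`.
#' @param params named numeric parameter vector (see details).
#' @param times numeric measurement days.
#' @return T x T covariance matrix.
#' @export
covarianceMatrix <- function(structure, params, times) {
  structure <- match.arg(structure, COV_STRUCTURES)
  T <- length(times)
  D <- abs(outer(times, times, "-"))
  switch(structure,
    UN = {
      s2 <- params[["sigma2"]]; rho <- params[["rho"]]
      s2 * ((1 - rho) * diag(T) + rho * matrix(1, T, T))
    },
    POWER = {
      params[["sigma2"]] * powRho(params[["rho"]], D)
    },
    HETPOWER = {
      sig <- params[paste0("sigma", seq_len(T))]
      outer(sig, sig) * powRho(params[["rho"]], D)
    },
    ANTE = {
      sig <- params[paste0("sigma", seq_len(T))]
      rho <- params[paste0("rho", seq_len(T - 1))]
      R <- diag(T)
      for (i in seq_len(T - 1)) for (j in (i + 1):T)
        R[i, j] <- R[j, i] <- prod(rho[i:(j - 1)])
      outer(sig, sig) * R
    },
    US = {
      M <- matrix(0, T, T)
      M[lower.tri(M, diag = TRUE)] <- params
      M[upper.tri(M)] <- t(M)[upper.tri(M)]
      M
    })
}

covNParams <- function(structure, T)
  switch(structure, UN = 2L, POWER = 2L, HETPOWER = T + 1L,
         ANTE = 2L * T - 1L, US = as.integer(T * (T + 1L) / 2L))

## Gaussian log-likelihood of Y (n x T) with saturated per-time means and
## covariance sigma; S is the ML (divisor n) sample covariance.
gaussLogLik <- function(n, T, S, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  ldet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  -n / 2 * (T * log(2 * pi) + ldet + tr)
}

#' CovarianceFit: one fitted repeated-measures covariance model
#'
#' @slot structure structure name.
#' @slot params named ML parameter estimates.
#' @slot sigma fitted T x T covariance matrix (symmetric positive
#'   definite).
#' @slot logLik maximized Gaussian log-likelihood (saturated per-time
#'   means).
#' @slot nParams number of covariance parameters.
#' @slot nSubjects number of subject rows.
#' @slot times measurement days.
#' @slot bic `-2 logLik + nParams log(nSubjects)`.
#' @slot convergence 0 for success (optimizer status otherwise).
#' @export
setClass("CovarianceFit",
  representation(structure = "character", params = "numeric",
                 sigma = "matrix", logLik = "numeric", nParams = "integer",
                 nSubjects = "integer", times = "numeric", bic = "numeric",
                 convergence = "integer"),
  validity = function(object) {
    if (!object@structure %in% COV_STRUCTURES)
      return("unknown covariance structure")
    if (!isSymmetric(object@sigma, tol = 1e-8))
      return("fitted covariance must be symmetric")
    ev <- eigen(object@sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return("fitted covariance must be positive definite")
    if (object@nParams != covNParams(object@structure, length(object@times)))
      return("nParams inconsistent with structure")
    TRUE
  }
)

setMethod("show", "CovarianceFit", function(object) {
  cat(sprintf("CovarianceFit %s: T = %d, n = %d, logLik = %.3f, BIC = %.3f%s\n",
              object@structure, length(object@times), object@nSubjects,
              object@logLik, object@bic,
              if (object@convergence != 0L) " (NOT converged)" else ""))
})

#' @rdname datGrid
#' @export
bicValue <- function(x) x@bic

#' @rdname datGrid
#' @export
fittedCovariance <- function(x) x@sigma

#' Fit one covariance structure to repeated measures by ML
#'
#' Maximizes the Gaussian log-likelihood of a subjects-by-times response
#' matrix under a saturated mean (one mean per time point) and the chosen
#' covariance structure (see [covarianceMatrix()]). `US` and `ANTE` have
#' closed-form ML solutions (the sample covariance with divisor n, and
#' matching the sample variances and adjacent-day correlations,
#' respectively); the others are optimized numerically with variance
#' parameters on the log scale and correlations through bounded links,
#' so every proposal is positive definite by construction. BIC uses the
#' number of subjects as the sample size:
#' `BIC = -2 logLik + nParams log(n)`.
#'
#' @param Y n x T numeric matrix (subjects x measurement days).
#' @param times numeric measurement days (actual day values; gaps count
#'   as true distances).
#' @param structure one of `"UN"`, `"POWER"`, `"HETPOWER"`, `"ANTE"`,
#'   `"US"`.
#' @return A [CovarianceFit-class].
#' @export
fitCovarianceStructure <- function(Y, times,
                                   structure = c("UN", "POWER", "HETPOWER",
                                                 "ANTE", "US")) {
  structure <- match.arg(structure)
  Y <- as.matrix(Y)
  T <- ncol(Y)
  n <- nrow(Y)
  stopifnot(length(times) == T, T >= 2)
  nPar <- covNParams(structure, T)
  if (n <= nPar)
    warning(sprintf("%s has %d parameters but only %d subjects; estimates unreliable",
                    structure, nPar, n))
  ctr <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(ctr) / n
  Rcor <- stats::cov2cor(S)
  D <- abs(outer(times, times, "-"))

  finish <- function(params, sigma, convergence = 0L) {
    ll <- gaussLogLik(n, T, S, sigma)
    new("CovarianceFit", structure = structure, params = params,
        sigma = sigma, logLik = ll, nParams = nPar, nSubjects = as.integer(n),
        times = as.numeric(times), bic = -2 * ll + nPar * log(n),
        convergence = as.integer(convergence))
  }

  if (structure == "US") {
    params <- S[lower.tri(S, diag = TRUE)]
    names(params) <- paste0("s", which(lower.tri(S, diag = TRUE)))
    return(finish(params, S))
  }
  if (structure == "ANTE") {
    sig <- sqrt(diag(S))
    rho <- diag(Rcor[-T, -1, drop = FALSE])
    params <- c(stats::setNames(sig, paste0("sigma", 1:T)),
                stats::setNames(rho, paste0("rho", seq_len(T - 1))))
    return(finish(params, covarianceMatrix("ANTE", params, times)))
  }

  ## numerically optimized structures
  adj <- D > 0 & D == min(D[D > 0])      # adjacent (closest-spaced) pairs
  r1 <- mean(Rcor[adj])
  rho0 <- max(min(sign(r1) * abs(r1)^(1 / min(D[D > 0])), 0.95), -0.95)
  bounds <- if (structure == "UN") c(-1 / (T - 1) + 1e-6, 1 - 1e-6)
            else c(-1 + 1e-6, 1 - 1e-6)
  toRho <- function(z) bounds[1] + (bounds[2] - bounds[1]) * stats::plogis(z)
  fromRho <- function(r) stats::qlogis(
    (max(min(r, bounds[2] - 1e-8), bounds[1] + 1e-8) - bounds[1]) /
      (bounds[2] - bounds[1]))
  unpack <- switch(structure,
    UN = function(p) c(sigma2 = exp(p[1]), rho = toRho(p[2])),
    POWER = function(p) c(sigma2 = exp(p[1]), rho = toRho(p[2])),
    HETPOWER = function(p) {
      out <- c(exp(p[1:T]), toRho(p[T + 1]))
      names(out) <- c(paste0("sigma", 1:T), "rho")
      out
    })
  init <- switch(structure,
    UN = c(log(mean(diag(S))), fromRho(mean(Rcor[upper.tri(Rcor)]))),
    POWER = c(log(mean(diag(S))), fromRho(rho0)),
    HETPOWER = c(log(sqrt(diag(S))), fromRho(rho0)))
  nll <- function(p) {
    sigma <- covarianceMatrix(structure, unpack(p), times)
    ll <- gaussLogLik(n, T, S, sigma)
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt <- stats::optim(opt$par, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  params <- unpack(opt$par)
  finish(params, covarianceMatrix(structure, params, times), opt$convergence)
}

#' Fit all five covariance structures
#'
#' @inheritParams fitCovarianceStructure
#' @param structures subset of structures to fit (default all five).
#' @return Named list of [CovarianceFit-class] objects.
#' @export
fitAllCovarianceStructures <- function(Y, times, structures = COV_STRUCTURES) {
  stats::setNames(lapply(structures, function(s)
    fitCovarianceStructure(Y, times, s)), structures)
}

#' Select the best-fitting covariance structure by BIC
#'
#' Lower BIC is better. Non-converged fits are excluded.
#'
#' @param fits list of [CovarianceFit-class] objects on identical data.
#' @return list with `best` (the winning fit), `structure` (its name) and
#'   `table` (data.frame of structure, logLik, nParams, BIC,
#'   convergence, sorted by BIC).
#' @export
selectStructureBIC <- function(fits) {
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(structure = f@structure, logLik = f@logLik,
               nParams = f@nParams, bic = f@bic,
               convergence = f@convergence)))
  rownames(tab) <- NULL
  ok <- tab$convergence == 0L & is.finite(tab$bic)
  if (sum(ok) < 1)
    stop(gdCondition("growthdyn_no_fit", "no converged covariance fit"))
  okFits <- fits[ok]
  best <- okFits[[which.min(vapply(okFits, function(f) f@bic, 0))]]
  tab <- tab[order(tab$bic), ]
  rownames(tab) <- NULL
  list(best = best, structure = best@structure, table = tab)
}

#' Simulate Gaussian repeated measures
#'
#' Draws n subject rows from a multivariate normal with the given
#' covariance (and optional per-time means); used by the
#' selection-consistency and parameter-recovery simulations.
#'
#' @param n number of subjects.
#' @param sigma T x T covariance matrix.
#' @param mean per-time mean vector (default 0).
#' @param seed optional RNG seed.
#' @return n x T matrix.
#' @export
simulateRepeatedMeasures <- function(n, sigma, mean = rep(0, ncol(sigma)),
                                     seed = NULL) {
  draw <- function() MASS::mvrnorm(n, mu = mean, Sigma = sigma)
  if (is.null(seed)) draw() else withSimSeed(seed, draw())
}
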