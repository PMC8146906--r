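#' FuzzyPartition: result of fuzzy c-means clustering
#'
#' @slot profiles the clustered n x T profile matrix (rows are profiles,
#'   e.g. genotype-mean trajectories).
#' @slot membership n x c matrix of memberships in [0,1]; rows sum to 1.
#' @slot centers c x T cluster-center matrix, rows ordered by descending
#'   mean level so cluster 1 ("A") is the largest-biomass cluster.
#' @slot objective the fuzzy within-cluster objective
#'   `sum_i sum_k u_ik^m ||x_i - v_k||^2` at convergence.
#' @slot m fuzzifier (> 1).
#' @slot hardLabels integer argmax-membership label per profile.
#' @slot seed,restarts the RNG seed and number of random restarts used.
#' @slot objectiveTrace per-iteration objective of the winning restart
#'   (non-increasing).
#' @slot iterations iterations used by the winning restart.
#' @slot flagged character notes (e.g. duplicate profiles).
#' @export
setClass("FuzzyPartition",
  representation(profiles = "matrix", membership = "matrix",
                 centers = "matrix", objective = "numeric", m = "numeric",
                 hardLabels = "integer", seed = "integer",
                 restarts = "integer", objectiveTrace = "numeric",
                 iterations = "integer", flagged = "character"),
  validity = function(object) {
    U <- object@membership
    if (any(abs(rowSums(U) - 1) > 1e-9))
      return("membership rows must sum to 1 (tol 1e-9)")
    if (any(U < -1e-12 | U > 1 + 1e-12))
      return("memberships must lie in [0, 1]")
    if (!identical(object@hardLabels, as.integer(max.col(U, "first"))))
      return("hardLabels inconsistent with membership argmax")
    d2 <- profileDistances(object@profiles, object@centers)
    obj <- sum(U^object@m * d2)
    if (abs(obj - object@objective) > 1e-8 * max(1, abs(obj)))
      return("stored objective does not match recomputation")
    TRUE
  }
)

setMethod("show", "FuzzyPartition", function(object) {
  cat(sprintf("FuzzyPartition: %d profiles, c = %d, m = %g, objective = %.6g\n",
              nrow(object@membership), ncol(object@membership), object@m,
              object@objective))
  cat("  hard cluster sizes:",
      paste(sprintf("%s=%d", LETTERS[seq_len(ncol(object@membership))],
                    tabulate(object@hardLabels, ncol(object@membership))),
            collapse = ", "), "\n")
})

#' @rdname datGrid
#' @export
hardLabels <- function(x) x@hardLabels

#' @rdname datGrid
#' @export
clusterLabels <- function(x)
  stats::setNames(LETTERS[x@hardLabels], rownames(x@profiles))

#' @rdname datGrid
#' @export
membershipMatrix <- function(x) x@membership

#' @rdname datGrid
#' @export
clusterCenters <- function(x) x@centers

## squared Euclidean distances between profile rows and center rows
profileDistances <- function(x, v) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(v))) - 2 * x %*% t(v) +
    outer(rep(1, nrow(x)), rowSums(v^2))
  pmax(d2, 0)
}

fcmMembership <- function(d2, m) {
  n <- nrow(d2)
  expo <- 1 / (m - 1)
  U <- matrix(0, n, ncol(d2))
  zero <- d2 <= .Machine$double.eps
  hasZero <- rowSums(zero) > 0
  if (any(hasZero))            # coincident with a center: crisp membership
    U[hasZero, ] <- zero[hasZero, , drop = FALSE] /
      rowSums(zero[hasZero, , drop = FALSE])
  if (any(!hasZero)) {
    w <- d2[!hasZero, , drop = FALSE]^(-expo)
    U[!hasZero, ] <- w / rowSums(w)
  }
  U
}

fcmOnce <- function(x, c, m, tol, maxIter) {
  n <- nrow(x)
  U <- matrix(stats::rexp(n * c), n, c)
  U <- U / rowSums(U)
  trace <- numeric(0)
  V <- NULL
  for (it in seq_len(maxIter)) {
    Um <- U^m
    den <- colSums(Um)
    Vnew <- (t(Um) %*% x) / den
    ## a cluster abandoned by every profile keeps its previous center
    if (any(den < 1e-300))
      Vnew[den < 1e-300, ] <- if (is.null(V)) x[sample(nrow(x), sum(den < 1e-300)), , drop = FALSE]
                              else V[den < 1e-300, , drop = FALSE]
    V <- Vnew
    d2 <- profileDistances(x, V)
    Unew <- fcmMembership(d2, m)
    trace <- c(trace, sum(Unew^m * d2))
    delta <- max(abs(Unew - U))
    U <- Unew
    if (delta < tol) break
  }
  list(U = U, V = V, objective = trace[length(trace)], trace = trace,
       iterations = it)
}

#' Fuzzy c-means clustering of temporal profiles
#'
#' Standard alternating optimization of the fuzzy objective
#' `J = sum_i sum_k u_ik^m ||x_i - v_k||^2`: centers
#' `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`, memberships
#' `u_ik = 1 / sum_j (||x_i - v_k|| / ||x_i - v_j||)^{2/(m-1)}`.
#' Memberships are initialized from a uniform Dirichlet; the best of
#' `restarts` seeded restarts (lowest objective) is returned, with
#' cluster labels canonicalized by descending mean center level
#' (cluster 1 = "A" = larger profiles). A profile coinciding with a
#' center receives membership 1 on that center. Iteration stops when the
#' maximum absolute membership change drops below `tol`.
#'
#' @param x n x T numeric profile matrix (no missing cells).
#' @param c number of clusters, `1 <= c <= n`.
#' @param m fuzzifier, > 1 (default 2).
#' @param seed RNG seed for the restarts (default 1).
#' @param restarts number of random restarts (default 20).
#' @param tol membership-change convergence tolerance.
#' @param maxIter iteration cap per restart.
#' @return A [FuzzyPartition-class].
#' @export
fcm <- function(x, c, m = 2, seed = 1L, restarts = 20L, tol = 1e-6,
                maxIter = 500L) {
  x <- as.matrix(x)
  if (anyNA(x))
    stop(gdCondition("growthdyn_missing_cells",
                     "profiles contain missing cells; handle gaps upstream"))
  n <- nrow(x)
  if (n < c)
    stop(gdCondition("growthdyn_too_few",
                     sprintf("need at least c = %d profiles, got %d", c, n)))
  if (m <= 1) stop(gdCondition("growthdyn_invalid_config", "fuzzifier m must be > 1"))
  flagged <- character()
  nDistinct <- nrow(unique(x))
  if (nDistinct < c)
    flagged <- c(flagged, sprintf(
      "only %d distinct profiles for c = %d clusters; memberships will split",
      nDistinct, c))
  if (c == 1L) {
    V <- matrix(colMeans(x), 1, ncol(x), dimnames = list(NULL, colnames(x)))
    d2 <- profileDistances(x, V)
    U <- matrix(1, n, 1)
    return(new("FuzzyPartition", profiles = x, membership = U, centers = V,
               objective = sum(d2), m = m,
               hardLabels = rep(1L, n), seed = as.integer(seed),
               restarts = 1L, objectiveTrace = sum(d2), iterations = 1L,
               flagged = flagged))
  }
  best <- withSimSeed(seed, {
    res <- NULL
    for (s in seq_len(restarts)) {
      cand <- fcmOnce(x, c, m, tol, maxIter)
      if (is.null(res) || cand$objective < res$objective) res <- cand
    }
    res
  })
  ## canonical order: descending mean center level ("A" = biggest biomass)
  ord <- order(rowMeans(best$V), decreasing = TRUE)
  V <- best$V[ord, , drop = FALSE]
  U <- best$U[, ord, drop = FALSE]
  dimnames(V) <- list(LETTERS[seq_len(c)], colnames(x))
  dimnames(U) <- list(rownames(x), LETTERS[seq_len(c)])
  new("FuzzyPartition", profiles = x, membership = U, centers = V,
      objective = best$objective, m = m,
      hardLabels = as.integer(max.col(U, "first")), seed = as.integer(seed),
      restarts = as.integer(restarts), objectiveTrace = best$trace,
      iterations = as.integer(best$iterations), flagged = flagged)
}

#' Cluster-validity indices of a fuzzy partition
#'
#' The six indices behind the majority rule, with their optimum
#' conventions: partition coefficient (PC, max), modified partition
#' coefficient (MPC, max), partition entropy (PE, min), Xie-Beni (XB,
#' min), Fukuyama-Sugeno (FS, min), and fuzzy silhouette (FSIL, max; the
#' crisp silhouette of each profile weighted by the margin between its
#' two largest memberships).
#'
#' @param partition a [FuzzyPartition-class].
#' @return Named numeric vector `c(pc, mpc, pe, xb, fs, fsil)`.
#' @export
validityIndices <- function(partition) {
  U <- partition@membership
  V <- partition@centers
  x <- partition@profiles
  m <- partition@m
  n <- nrow(U)
  c <- ncol(U)
  d2 <- profileDistances(x, V)
  pc <- sum(U^2) / n
  mpc <- if (c > 1) 1 - c / (c - 1) * (1 - pc) else NA_real_
  pe <- -sum(ifelse(U > 0, U * log(U), 0)) / n
  sep <- if (c > 1) min(profileDistances(V, V)[upper.tri(diag(c))]) else NA_real_
  xb <- sum(U^m * d2) / (n * sep)
  vbar <- colMeans(x)
  fs <- sum(U^m * (d2 - matrix(rowSums(sweep(V, 2, vbar)^2), n, c,
                               byrow = TRUE)))
  fsil <- fuzzySilhouette(x, U, partition@hardLabels)
  c(pc = pc, mpc = mpc, pe = pe, xb = xb, fs = fs, fsil = fsil)
}

fuzzySilhouette <- function(x, U, labels, alpha = 1) {
  n <- nrow(x)
  c <- ncol(U)
  if (c < 2) return(NA_real_)
  D <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(D[i, own]) else NA_real_
    b <- Inf
    for (k in seq_len(c)[-labels[i]]) {
      other <- labels == k
      if (any(other)) b <- min(b, mean(D[i, other]))
    }
    s[i] <- if (is.na(a) || !is.finite(b)) 0 else (b - a) / max(a, b)
  }
  sortU <- apply(U, 1, function(u) sort(u, decreasing = TRUE)[1:2])
  w <- (sortU[1, ] - sortU[2, ])^alpha
  if (sum(w) == 0) return(0)
  sum(w * s) / sum(w)
}

#' ValidityReport: majority-rule selection of the cluster number
#'
#' @slot cValues candidate cluster numbers.
#' @slot indexValues matrix of index values (candidates x indices).
#' @slot votes named integer vector: the candidate each index voted for.
#' @slot selectedC the majority winner (ties broken toward smaller c).
#' @slot partitions list of the fitted [FuzzyPartition-class] objects,
#'   named by candidate c.
#' @export
setClass("ValidityReport",
  representation(cValues = "integer", indexValues = "matrix",
                 votes = "integer", selectedC = "integer",
                 partitions = "list"))

setMethod("show", "ValidityReport", function(object) {
  cat(sprintf("ValidityReport: candidates c = %s; selected c = %d\n",
              paste(object@cValues, collapse = ", "), object@selectedC))
  cat("  votes:", paste(sprintf("%s->%d", names(object@votes), object@votes),
                        collapse = ", "), "\n")
})

#' @rdname datGrid
#' @export
selectedC <- function(x) x@selectedC

#' @rdname datGrid
#' @export
selectedPartition <- function(x) x@partitions[[as.character(x@selectedC)]]

#' Majority-rule selection of the number of clusters
#'
#' Runs [fcm()] for each candidate c, computes the six validity indices,
#' lets each index vote for its optimal candidate (by its own max/min
#' convention), and selects the candidate with the most votes, breaking
#' ties toward the smallest c (parsimony). Candidates producing a
#' degenerate partition (an empty hard cluster) are excluded from voting
#' with a warning.
#'
#' @inheritParams fcm
#' @param cRange candidate cluster numbers (default 2:6), within
#'   `[2, n - 1]`.
#' @return A [ValidityReport-class].
#' @export
selectCMajority <- function(x, cRange = 2:6, m = 2, seed = 1L,
                            restarts = 20L, tol = 1e-6, maxIter = 500L) {
  x <- as.matrix(x)
  cRange <- sort(unique(as.integer(cRange)))
  if (min(cRange) < 2 || max(cRange) > nrow(x) - 1)
    stop(gdCondition("growthdyn_invalid_config",
                     "cRange must lie within [2, n - 1]"))
  parts <- list()
  vals <- matrix(NA_real_, length(cRange), 6,
                 dimnames = list(as.character(cRange),
                                 c("pc", "mpc", "pe", "xb", "fs", "fsil")))
  ok <- logical(length(cRange))
  for (i in seq_along(cRange)) {
    p <- fcm(x, cRange[i], m = m, seed = seed, restarts = restarts,
             tol = tol, maxIter = maxIter)
    parts[[as.character(cRange[i])]] <- p
    if (min(tabulate(p@hardLabels, cRange[i])) == 0L) {
      warning(sprintf("c = %d produced an empty hard cluster; excluded from voting",
                      cRange[i]))
      next
    }
    ok[i] <- TRUE
    vals[i, ] <- validityIndices(p)
  }
  if (!any(ok))
    stop(gdCondition("growthdyn_degenerate",
                     "all candidate partitions were degenerate"))
  conventions <- c(pc = "max", mpc = "max", pe = "min", xb = "min",
                   fs = "min", fsil = "max")
  votes <- vapply(names(conventions), function(ix) {
    v <- vals[ok, ix]
    cs <- cRange[ok]
    cs[if (conventions[ix] == "max") which.max(v) else which.min(v)]
  }, integer(1))
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  new("ValidityReport", cValues = cRange, indexValues = vals, votes = votes,
      selectedC = min(winners), partitions = parts)
}

#' Typical per-cluster curves around maximum stress
#'
#' The mean polyline of each cluster's hard members over the window from
#' the last pre-stress growth peak to the day after maximum stress
#' (default DAT 19..23), summarizing when each group's biomass turns
#' down and back up.
#'
#' @param partition a [FuzzyPartition-class] whose profiles have `DAT<d>`
#'   column names.
#' @param window integer days of the polyline (default 19:23).
#' @return data.frame with `cluster`, `dat`, `mean`, `n`.
#' @export
typicalCurves <- function(partition, window = 19:23) {
  cols <- paste0("DAT", window)
  off <- setdiff(cols, colnames(partition@profiles))
  if (length(off))
    stop(gdCondition("growthdyn_off_grid", sprintf(
      "window day(s) not in the profiles: %s",
      paste(sub("DAT", "", off), collapse = ", "))))
  c <- ncol(partition@membership)
  out <- list()
  for (k in seq_len(c)) {
    mem <- partition@hardLabels == k
    if (!any(mem))
      stop(gdCondition("growthdyn_degenerate",
                       sprintf("cluster %s has no hard members", LETTERS[k])))
    sub <- partition@profiles[mem, cols, drop = FALSE]
    out[[k]] <- data.frame(cluster = LETTERS[k], dat = window,
                           mean = colMeans(sub), n = sum(mem))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-day differential profile between two clusters
#'
#' For each imaging day, a two-sample Welch t-test compares the genotype
#' means of `trait` between the two hard clusters; the profile is
#' `-log10` of the two-sided p-value per day (values above
#' `-log10(0.05) ~ 1.3` mark days of significant cluster separation).
#'
#' @param partition a [FuzzyPartition-class] with exactly 2 hard clusters,
#'   each with >= 2 members; profile rownames are genotype ids.
#' @param table a [TraitTable-class].
#' @param trait trait to compare.
#' @param treatment treatment in which to compare (defaults to all rows
#'   matching the partition's genotypes).
#' @return data.frame with `dat`, `p`, `negLog10P`.
#' @export
clusterDiffProfile <- function(partition, table, trait, treatment) {
  if (ncol(partition@membership) != 2L)
    stop(gdCondition("growthdyn_invalid_config",
                     "differential profile requires exactly 2 hard clusters"))
  sizes <- tabulate(partition@hardLabels, 2L)
  if (any(sizes < 2L))
    stop(gdCondition("growthdyn_degenerate",
                     "each cluster needs >= 2 hard members"))
  cs <- genotypeMeans(table, trait)
  d <- cs@data[cs@data$treatment == treatment & cs@data$n >= 1, ]
  lab <- stats::setNames(partition@hardLabels, rownames(partition@profiles))
  out <- do.call(rbind, lapply(split(d, d$dat), function(s) {
    g <- lab[s$genotype]
    p <- stats::t.test(s$mean[g == 1L], s$mean[g == 2L])$p.value
    data.frame(dat = s$dat[1], p = p, negLog10P = -log10(p))
  }))
  out <- out[order(out$dat), ]
  rownames(out) <- NULL
  out
}
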