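#' Per-day pairwise treatment comparison with Tukey adjustment
#'
#' Fits the one-day linear model `value ~ treatment + replicate` on the
#' genotype-replicate observations of one imaging day and returns
#' Tukey HSD adjusted p-values (studentized range on the model's
#' residual df) for every treatment pair. Days are tested independently;
#' no adjustment is applied across days.
#'
#' @param table a [TraitTable-class].
#' @param trait trait name.
#' @param dat imaging day.
#' @return data.frame with `pair` (e.g. `"W-C"`), `estimate` (difference
#'   in means), `lwr`, `upr`, `pAdj`.
#' @export
perDayTreatmentTest <- function(table, trait, dat) {
  d <- table@data[table@data$trait == trait & table@data$dat == dat &
                  !is.na(table@data$value), ]
  counts <- table(d$treatment)
  if (length(counts) < 2 || any(counts < 2))
    stop(gdCondition("growthdyn_singular_design", sprintf(
      "need >= 2 treatments with >= 2 observations each at DAT %d", dat)))
  d$treatment <- factor(d$treatment, levels = intersect(TREATMENT_LEVELS,
                                                        names(counts)))
  d$replicate <- factor(d$replicate)
  fit <- stats::aov(value ~ treatment + replicate, data = d)
  tk <- stats::TukeyHSD(fit, which = "treatment")$treatment
  out <- data.frame(pair = rownames(tk), estimate = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    pAdj = tk[, "p adj"])
  rownames(out) <- NULL
  out
}

#' Onset of significance from a per-day p-value series
#'
#' Given adjusted p-values for one contrast along the imaging-day grid,
#' finds all maximal runs of consecutive significant days and reports
#' the onset: the first day starting a run of at least `k` consecutive
#' significant days (a persistence filter against isolated dips). With
#' no qualifying run the onset is `NA`.
#'
#' @param pvals numeric p-values, named by day (or supply `dats`).
#' @param dats integer days matching `pvals`.
#' @param alpha significance level (default 0.05).
#' @param k persistence: minimum run length to declare an onset
#'   (default 1).
#' @return list with `onsetDat` (integer or `NA`), `runs` (data.frame
#'   `startDat`, `endDat`, `length` of all maximal significant runs),
#'   `alpha`, `k`.
#' @export
onsetDetection <- function(pvals, dats = as.integer(names(pvals)),
                           alpha = 0.05, k = 1L) {
  stopifnot(length(pvals) == length(dats))
  ord <- order(dats)
  dats <- dats[ord]
  sig <- !is.na(pvals[ord]) & pvals[ord] <= alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(startDat = dats[starts[r$values]],
                     endDat = dats[ends[r$values]],
                     length = r$lengths[r$values])
  rownames(runs) <- NULL
  qual <- runs$length >= k
  list(onsetDat = if (any(qual)) runs$startDat[which(qual)[1]] else NA_integer_,
       runs = runs, alpha = alpha, k = as.integer(k))
}

#' Onset of a treatment effect along the imaging grid
#'
#' Runs [perDayTreatmentTest()] at every imaging day, extracts the
#' adjusted p-value of one treatment contrast, and applies
#' [onsetDetection()].
#'
#' @param table a [TraitTable-class].
#' @param trait trait name.
#' @param contrast length-2 character vector, e.g. `c("W", "C")`.
#' @inheritParams onsetDetection
#' @return list with `trait`, `contrast`, `pvals` (data.frame `dat`,
#'   `pAdj`), `onsetDat`, `runs`, `alpha`, `k`.
#' @export
onsetSeries <- function(table, trait, contrast = c("W", "C"), alpha = 0.05,
                        k = 1L) {
  stopifnot(length(contrast) == 2)
  keys <- c(paste(contrast, collapse = "-"), paste(rev(contrast), collapse = "-"))
  ps <- vapply(datGrid(table), function(day) {
    tk <- perDayTreatmentTest(table, trait, day)
    hit <- tk$pAdj[tk$pair %in% keys]
    if (!length(hit)) NA_real_ else hit[1]
  }, 0)
  det <- onsetDetection(ps, datGrid(table), alpha, k)
  c(list(trait = trait, contrast = contrast,
         pvals = data.frame(dat = datGrid(table), pAdj = ps)), det)
}

vcShape <- function(dat, vG, vT, vGT, vE) {
  v <- pmax(c(vG, vT, vGT, vE), 0)
  data.frame(dat = dat,
             component = c("genotype", "treatment",
                           "genotype:treatment", "residual"),
             variance = v, percent = 100 * v / sum(v))
}

## Fisher-scoring REML for y = X beta + sum_i u_i, u_i ~ N(0, s2_i Z_i Z_i'),
## with analytic score and information. Nonnegativity by pinning a
## component at zero when its update is drawn negative and its score
## stays negative there (active-set). Converges quadratically, so the
## balanced-case estimates match the ANOVA closed form to machine
## precision when that solution is interior.
remlFisherScoring <- function(y, X, Zlist, tol = 1e-10, maxIter = 100L) {
  n <- length(y)
  k <- length(Zlist) + 1L                # + residual
  ## standardize the response: the score criterion below is calibrated for
  ## unit-scale data (scores carry inverse-variance units), and the
  ## normal equations are better conditioned; estimates scale back by sd^2
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy <= 0)
    stop(gdCondition("growthdyn_singular_design", "response has no variance"))
  y <- y / sdy
  A <- c(lapply(Zlist, tcrossprod), list(diag(n)))
  s2 <- rep(stats::var(y) / k, k)
  pinned <- rep(FALSE, k)
  for (it in seq_len(maxIter)) {
    V <- matrix(0, n, n)
    for (i in seq_len(k)) if (s2[i] > 0) V <- V + s2[i] * A[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch))
      stop(gdCondition("growthdyn_no_fit", "REML iteration produced a singular V"))
    W <- chol2inv(ch)
    WX <- W %*% X
    P <- W - WX %*% solve(crossprod(X, WX), t(WX))
    Py <- P %*% y
    PA <- lapply(A, function(a) P %*% a)
    score <- vapply(seq_len(k), function(i)
      -0.5 * (sum(diag(PA[[i]])) - crossprod(Py, A[[i]] %*% Py)[1]), 0)
    free <- !pinned
    info <- matrix(0, k, k)
    for (i in which(free)) for (j in which(free)) if (j >= i)
      info[i, j] <- info[j, i] <- 0.5 * sum(PA[[i]] * t(PA[[j]]))
    if (max(abs(score[free])) < tol * max(s2[k], 1)) break
    delta <- rep(0, k)
    delta[free] <- solve(info[free, free, drop = FALSE], score[free])
    new <- s2 + delta
    halv <- 0
    while (any(new[free] < 0) && halv < 30) {
      neg <- free & new < 0
      if (all(abs(new[neg]) < 1e-8 * max(s2[k], 1))) break
      delta <- delta / 2
      new <- s2 + delta
      halv <- halv + 1
    }
    hitZero <- free & new <= 0
    new[hitZero] <- 0
    pinned[hitZero & score < 0] <- TRUE
    s2 <- pmax(new, 0)
  }
  s2 * sdy^2
}

#' Per-day REML variance-component decomposition
#'
#' Fits the Gaussian mixed model of one imaging day,
#' `value = replicate (fixed) + genotype + treatment +
#' genotype:treatment + error`, with genotype, treatment, and their
#' interaction as random effects, by REML (Fisher scoring on the REML
#' score equations with analytic information; variances constrained
#' nonnegative by an active set). Percentages are of the total of the
#' four components. For balanced data the estimates coincide with the
#' closed-form expected-mean-squares estimators of
#' [varianceComponentsEMS()] whenever those are nonnegative.
#'
#' @param table a [TraitTable-class].
#' @param trait trait name.
#' @param dat imaging day.
#' @return data.frame with `dat`, `component`, `variance`, `percent`
#'   (percentages sum to 100).
#' @export
varianceComponentsDay <- function(table, trait, dat) {
  d <- table@data[table@data$trait == trait & table@data$dat == dat &
                  !is.na(table@data$value), ]
  if (length(unique(d$genotype)) < 2 || length(unique(d$treatment)) < 2)
    stop(gdCondition("growthdyn_singular_design",
                     "need >= 2 levels of genotype and treatment"))
  tab <- table(d$genotype, d$treatment)
  if (length(unique(as.vector(tab))) != 1L)
    warning("unbalanced genotype x treatment layout; estimates from the iterative algorithm only")
  X <- stats::model.matrix(~ factor(replicate), data = d)
  Zlist <- list(
    genotype = stats::model.matrix(~ 0 + factor(genotype), data = d),
    treatment = stats::model.matrix(~ 0 + factor(treatment), data = d),
    interaction = stats::model.matrix(~ 0 + factor(genotype):factor(treatment),
                                      data = d))
  s2 <- remlFisherScoring(d$value, X, Zlist)
  vcShape(dat, s2[1], s2[2], s2[3], s2[4])
}

#' Closed-form variance components for a balanced layout
#'
#' Moment (expected-mean-squares) estimators from the balanced two-way
#' random ANOVA with a fixed replicate block: with G genotypes, T
#' treatments, R replicates and mean squares from
#' `value ~ replicate + genotype * treatment`,
#' `sigma2_e = MSE`, `sigma2_GT = (MS_GT - MSE) / R`,
#' `sigma2_G = (MS_G - MS_GT) / (R T)`,
#' `sigma2_T = (MS_T - MS_GT) / (R G)`, truncated at zero. Serves as the
#' independent cross-check of the iterative REML fit on balanced data
#' (the two coincide when the moment solution is interior).
#'
#' @inheritParams varianceComponentsDay
#' @return As [varianceComponentsDay()]; attribute `interior` is `TRUE`
#'   when no truncation occurred (REML and EMS must then agree).
#' @export
varianceComponentsEMS <- function(table, trait, dat) {
  d <- table@data[table@data$trait == trait & table@data$dat == dat &
                  !is.na(table@data$value), ]
  tab <- table(d$genotype, d$treatment)
  if (length(unique(as.vector(tab))) != 1L)
    stop(gdCondition("growthdyn_unbalanced",
                     "closed-form estimators require a balanced layout"))
  G <- nrow(tab); T <- ncol(tab); R <- unique(as.vector(tab))
  d$replicate <- factor(d$replicate)
  d$genotype <- factor(d$genotype)
  d$treatment <- factor(d$treatment)
  ms <- summary(stats::aov(value ~ replicate + genotype * treatment,
                           data = d))[[1]][, "Mean Sq"]
  names(ms) <- c("replicate", "genotype", "treatment",
                 "genotype:treatment", "residual")
  vE <- ms[["residual"]]
  vGT <- (ms[["genotype:treatment"]] - vE) / R
  vG <- (ms[["genotype"]] - ms[["genotype:treatment"]]) / (R * T)
  vT <- (ms[["treatment"]] - ms[["genotype:treatment"]]) / (R * G)
  out <- vcShape(dat, vG, vT, vGT, vE)
  attr(out, "interior") <- all(c(vG, vT, vGT, vE) >= 0)
  out
}

#' Variance decomposition across the imaging grid
#'
#' @param table a [TraitTable-class].
#' @param trait trait name.
#' @param dats days to decompose (default the full grid).
#' @return data.frame stacking [varianceComponentsDay()] rows.
#' @export
varianceComponentsSeries <- function(table, trait, dats = datGrid(table)) {
  out <- do.call(rbind, lapply(dats, function(day)
    varianceComponentsDay(table, trait, day)))
  rownames(out) <- NULL
  out
}

#' Per-day Pearson correlation between two traits
#'
#' Tracks the correlation between a trait and the biomass proxy (or any
#' trait pair) across genotype means over the imaging grid, together
#' with the two-sided p = 0.05 critical value for the realized n,
#' `r* = t / sqrt(t^2 + n - 2)` with `t` the 0.975 quantile of the
#' t distribution on n - 2 df. Days where either trait is constant are
#' flagged as degenerate with `r = NA`.
#'
#' @param table a [TraitTable-class].
#' @param traitX first trait.
#' @param traitY second trait (default `"EBv"`).
#' @param treatment treatment code.
#' @return data.frame with `dat`, `r`, `n`, `rCrit`, `significant`,
#'   `degenerate`.
#' @export
correlationSeries <- function(table, traitX, traitY = "EBv", treatment) {
  cx <- genotypeMeans(table, traitX)@data
  cy <- genotypeMeans(table, traitY)@data
  cx <- cx[cx$treatment == treatment & cx$n >= 1, ]
  cy <- cy[cy$treatment == treatment & cy$n >= 1, ]
  out <- do.call(rbind, lapply(datGrid(table), function(day) {
    mx <- cx[cx$dat == day, ]
    my <- cy[cy$dat == day, ]
    g <- intersect(mx$genotype, my$genotype)
    n <- length(g)
    if (n < 4)
      stop(gdCondition("growthdyn_too_few", sprintf(
        "need >= 4 genotypes with both traits at DAT %d", day)))
    x <- mx$mean[match(g, mx$genotype)]
    y <- my$mean[match(g, my$genotype)]
    tq <- stats::qt(0.975, n - 2)
    rCrit <- tq / sqrt(tq^2 + n - 2)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(dat = day, r = NA_real_, n = n, rCrit = rCrit,
                        significant = NA, degenerate = TRUE))
    r <- stats::cor(x, y)
    data.frame(dat = day, r = r, n = n, rCrit = rCrit,
               significant = abs(r) >= rCrit, degenerate = FALSE)
  }))
  rownames(out) <- NULL
  out
}
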