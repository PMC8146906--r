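# Shared fixtures, all built in code.

## tiny long table: 1 genotype, 2 treatments, 3 days, values 1..6
toyTable <- function() {
  d <- expand.grid(genotype = "G01", treatment = c("C", "W"),
                   replicate = 1L, dat = c(2L, 3L, 4L), trait = "EBv",
                   stringsAsFactors = FALSE)
  d <- d[order(d$treatment, d$dat), ]
  d$value <- 1:6
  traitTable(d, grid = c(2L, 3L, 4L))
}

## balanced one-day layout with known variance components
balancedDayTable <- function(seed, sG = 5, sT = 2, sGT = 3, sE = 4,
                             G = 20, Tn = 4, R = 8) {
  set.seed(seed)
  trt <- c("C", "N", "W", "NW")[seq_len(Tn)]
  g <- rnorm(G, 0, sG); t <- rnorm(Tn, 0, sT); gt <- rnorm(G * Tn, 0, sGT)
  repEff <- rnorm(R, 0, 1)
  d <- expand.grid(genotype = sprintf("G%02d", 1:G), treatment = trt,
                   replicate = 1:R, dat = 10L, trait = "EBv",
                   stringsAsFactors = FALSE)
  gi <- match(d$genotype, sprintf("G%02d", 1:G))
  ti <- match(d$treatment, trt)
  d$value <- 100 + g[gi] + t[ti] + gt[(gi - 1) * Tn + ti] +
    repEff[d$replicate] + rnorm(nrow(d), 0, sE)
  traitTable(d, grid = 10L)
}

## two well-separated point clouds (spread << separation)
separatedProfiles <- function(seed, nPer = 12, T = 8, gap = 50, spread = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(nPer * T, 0, spread), nPer),
             matrix(rnorm(nPer * T, gap, spread), nPer))
  rownames(x) <- sprintf("P%02d", seq_len(2 * nPer))
  colnames(x) <- paste0("DAT", seq_len(T))
  list(x = x, truth = rep(1:2, each = nPer))
}

## build a TraitTable from per-genotype constant curves (full grid coverage)
curveTable <- function(values, grid = c(2L, 9L, 22L, 23L, 35L),
                       treatments = c("C", "W")) {
  rows <- list()
  for (g in names(values)) for (tr in treatments) {
    v <- values[[g]][[tr]]
    rows[[length(rows) + 1L]] <- data.frame(
      genotype = g, treatment = tr, replicate = 1L, dat = grid,
      trait = "EBv", value = v, stringsAsFactors = FALSE)
  }
  traitTable(do.call(rbind, rows), grid = grid)
}

expect_classed_error <- function(expr, class) {
  expect_error(expr, class = class)
}
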