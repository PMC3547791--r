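## Shared fixtures: tiny hand-built traces and an independent brute-force
## Fisher oracle.

## a trace with constant force along +z and linear end-to-end growth
constantForceTrace <- function(n = 11L, force = 100, dz = 1,
                               direction = c(0, 0, 1)) {
  tt <- seq(0, n - 1L)
  fv <- matrix(rep(force * direction, each = n), n, 3L)
  ee <- cbind(0, 0, tt * dz)
  ForceTrace(tt, fv, ee, params = list(runId = "const"))
}

## quick simulator settings: fewer repeats / shorter pull for cheap tests
quickParams <- function(...) {
  SimParams(nRepeats = 3L, pullDistance = 420, ...)
}

## trace of pure Gaussian noise around a constant force plateau
noiseTrace <- function(n = 2000L, mean = 150, sd = 10) {
  tt <- seq_len(n)
  ForceTrace(tt, cbind(0, 0, mean + stats::rnorm(n, 0, sd)),
             cbind(0, 0, tt * 0.05), params = list(runId = "noise"))
}

## independent Fisher oracle: breadth-first enumeration of all tables with
## the observed margins via expand.grid compositions (no pruning, written
## independently of the package's depth-first implementation)
bruteFisher <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  logC <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N)
  prob <- function(m) exp(logC - sum(lfactorial(m)))
  compositions <- function(total, bounds) {
    g <- as.matrix(do.call(expand.grid, lapply(bounds, function(b) 0:b)))
    g[rowSums(g) == total, , drop = FALSE]
  }
  enumTables <- function(rs, cs) {
    if (length(rs) == 1L) return(list(matrix(cs, 1L)))
    out <- list()
    comps <- compositions(rs[1L], cs)
    for (i in seq_len(nrow(comps))) {
      row <- comps[i, ]
      for (sub in enumTables(rs[-1L], cs - row))
        out[[length(out) + 1L]] <- rbind(row, sub)
    }
    out
  }
  pObs <- prob(tab)
  sum(vapply(enumTables(rs, cs), function(m) {
    pm <- prob(m)
    if (pm <= pObs * (1 + 1e-7)) pm else 0
  }, numeric(1)))
}

## random small contingency table with non-degenerate margins
randomSmallTable <- function(maxTotal = 20L) {
  repeat {
    nr <- sample(2:3, 1L); nc <- sample(2:4, 1L)
    N <- sample(6:maxTotal, 1L)
    m <- matrix(stats::rmultinom(1L, N, rep(1, nr * nc)), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
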