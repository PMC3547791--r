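## Per-repeat RMSD unfolding midpoints, unfolding-order statistics, exact
## Fisher r x c test, and 1-D kernel density estimation.

#' Per-repeat CaCb RMSD from the native structure
#'
#' For each repeat and frame, the repeat's Ca and Cb atoms are optimally
#' superposed (least-squares rotation + translation) onto their native
#' coordinates and the RMSD is computed.  Folded repeats stay below a few A;
#' unfolding produces an abrupt rise to 20 A and beyond when fully
#' extended.
#'
#' @param traj A [PullingTrajectory-class].
#' @param repeatMap A [RepeatMap-class] valid for the trajectory topology.
#' @param native nAtoms x 3 native coordinates on the same topology.
#' @return A list with `time` (frame times, ps) and `rmsd` (nFrames x
#'   nRepeats matrix, A).
#' @export
repeatRMSD <- function(traj, repeatMap, native) {
  topo <- topology(traj)
  if (nrow(native) != nrow(topo@atoms))
    stop("native coordinates do not match the topology", call. = FALSE)
  rr <- repeatRanges(repeatMap)
  nF <- nFrames(traj)
  out <- matrix(NA_real_, nF, nrow(rr))
  colnames(out) <- rr$repeatId
  atoms <- topo@atoms
  for (i in seq_len(nrow(rr))) {
    sel <- which(atoms$resid >= rr$first[i] & atoms$resid <= rr$last[i] &
                 atoms$name %in% c("CA", "CB"))
    if (length(sel) < 3L)
      stop("repeat ", rr$repeatId[i], " has fewer than 3 CaCb atoms",
           call. = FALSE)
    ref <- as.vector(t(native[sel, , drop = FALSE]))
    frames <- t(apply(traj@coords[sel, , , drop = FALSE], 3L,
                      function(m) as.vector(t(m))))
    ## bio3d can warn on sqrt of tiny negative eigenvalues in the
    ## superposition of nearly degenerate (extended) conformers; the RMSD
    ## values themselves are finite
    out[, i] <- suppressWarnings(bio3d::rmsd(ref, frames, fit = TRUE))
    if (any(!is.finite(out[, i])))
      stop("degenerate superposition for repeat ", rr$repeatId[i],
           call. = FALSE)
  }
  list(time = frameTimes(traj), rmsd = out)
}

#' Unfolding midpoints from per-repeat RMSD series
#'
#' The unfolding midpoint of a repeat is the first time its RMSD reaches
#' the threshold (default 10 A), with linear interpolation between frames.
#' Repeats that never cross are flagged as non-unfolded (`NA` midpoint) and
#' excluded from the rank permutation.  Ties across repeats are broken by
#' interpolated time, then repeat index.
#'
#' @param rmsdSeries Output of [repeatRMSD()] (list with `time`, `rmsd`).
#' @param threshold RMSD threshold in A (default 10).
#' @param run Run identifier stored in the output.
#' @return data.frame with one row per repeat: `run`, `repeatId`,
#'   `midpoint` (ps, `NA` if never crossed), `rank` (`NA` if never
#'   crossed), `unfolded`.
#' @export
unfoldingMidpoints <- function(rmsdSeries, threshold = 10, run = "run1") {
  tt <- rmsdSeries$time
  rm <- rmsdSeries$rmsd
  if (is.null(dim(rm)) || length(tt) == 0L)
    stop("empty RMSD series", call. = FALSE)
  nRep <- ncol(rm)
  mid <- rep(NA_real_, nRep)
  for (r in seq_len(nRep)) {
    y <- rm[, r]
    i <- which(y >= threshold)
    if (!length(i)) next
    i <- i[1L]
    if (i == 1L) mid[r] <- tt[1L]
    else mid[r] <- tt[i - 1L] + (tt[i] - tt[i - 1L]) *
        (threshold - y[i - 1L]) / (y[i] - y[i - 1L])
  }
  rk <- rep(NA_integer_, nRep)
  unf <- which(!is.na(mid))
  if (length(unf))
    rk[unf] <- rank(mid[unf], ties.method = "first")
  data.frame(run = run, repeatId = seq_len(nRep), midpoint = mid,
             rank = rk, unfolded = !is.na(mid))
}

#' Contingency table of unfolding order
#'
#' Counts, over runs, how often each repeat unfolds first, second, third
#' and so on.  Rows are repeats, columns are order positions; each row sums
#' to the number of runs in which that repeat unfolded.
#'
#' @param events data.frame of unfolding events pooled over runs, with
#'   columns `run`, `repeatId`, `rank` (as from [unfoldingMidpoints()]).
#' @return Integer matrix nRepeats x nPositions with dimnames
#'   (`r1`..`rR`, `1st`..).
#' @export
orderContingency <- function(events) {
  ev <- events[!is.na(events$rank), ]
  for (runId in unique(ev$run)) {
    rk <- ev$rank[ev$run == runId]
    if (anyDuplicated(rk))
      stop("duplicate ranks in run ", runId, call. = FALSE)
  }
  nRep <- max(events$repeatId)
  nPos <- max(ev$rank)
  tab <- matrix(0L, nRep, nPos,
                dimnames = list(paste0("r", seq_len(nRep)),
                                .ordinalNames(nPos)))
  for (i in seq_len(nrow(ev)))
    tab[ev$repeatId[i], ev$rank[i]] <- tab[ev$repeatId[i], ev$rank[i]] + 1L
  tab
}

.ordinalNames <- function(n) {
  suf <- c("1st", "2nd", "3rd", paste0(4:20, "th"))
  suf[seq_len(n)]
}

#' Condition-versus-position contingency table for one repeat
#'
#' Builds the 2 x nPositions table counting, for a fixed repeat, in how
#' many runs of each condition (e.g. ligand-bound versus free) it occupied
#' each position of the unfolding sequence.
#'
#' @param eventsA,eventsB Event data.frames (as [unfoldingMidpoints()]) for
#'   the two conditions.
#' @param repeatId The repeat to tabulate.
#' @param nPositions Number of order positions (default: largest rank seen).
#' @return 2 x nPositions integer matrix with rows `A`, `B`.
#' @export
conditionContingency <- function(eventsA, eventsB, repeatId,
                                 nPositions = NULL) {
  rkA <- eventsA$rank[eventsA$repeatId == repeatId & !is.na(eventsA$rank)]
  rkB <- eventsB$rank[eventsB$repeatId == repeatId & !is.na(eventsB$rank)]
  if (is.null(nPositions)) nPositions <- max(rkA, rkB)
  tab <- rbind(A = tabulate(rkA, nPositions), B = tabulate(rkB, nPositions))
  colnames(tab) <- .ordinalNames(nPositions)
  tab
}

#' Exact Fisher test for an r x c contingency table
#'
#' Conditional exact test with fixed margins: the p-value is the total
#' multivariate hypergeometric probability of all tables with the observed
#' margins that are no more probable than the observed table.  Tables are
#' enumerated depth-first with margin pruning; beyond `maxTables`
#' enumerated tables (or when `simulate = TRUE`) a seeded Monte-Carlo
#' estimate over `B` tables drawn with [r2dtable()] is returned instead,
#' using the add-one estimator `(1 + #{P(T) <= P(obs)}) / (B + 1)`.
#'
#' @param tab Integer matrix of non-negative counts.
#' @param simulate Force Monte-Carlo mode.
#' @param B Number of Monte-Carlo tables (default 1e5).
#' @param maxTables Enumeration cap before falling back to Monte Carlo.
#' @param seed Optional seed for the Monte-Carlo mode.
#' @return A list with `p`, `method` (`"exact"` or `"monte-carlo"`), and
#'   `nTables` (tables enumerated, or `B`).
#' @export
fisherExactRxC <- function(tab, simulate = FALSE, B = 1e5L,
                           maxTables = 2e6, seed = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts", call. = FALSE)
  if (any(tab != round(tab))) stop("counts must be integers", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  ## drop empty margins: they contribute nothing to the conditional test
  tab <- tab[rs > 0, cs > 0, drop = FALSE]
  rs <- rowSums(tab); cs <- colSums(tab)
  if (length(tab) == 0L || nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(p = 1, method = "exact", nTables = 1))

  logConst <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N)
  logP <- function(cells) logConst - sum(lfactorial(cells))
  obsLogP <- logP(tab)
  tol <- 1e-7

  if (!simulate) {
    res <- .fisherEnumerate(rs, cs, obsLogP, logConst, maxTables)
    if (!is.null(res))
      return(list(p = min(1, res$p), method = "exact",
                  nTables = res$nTables))
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::r2dtable(B, rs, cs)
  lp <- vapply(draws, function(m) logConst - sum(lfactorial(m)), numeric(1))
  p <- (1 + sum(lp <= obsLogP + tol)) / (B + 1)
  list(p = p, method = "monte-carlo", nTables = B)
}

## depth-first enumeration of all tables with the given margins, summing
## the probability of tables no more probable than the observed one
.fisherEnumerate <- function(rs, cs, obsLogP, logConst, maxTables) {
  nr <- length(rs); nc <- length(cs)
  tol <- 1e-7
  pSum <- 0
  nTab <- 0L
  overflow <- FALSE

  ## recursively fill row by row; within a row, cell by cell
  fillRow <- function(rowIdx, colRemain, logAcc) {
    if (overflow) return()
    if (rowIdx == nr) {
      ## last row forced by the remaining column margins
      lp <- logConst - (logAcc + sum(lfactorial(colRemain)))
      nTab <<- nTab + 1L
      if (nTab > maxTables) { overflow <<- TRUE; return() }
      if (lp <= obsLogP + tol) pSum <<- pSum + exp(lp)
      return()
    }
    target <- rs[rowIdx]
    row <- integer(nc)
    fillCell <- function(colIdx, remain) {
      if (overflow) return()
      if (colIdx == nc) {
        if (remain > colRemain[nc]) return()
        row[nc] <<- remain
        fillRow(rowIdx + 1L, colRemain - row,
                logAcc + sum(lfactorial(row)))
        return()
      }
      maxHere <- min(remain, colRemain[colIdx])
      for (v in 0:maxHere) {
        row[colIdx] <<- v
        fillCell(colIdx + 1L, remain - v)
        if (overflow) return()
      }
    }
    fillCell(1L, target)
  }
  fillRow(1L, cs, 0)
  if (overflow) return(NULL)
  list(p = pSum, nTables = nTab)
}

#' One-dimensional Gaussian kernel density estimate
#'
#' Replaces each data point by a Gaussian of the given bandwidth and sums;
#' the result is normalized to integrate to 1 over the grid, which spans
#' the data plus four bandwidths.
#'
#' @param values Numeric data (>= 1 value).
#' @param bandwidth Gaussian sd of the kernel (> 0).
#' @param gridSize Number of grid points (default 512).
#' @return A list with `x` (grid) and `density`.
#' @export
kde1d <- function(values, bandwidth, gridSize = 512L) {
  if (!length(values)) stop("need at least 1 value", call. = FALSE)
  .assertScalarPositive(bandwidth, "bandwidth")
  dens <- stats::density(values, bw = bandwidth, kernel = "gaussian",
                         from = min(values) - 4 * bandwidth,
                         to = max(values) + 4 * bandwidth, n = gridSize)
  dx <- dens$x[2L] - dens$x[1L]
  area <- sum((dens$y[-1L] + dens$y[-gridSize]) / 2) * dx
  list(x = dens$x, density = dens$y / area)
}
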