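## Transferred work and its exact per-repeat decomposition.
##
## W(t_N) = sum_{n<=N} Fbar_n . Dd_n, with Fbar_n the average of the force
## vectors at frames n-1 and n and Dd_n the change in the end-to-end vector.
## Decomposing the end-to-end vector into telescoping per-repeat anchor
## segments e_r gives per-repeat components W_r that sum to W exactly.

#' Cumulative work transferred by the external force
#'
#' Discrete work integral over the saved frames: at each frame step the
#' average of the two successive force vectors is dotted with the change in
#' the end-to-end vector.
#'
#' @param trace A [ForceTrace-class] with at least 2 frames.
#' @param magnitudeAlongExtension Logical; when `TRUE` the force vector is
#'   rebuilt as magnitude times the instantaneous end-to-end unit vector
#'   (the loading geometry of end-pulled constructs, useful for traces that
#'   store only a magnitude).  Default `FALSE`: use the stored vectors.
#'   When the stored force is already along the end-to-end vector, as the
#'   simulator emits, the two options agree.
#' @return A [WorkProfile-class] with the total only (no components).
#' @seealso [repeatWorkComponents()] for the per-repeat decomposition.
#' @export
cumulativeWork <- function(trace, magnitudeAlongExtension = FALSE) {
  n <- nFrames(trace)
  if (n < 2L) stop("need at least 2 frames", call. = FALSE)
  Fv <- forceVectors(trace)
  if (magnitudeAlongExtension) {
    ee <- trace@endToEnd
    nrm <- sqrt(rowSums(ee^2))
    unit <- ee / ifelse(nrm > 0, nrm, 1)
    Fv <- forceMagnitudes(trace) * unit
  }
  dd <- diff(trace@endToEnd)
  fbar <- (Fv[-1L, , drop = FALSE] + Fv[-n, , drop = FALSE]) / 2
  w <- c(0, cumsum(rowSums(fbar * dd)))
  new("WorkProfile", time = frameTimes(trace), total = w,
      components = matrix(0, n, 0), runId = runParams(trace)$runId %||%
        "run1", bound = isTRUE(runParams(trace)$bound))
}

#' Per-repeat components of the transferred work
#'
#' Decomposes the end-to-end vector into per-repeat segments
#' `e_r = anchor_{r+1} - anchor_r` (adjacent repeats share boundary anchors,
#' so the segments telescope) and accumulates
#' `W_r(t_N) = sum_n Fbar_n . De_r,n`.  The components sum to the total
#' work exactly at every frame.
#'
#' @param trace A [ForceTrace-class] carrying per-boundary anchor positions.
#' @return A [WorkProfile-class] with per-repeat components.
#' @export
repeatWorkComponents <- function(trace) {
  n <- nFrames(trace)
  if (n < 2L) stop("need at least 2 frames", call. = FALSE)
  anc <- anchorPositions(trace)
  nAnch <- dim(anc)[2L]
  if (nAnch < 2L)
    stop("trace carries no per-repeat anchor positions", call. = FALSE)
  if (any(!is.finite(anc)))
    stop("anchors missing for a frame", call. = FALSE)
  nRep <- nAnch - 1L
  Fv <- forceVectors(trace)
  fbar <- (Fv[-1L, , drop = FALSE] + Fv[-n, , drop = FALSE]) / 2
  comp <- matrix(0, n, nRep)
  for (r in seq_len(nRep)) {
    er <- anc[, r + 1L, ] - anc[, r, ]          # n x 3
    der <- diff(er)
    comp[, r] <- c(0, cumsum(rowSums(fbar * der)))
  }
  total <- rowSums(comp)
  new("WorkProfile", time = frameTimes(trace), total = total,
      components = comp, runId = runParams(trace)$runId %||% "run1",
      bound = isTRUE(runParams(trace)$bound))
}

#' Kernel density of final transferred works
#'
#' One-dimensional Gaussian KDE of per-run work values (in kBT), bandwidth
#' 50 kBT by default; a thin wrapper around [kde1d()].
#'
#' @param works Per-run final works in kBT.
#' @param bandwidth Gaussian bandwidth in kBT (default 50).
#' @param gridSize Number of grid points.
#' @return A list with `x` (grid) and `density`.
#' @export
workDistribution <- function(works, bandwidth = 50, gridSize = 512L) {
  kde1d(works, bandwidth, gridSize = gridSize)
}

#' Compare two groups of work values
#'
#' Welch two-sample, two-sided t-test with significance flagged at `alpha`
#' (default the 1% level).  Degenerate groups (zero variance in both) are
#' handled by convention: p = 1 for equal means, p = 0 for different means.
#'
#' @param groupA,groupB Numeric vectors (>= 3 values each).
#' @param alpha Significance level (default 0.01).
#' @return A list with `statistic`, `p`, `significant`, and the group
#'   means.
#' @export
compareWork <- function(groupA, groupB, alpha = 0.01) {
  if (length(groupA) < 3L || length(groupB) < 3L)
    stop("need at least 3 values per group", call. = FALSE)
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    same <- isTRUE(all.equal(mean(groupA), mean(groupB)))
    return(list(statistic = if (same) 0 else Inf, p = if (same) 1 else 0,
                significant = !same, meanA = mean(groupA),
                meanB = mean(groupB)))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha,
       meanA = mean(groupA), meanB = mean(groupB))
}
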