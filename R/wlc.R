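## Worm-like chain elasticity and contour-length analysis.

#' Worm-like chain restoring force (Marko-Siggia interpolation)
#'
#' Entropic restoring force of a worm-like chain at end-to-end extension `x`:
#' \deqn{F = (k_B T / p) [ 1/(4 (1 - x/L_c)^2) - 1/4 + x/L_c ]}
#' The force is zero at zero extension, strictly increasing in `x`, and
#' diverges as `x` approaches the contour length `Lc`.
#'
#' @param x Extension in A (vectorised); must satisfy `0 <= x < Lc`.
#' @param Lc Contour length in A.
#' @param p Persistence length in A (default 3.8).
#' @param temperature Temperature in K (default 300).
#' @return Force in pN.
#' @seealso [fitContourLength()], [wlcStretchEnergy()]
#' @export
wlcForce <- function(x, Lc, p = 3.8, temperature = 300) {
  .assertScalarPositive(Lc, "Lc")
  .assertScalarPositive(p, "p")
  if (any(x < 0) || any(x >= Lc))
    stop("extension must satisfy 0 <= x < Lc", call. = FALSE)
  z <- x / Lc
  (kBT(temperature) / p) * (0.25 / (1 - z)^2 - 0.25 + z)
}

#' Analytic WLC stretching energy
#'
#' Closed-form integral of the Marko-Siggia force from 0 to `x`:
#' \deqn{E = (k_B T / p) [ x^2/(2 L_c) + L_c/(4(1 - x/L_c)) - L_c/4 - x/4 ]}
#' Used as the independent oracle for the transferred-work integral on
#' rupture-free traces.
#'
#' @inheritParams wlcForce
#' @return Stretching energy in pN A.
#' @export
wlcStretchEnergy <- function(x, Lc, p = 3.8, temperature = 300) {
  if (any(x < 0) || any(x >= Lc))
    stop("extension must satisfy 0 <= x < Lc", call. = FALSE)
  z <- x / Lc
  (kBT(temperature) / p) * (x^2 / (2 * Lc) + Lc / (4 * (1 - z)) - Lc / 4 - x / 4)
}

#' Fit the contour length of a pre-peak segment
#'
#' Least-squares fit of the Marko-Siggia force-extension curve to one
#' segment of a force-extension profile, with the persistence length held
#' fixed (default 3.8 A) and only the contour length free.  The search is
#' bracketed in `(1.001, 5) * max(extension)`.
#'
#' @param extension Extensions in A, strictly increasing, length >= 5.
#' @param force Forces in pN, same length.
#' @param p Fixed persistence length in A.
#' @param temperature Temperature in K.
#' @param segmentId Identifier carried through error messages and output.
#' @return A list with elements `Lc` (fitted contour length, A), `p`,
#'   `rss` (residual sum of squares, pN^2), `rmsResidual` (pN), `n`, and
#'   `segmentId`.
#' @export
fitContourLength <- function(extension, force, p = 3.8, temperature = 300,
                             segmentId = NA) {
  if (length(extension) < 5L)
    stop("need at least 5 records to fit a segment (segment ",
         segmentId, ")", call. = FALSE)
  .assertStrictlyIncreasing(extension, "extension")
  if (length(force) != length(extension))
    stop("extension and force lengths differ", call. = FALSE)
  xmax <- max(extension)
  obj <- function(Lc)
    sum((wlcForce(extension, Lc, p, temperature) - force)^2)
  opt <- stats::optimize(obj, lower = xmax * 1.001, upper = xmax * 5,
                         tol = xmax * 1e-7)
  ## refine near the lower bracket edge: optimize() can sit on a boundary
  if (!is.finite(opt$objective))
    stop("contour-length fit failed to converge (segment ", segmentId, ")",
         call. = FALSE)
  list(Lc = opt$minimum, p = p, rss = opt$objective,
       rmsResidual = sqrt(opt$objective / length(force)),
       n = length(force), segmentId = segmentId)
}

#' WLC fits for the segments preceding each detected peak
#'
#' For every peak in a [PeakSet-class], takes the stretch of the
#' force-extension profile from the force minimum after the previous peak up
#' to the peak frame and fits its contour length with [fitContourLength()].
#' Segments with fewer than `minPoints` frames are skipped.
#'
#' @param trace A [ForceTrace-class].
#' @param peakSet A [PeakSet-class] detected on `trace`.
#' @param p Fixed persistence length in A.
#' @param minPoints Minimum frames per fitted segment (default 5).
#' @return data.frame with one row per fitted peak: `run`, `peakTime`,
#'   `extension`, `force`, `Lc`, `rmsResidual`.
#' @export
fitPeakContours <- function(trace, peakSet, p = 3.8, minPoints = 5L) {
  pk <- peaks(peakSet)
  tt <- frameTimes(trace)
  ext <- extensions(trace)
  fmag <- forceMagnitudes(trace)
  out <- vector("list", nrow(pk))
  prevIdx <- 1L
  for (i in seq_len(nrow(pk))) {
    peakIdx <- which.min(abs(tt - pk$time[i]))
    segStart <- if (i == 1L) 1L else {
      prevPeak <- which.min(abs(tt - pk$time[i - 1L]))
      prevPeak + which.min(fmag[prevPeak:peakIdx]) - 1L
    }
    idx <- segStart:peakIdx
    ## keep a strictly increasing extension subsequence (drops back-steps)
    e <- ext[idx]
    keepLocal <- which(e >= cummax(e))
    keepLocal <- keepLocal[!duplicated(e[keepLocal])]
    keep <- idx[keepLocal]
    if (length(keep) < minPoints) next
    fit <- fitContourLength(ext[keep], fmag[keep], p = p,
                            segmentId = paste0(pk$run[i], ":", i))
    out[[i]] <- data.frame(run = pk$run[i], peakTime = pk$time[i],
                           extension = pk$extension[i], force = pk$force[i],
                           Lc = fit$Lc, rmsResidual = fit$rmsResidual)
  }
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(make.row.names = FALSE)))
}

#' All-pairs within-run contour-length differences
#'
#' Differences of fitted contour lengths between all ordered pairs of peaks
#' within the same run (not only adjacent peaks), pooled across runs, with a
#' histogram at a configurable bin width.
#'
#' @param fits data.frame with at least columns `run` and `Lc` (such as the
#'   output of [fitPeakContours()]).
#' @param binWidth Histogram bin width in A (default 5).
#' @return A [ContourHistogram-class].
#' @export
contourLengthDifferences <- function(fits, binWidth = 5) {
  if (is.null(fits) || nrow(fits) < 2L)
    stop("need at least 2 fits", call. = FALSE)
  diffs <- unlist(lapply(split(fits$Lc, fits$run), function(lc) {
    if (length(lc) < 2L) return(numeric(0))
    d <- outer(lc, lc, "-")
    abs(d[upper.tri(d)])
  }), use.names = FALSE)
  diffs <- diffs[diffs > 0]
  if (length(diffs)) {
    breaks <- seq(0, max(diffs) + binWidth, by = binWidth)
    h <- graphics::hist(diffs, breaks = breaks, plot = FALSE)
    mids <- h$mids; counts <- h$counts
  } else {
    mids <- numeric(0); counts <- numeric(0)
  }
  new("ContourHistogram", diffs = diffs, mids = mids, counts = counts,
      binWidth = binWidth, period = NA_real_, score = NA_real_)
}

#' Detect the dominant period of contour-length differences
#'
#' Scores each candidate period P by the fraction of pairwise differences
#' lying within `tolerance` of a positive multiple of P.  Because every
#' multiple of 2L is also a multiple of L, the raw fraction can never prefer
#' the longer of two harmonically related periods; the period is therefore
#' selected by the raw fraction minus the fraction expected for a uniform
#' distribution of differences (the portion of the axis covered by the
#' tolerance windows), which penalises short periods whose extra multiples
#' go unused.  The reported score is the raw fraction at the selected
#' period.
#'
#' @param hist A [ContourHistogram-class] with at least 10 differences.
#' @param candidates Candidate periods in A (default `seq(40, 130, 0.2)`).
#' @param tolerance Half-width of the window around each multiple (A).
#' @return The input [ContourHistogram-class] with `period` and `score`
#'   filled in.
#' @export
estimatePeriodicity <- function(hist, candidates = seq(40, 130, by = 0.2),
                                tolerance = 10) {
  if (!length(candidates)) stop("empty candidate range", call. = FALSE)
  d <- hist@diffs
  if (length(d) < 10L)
    stop("need at least 10 pairwise differences", call. = FALSE)
  dmax <- max(d)
  raw <- adj <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    P <- candidates[i]
    resid <- abs(d - P * round(d / P))
    hit <- resid <= tolerance & round(d / P) >= 1
    raw[i] <- mean(hit)
    nMult <- floor((dmax + tolerance) / P)
    covered <- min(1, nMult * 2 * tolerance / dmax)
    adj[i] <- raw[i] - covered
  }
  best <- which.max(adj)
  P <- candidates[best]
  ## refine by least squares through the origin on the assigned multiples:
  ## an exact comb at multiples of L snaps to L exactly
  m <- round(d / P)
  sel <- m >= 1 & abs(d - m * P) <= tolerance
  if (any(sel)) {
    P <- sum(d[sel] * m[sel]) / sum(m[sel]^2)
    resid <- abs(d - P * round(d / P))
    hist@score <- mean(resid <= tolerance & round(d / P) >= 1)
  } else {
    hist@score <- raw[best]
  }
  hist@period <- P
  hist
}
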