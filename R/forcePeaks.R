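## Force-peak identification: Gaussian fit of the force-distribution body,
## threshold at the maximal normalized deviation, hysteresis peak picking.

#' Fit the Gaussian body of a force distribution
#'
#' Histograms the sampled force magnitudes (default 5 pN bins) and fits a
#' Gaussian to the body of the distribution: bins within 2 fitted sd of the
#' mode, with the window re-centred once on the fitted parameters (two
#' passes).  The per-bin normalized deviation is
#' `(count - fit) / sqrt(max(count, 1))`, i.e. the deviation in units of the
#' Poisson error on the observed histogram; rupture events populate a
#' high-force tail that stands out from the Gaussian body in this quantity.
#'
#' @param forces Sample of force magnitudes (pN), at least 1000 values.
#' @param binWidth Histogram bin width (pN, default 5).
#' @return A [ForceDistributionFit-class].
#' @export
fitForceDistribution <- function(forces, binWidth = 5) {
  if (length(forces) < 1000L)
    stop("need at least 1000 force samples", call. = FALSE)
  if (stats::sd(forces) == 0)
    stop("degenerate (single-valued) force sample", call. = FALSE)
  .assertScalarPositive(binWidth, "binWidth")
  lo <- floor(min(forces) / binWidth) * binWidth
  hi <- ceiling(max(forces) / binWidth) * binWidth
  breaks <- seq(lo, hi + binWidth, by = binWidth)
  hh <- graphics::hist(forces, breaks = breaks, plot = FALSE)
  mids <- hh$mids; counts <- hh$counts

  ## initial window around the mode, then refit around the fitted mean
  mode0 <- mids[which.max(counts)]
  centre <- mode0
  width <- 2 * stats::sd(forces)
  fit <- NULL
  for (pass in 1:2) {
    sel <- which(mids >= centre - width & mids <= centre + width &
                 counts > 0)
    if (length(sel) < 4L)
      stop("too few body bins to fit a Gaussian", call. = FALSE)
    ## least squares on counts; weights ~ Poisson
    df <- data.frame(m = mids[sel], c = counts[sel])
    start <- list(A = max(df$c), mu = centre, s = width / 2)
    fit <- tryCatch(
      stats::nls(c ~ A * exp(-(m - mu)^2 / (2 * s^2)), data = df,
                 start = start, weights = 1 / pmax(df$c, 1),
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) stop("Gaussian body fit failed", call. = FALSE)
    cf <- stats::coef(fit)
    centre <- cf[["mu"]]; width <- 2 * abs(cf[["s"]])
  }
  cf <- stats::coef(fit)
  mu <- cf[["mu"]]; s <- abs(cf[["s"]]); A <- cf[["A"]]
  pred <- A * exp(-(mids - mu)^2 / (2 * s^2))
  deviation <- (counts - pred) / sqrt(pmax(counts, 1))
  new("ForceDistributionFit", mids = mids, counts = as.numeric(counts),
      mean = mu, sd = s, amplitude = A, deviation = deviation,
      binWidth = binWidth)
}

#' Select the unambiguous-peak force threshold
#'
#' The threshold is the bin centre at which the normalized deviation from
#' the Gaussian body is maximal, among bins above mean + 1 sd (ties broken
#' toward the lower force).  When the maximal deviation is below
#' `minDeviation` the distribution has no resolvable tail and the threshold
#' is flagged unreliable.
#'
#' @param fit A [ForceDistributionFit-class].
#' @param minDeviation Smallest maximal deviation regarded as a real tail
#'   (default 3).
#' @return A list with `threshold` (pN), `deviation` (its normalized
#'   deviation) and `reliable` (logical).
#' @export
selectForceThreshold <- function(fit, minDeviation = 3) {
  sel <- which(fit@mids > fit@mean + fit@sd)
  if (!length(sel))
    stop("no bins above mean + 1 sd: trace has no force tail",
         call. = FALSE)
  dev <- fit@deviation[sel]
  best <- sel[which.max(dev)]          # which.max takes the first (lowest
  list(threshold = fit@mids[best],     # force) among exact ties
       deviation = fit@deviation[best],
       reliable = fit@deviation[best] >= minDeviation)
}

#' Detect force peaks in a trace
#'
#' Local maxima of the (optionally smoothed) force series with force at or
#' above `threshold` and hysteresis prominence at least `minProminence`:
#' after a candidate maximum, the force must drop by `minProminence` before
#' a new peak can open, which prevents noise from splitting one rupture into
#' several peaks.  Boundary frames are never peaks (a rising final segment
#' is not a rupture).  Each peak is annotated with the end-to-end extension
#' at the peak frame.
#'
#' @param trace A [ForceTrace-class].
#' @param threshold Minimum peak force (pN).
#' @param minProminence Hysteresis prominence (pN, default 30).
#' @param smooth Width of the centred moving-average smoothing window in
#'   frames (default 15; 1 disables smoothing).  The default keeps the
#'   smoothed noise extremes of a full-length trace well inside the
#'   hysteresis band at the simulator's reference noise level.
#' @return A [PeakSet-class] (possibly empty).
#' @export
detectPeaks <- function(trace, threshold, minProminence = 30, smooth = 15L) {
  f <- forceMagnitudes(trace)
  tt <- frameTimes(trace)
  ext <- extensions(trace)
  n <- length(f)
  if (n == 0L) stop("empty trace", call. = FALSE)
  runId <- runParams(trace)$runId %||% "run1"
  if (smooth > 1L) {
    ## centred moving average with shrinking windows at the edges
    h <- smooth %/% 2L
    cs <- cumsum(c(0, f))
    lo <- pmax(0L, seq_len(n) - h - 1L)
    hi <- pmin(n, seq_len(n) + h)
    s <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  } else s <- f

  peakIdx <- integer(0); promin <- numeric(0)
  candIdx <- NA_integer_; candVal <- -Inf
  valley <- s[1L]
  searchingMax <- TRUE
  for (i in seq_len(n)) {
    if (searchingMax) {
      if (s[i] > candVal) { candVal <- s[i]; candIdx <- i }
      if (candVal - s[i] >= minProminence) {
        rise <- candVal - valley
        if (candIdx > 1L && candIdx < n && rise >= minProminence) {
          peakIdx <- c(peakIdx, candIdx)
          promin <- c(promin, min(rise, candVal - s[i]))
        }
        searchingMax <- FALSE
        valley <- s[i]
      }
    } else {
      if (s[i] < valley) valley <- s[i]
      if (s[i] - valley >= minProminence) {
        searchingMax <- TRUE
        candVal <- s[i]; candIdx <- i
      }
    }
  }
  ## refine each smoothed maximum to the raw-force apex nearby (the
  ## smoothed argmax lags the rupture by up to half the window)
  w <- max(1L, as.integer(smooth))
  peakIdx <- vapply(peakIdx, function(i) {
    lo <- max(2L, i - w); hi <- min(n - 1L, i + w)
    lo + which.max(f[lo:hi]) - 1L
  }, integer(1))
  keep <- which(f[peakIdx] >= threshold)
  pk <- data.frame(run = rep(runId, length(keep)),
                   time = tt[peakIdx[keep]],
                   extension = ext[peakIdx[keep]],
                   force = f[peakIdx[keep]],
                   prominence = promin[keep])
  new("PeakSet", peaks = pk, threshold = threshold)
}

#' Two-dimensional kernel density of peaks on the extension-force plane
#'
#' Gaussian kernel density estimate of a collection of force peaks on the
#' extension-force plane with independent bandwidths for the two axes
#' (defaults 20 A and 20 pN).  The density is normalized to integrate to 1
#' over the returned grid, which spans the data plus four bandwidths.
#'
#' @param peakSets A [PeakSet-class] or list of them.
#' @param bandwidth Length-2 numeric: extension bandwidth (A) and force
#'   bandwidth (pN).
#' @param gridSize Grid points per axis (default 120).
#' @return A list with `extension`, `force` (grid vectors) and `density`
#'   (matrix, rows = extension grid).
#' @export
peakDensity <- function(peakSets, bandwidth = c(20, 20), gridSize = 120L) {
  if (is(peakSets, "PeakSet")) peakSets <- list(peakSets)
  pk <- do.call(rbind, lapply(peakSets, peaks))
  if (is.null(pk) || nrow(pk) == 0L)
    stop("need at least one peak", call. = FALSE)
  if (any(bandwidth <= 0)) stop("non-positive bandwidth", call. = FALSE)
  bx <- bandwidth[1L]; by <- bandwidth[2L]
  gx <- seq(min(pk$extension) - 4 * bx, max(pk$extension) + 4 * bx,
            length.out = gridSize)
  gy <- seq(min(pk$force) - 4 * by, max(pk$force) + 4 * by,
            length.out = gridSize)
  dens <- matrix(0, gridSize, gridSize)
  for (i in seq_len(nrow(pk))) {
    kx <- stats::dnorm(gx, pk$extension[i], bx)
    ky <- stats::dnorm(gy, pk$force[i], by)
    dens <- dens + outer(kx, ky)
  }
  dens <- dens / nrow(pk)
  list(extension = gx, force = gy, density = dens)
}
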