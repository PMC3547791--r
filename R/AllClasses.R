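#' @import methods
NULL

## ---------------------------------------------------------------------------
## Topology
## ---------------------------------------------------------------------------

#' Topology of a pulled construct
#'
#' Residue- and atom-level description of the system: residue indices, names,
#' repeat assignment and a protein/ligand chain tag, plus the atom records
#' (owning residue, atom name, element).  Protein residue indices must be
#' contiguous and unique; ligand residues never carry a repeat id.
#'
#' @slot residues data.frame with columns `resid` (integer), `resname`
#'   (character), `repeatId` (integer, `NA` for residues outside any repeat,
#'   e.g. ligand beads), `chain` (`"protein"` or `"ligand"`) and `region`
#'   (character secondary-structure-like tag, e.g. `"turn"`/`"helix"`,
#'   `NA` when unannotated).
#' @slot atoms data.frame with columns `resid` (integer), `name` (character)
#'   and `element` (character).
#' @exportClass Topology
setClass("Topology",
  representation(residues = "data.frame", atoms = "data.frame"))

setValidity("Topology", function(object) {
  res <- object@residues
  atm <- object@atoms
  need <- c("resid", "resname", "repeatId", "chain", "region")
  if (!all(need %in% names(res)))
    return(paste("residues must have columns", paste(need, collapse = ", ")))
  if (!all(c("resid", "name", "element") %in% names(atm)))
    return("atoms must have columns resid, name, element")
  for (ch in unique(res$chain)) {
    ri <- res$resid[res$chain == ch]
    if (anyDuplicated(ri)) return(paste("duplicate residue index in chain", ch))
    if (length(ri) > 1L && !all(diff(sort(ri)) == 1L))
      return(paste("residue indices not contiguous in chain", ch))
  }
  if (any(!is.na(res$repeatId) & res$chain == "ligand"))
    return("ligand residues must not carry a repeatId")
  if (!all(atm$resid %in% res$resid))
    return("atom references a residue absent from the residue table")
  TRUE
})

## ---------------------------------------------------------------------------
## RepeatMap
## ---------------------------------------------------------------------------

#' Map of repeats onto the residue sequence
#'
#' Ordered, non-overlapping residue ranges for each repeat (N to C), plus the
#' names of the pulling anchor atoms.  Adjacent repeats share boundary
#' anchors so the per-repeat end-to-end vectors telescope: the sum of the
#' repeat segment vectors equals the full end-to-end vector.
#'
#' @slot repeats data.frame with columns `repeatId`, `first`, `last`
#'   (residue indices, inclusive).
#' @slot anchorAtoms named list with entries `nTerm`, `cTerm` and `boundary`
#'   (atom names used as pulling/boundary anchors).
#' @exportClass RepeatMap
setClass("RepeatMap",
  representation(repeats = "data.frame", anchorAtoms = "list"))

setValidity("RepeatMap", function(object) {
  rp <- object@repeats
  if (!all(c("repeatId", "first", "last") %in% names(rp)))
    return("repeats must have columns repeatId, first, last")
  if (nrow(rp) == 0L) return("at least one repeat required")
  if (any(rp$last < rp$first)) return("repeat range with last < first")
  if (nrow(rp) > 1L) {
    if (any(diff(rp$first) <= 0)) return("repeats must be ordered N to C")
    if (any(rp$first[-1L] != rp$last[-nrow(rp)] + 1L))
      return("repeat ranges must be adjacent and non-overlapping")
  }
  if (!all(c("nTerm", "cTerm", "boundary") %in% names(object@anchorAtoms)))
    return("anchorAtoms needs entries nTerm, cTerm, boundary")
  TRUE
})

#' @describeIn RepeatMap-class Construct a repeat map from residue ranges.
#' @param first,last Integer vectors of first/last residue per repeat.
#' @param repeatId Integer repeat identifiers (default `seq_along(first)`).
#' @param anchorAtoms Named list of anchor atom names.
#' @export
RepeatMap <- function(first, last, repeatId = seq_along(first),
                      anchorAtoms = list(nTerm = "N", cTerm = "C",
                                         boundary = "CA")) {
  new("RepeatMap",
      repeats = data.frame(repeatId = as.integer(repeatId),
                           first = as.integer(first),
                           last = as.integer(last)),
      anchorAtoms = anchorAtoms)
}

## ---------------------------------------------------------------------------
## PullingTrajectory
## ---------------------------------------------------------------------------

#' Coordinate trajectory of a pulling run
#'
#' Per-frame atomic coordinates with the owning [Topology-class].  Frame
#' times are in ps and strictly increasing; coordinates are in Angstrom.
#'
#' @slot topology A [Topology-class] object.
#' @slot times Numeric vector of frame times (ps).
#' @slot coords Numeric array `c(nAtoms, 3, nFrames)`.
#' @exportClass PullingTrajectory
setClass("PullingTrajectory",
  representation(topology = "Topology", times = "numeric", coords = "array"))

setValidity("PullingTrajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an nAtoms x 3 x nFrames array")
  if (d[1] != nrow(object@topology@atoms))
    return("coordinate count does not match atom count")
  if (d[3] != length(object@times))
    return("frame count does not match length(times)")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("frame times must be strictly increasing")
  TRUE
})

## ---------------------------------------------------------------------------
## ForceTrace
## ---------------------------------------------------------------------------

#' Force trace of a pulling run
#'
#' Per-frame applied spring force vector, end-to-end vector and per-repeat
#' boundary anchor positions, plus run metadata (pulling speed, spring
#' constant, seed, ligand-bound flag).  The end-to-end vector must equal the
#' difference between the terminal anchors frame by frame (within 1e-6 A),
#' which guarantees the per-repeat work components telescope exactly.
#'
#' @slot time Numeric frame times (ps), strictly increasing.
#' @slot force nFrames x 3 matrix of applied force vectors (pN).
#' @slot endToEnd nFrames x 3 matrix of end-to-end vectors (A).
#' @slot anchors numeric array `c(nFrames, nAnchors, 3)` of boundary anchor
#'   positions (A); `nAnchors = nRepeats + 1`, may have zero columns when a
#'   trace carries no per-repeat information.
#' @slot params Named list of run metadata (`speed`, `springK`, `seed`,
#'   `bound`, ...).
#' @exportClass ForceTrace
setClass("ForceTrace",
  representation(time = "numeric", force = "matrix", endToEnd = "matrix",
                 anchors = "array", params = "list"))

setValidity("ForceTrace", function(object) {
  n <- length(object@time)
  if (n > 1L && any(diff(object@time) <= 0))
    return("times must be strictly increasing")
  if (nrow(object@force) != n || ncol(object@force) != 3L)
    return("force must be an nFrames x 3 matrix")
  if (nrow(object@endToEnd) != n || ncol(object@endToEnd) != 3L)
    return("endToEnd must be an nFrames x 3 matrix")
  da <- dim(object@anchors)
  if (length(da) != 3L || da[1] != n || da[3] != 3L)
    return("anchors must be an nFrames x nAnchors x 3 array")
  if (da[2] >= 2L) {
    span <- object@anchors[, da[2], , drop = FALSE] -
      object@anchors[, 1L, , drop = FALSE]
    if (max(abs(span - array(object@endToEnd, dim = c(n, 1, 3)))) > 1e-6)
      return("endToEnd does not match the terminal anchor difference")
  }
  TRUE
})

#' @describeIn ForceTrace-class Construct a force trace.
#' @param time,force,endToEnd,anchors,params See slot descriptions.
#' @export
ForceTrace <- function(time, force, endToEnd,
                       anchors = array(0, dim = c(length(time), 0, 3)),
                       params = list()) {
  new("ForceTrace", time = as.numeric(time), force = force,
      endToEnd = endToEnd, anchors = anchors, params = params)
}

## ---------------------------------------------------------------------------
## SimParams
## ---------------------------------------------------------------------------

#' Parameters of the synthetic pulling simulator
#'
#' Conditions of a constant-velocity harmonic-spring pulling run with Bell
#' unfolding kinetics at half-repeat granularity and Marko-Siggia worm-like
#' chain elasticity for the unfolded contour.  See [simulatePull()].
#'
#' @slot nRepeats Number of repeats (default 7).
#' @slot contourPerHalf Unfolded contour length released per half-repeat
#'   event, L, in A (default 56.8).
#' @slot foldedRise Rigid end-to-end contribution of a folded repeat in A.
#'   Default 0: the folded core is treated as an inextensible point, so
#'   fitted contour-length increments are exact multiples of L.
#' @slot linkerContour Initially unfolded terminal contour in A (default 30).
#' @slot persistence WLC persistence length in A (default 3.8).
#' @slot springK Pulling spring constant in pN/A (default 20).
#' @slot speed Pulling speed in A/ps (0.05 or 0.01; default 0.05).
#' @slot temperature Temperature in K (default 300).
#' @slot k0 Intrinsic (zero-force) unfolding rate per half-repeat in 1/ps.
#' @slot bellDx Bell activation distance in A.
#' @slot stabilityGradient Extra stability per repeat toward the N-terminus,
#'   in kBT; repeat r carries `stabilityGradient * (nRepeats - r)` so the
#'   C-terminal repeat is the most labile.
#' @slot ligand Logical: ligand bound.
#' @slot ddG Per-repeat ligand stabilisation in kBT (length `nRepeats`;
#'   nonzero entries restricted to repeats 1..6).
#' @slot halfCoupling Probability q that the second half of a repeat ruptures
#'   immediately after the first; q near 1 gives whole-repeat (2L) steps,
#'   small q gives half-repeat (L) steps.
#' @slot noiseSd Gaussian noise added to the reported force, pN.
#' @slot frameInterval Frame saving interval in ps.
#' @slot kineticsStep Bernoulli kinetics time step in ps (default 0.1).
#' @slot pullDistance Total spring-end displacement in A (default 800).
#' @exportClass SimParams
setClass("SimParams",
  representation(nRepeats = "integer", contourPerHalf = "numeric",
                 foldedRise = "numeric", linkerContour = "numeric",
                 persistence = "numeric", springK = "numeric",
                 speed = "numeric", temperature = "numeric",
                 k0 = "numeric", bellDx = "numeric",
                 stabilityGradient = "numeric", ligand = "logical",
                 ddG = "numeric", halfCoupling = "numeric",
                 noiseSd = "numeric", frameInterval = "numeric",
                 kineticsStep = "numeric", pullDistance = "numeric"))

setValidity("SimParams", function(object) {
  pos <- c(contourPerHalf = object@contourPerHalf,
           persistence = object@persistence, springK = object@springK,
           speed = object@speed, temperature = object@temperature,
           k0 = object@k0, frameInterval = object@frameInterval,
           kineticsStep = object@kineticsStep,
           pullDistance = object@pullDistance)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return(paste("non-positive parameter:",
                 paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@nRepeats < 1L) return("nRepeats must be >= 1")
  if (object@bellDx < 0) return("bellDx must be >= 0")
  if (object@foldedRise < 0 || object@linkerContour < 0)
    return("foldedRise and linkerContour must be >= 0")
  if (length(object@ddG) != object@nRepeats)
    return("ddG must have one entry per repeat")
  if (any(object@ddG < 0)) return("ddG must be >= 0")
  if (object@ligand && any(object@ddG > 0)) {
    stab <- which(object@ddG > 0)
    if (any(stab > min(object@nRepeats - 1L, 6L)))
      return("ligand stabilisation is restricted to repeats 1..6")
  }
  if (object@halfCoupling < 0 || object@halfCoupling > 1)
    return("halfCoupling must be in [0, 1]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' @describeIn SimParams-class Construct simulator parameters.
#'
#' `bound = TRUE` applies the ligand defaults: a 4 kBT stabilisation of
#' repeats 1-5 and 1.5 kBT of repeat 6 (the interface spans repeats 1-6 with
#' the weakest effect on repeat 6), and strong half-repeat coupling
#' (q = 0.95) so unfolding proceeds in whole-repeat steps.  The free-state
#' defaults use q = 0.25, which yields frequent half-repeat (L) steps.
#' @param bound Logical, simulate the ligand-bound construct.
#' @param ... Any slot value to override.
#' @export
SimParams <- function(bound = FALSE, ...) {
  dots <- list(...)
  nR <- as.integer(dots$nRepeats %||% 7L)
  ddG <- if (bound) {
    d <- rep(0, nR)
    idx <- seq_len(min(nR - 1L, 6L))
    d[idx] <- 4
    if (length(idx) >= 6L) d[6L] <- 1.5
    d
  } else rep(0, nR)
  defaults <- list(
    nRepeats = nR, contourPerHalf = 56.8, foldedRise = 0,
    linkerContour = 30, persistence = 3.8, springK = 20, speed = 0.05,
    temperature = 300, k0 = 2e-5, bellDx = 2, stabilityGradient = 0.7,
    ligand = bound, ddG = ddG,
    halfCoupling = if (bound) 0.95 else 0.25,
    noiseSd = 10, kineticsStep = 0.1, pullDistance = 800)
  defaults$frameInterval <- dots$frameInterval %||%
    if ((dots$speed %||% defaults$speed) >= 0.05) 1 else 4
  args <- utils::modifyList(defaults, dots)
  args$nRepeats <- as.integer(args$nRepeats)
  do.call(new, c(list(Class = "SimParams"), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Ground truth of a synthetic pulling run
#'
#' Everything the simulator knows that the analysis modules must recover:
#' individual half-repeat rupture events (time, noise-free rupture force,
#' cumulative contour released), per-repeat unfolding times and order ranks,
#' and the transferred work with its per-repeat components.
#'
#' @slot events data.frame with one row per half-repeat rupture: `repeatId`,
#'   `half` (1 or 2), `time` (ps), `force` (pN, noise-free),
#'   `cumContour` (A of unfolded contour after the event).
#' @slot repeatTimes Per-repeat unfolding time (first half rupture, ps; `NA`
#'   if the repeat never unfolded).
#' @slot orderRanks Integer rank of each repeat in the unfolding sequence
#'   (`NA` for repeats that never unfolded).
#' @slot workTotal Total transferred work, pN A (noise-free).
#' @slot workPerRepeat Per-repeat work components, pN A (sum equals
#'   `workTotal`).
#' @slot duration Run duration in ps.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(events = "data.frame", repeatTimes = "numeric",
                 orderRanks = "integer", workTotal = "numeric",
                 workPerRepeat = "numeric", duration = "numeric"))

setValidity("GroundTruth", function(object) {
  ev <- object@events
  if (nrow(ev)) {
    if (any(diff(ev$time) < 0)) return("event times must be non-decreasing")
    for (r in unique(ev$repeatId)) {
      h <- ev[ev$repeatId == r, ]
      if (nrow(h) == 2L && h$time[h$half == 1L] > h$time[h$half == 2L])
        return("second half ruptured before the first")
    }
  }
  TRUE
})

## ---------------------------------------------------------------------------
## PeakSet, ForceDistributionFit
## ---------------------------------------------------------------------------

#' Detected force peaks
#'
#' Local maxima of the (smoothed) force series that exceed the force
#' threshold with the required hysteresis prominence, annotated with the
#' end-to-end extension at the peak frame.
#'
#' @slot peaks data.frame with columns `run`, `time` (ps), `extension` (A),
#'   `force` (pN), `prominence` (pN).
#' @slot threshold Force threshold used (pN).
#' @exportClass PeakSet
setClass("PeakSet",
  representation(peaks = "data.frame", threshold = "numeric"))

setValidity("PeakSet", function(object) {
  need <- c("run", "time", "extension", "force", "prominence")
  if (!all(need %in% names(object@peaks)))
    return(paste("peaks must have columns", paste(need, collapse = ", ")))
  if (nrow(object@peaks) && length(object@threshold) == 1L &&
      is.finite(object@threshold) &&
      any(object@peaks$force < object@threshold))
    return("peak below threshold")
  TRUE
})

#' Gaussian fit of the force-distribution body
#'
#' Histogram of sampled force magnitudes together with a Gaussian fitted to
#' the body of the distribution and the per-bin normalized deviation
#' (count - fit) / sqrt(count), used to locate the force threshold above
#' which peaks are unambiguous.
#'
#' @slot mids Histogram bin centres (pN).
#' @slot counts Bin counts.
#' @slot mean,sd,amplitude Fitted Gaussian body parameters.
#' @slot deviation Normalized deviation per bin.
#' @slot binWidth Bin width (pN).
#' @exportClass ForceDistributionFit
setClass("ForceDistributionFit",
  representation(mids = "numeric", counts = "numeric", mean = "numeric",
                 sd = "numeric", amplitude = "numeric",
                 deviation = "numeric", binWidth = "numeric"))

setValidity("ForceDistributionFit", function(object) {
  if (any(object@counts < 0)) return("negative bin count")
  if (object@sd <= 0) return("sd must be positive")
  TRUE
})

## ---------------------------------------------------------------------------
## WorkProfile
## ---------------------------------------------------------------------------

#' Cumulative transferred work and its per-repeat decomposition
#'
#' Cumulative work transferred by the external force up to each frame,
#' internally in pN A, optionally with per-repeat components from the
#' telescoping anchor decomposition of the end-to-end vector.  The
#' components sum to the total at every frame by construction.
#'
#' @slot time Frame times (ps).
#' @slot total Cumulative total work (pN A).
#' @slot components nFrames x nRepeats matrix of cumulative per-repeat work
#'   (pN A); zero columns when no decomposition was requested.
#' @slot runId Character run identifier.
#' @slot bound Logical ligand flag.
#' @exportClass WorkProfile
setClass("WorkProfile",
  representation(time = "numeric", total = "numeric",
                 components = "matrix", runId = "character",
                 bound = "logical"))

setValidity("WorkProfile", function(object) {
  if (length(object@total) != length(object@time))
    return("total must have one value per frame")
  if (nrow(object@components) &&
      nrow(object@components) != length(object@time))
    return("components must have one row per frame")
  TRUE
})

## ---------------------------------------------------------------------------
## ContourHistogram
## ---------------------------------------------------------------------------

#' Pairwise contour-length differences
#'
#' All within-run ordered-pair differences of fitted contour lengths, pooled
#' across runs, with their histogram and (after [estimatePeriodicity()]) the
#' detected period.
#'
#' @slot diffs Pairwise contour-length differences, A (all positive).
#' @slot mids,counts Histogram bin centres and counts.
#' @slot binWidth Histogram bin width, A.
#' @slot period Detected period, A (`NA` until estimated).
#' @slot score Fraction of difference mass within tolerance of the period's
#'   multiples (`NA` until estimated).
#' @exportClass ContourHistogram
setClass("ContourHistogram",
  representation(diffs = "numeric", mids = "numeric", counts = "numeric",
                 binWidth = "numeric", period = "numeric", score = "numeric"))

setValidity("ContourHistogram", function(object) {
  if (any(object@diffs <= 0)) return("differences must be positive")
  if (length(object@diffs) && sum(object@counts) != length(object@diffs))
    return("histogram counts must sum to the number of pairs")
  TRUE
})
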