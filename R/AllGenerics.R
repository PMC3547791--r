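## Generics and accessors.  Slot access from user code should go through
## these; the slots themselves are an implementation detail.

#' @name accessors
#' @title Accessors for RepeatPull classes
#' @description Small accessor generics shared by the trajectory, force
#'   trace, and result containers.
#' @param x An object.
#' @param ... Unused.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x, ...) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("nRepeats", function(x, ...) standardGeneric("nRepeats"))

#' @rdname accessors
#' @export
setGeneric("forceVectors", function(x, ...) standardGeneric("forceVectors"))

#' @rdname accessors
#' @export
setGeneric("forceMagnitudes",
           function(x, ...) standardGeneric("forceMagnitudes"))

#' @rdname accessors
#' @export
setGeneric("extensions", function(x, ...) standardGeneric("extensions"))

#' @rdname accessors
#' @export
setGeneric("anchorPositions",
           function(x, ...) standardGeneric("anchorPositions"))

#' @rdname accessors
#' @export
setGeneric("runParams", function(x, ...) standardGeneric("runParams"))

#' @rdname accessors
#' @export
setGeneric("topology", function(x, ...) standardGeneric("topology"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("repeatRanges", function(x, ...) standardGeneric("repeatRanges"))

#' @rdname accessors
#' @export
setGeneric("peaks", function(x, ...) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setGeneric("events", function(x, ...) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("repeatUnfoldingTimes",
           function(x, ...) standardGeneric("repeatUnfoldingTimes"))

#' @rdname accessors
#' @export
setGeneric("unfoldingOrder",
           function(x, ...) standardGeneric("unfoldingOrder"))

#' @rdname accessors
#' @export
setGeneric("workTotal", function(x, ...) standardGeneric("workTotal"))

#' @rdname accessors
#' @export
setGeneric("workComponents",
           function(x, ...) standardGeneric("workComponents"))

## ---------------------------------------------------------------------------
## ForceTrace methods
## ---------------------------------------------------------------------------

#' @rdname accessors
#' @aliases nFrames,ForceTrace-method
setMethod("nFrames", "ForceTrace", function(x, ...) length(x@time))

#' @rdname accessors
setMethod("frameTimes", "ForceTrace", function(x, ...) x@time)

#' @rdname accessors
setMethod("forceVectors", "ForceTrace", function(x, ...) x@force)

#' @rdname accessors
setMethod("forceMagnitudes", "ForceTrace",
          function(x, ...) sqrt(rowSums(x@force^2)))

#' @rdname accessors
setMethod("extensions", "ForceTrace",
          function(x, ...) sqrt(rowSums(x@endToEnd^2)))

#' @rdname accessors
setMethod("anchorPositions", "ForceTrace", function(x, ...) x@anchors)

#' @rdname accessors
setMethod("runParams", "ForceTrace", function(x, ...) x@params)

#' @rdname accessors
setMethod("nRepeats", "ForceTrace",
          function(x, ...) max(0L, dim(x@anchors)[2] - 1L))

setMethod("show", "ForceTrace", function(object) {
  p <- object@params
  cat("ForceTrace:", length(object@time), "frames,",
      sprintf("%.1f-%.1f ps", object@time[1],
              object@time[length(object@time)]), "\n")
  cat("  anchors:", dim(object@anchors)[2],
      " speed:", p$speed %||% NA, "A/ps",
      " springK:", p$springK %||% NA, "pN/A",
      " bound:", isTRUE(p$bound), "\n")
})

## ---------------------------------------------------------------------------
## PullingTrajectory methods
## ---------------------------------------------------------------------------

#' @rdname accessors
setMethod("nFrames", "PullingTrajectory", function(x, ...) length(x@times))

#' @rdname accessors
setMethod("frameTimes", "PullingTrajectory", function(x, ...) x@times)

#' @rdname accessors
setMethod("topology", "PullingTrajectory", function(x, ...) x@topology)

#' @rdname accessors
#' @param frame Optional frame index; when given, returns an nAtoms x 3
#'   matrix for that frame.
setMethod("coords", "PullingTrajectory", function(x, frame = NULL, ...) {
  if (is.null(frame)) x@coords else x@coords[, , frame]
})

setMethod("show", "PullingTrajectory", function(object) {
  cat("PullingTrajectory:", dim(object@coords)[1], "atoms,",
      length(object@times), "frames\n")
  res <- object@topology@residues
  cat("  protein residues:", sum(res$chain == "protein"),
      " ligand residues:", sum(res$chain == "ligand"),
      " repeats:", length(unique(stats::na.omit(res$repeatId))), "\n")
})

## ---------------------------------------------------------------------------
## RepeatMap / Topology methods
## ---------------------------------------------------------------------------

#' @rdname accessors
setMethod("nRepeats", "RepeatMap", function(x, ...) nrow(x@repeats))

#' @rdname accessors
setMethod("repeatRanges", "RepeatMap", function(x, ...) x@repeats)

#' @rdname accessors
setMethod("nRepeats", "Topology", function(x, ...)
  length(unique(stats::na.omit(x@residues$repeatId))))

setMethod("show", "RepeatMap", function(object) {
  cat("RepeatMap:", nrow(object@repeats), "repeats, residues",
      min(object@repeats$first), "-", max(object@repeats$last), "\n")
})

setMethod("show", "Topology", function(object) {
  cat("Topology:", nrow(object@residues), "residues,",
      nrow(object@atoms), "atoms\n")
})

## ---------------------------------------------------------------------------
## GroundTruth methods
## ---------------------------------------------------------------------------

#' @rdname accessors
setMethod("events", "GroundTruth", function(x, ...) x@events)

#' @rdname accessors
setMethod("repeatUnfoldingTimes", "GroundTruth",
          function(x, ...) x@repeatTimes)

#' @rdname accessors
setMethod("unfoldingOrder", "GroundTruth", function(x, ...) x@orderRanks)

#' @rdname accessors
setMethod("workTotal", "GroundTruth", function(x, ...) x@workTotal)

#' @rdname accessors
setMethod("workComponents", "GroundTruth", function(x, ...) x@workPerRepeat)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@events), "rupture events,",
      sum(!is.na(object@repeatTimes)), "repeats unfolded\n")
  cat(sprintf("  total work %.0f pN A (%.0f kBT)\n", object@workTotal,
              object@workTotal / kBT()))
})

## ---------------------------------------------------------------------------
## PeakSet / WorkProfile / ContourHistogram methods
## ---------------------------------------------------------------------------

#' @rdname accessors
setMethod("peaks", "PeakSet", function(x, ...) x@peaks)

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet:", nrow(object@peaks), "peaks, threshold",
      object@threshold, "pN\n")
})

#' @rdname accessors
setMethod("frameTimes", "WorkProfile", function(x, ...) x@time)

#' @rdname accessors
#' @param units `"pNA"` or `"kbt"`.
setMethod("workTotal", "WorkProfile", function(x, units = "pNA", ...) {
  if (identical(units, "kbt")) x@total / kBT() else x@total
})

#' @rdname accessors
setMethod("workComponents", "WorkProfile", function(x, units = "pNA", ...) {
  if (identical(units, "kbt")) x@components / kBT() else x@components
})

setMethod("show", "WorkProfile", function(object) {
  n <- length(object@time)
  cat(sprintf("WorkProfile (%s): final W = %.0f pN A (%.0f kBT), %d repeats\n",
              object@runId, object@total[n], object@total[n] / kBT(),
              ncol(object@components)))
})

setMethod("show", "ContourHistogram", function(object) {
  cat("ContourHistogram:", length(object@diffs), "pairwise differences")
  if (is.finite(object@period))
    cat(sprintf("; period %.1f A (score %.2f)", object@period, object@score))
  cat("\n")
})

setMethod("show", "ForceDistributionFit", function(object) {
  cat(sprintf("ForceDistributionFit: body mean %.1f pN, sd %.1f pN, %d bins\n",
              object@mean, object@sd, length(object@mids)))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: %d repeats, L=%.1f A, v=%g A/ps, k=%g pN/A, %s\n",
    object@nRepeats, object@contourPerHalf, object@speed, object@springK,
    if (object@ligand) "ligand-bound" else "free"))
})
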