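#' @rdname maskArray
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname voxelSpacing
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname patientId
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname sessionTable
#' @export
setGeneric("sessionTable", function(x) standardGeneric("sessionTable"))

#' @rdname cleanMask
#' @export
setGeneric("cleanMask", function(x, minVoxels = 5L) standardGeneric("cleanMask"))

#' @rdname maxDiameter
#' @export
setGeneric("maxDiameter",
  function(x, region = c("whole", "extrameatal", "intrameatal"))
    standardGeneric("maxDiameter"))

#' @rdname meatalAxis
#' @export
setGeneric("meatalAxis", function(x) standardGeneric("meatalAxis"))

#' @rdname directionalExtents
#' @export
setGeneric("directionalExtents",
  function(x, axis, referenceSlice = NULL) standardGeneric("directionalExtents"))

#' @rdname regionVolumes
#' @export
setGeneric("regionVolumes", function(x) standardGeneric("regionVolumes"))

#' @rdname measureSession
#' @export
setGeneric("measureSession", function(x) standardGeneric("measureSession"))

#' Accessors for LabeledVolume
#'
#' `maskArray` returns the 3D integer label array; `voxelSpacing` the mm
#' voxel spacing along the (canonical) array axes.
#'
#' @param x A [LabeledVolume-class].
#' @return `maskArray`: 3D integer array; `voxelSpacing`: numeric length 3.
#' @name maskArray
#' @aliases voxelSpacing
NULL

setMethod("maskArray", "LabeledVolume", function(x) x@labels)
setMethod("voxelSpacing", "LabeledVolume", function(x) x@spacing)

#' Accessors for PatientTimeline
#'
#' `patientId` returns the patient identifier; `sessionTable` the date-ordered
#' session data.frame.
#'
#' @param x A [PatientTimeline-class].
#' @name patientId
#' @aliases sessionTable
NULL

setMethod("patientId", "PatientTimeline", function(x) x@patientId)
setMethod("sessionTable", "PatientTimeline", function(x) x@sessions)

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@labels)
  n1 <- sum(object@labels == 1L); n2 <- sum(object@labels == 2L)
  cat(sprintf("LabeledVolume %d x %d x %d [%s], spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@orientation,
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intrameatal voxels: %d, extrameatal voxels: %d\n", n1, n2))
})

setMethod("show", "SessionMeasurements", function(object) {
  fmt <- function(x, unit) if (is.na(x)) "undefined" else sprintf("%.2f %s", x, unit)
  cat("SessionMeasurements\n")
  cat(sprintf("  DWT: %s, DEM: %s\n", fmt(object@dWT, "mm"), fmt(object@dEM, "mm")))
  cat(sprintf("  d(intra,par): %s, d(extra,par): %s, d(extra,perp): %s\n",
              fmt(object@dIntraPar, "mm"), fmt(object@dExtraPar, "mm"),
              fmt(object@dExtraPerp, "mm")))
  cat(sprintf("  volumes (intra/extra/whole): %.3f / %.3f / %.3f cm^3\n",
              object@vIntra, object@vExtra, object@vWhole))
  cat(sprintf("  axial slices with tumour: %d%s\n", object@nAxialSlices,
              if (object@entirelyIntrameatal) " (entirely intrameatal)" else ""))
})

setMethod("show", "DiameterChoice", function(object) {
  cat(sprintf("DiameterChoice: %s = %.2f mm (branch: %s%s)\n",
              object@chosen, object@value, object@branch,
              if (object@axisAvailable) "" else ", no meatal axis"))
})

setMethod("show", "GrowthAssessment", function(object) {
  cat(sprintf("GrowthAssessment [%s]: %s\n", object@comparison, object@status))
  if (!is.na(object@deltaD))
    cat(sprintf("  deltaD = %+.2f mm, deltaV = %+.3f cm^3 (%s)\n",
                object@deltaD, object@deltaV,
                if (is.na(object@deltaVPct)) "pct undefined"
                else sprintf("%+.1f%%", object@deltaVPct)))
  if (length(object@triggeredBy))
    cat(sprintf("  triggered by: %s\n", paste(object@triggeredBy, collapse = ", ")))
})

setMethod("show", "PatientTimeline", function(object) {
  cat(sprintf("PatientTimeline '%s': %d session(s), %s to %s\n",
              object@patientId, nrow(object@sessions),
              format(min(object@sessions$session_date)),
              format(max(object@sessions$session_date))))
})

setMethod("show", "Thresholds", function(object) {
  cat(sprintf(
    "Growth thresholds: >%.1f mm diameter, >%.1f cm^3 volume, >%.0f%% volume (equivocal band fraction %.2f)\n",
    object@diameterMM, object@volumeCM3, object@volumePct,
    object@equivocalFraction))
})
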