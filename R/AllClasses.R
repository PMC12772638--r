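#' @import methods
NULL

#' Labelled segmentation volume
#'
#' A 3D integer label volume in a canonical anatomical frame, holding the
#' intra-/extrameatal segmentation mask for one imaging session. Label 0 is
#' background, 1 the intrameatal compartment (inside the internal auditory
#' canal) and 2 the extrameatal compartment. After canonicalization the third
#' array axis is inferior-superior, so an "axial slice" is always a 2D section
#' across the third axis.
#'
#' @slot labels 3D integer array with values in \{0, 1, 2\}.
#' @slot spacing Numeric length-3 voxel spacing in mm along the array axes.
#' @slot orientation Anatomical frame tag of the stored array (always "RAS"
#'   after canonicalization).
#' @slot axialAxis Index of the inferior-superior axis (3 after
#'   canonicalization).
#'
#' @seealso [readLabeledVolume()], [measureSession()]
#' @export
setClass("LabeledVolume",
  representation(
    labels = "array",
    spacing = "numeric",
    orientation = "character",
    axialAxis = "integer"
  ),
  prototype(
    labels = array(0L, c(1L, 1L, 1L)),
    spacing = c(1, 1, 1),
    orientation = "RAS",
    axialAxis = 3L
  )
)

setValidity("LabeledVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "'labels' must be a 3D array")
  if (!is.integer(object@labels))
    msg <- c(msg, "'labels' must be an integer array")
  else if (!all(object@labels %in% c(0L, 1L, 2L)))
    msg <- c(msg, "unknown label: label values must be in {0, 1, 2}")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive finite values (mm)")
  if (!identical(object@axialAxis, 3L))
    msg <- c(msg, "'axialAxis' must be 3 (canonical frame)")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledVolume
#'
#' @param labels 3D array with values in \{0, 1, 2\} (numeric values within
#'   1e-6 of integers are rounded).
#' @param spacing Voxel spacing in mm, length 3 (recycled from length 1).
#' @param orientation Anatomical frame tag; the constructor assumes the array
#'   is already in the canonical frame (third axis inferior-superior).
#' @return A [LabeledVolume-class] object.
#' @export
LabeledVolume <- function(labels, spacing = c(1, 1, 1), orientation = "RAS") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!is.integer(labels)) {
    r <- round(labels)
    if (any(abs(labels - r) > 1e-6))
      stop("non-integer voxel values in label volume")
    labels <- array(as.integer(r), dim(labels))
  }
  new("LabeledVolume", labels = labels, spacing = as.numeric(spacing),
      orientation = orientation, axialAxis = 3L)
}

#' Maximum in-plane diameter on one axial slice
#'
#' @slot length Diameter in mm (0 for empty or single-pixel masks).
#' @slot sliceIndex Axial slice index the diameter was measured on (NA when
#'   the region is empty).
#' @slot endpointA,endpointB In-plane physical coordinates (mm) of the two
#'   pixel centres realising the diameter; NA when undefined.
#' @export
setClass("InPlaneDiameter",
  representation(
    length = "numeric",
    sliceIndex = "integer",
    endpointA = "numeric",
    endpointB = "numeric"
  ),
  prototype(
    length = 0, sliceIndex = NA_integer_,
    endpointA = c(NA_real_, NA_real_), endpointB = c(NA_real_, NA_real_)
  )
)

setValidity("InPlaneDiameter", function(object) {
  if (length(object@length) != 1L || (!is.na(object@length) && object@length < 0))
    return("'length' must be a single non-negative number")
  if (length(object@endpointA) != 2L || length(object@endpointB) != 2L)
    return("endpoints must have 2 in-plane coordinates")
  TRUE
})

#' Meatal axis estimated from the intra/extrameatal interface
#'
#' The in-plane principal direction of the voxels on the boundary between the
#' intrameatal and extrameatal compartments. `uPar` is the in-plane trace of
#' the porus plane (the direction along which the interface extends); `uPerp`
#' is orthogonal to it in-plane and points along the canal direction.
#'
#' @slot uPar In-plane unit vector, principal direction of the interface.
#' @slot uPerp In-plane unit vector orthogonal to `uPar`.
#' @slot nInterfaceVoxels Number of interface voxels the fit used.
#' @export
setClass("MeatalAxis",
  representation(
    uPar = "numeric",
    uPerp = "numeric",
    nInterfaceVoxels = "integer"
  )
)

setValidity("MeatalAxis", function(object) {
  if (length(object@uPar) != 2L || length(object@uPerp) != 2L)
    return("axis vectors must be in-plane (length 2)")
  if (abs(sqrt(sum(object@uPar^2)) - 1) > 1e-8 ||
      abs(sqrt(sum(object@uPerp^2)) - 1) > 1e-8)
    return("axis vectors must be unit length")
  if (abs(sum(object@uPar * object@uPerp)) > 1e-8)
    return("uPar and uPerp must be orthogonal")
  if (object@nInterfaceVoxels < 2L)
    return("a meatal axis needs at least 2 interface voxels")
  TRUE
})

#' Per-session measurement set
#'
#' All scalar measurements for one imaging session: the maximum in-plane
#' whole-tumour diameter (DWT), the maximum in-plane extrameatal diameter
#' (DEM, undefined for entirely intrameatal tumours), directional extents of
#' the two compartments relative to the meatal axis, compartment volumes, and
#' bookkeeping (slice counts, reference slice). Undefined quantities are NA.
#'
#' @slot dWT Maximum whole-tumour in-plane diameter, mm.
#' @slot dEM Maximum extrameatal in-plane diameter, mm, or NA.
#' @slot dIntraPar Intrameatal extent along the porus-plane trace (parallel
#'   direction), mm, or NA.
#' @slot dExtraPar Extrameatal extent along the parallel direction, mm, or NA.
#' @slot dExtraPerp Extrameatal extent along the canal (perpendicular)
#'   direction, mm, or NA.
#' @slot vIntra,vExtra,vWhole Compartment and whole-tumour volumes, cm^3.
#' @slot nAxialSlices Number of axial slices containing any tumour label.
#' @slot referenceSlice Axial slice index of the whole-tumour maximum
#'   diameter (NA for empty masks).
#' @slot entirelyIntrameatal TRUE when no extrameatal compartment exists.
#' @slot diamWhole,diamExtra [InPlaneDiameter-class] detail for the two
#'   regions (endpoints, slice) used for report rendering.
#' @export
setClass("SessionMeasurements",
  representation(
    dWT = "numeric", dEM = "numeric",
    dIntraPar = "numeric", dExtraPar = "numeric", dExtraPerp = "numeric",
    vIntra = "numeric", vExtra = "numeric", vWhole = "numeric",
    nAxialSlices = "integer", referenceSlice = "integer",
    entirelyIntrameatal = "logical",
    diamWhole = "InPlaneDiameter", diamExtra = "InPlaneDiameter"
  )
)

setValidity("SessionMeasurements", function(object) {
  msg <- character()
  vols <- c(object@vIntra, object@vExtra, object@vWhole)
  if (any(is.na(vols)) || any(vols < 0))
    msg <- c(msg, "volumes must be non-negative")
  if (abs(object@vWhole - (object@vIntra + object@vExtra)) > 1e-9)
    msg <- c(msg, "vWhole must equal vIntra + vExtra")
  if (!is.na(object@dWT) && object@dWT < 0)
    msg <- c(msg, "diameters must be non-negative")
  if (!is.na(object@dEM) && !is.na(object@dWT) && object@dEM > object@dWT + 1e-9)
    msg <- c(msg, "dWT must be >= dEM")
  if (object@entirelyIntrameatal != (object@vExtra == 0))
    msg <- c(msg, "entirelyIntrameatal must match vExtra == 0")
  if (object@entirelyIntrameatal && !is.na(object@dEM))
    msg <- c(msg, "dEM must be NA for entirely intrameatal tumours")
  if (length(msg)) msg else TRUE
})

#' Construct a SessionMeasurements object directly
#'
#' Mostly useful for threshold sweeps and tests; pipeline code obtains
#' measurements from [measureSession()].
#'
#' @param dWT,dEM,dIntraPar,dExtraPar,dExtraPerp Diameters/extents in mm
#'   (NA = undefined).
#' @param vIntra,vExtra Compartment volumes in cm^3; `vWhole` is their sum.
#' @param nAxialSlices,referenceSlice Slice bookkeeping.
#' @param diamWhole,diamExtra Optional [InPlaneDiameter-class] details.
#' @return A [SessionMeasurements-class] object.
#' @export
SessionMeasurements <- function(dWT = 0, dEM = NA_real_,
                                dIntraPar = NA_real_, dExtraPar = NA_real_,
                                dExtraPerp = NA_real_,
                                vIntra = 0, vExtra = 0,
                                nAxialSlices = 0L,
                                referenceSlice = NA_integer_,
                                diamWhole = new("InPlaneDiameter"),
                                diamExtra = new("InPlaneDiameter")) {
  new("SessionMeasurements",
      dWT = as.numeric(dWT), dEM = as.numeric(dEM),
      dIntraPar = as.numeric(dIntraPar), dExtraPar = as.numeric(dExtraPar),
      dExtraPerp = as.numeric(dExtraPerp),
      vIntra = as.numeric(vIntra), vExtra = as.numeric(vExtra),
      vWhole = as.numeric(vIntra) + as.numeric(vExtra),
      nAxialSlices = as.integer(nAxialSlices),
      referenceSlice = as.integer(referenceSlice),
      entirelyIntrameatal = (vExtra == 0),
      diamWhole = diamWhole, diamExtra = diamExtra)
}

#' Which diameter is displayed to the clinical team
#'
#' @slot chosen "DWT" (whole tumour) or "DEM" (extrameatal).
#' @slot value The displayed diameter in mm.
#' @slot branch Which rule produced the choice: "postoperative",
#'   "entirely_intrameatal", "intra_dominant", "extra_perp_gt2",
#'   "extra_perp_le2" or "axis_unavailable".
#' @slot axisAvailable FALSE when an extrameatal compartment exists but no
#'   meatal axis could be estimated (choice falls back to DWT).
#' @export
setClass("DiameterChoice",
  representation(
    chosen = "character",
    value = "numeric",
    branch = "character",
    axisAvailable = "logical"
  )
)

.diameterBranches <- c("postoperative", "entirely_intrameatal",
                       "intra_dominant", "extra_perp_gt2", "extra_perp_le2",
                       "axis_unavailable")

setValidity("DiameterChoice", function(object) {
  if (!object@chosen %in% c("DWT", "DEM"))
    return("'chosen' must be DWT or DEM")
  if (!object@branch %in% .diameterBranches)
    return(sprintf("unknown branch '%s'", object@branch))
  if (object@chosen == "DEM" && object@branch != "extra_perp_gt2")
    return("DEM can only be chosen via the extra_perp_gt2 branch")
  TRUE
})

#' Growth classification thresholds
#'
#' The EAONO significant-growth criteria: a >2 mm diameter increase, a
#' >1.2 cm^3 volume change, or a >20% volume change. The equivocal band is
#' this package's configurable addition: a change larger than
#' `equivocalFraction` times a threshold, but not past it, is reported as
#' equivocal rather than no growth.
#'
#' @slot diameterMM Diameter increase threshold, mm.
#' @slot volumeCM3 Absolute volume change threshold, cm^3.
#' @slot volumePct Relative volume change threshold, percent.
#' @slot equivocalFraction Fraction of each threshold above which a change is
#'   equivocal, in (0, 1).
#' @export
setClass("Thresholds",
  representation(
    diameterMM = "numeric",
    volumeCM3 = "numeric",
    volumePct = "numeric",
    equivocalFraction = "numeric"
  ),
  prototype(diameterMM = 2.0, volumeCM3 = 1.2, volumePct = 20.0,
            equivocalFraction = 0.5)
)

setValidity("Thresholds", function(object) {
  v <- c(object@diameterMM, object@volumeCM3, object@volumePct)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all thresholds must be positive")
  f <- object@equivocalFraction
  if (!is.finite(f) || f <= 0 || f >= 1)
    return("'equivocalFraction' must lie in (0, 1)")
  TRUE
})

#' Construct growth thresholds
#'
#' @param diameterMM Diameter increase threshold in mm (default 2).
#' @param volumeCM3 Absolute volume change threshold in cm^3 (default 1.2).
#' @param volumePct Relative volume change threshold in percent (default 20).
#' @param equivocalFraction Equivocal band fraction in (0, 1) (default 0.5).
#' @return A [Thresholds-class] object.
#' @export
vsThresholds <- function(diameterMM = 2.0, volumeCM3 = 1.2, volumePct = 20.0,
                         equivocalFraction = 0.5) {
  new("Thresholds", diameterMM = diameterMM, volumeCM3 = volumeCM3,
      volumePct = volumePct, equivocalFraction = equivocalFraction)
}

#' Growth assessment between two sessions
#'
#' @slot status One of "growth", "equivocal", "no_growth", "reduction",
#'   "not_assessable".
#' @slot deltaD Change in the displayed diameter, mm.
#' @slot deltaV Change in whole-tumour volume, cm^3.
#' @slot deltaVPct Relative whole-tumour volume change, percent (NA when the
#'   baseline volume is zero).
#' @slot triggeredBy Which criteria fired: subset of "diameter",
#'   "volume_abs", "volume_pct".
#' @slot comparison "index_vs_latest", "penultimate_vs_latest" or
#'   "consecutive".
#' @slot basisSwitched TRUE when the two sessions displayed different
#'   diameter types and the delta was computed on DWT for both.
#' @slot from,to Session indices (1-based within the timeline) compared.
#' @export
setClass("GrowthAssessment",
  representation(
    status = "character",
    deltaD = "numeric",
    deltaV = "numeric",
    deltaVPct = "numeric",
    triggeredBy = "character",
    comparison = "character",
    basisSwitched = "logical",
    from = "integer",
    to = "integer"
  ),
  prototype(status = "not_assessable", deltaD = NA_real_, deltaV = NA_real_,
            deltaVPct = NA_real_, triggeredBy = character(),
            comparison = "consecutive", basisSwitched = FALSE,
            from = NA_integer_, to = NA_integer_)
)

setValidity("GrowthAssessment", function(object) {
  if (!object@status %in% c("growth", "equivocal", "no_growth", "reduction",
                            "not_assessable"))
    return(sprintf("unknown status '%s'", object@status))
  if (!all(object@triggeredBy %in% c("diameter", "volume_abs", "volume_pct")))
    return("unknown trigger")
  if (!object@comparison %in% c("index_vs_latest", "penultimate_vs_latest",
                                "consecutive"))
    return("unknown comparison tag")
  if (object@status == "growth" && length(object@triggeredBy) == 0L)
    return("growth status requires at least one triggered criterion")
  TRUE
})

#' Ordered surveillance timeline for one patient
#'
#' @slot patientId Patient identifier.
#' @slot sessions data.frame with one row per imaging session, ordered by
#'   date, with columns `session_date` (Date), `months_since_index`,
#'   `operative_status` ("preoperative", "postoperative" or "post-SRS"),
#'   `mask_path`, `image_path` (NA allowed) and `decision_label` (NA
#'   allowed).
#' @export
setClass("PatientTimeline",
  representation(patientId = "character", sessions = "data.frame")
)

.timelineCols <- c("session_date", "months_since_index", "operative_status",
                   "mask_path", "image_path", "decision_label")

setValidity("PatientTimeline", function(object) {
  s <- object@sessions
  if (!all(.timelineCols %in% names(s)))
    return(sprintf("sessions must have columns: %s",
                   paste(.timelineCols, collapse = ", ")))
  if (nrow(s) < 1L)
    return("a timeline needs at least one session")
  d <- s$session_date
  if (anyNA(d)) return("unparseable session date")
  if (is.unsorted(d, strictly = TRUE))
    return("session dates must be strictly increasing")
  m <- s$months_since_index
  if (any(m < 0) || abs(m[1L]) > 1e-9)
    return("months_since_index must be >= 0 and 0 at the index session")
  if (!all(s$operative_status %in% c("preoperative", "postoperative",
                                     "post-SRS")))
    return("operative_status must be preoperative, postoperative or post-SRS")
  TRUE
})

#' Report specification
#'
#' The fully resolved, render-ready content of a patient's summary report:
#' one panel per session (axial snapshot at the displayed-diameter slice with
#' the mask and diameter endpoints, the displayed diameter value, volumes or
#' a suppression marker), the stacked intra-/extrameatal volume bar chart,
#' the diameter line chart against months, a colour per session-to-session
#' change (growth red, equivocal orange, no growth/reduction green), decision
#' icons and a legend. Building the spec is a pure function of measured,
#' assessed inputs: no re-measurement happens in the report layer.
#'
#' @slot patientId Patient identifier.
#' @slot styleVersion Version tag of the fixed report style sheet.
#' @slot panels List with one entry per session (slice matrix, endpoints,
#'   values; see [buildReportSpec()]).
#' @slot months Numeric months-since-index per session.
#' @slot colors Per-session colour, in \{"red", "orange", "green"\}.
#' @slot decisions Per-session decision label (NA when none).
#' @slot barIntra,barExtra Per-session compartment volumes (cm^3) for the bar
#'   chart.
#' @slot lineValues,lineTypes Displayed diameter values (mm) and types
#'   ("DWT"/"DEM") for the line chart.
#' @slot suppressed Per-session volume-suppression flags.
#' @slot headline List with the two headline [GrowthAssessment-class]
#'   objects (index vs latest, penultimate vs latest).
#' @slot notes Character notes rendered under the legend.
#' @export
setClass("ReportSpec",
  representation(
    patientId = "character",
    styleVersion = "character",
    panels = "list",
    months = "numeric",
    colors = "character",
    decisions = "character",
    barIntra = "numeric",
    barExtra = "numeric",
    lineValues = "numeric",
    lineTypes = "character",
    suppressed = "logical",
    headline = "list",
    notes = "character"
  )
)

setValidity("ReportSpec", function(object) {
  n <- length(object@panels)
  if (length(object@months) != n || length(object@colors) != n ||
      length(object@suppressed) != n || length(object@lineValues) != n)
    return("per-session fields must all have one entry per panel")
  if (!all(object@colors %in% c("red", "orange", "green")))
    return("panel colours must be red, orange or green")
  TRUE
})

#' Analytic ground truth for a phantom
#'
#' @slot dWT,dEM Analytic maximum in-plane diameters, mm (dEM is NA for
#'   entirely intrameatal phantoms).
#' @slot vIntra,vExtra Analytic compartment volumes, cm^3.
#' @slot uPar True in-plane porus-plane trace direction (unit vector).
#' @slot params The [phantomParams()] list the phantom was built from.
#' @export
setClass("PhantomTruth",
  representation(
    dWT = "numeric", dEM = "numeric",
    vIntra = "numeric", vExtra = "numeric",
    uPar = "numeric",
    params = "list"
  )
)
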