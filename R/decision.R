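#' Choose the diameter displayed to the clinical team
#'
#' One diameter is shown per session, chosen from the maximum whole-tumour
#' diameter (DWT) and the maximum extrameatal diameter (DEM):
#' \itemize{
#'   \item postoperative or post-SRS sessions always display DWT;
#'   \item preoperative, entirely intrameatal tumours display DWT (the
#'     intrameatal region is the whole tumour);
#'   \item otherwise the directional extents decide: if the intrameatal
#'     extent along the porus-plane trace is at least the extrameatal one
#'     (`dIntraPar >= dExtraPar`), DWT; else DEM if the extrameatal extent
#'     along the canal direction exceeds 2 mm (`dExtraPerp > 2`), DWT
#'     otherwise.
#' }
#' When an extrameatal compartment exists but the meatal axis (and hence the
#' extents) is unavailable, the choice falls back to DWT with
#' `axisAvailable = FALSE`.
#'
#' @param m A [SessionMeasurements-class] from [measureSession()].
#' @param status Operative status: "preoperative", "postoperative" or
#'   "post-SRS".
#' @return A [DiameterChoice-class].
#' @export
selectDisplayDiameter <- function(m,
    status = c("preoperative", "postoperative", "post-SRS")) {
  stopifnot(is(m, "SessionMeasurements"))
  status <- match.arg(status)
  mk <- function(chosen, value, branch, axisAvailable = TRUE)
    new("DiameterChoice", chosen = chosen, value = value, branch = branch,
        axisAvailable = axisAvailable)
  if (status != "preoperative")
    return(mk("DWT", m@dWT, "postoperative"))
  if (m@entirelyIntrameatal)
    return(mk("DWT", m@dWT, "entirely_intrameatal"))
  if (is.na(m@dIntraPar) || is.na(m@dExtraPar) || is.na(m@dExtraPerp))
    return(mk("DWT", m@dWT, "axis_unavailable", axisAvailable = FALSE))
  if (m@dIntraPar >= m@dExtraPar)
    mk("DWT", m@dWT, "intra_dominant")
  else if (m@dExtraPerp > 2)
    mk("DEM", m@dEM, "extra_perp_gt2")
  else
    mk("DWT", m@dWT, "extra_perp_le2")
}

#' Classify growth between two sessions
#'
#' Applies the EAONO significant-growth criteria to the change between a
#' baseline and a follow-up session: growth when the displayed diameter
#' increased by more than `diameterMM` (default 2 mm), or the whole-tumour
#' volume by more than `volumeCM3` (default 1.2 cm^3), or by more than
#' `volumePct` (default 20%) - all strict inequalities. Mirrored decreases of
#' the same magnitudes give "reduction". Otherwise, any change whose
#' magnitude exceeds `equivocalFraction` times its threshold gives
#' "equivocal", else "no_growth".
#'
#' The diameter delta is computed on the displayed diameter. When the two
#' sessions display different diameter types (e.g. DEM then DWT), serial
#' values are not comparable, so the delta is computed on DWT for both and
#' the assessment is flagged (`basisSwitched`). The volume criteria always
#' use the whole-tumour volume; the percentage is undefined (and never
#' triggers) when the baseline volume is zero.
#'
#' @param baseline,follow [SessionMeasurements-class] for the two sessions.
#' @param baselineChoice,followChoice Optional [DiameterChoice-class] per
#'   session; when omitted the delta is computed on DWT.
#' @param thresholds A [Thresholds-class] (default [vsThresholds()]).
#' @param comparison Tag: "consecutive", "index_vs_latest" or
#'   "penultimate_vs_latest".
#' @param from,to Optional session indices recorded in the result.
#' @return A [GrowthAssessment-class].
#' @export
assessGrowth <- function(baseline, follow,
                         baselineChoice = NULL, followChoice = NULL,
                         thresholds = vsThresholds(),
                         comparison = "consecutive",
                         from = NA_integer_, to = NA_integer_) {
  stopifnot(is(baseline, "SessionMeasurements"),
            is(follow, "SessionMeasurements"),
            is(thresholds, "Thresholds"))
  basisSwitched <- FALSE
  if (!is.null(baselineChoice) && !is.null(followChoice) &&
      baselineChoice@chosen == followChoice@chosen) {
    deltaD <- followChoice@value - baselineChoice@value
  } else {
    basisSwitched <- !is.null(baselineChoice) && !is.null(followChoice)
    deltaD <- follow@dWT - baseline@dWT
  }
  deltaV <- follow@vWhole - baseline@vWhole
  deltaVPct <- if (baseline@vWhole > 0) 100 * deltaV / baseline@vWhole
               else NA_real_

  th <- c(diameter = thresholds@diameterMM,
          volume_abs = thresholds@volumeCM3,
          volume_pct = thresholds@volumePct)
  deltas <- c(diameter = deltaD, volume_abs = deltaV, volume_pct = deltaVPct)
  up <- !is.na(deltas) & deltas > th
  down <- !is.na(deltas) & deltas < -th
  f <- thresholds@equivocalFraction
  band <- !is.na(deltas) & abs(deltas) > f * th

  status <- if (any(up)) "growth"
            else if (any(down)) "reduction"
            else if (any(band)) "equivocal"
            else "no_growth"
  triggered <- names(deltas)[if (any(up)) up else if (any(down)) down
                             else rep(FALSE, 3L)]
  new("GrowthAssessment", status = status,
      deltaD = deltaD, deltaV = deltaV, deltaVPct = deltaVPct,
      triggeredBy = triggered, comparison = comparison,
      basisSwitched = basisSwitched,
      from = as.integer(from), to = as.integer(to))
}

#' Assess growth across a surveillance timeline
#'
#' Computes the per-session display-diameter choices, every consecutive-pair
#' growth assessment (used for per-session report colouring), and the two
#' headline assessments used when preparing the multidisciplinary team
#' meeting: index vs most recent, and second-most-recent vs most recent.
#' With fewer than two sessions all statuses are "not_assessable"; with
#' exactly two, the two headline comparisons coincide.
#'
#' @param timeline A [PatientTimeline-class].
#' @param measurements List of [SessionMeasurements-class], one per session
#'   in timeline order.
#' @param thresholds A [Thresholds-class] (default [vsThresholds()]).
#' @return A list with elements `choices` (list of
#'   [DiameterChoice-class]), `consecutive` (list of n-1
#'   [GrowthAssessment-class]), `indexVsLatest` and `penultimateVsLatest`
#'   (each a [GrowthAssessment-class]).
#' @export
assessTimeline <- function(timeline, measurements,
                           thresholds = vsThresholds()) {
  stopifnot(is(timeline, "PatientTimeline"))
  n <- nrow(timeline@sessions)
  stopifnot(length(measurements) == n, n >= 1L)
  statuses <- timeline@sessions$operative_status
  choices <- lapply(seq_len(n), function(i)
    selectDisplayDiameter(measurements[[i]], statuses[i]))
  if (n < 2L) {
    na <- new("GrowthAssessment", status = "not_assessable",
              comparison = "index_vs_latest", from = 1L, to = 1L)
    nb <- na; nb@comparison <- "penultimate_vs_latest"
    return(list(choices = choices, consecutive = list(),
                indexVsLatest = na, penultimateVsLatest = nb))
  }
  pair <- function(i, j, tag)
    assessGrowth(measurements[[i]], measurements[[j]],
                 choices[[i]], choices[[j]], thresholds,
                 comparison = tag, from = i, to = j)
  consecutive <- lapply(seq_len(n - 1L), function(i)
    pair(i, i + 1L, "consecutive"))
  list(choices = choices,
       consecutive = consecutive,
       indexVsLatest = pair(1L, n, "index_vs_latest"),
       penultimateVsLatest = pair(n - 1L, n, "penultimate_vs_latest"))
}
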