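#' Phantom parameters
#'
#' Parameters of the synthetic two-compartment vestibular-schwannoma phantom:
#' an intrameatal cylinder of length `intraLength` and radius `intraRadius`
#' lying along the canal direction (at `canalAngle` degrees in-plane), cut
#' flat at the porus plane, joined there to an extrameatal half-ellipsoid
#' with semi-axes `extraAxes` (along the canal direction, along the
#' porus-plane trace, and along the axial direction). Setting `extraAxes` to
#' zero produces an entirely intrameatal tumour. `jitter` adds seeded smooth
#' surface noise (mm amplitude) emulating segmentation-boundary variability.
#'
#' Defaults emulate a moderate-size tumour on a high-resolution surveillance
#' scan: 0.5 mm isotropic voxels, a 10 x 3 mm canal portion at 30 degrees,
#' and a 9 x 6 x 5 mm extrameatal half-ellipsoid.
#'
#' @param spacing Voxel spacing in mm (length 1 or 3).
#' @param canalAngle In-plane canal direction, degrees.
#' @param intraLength,intraRadius Intrameatal cylinder length and radius, mm.
#' @param extraAxes Extrameatal half-ellipsoid semi-axes, mm (length 3).
#' @param porusOffset Shift of the ellipsoid centre along the canal
#'   direction from the porus plane, mm.
#' @param jitter Surface noise amplitude, mm (must stay below the smallest
#'   radius; 0 disables it and makes the ground truth exact).
#' @param seed Integer seed controlling all phantom randomness.
#' @param margin Empty margin around the shape, mm.
#' @return A named list of validated phantom parameters.
#' @export
phantomParams <- function(spacing = c(0.5, 0.5, 0.5), canalAngle = 30,
                          intraLength = 10, intraRadius = 3,
                          extraAxes = c(9, 6, 5), porusOffset = 0,
                          jitter = 0, seed = 1L, margin = 3) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0),
            intraLength >= 0, intraRadius >= 0,
            length(extraAxes) == 3L, all(extraAxes >= 0),
            jitter >= 0, margin >= 0)
  radii <- c(intraRadius, extraAxes)
  radii <- radii[radii > 0]
  if (jitter > 0 && length(radii) && jitter >= min(radii))
    stop("'jitter' must be smaller than the smallest radius")
  list(spacing = as.numeric(spacing), canalAngle = canalAngle,
       intraLength = intraLength, intraRadius = intraRadius,
       extraAxes = as.numeric(extraAxes), porusOffset = porusOffset,
       jitter = jitter, seed = as.integer(seed), margin = margin)
}

# Continuous z=0 cross-section extreme points of the phantom, in world mm
# coordinates (porus at the origin). Used for analytic diameters.
.phantomSection <- function(p, nArc = 1440L) {
  th <- p$canalAngle * pi / 180
  u <- c(cos(th), sin(th))   # canal direction (towards extrameatal side)
  tr <- c(-sin(th), cos(th)) # porus-plane trace
  toWorld <- function(pu, pt) cbind(pu * u[1] + pt * tr[1],
                                    pu * u[2] + pt * tr[2])
  a <- p$extraAxes[1]; b <- p$extraAxes[2]
  em <- NULL
  if (a > 0 && b > 0) {
    phi <- seq(-pi / 2, pi / 2, length.out = nArc + 1L)
    em <- toWorld(p$porusOffset + a * cos(phi), b * sin(phi))
  }
  wt <- em
  if (p$intraLength > 0 && p$intraRadius > 0) {
    r <- p$intraRadius; L <- p$intraLength
    corners <- toWorld(c(-L, -L, 0, 0), c(-r, r, -r, r))
    wt <- rbind(wt, corners)
  }
  list(u = u, trace = tr, em = em, wt = wt)
}

.maxPairDist <- function(P) {
  if (is.null(P) || nrow(P) < 2L) return(0)
  max(stats::dist(P))
}

#' Generate a phantom label volume with analytic ground truth
#'
#' Voxelizes the two-compartment phantom described by [phantomParams()] on a
#' grid just covering the shape plus its margin. Voxel centres inside the
#' intrameatal cylinder (canal side of the porus plane) get label 1, those
#' inside the extrameatal half-ellipsoid (far side) label 2; the two regions
#' are disjoint by construction. Output is deterministic given the seed.
#'
#' Ground truth (exact for `jitter = 0`): compartment volumes by closed form
#' (pi r^2 L and 2/3 pi abc), the porus-plane trace direction, and maximum
#' in-plane diameters from densely sampled boundary points of the continuous
#' central cross-section.
#'
#' @param p Parameter list from [phantomParams()].
#' @return A list with elements `volume` (a [LabeledVolume-class]) and
#'   `truth` (a [PhantomTruth-class]).
#' @export
makePhantom <- function(p = phantomParams()) {
  sec <- .phantomSection(p)
  u <- sec$u; tr <- sec$trace
  a <- p$extraAxes[1]; b <- p$extraAxes[2]; cz <- p$extraAxes[3]
  r <- p$intraRadius; L <- p$intraLength
  j <- p$jitter

  # world-space bounding box from the (u, trace, z) boxes of the two shapes
  boxes <- list()
  if (L > 0 && r > 0)
    boxes$cyl <- list(pu = c(-L, 0), pt = c(-r, r), z = c(-r, r))
  if (a > 0 && b > 0 && cz > 0)
    boxes$ell <- list(pu = p$porusOffset + c(-a, a), pt = c(-b, b),
                      z = c(-cz, cz))
  if (!length(boxes))
    stop("phantom is empty: no positive compartment dimensions")
  cornersXY <- do.call(rbind, lapply(boxes, function(bx) {
    g <- expand.grid(pu = bx$pu, pt = bx$pt)
    cbind(g$pu * u[1] + g$pt * tr[1], g$pu * u[2] + g$pt * tr[2])
  }))
  zr <- range(unlist(lapply(boxes, `[[`, "z")))
  lo <- c(min(cornersXY[, 1]), min(cornersXY[, 2]), zr[1]) - p$margin - j
  hi <- c(max(cornersXY[, 1]), max(cornersXY[, 2]), zr[2]) + p$margin + j
  nd <- pmax(1L, as.integer(ceiling((hi - lo) / p$spacing)) + 1L)
  xs <- lo[1] + (seq_len(nd[1]) - 1) * p$spacing[1]
  ys <- lo[2] + (seq_len(nd[2]) - 1) * p$spacing[2]
  zs <- lo[3] + (seq_len(nd[3]) - 1) * p$spacing[3]

  X <- matrix(xs, nd[1], nd[2])
  Y <- matrix(ys, nd[1], nd[2], byrow = TRUE)
  PU <- X * u[1] + Y * u[2]
  PT <- X * tr[1] + Y * tr[2]

  noise <- NULL
  if (j > 0) {
    K <- 6L
    noise <- withr::with_seed(p$seed, {
      dirs <- matrix(stats::rnorm(3L * K), K, 3L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      list(w = dirs * stats::runif(K, 0.2, 0.8),
           phi = stats::runif(K, 0, 2 * pi))
    })
  }
  etaAt <- function(z) {
    if (is.null(noise)) return(0)
    acc <- matrix(0, nd[1], nd[2])
    for (k in seq_len(nrow(noise$w)))
      acc <- acc + cos(noise$w[k, 1] * X + noise$w[k, 2] * Y +
                       noise$w[k, 3] * z + noise$phi[k])
    j * acc / nrow(noise$w)
  }

  lab <- array(0L, nd)
  minAx <- min(c(a, b, cz)[c(a, b, cz) > 0], Inf)
  for (k in seq_len(nd[3])) {
    z <- zs[k]
    eta <- etaAt(z)
    sl <- matrix(0L, nd[1], nd[2])
    if (!is.null(boxes$cyl)) {
      inCyl <- PU >= -L & PU <= 0 & (PT^2 + z^2) <= (r + eta)^2
      sl[inCyl] <- 1L
    }
    if (!is.null(boxes$ell)) {
      q <- ((PU - p$porusOffset) / a)^2 + (PT / b)^2 + (z / cz)^2
      inEll <- PU > 0 & sqrt(q) <= 1 + eta / minAx
      sl[inEll] <- 2L
    }
    lab[, , k] <- sl
  }

  vIntra <- if (is.null(boxes$cyl)) 0 else pi * r^2 * L / 1000
  vExtra <- if (is.null(boxes$ell)) 0 else (2 / 3) * pi * a * b * cz / 1000
  uPar <- tr
  if (uPar[1] < 0 || (uPar[1] == 0 && uPar[2] < 0)) uPar <- -uPar
  truth <- new("PhantomTruth",
               dWT = .maxPairDist(sec$wt),
               dEM = if (is.null(sec$em)) NA_real_ else .maxPairDist(sec$em),
               vIntra = vIntra, vExtra = vExtra,
               uPar = uPar, params = p)
  list(volume = LabeledVolume(lab, spacing = p$spacing), truth = truth)
}

.scaleParams <- function(p, s) {
  q <- p
  q$intraLength <- p$intraLength * s
  q$intraRadius <- p$intraRadius * s
  q$extraAxes <- p$extraAxes * s
  q$porusOffset <- p$porusOffset * s
  q
}

#' Generate a longitudinal phantom series on disk
#'
#' Builds one phantom per session by scaling every linear dimension of the
#' base phantom by the session's scale factor (so volumes scale with the
#' factor cubed), writes the NIfTI masks and a CSV manifest consumable by
#' [readTimelineManifest()], and records the analytic ground truth per
#' session.
#'
#' @param p Base [phantomParams()] (session 1 uses `scales[1]`).
#' @param scales Numeric scale factors, one per session.
#' @param dates Session dates (Date or "YYYY-MM-DD" character), one per
#'   session, strictly increasing.
#' @param statuses Operative status per session (default "preoperative").
#' @param decisions Optional decision label per session (e.g. "surveillance",
#'   "SRS"); NA omits the icon.
#' @param dir Output directory (created if needed).
#' @param patientId Patient identifier used in file names and the manifest.
#' @return A list with `manifest` (path to the manifest CSV), `truth` (a
#'   data.frame of per-session analytic truth) and `dir`.
#' @export
makePhantomTimeline <- function(p = phantomParams(), scales, dates,
                                statuses = NULL, decisions = NULL,
                                dir = tempfile("phantom"),
                                patientId = "PHANTOM01") {
  stopifnot(length(scales) == length(dates), length(scales) >= 1L)
  dates <- as.Date(dates)
  if (anyNA(dates) || is.unsorted(dates, strictly = TRUE))
    stop("'dates' must be parseable and strictly increasing")
  n <- length(scales)
  if (is.null(statuses)) statuses <- rep("preoperative", n)
  if (is.null(decisions)) decisions <- rep(NA_character_, n)
  stopifnot(length(statuses) == n, length(decisions) == n)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- makePhantom(.scaleParams(p, scales[i]))
    fn <- sprintf("%s_s%02d.nii.gz", patientId, i)
    writeLabeledVolume(ph$volume, file.path(dir, fn))
    rows[[i]] <- data.frame(patient_id = patientId,
                            date = format(dates[i]),
                            status = statuses[i],
                            mask_path = fn,
                            image_path = NA_character_,
                            decision = decisions[i],
                            stringsAsFactors = FALSE)
    tt <- ph$truth
    truth[[i]] <- data.frame(session = i, scale = scales[i],
                             date = format(dates[i]),
                             d_wt_mm = tt@dWT, d_em_mm = tt@dEM,
                             v_intra_cm3 = tt@vIntra,
                             v_extra_cm3 = tt@vExtra,
                             v_whole_cm3 = tt@vIntra + tt@vExtra,
                             u_par_x = tt@uPar[1], u_par_y = tt@uPar[2],
                             stringsAsFactors = FALSE)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  truthDf <- do.call(rbind, truth)
  utils::write.csv(truthDf, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  list(manifest = manifest, truth = truthDf, dir = dir)
}
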