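# Shift a logical 3D array by one voxel along an axis, padding with FALSE.
.shift3 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (by > 0) {
    dst[[axis]] <- seq_len(d[axis] - by) + by
    src[[axis]] <- seq_len(d[axis] - by)
  } else {
    dst[[axis]] <- seq_len(d[axis] + by)
    src[[axis]] <- seq_len(d[axis] + by) - by
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 26-connected component labelling of a logical 3D mask. Returns the
# component membership for each foreground voxel (in `which(mask)` order)
# together with the foreground indices.
.components26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L)
    return(list(idx = idx, membership = integer(), sizes = integer()))
  id <- array(0L, d)
  id[idx] <- seq_len(n)
  ai <- arrayInd(idx, d)
  # 13 half-shifts cover all 26 neighbours once
  shifts <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  lex <- shifts[, 1] * 9 + shifts[, 2] * 3 + shifts[, 3]
  shifts <- shifts[lex > 0, , drop = FALSE]
  edges <- vector("list", nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    ni <- ai[, 1] + shifts[s, 1]
    nj <- ai[, 2] + shifts[s, 2]
    nk <- ai[, 3] + shifts[s, 3]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] & nk >= 1L & nk <= d[3]
    nb <- integer(n)
    nb[ok] <- id[cbind(ni[ok], nj[ok], nk[ok])]
    hit <- nb > 0L
    if (any(hit)) edges[[s]] <- cbind(which(hit), nb[hit])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(em)) g <- igraph::add_edges(g, t(em))
  cl <- igraph::components(g)
  list(idx = idx, membership = as.integer(cl$membership),
       sizes = as.integer(cl$csize))
}

#' Keep the dominant connected component of a mask
#'
#' Removes satellite components from a segmentation: the largest 26-connected
#' component of the whole-tumour (label > 0) mask is kept with its labels
#' intact; all other components are removed, as is the largest itself if it
#' holds fewer than `minVoxels` voxels. Ties between equal-sized components
#' are broken towards the component with the lexicographically smallest voxel
#' centroid.
#'
#' @param x A [LabeledVolume-class].
#' @param minVoxels Minimum component size in voxels (default 5).
#' @return A cleaned [LabeledVolume-class]. An empty mask passes through
#'   empty.
#' @rdname cleanMask
#' @export
setMethod("cleanMask", "LabeledVolume", function(x, minVoxels = 5L) {
  comp <- .components26(x@labels > 0L)
  if (length(comp$membership) == 0L) return(x)
  keepable <- which(comp$sizes >= minVoxels)
  out <- array(0L, dim(x@labels))
  if (length(keepable)) {
    big <- keepable[comp$sizes[keepable] == max(comp$sizes[keepable])]
    if (length(big) > 1L) {
      cents <- t(vapply(big, function(cc) {
        colMeans(arrayInd(comp$idx[comp$membership == cc], dim(x@labels)))
      }, numeric(3)))
      ord <- do.call(order, as.data.frame(cents))
      big <- big[ord[1L]]
    }
    keep <- comp$idx[comp$membership == big]
    out[keep] <- x@labels[keep]
  }
  new("LabeledVolume", labels = out, spacing = x@spacing,
      orientation = x@orientation, axialAxis = 3L)
})

# Drop hull vertices that are not strictly convex (chull may return
# collinear vertices, which break the antipodal advance). Removing a
# collinear vertex never removes a diameter endpoint: it lies between its
# neighbours, so either neighbour is at least as far from any other point.
.pruneCollinear <- function(H) {
  repeat {
    m <- nrow(H)
    if (m < 3L) return(H)
    prv <- c(m, seq_len(m - 1L))
    nxt <- c(seq_len(m - 1L) + 1L, 1L)
    cr <- (H[, 1] - H[prv, 1]) * (H[nxt, 2] - H[, 2]) -
          (H[, 2] - H[prv, 2]) * (H[nxt, 1] - H[, 1])
    tol <- 1e-12 * max(1, max(abs(H))^2)
    if (all(cr > tol)) return(H)
    H <- H[cr > tol, , drop = FALSE]
  }
}

# Maximum pairwise distance over the ordered vertices of a convex hull by
# rotating calipers (antipodal pairs). H must be the hull vertices in
# counter-clockwise order.
.rotatingCalipers <- function(H) {
  m <- nrow(H)
  d2 <- function(a, b) sum((H[a, ] - H[b, ])^2)
  if (m == 1L) return(list(d = 0, a = 1L, b = 1L))
  if (m == 2L) return(list(d = sqrt(d2(1L, 2L)), a = 1L, b = 2L))
  nxt <- function(i) if (i == m) 1L else i + 1L
  # twice the signed area of triangle (a, b, c)
  tri <- function(a, b, c)
    (H[b, 1] - H[a, 1]) * (H[c, 2] - H[a, 2]) -
    (H[b, 2] - H[a, 2]) * (H[c, 1] - H[a, 1])
  best <- 0; ba <- 1L; bb <- 1L
  upd <- function(a, b) {
    dd <- d2(a, b)
    if (dd > best) { best <<- dd; ba <<- a; bb <<- b }
  }
  j <- 2L
  for (i in seq_len(m)) {
    i2 <- nxt(i)
    # advance j to the vertex farthest from edge (i, i2), checking every
    # vertex passed on the way: on parallel-edge ties the far chain holds
    # several antipodal partners and the sweep must not skip them
    repeat {
      upd(i, j); upd(i2, j)
      j2 <- nxt(j)
      if (tri(i, i2, j2) > tri(i, i2, j)) j <- j2 else break
    }
    upd(i, nxt(j))
  }
  list(d = sqrt(best), a = ba, b = bb)
}

#' Maximum in-plane diameter of a 2D mask
#'
#' The maximum Euclidean distance between the centres of any two foreground
#' pixels, computed over the convex hull of the pixel-centre coordinates by
#' rotating calipers. Coordinates follow the pixel-centre convention:
#' pixel (i, j) sits at ((i-1) sx, (j-1) sy) mm.
#'
#' @param sliceMask Logical (or 0/1) matrix.
#' @param spacing In-plane pixel spacing (sx, sy) in mm.
#' @return An [InPlaneDiameter-class]; length 0 with undefined endpoints for
#'   an empty mask, length 0 with coincident endpoints for a single pixel.
#' @export
inplaneDiameter <- function(sliceMask, spacing = c(1, 1)) {
  pts <- which(sliceMask != 0, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0L) return(new("InPlaneDiameter"))
  P <- cbind((pts[, 1] - 1) * spacing[1], (pts[, 2] - 1) * spacing[2])
  if (n == 1L)
    return(new("InPlaneDiameter", length = 0, sliceIndex = NA_integer_,
               endpointA = P[1, ], endpointB = P[1, ]))
  hull <- grDevices::chull(P)
  H <- P[hull, , drop = FALSE]
  if (nrow(H) >= 3L) {
    H <- H[rev(seq_len(nrow(H))), , drop = FALSE]  # chull is clockwise
    H <- .pruneCollinear(H)
  }
  rc <- .rotatingCalipers(H)
  new("InPlaneDiameter", length = rc$d, sliceIndex = NA_integer_,
      endpointA = H[rc$a, ], endpointB = H[rc$b, ])
}

.regionMask <- function(labels, region) {
  switch(region,
         whole = labels > 0L,
         extrameatal = labels == 2L,
         intrameatal = labels == 1L,
         stop(sprintf("unknown region '%s'", region)))
}

#' Maximum in-plane diameter of a tumour region
#'
#' Applies [inplaneDiameter()] to every axial slice of the requested region
#' and returns the largest, measured in mm with the axial slice index it was
#' found on. Ties between slices go to the smallest slice index.
#'
#' @param x A canonicalized [LabeledVolume-class].
#' @param region "whole" (any tumour label), "extrameatal" or "intrameatal".
#' @return An [InPlaneDiameter-class]; an empty region yields length 0 and an
#'   undefined slice.
#' @rdname maxDiameter
#' @export
setMethod("maxDiameter", "LabeledVolume",
  function(x, region = c("whole", "extrameatal", "intrameatal")) {
    region <- match.arg(region)
    mask <- .regionMask(x@labels, region)
    counts <- apply(mask, 3L, sum)
    best <- new("InPlaneDiameter")
    for (k in which(counts > 0L)) {
      d <- inplaneDiameter(mask[, , k], x@spacing[1:2])
      if (is.na(best@sliceIndex) || d@length > best@length) {
        best <- d
        best@sliceIndex <- as.integer(k)
      }
    }
    best
  })

# Interface voxels: extrameatal voxels 6-adjacent to an intrameatal voxel.
.interfaceMask <- function(labels) {
  intra <- labels == 1L
  inter <- array(FALSE, dim(labels))
  for (axis in 1:3) for (by in c(-1L, 1L))
    inter <- inter | .shift3(intra, axis, by)
  inter & (labels == 2L)
}

#' Estimate the meatal axis from the compartment interface
#'
#' The interface voxels (extrameatal voxels 6-adjacent to an intrameatal
#' voxel) are pooled over all axial slices; the dominant eigenvector of the
#' 2x2 covariance of their in-plane physical coordinates gives `uPar`, the
#' in-plane trace of the porus plane, with `uPerp` orthogonal to it (the
#' canal direction).
#'
#' @param x A canonicalized [LabeledVolume-class].
#' @return A [MeatalAxis-class], or `NULL` when undefined: fewer than 2
#'   interface voxels, or an isotropic coordinate covariance (within 1e-9).
#' @rdname meatalAxis
#' @export
setMethod("meatalAxis", "LabeledVolume", function(x) {
  idx <- which(.interfaceMask(x@labels))
  if (length(idx) < 2L) return(NULL)
  ai <- arrayInd(idx, dim(x@labels))
  P <- cbind((ai[, 1] - 1) * x@spacing[1], (ai[, 2] - 1) * x@spacing[2])
  C <- stats::cov(P)
  e <- eigen(C, symmetric = TRUE)
  if (abs(e$values[1] - e$values[2]) < 1e-9) return(NULL)
  uPar <- e$vectors[, 1]
  if (uPar[1] < 0 || (uPar[1] == 0 && uPar[2] < 0)) uPar <- -uPar
  uPar <- uPar / sqrt(sum(uPar^2))
  new("MeatalAxis", uPar = uPar, uPerp = c(-uPar[2], uPar[1]),
      nInterfaceVoxels = length(idx))
})

# Extent (max - min) of a compartment's pixel-centre projections onto a unit
# vector, on one axial slice. 0 when the compartment is absent on the slice.
.sliceExtent <- function(labels, k, lab, u, spacing) {
  pts <- which(labels[, , k] == lab, arr.ind = TRUE)
  if (nrow(pts) == 0L) return(0)
  proj <- (pts[, 1] - 1) * spacing[1] * u[1] + (pts[, 2] - 1) * spacing[2] * u[2]
  max(proj) - min(proj)
}

#' Directional extents of the two compartments
#'
#' On the reference axial slice (by default the slice of the whole-tumour
#' maximum diameter), measures the range of each compartment's pixel-centre
#' projections onto the meatal axis directions: the intrameatal and
#' extrameatal extents along `uPar` and the extrameatal extent along `uPerp`,
#' in mm. When a compartment is absent on the reference slice but present
#' elsewhere, the slice with the most interface voxels is used for it
#' instead; a compartment absent everywhere contributes 0.
#'
#' @param x A canonicalized [LabeledVolume-class].
#' @param axis A [MeatalAxis-class] (error if `NULL`).
#' @param referenceSlice Optional axial slice index override.
#' @return Named numeric: `dIntraPar`, `dExtraPar`, `dExtraPerp` (mm).
#' @rdname directionalExtents
#' @export
setMethod("directionalExtents", "LabeledVolume",
  function(x, axis, referenceSlice = NULL) {
    if (is.null(axis)) stop("no meatal axis")
    stopifnot(is(axis, "MeatalAxis"))
    labels <- x@labels
    ref <- if (is.null(referenceSlice))
      maxDiameter(x, "whole")@sliceIndex else as.integer(referenceSlice)
    if (is.na(ref)) stop("no meatal axis")  # empty volume cannot have an axis
    inter <- .interfaceMask(labels)
    fallback <- which.max(apply(inter, 3L, sum))  # ties -> smallest index
    sliceFor <- function(lab) {
      if (any(labels[, , ref] == lab)) ref
      else if (any(labels == lab)) fallback
      else NA_integer_
    }
    kIntra <- sliceFor(1L)
    kExtra <- sliceFor(2L)
    c(
      dIntraPar = if (is.na(kIntra)) 0 else
        .sliceExtent(labels, kIntra, 1L, axis@uPar, x@spacing),
      dExtraPar = if (is.na(kExtra)) 0 else
        .sliceExtent(labels, kExtra, 2L, axis@uPar, x@spacing),
      dExtraPerp = if (is.na(kExtra)) 0 else
        .sliceExtent(labels, kExtra, 2L, axis@uPerp, x@spacing)
    )
  })

#' Compartment volumes
#'
#' Voxel-count volumes: each voxel contributes sx sy sz mm^3; results are in
#' cm^3 and satisfy `vWhole = vIntra + vExtra` exactly.
#'
#' @param x A [LabeledVolume-class].
#' @return Named numeric: `vIntra`, `vExtra`, `vWhole` (cm^3).
#' @rdname regionVolumes
#' @export
setMethod("regionVolumes", "LabeledVolume", function(x) {
  vox <- prod(x@spacing) / 1000
  nIntra <- sum(x@labels == 1L)
  nExtra <- sum(x@labels == 2L)
  c(vIntra = nIntra * vox, vExtra = nExtra * vox,
    vWhole = (nIntra + nExtra) * vox)
})

#' Measure one session
#'
#' Computes the full per-session measurement set from a canonicalized,
#' cleaned label volume: whole-tumour and extrameatal maximum in-plane
#' diameters, meatal-axis directional extents, compartment volumes, the
#' number of axial slices containing tumour, and the reference slice. All
#' extrameatal and directional quantities are NA for entirely intrameatal
#' tumours; directional extents are also NA when no meatal axis can be
#' estimated.
#'
#' @param x A [LabeledVolume-class].
#' @return A [SessionMeasurements-class].
#' @rdname measureSession
#' @export
setMethod("measureSession", "LabeledVolume", function(x) {
  vols <- regionVolumes(x)
  diamWhole <- maxDiameter(x, "whole")
  nSlices <- sum(apply(x@labels > 0L, 3L, any))
  if (vols[["vExtra"]] == 0) {
    return(new("SessionMeasurements",
               dWT = diamWhole@length, dEM = NA_real_,
               dIntraPar = NA_real_, dExtraPar = NA_real_,
               dExtraPerp = NA_real_,
               vIntra = vols[["vIntra"]], vExtra = 0,
               vWhole = vols[["vWhole"]],
               nAxialSlices = as.integer(nSlices),
               referenceSlice = diamWhole@sliceIndex,
               entirelyIntrameatal = TRUE,
               diamWhole = diamWhole, diamExtra = new("InPlaneDiameter")))
  }
  diamExtra <- maxDiameter(x, "extrameatal")
  axis <- meatalAxis(x)
  ext <- if (is.null(axis)) c(dIntraPar = NA_real_, dExtraPar = NA_real_,
                              dExtraPerp = NA_real_)
         else directionalExtents(x, axis, referenceSlice = diamWhole@sliceIndex)
  new("SessionMeasurements",
      dWT = diamWhole@length, dEM = diamExtra@length,
      dIntraPar = ext[["dIntraPar"]], dExtraPar = ext[["dExtraPar"]],
      dExtraPerp = ext[["dExtraPerp"]],
      vIntra = vols[["vIntra"]], vExtra = vols[["vExtra"]],
      vWhole = vols[["vWhole"]],
      nAxialSlices = as.integer(nSlices),
      referenceSlice = diamWhole@sliceIndex,
      entirelyIntrameatal = FALSE,
      diamWhole = diamWhole, diamExtra = diamExtra)
})
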