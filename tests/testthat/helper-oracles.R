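# Independent oracles and small fixture builders shared across tests.

# O(n^2) maximum pairwise pixel-centre distance; the independent check for
# the convex-hull + rotating-calipers implementation.
bruteDiameter <- function(mask, spacing = c(1, 1)) {
  pts <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pts) < 2L) return(0)
  P <- cbind((pts[, 1] - 1) * spacing[1], (pts[, 2] - 1) * spacing[2])
  max(stats::dist(P))
}

# Signed volume enclosed by an ASCII STL mesh (divergence theorem over
# triangles); independent of the package's voxel bookkeeping.
stlVolume <- function(path) {
  txt <- readLines(path)
  vl <- grep("^vertex", txt, value = TRUE)
  V <- matrix(as.numeric(unlist(strsplit(sub("vertex ", "", vl), " "))),
              ncol = 3, byrow = TRUE)
  stopifnot(nrow(V) %% 3 == 0)
  i1 <- seq(1, nrow(V), by = 3)
  v1 <- V[i1, , drop = FALSE]
  v2 <- V[i1 + 1, , drop = FALSE]
  v3 <- V[i1 + 2, , drop = FALSE]
  cr <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
              v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
              v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(rowSums(v1 * cr)) / 6
}

# Random sparse 2D mask with up to nMax foreground pixels.
randomMask <- function(dims, nMax = 500L) {
  n <- sample.int(nMax, 1L)
  m <- matrix(FALSE, dims[1], dims[2])
  m[cbind(sample.int(dims[1], n, TRUE), sample.int(dims[2], n, TRUE))] <- TRUE
  m
}

# A small two-compartment volume built directly (no phantom machinery):
# an intrameatal bar along x touching an extrameatal block.
tinyTwoCompartment <- function(spacing = c(1, 1, 1)) {
  a <- array(0L, c(16L, 12L, 5L))
  a[3:8, 5:7, 2:4] <- 1L
  a[9:14, 4:9, 2:4] <- 2L
  LabeledVolume(a, spacing = spacing)
}

# Coarse phantom used where speed matters more than voxelization accuracy.
coarsePhantomParams <- function(...) {
  base <- list(spacing = c(1, 1, 1), canalAngle = 30, intraLength = 10,
               intraRadius = 3, extraAxes = c(9, 6, 5))
  do.call(phantomParams, utils::modifyList(base, list(...)))
}

# Direct translation of the printed diameter-selection rules; kept separate
# from the implementation so the truth table test has an independent arbiter.
oracleChoice <- function(status, entirelyIntrameatal, dIntraPar, dExtraPar,
                         dExtraPerp) {
  if (status != "preoperative") return("DWT")
  if (entirelyIntrameatal) return("DWT")
  if (dIntraPar >= dExtraPar) return("DWT")
  if (dExtraPerp > 2) return("DEM")
  "DWT"
}
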