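test_that("cleanMask keeps the dominant component and drops islands", {
  a <- array(0L, c(20, 20, 10))
  a[2:6, 2:6, 2:5] <- 1L            # 100-voxel blob
  a[15, 15, 8] <- 2L; a[15, 16, 8] <- 2L  # 2-voxel island
  v <- cleanMask(LabeledVolume(a), minVoxels = 5L)
  expect_identical(sum(maskArray(v) == 2L), 0L)
  expect_identical(sum(maskArray(v) == 1L), 100L)

  # labels within the kept component are preserved
  a2 <- array(0L, c(10, 10, 4))
  a2[2:5, 2:5, 2] <- 1L; a2[6, 2:5, 2] <- 2L
  v2 <- cleanMask(LabeledVolume(a2))
  expect_identical(sum(maskArray(v2) == 1L), 16L)
  expect_identical(sum(maskArray(v2) == 2L), 4L)

  # empty passes through empty; a lone sub-threshold component is removed
  expect_identical(sum(maskArray(cleanMask(LabeledVolume(array(0L, c(4, 4, 4)))))), 0L)
  a3 <- array(0L, c(6, 6, 6)); a3[2, 2, 2] <- 1L
  expect_identical(sum(maskArray(cleanMask(LabeledVolume(a3), minVoxels = 5L))), 0L)
})

test_that("cleanMask breaks exact size ties by lexicographic centroid", {
  a <- array(0L, c(20, 8, 4))
  a[12:14, 2:4, 2] <- 1L   # centroid i = 13
  a[2:4, 2:4, 2] <- 1L     # centroid i = 3 -> kept
  v <- cleanMask(LabeledVolume(a))
  kept <- which(maskArray(v) == 1L, arr.ind = TRUE)
  expect_identical(sort(unique(kept[, 1])), 2:4)
})

test_that("in-plane diameter handles degenerate masks", {
  expect_identical(inplaneDiameter(matrix(FALSE, 5, 5))@length, 0)
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_identical(inplaneDiameter(m)@length, 0)
  # two pixels at grid offset (3, 4): a 3-4-5 triangle
  m2 <- matrix(FALSE, 10, 10); m2[2, 2] <- TRUE; m2[5, 6] <- TRUE
  expect_equal(inplaneDiameter(m2, c(1, 1))@length, 5)
  # anisotropic spacing stretches the same offset
  expect_equal(inplaneDiameter(m2, c(2, 1))@length, sqrt(36 + 16))
})

test_that("rotating calipers equals brute force exactly on random masks", {
  withr::local_seed(101)
  for (rep in 1:250) {
    m <- randomMask(sample(3:40, 2, replace = TRUE))
    sp <- stats::runif(2, 0.3, 2)
    got <- inplaneDiameter(m, sp)
    expect_identical(got@length, bruteDiameter(m, sp))
    if (got@length > 0) {
      # endpoints realise the reported length
      expect_equal(sqrt(sum((got@endpointA - got@endpointB)^2)), got@length)
    }
  }
})

test_that("maxDiameter recovers a sphere's diameter and is monotone", {
  # voxelized sphere, radius 10 mm at 0.5 mm spacing: diameter ~ 20 mm
  r <- 10; sp <- 0.5
  n <- ceiling(2 * (r + 1) / sp)
  cs <- (seq_len(n) - 1) * sp
  cc <- cs[ceiling(n / 2)]
  g1 <- matrix(cs, n, n); g2 <- matrix(cs, n, n, byrow = TRUE)
  a <- array(0L, c(n, n, n))
  for (k in seq_len(n))
    a[, , k] <- ((g1 - cc)^2 + (g2 - cc)^2 + (cs[k] - cc)^2 <= r^2) * 1L
  v <- LabeledVolume(array(as.integer(a), dim(a)), spacing = sp)
  d <- maxDiameter(v, "whole")
  expect_gte(d@length, 19.0)
  expect_lte(d@length, 21.0)

  # subset monotonicity: whole >= extrameatal, whole >= intrameatal
  tv <- tinyTwoCompartment()
  expect_gte(maxDiameter(tv, "whole")@length,
             maxDiameter(tv, "extrameatal")@length)
  expect_gte(maxDiameter(tv, "whole")@length,
             maxDiameter(tv, "intrameatal")@length)

  # an entirely intrameatal mask: whole and intrameatal coincide
  a2 <- array(0L, c(12, 12, 6)); a2[3:9, 4:8, 2:4] <- 1L
  v2 <- LabeledVolume(a2)
  expect_equal(maxDiameter(v2, "whole")@length,
               maxDiameter(v2, "intrameatal")@length)
  expect_identical(maxDiameter(v2, "extrameatal")@length, 0)

  # adding pixels never decreases the diameter
  a3 <- a2; a3[10, 4:8, 3] <- 2L
  expect_gte(maxDiameter(LabeledVolume(a3), "whole")@length,
             maxDiameter(v2, "whole")@length)
})

test_that("meatal axis follows the interface principal direction", {
  # interface voxels collinear along array axis 1 -> uPar = (1, 0)
  a <- array(0L, c(20, 10, 4))
  a[3:14, 4, 2] <- 1L
  a[3:14, 5, 2] <- 2L
  ax <- meatalAxis(LabeledVolume(a))
  expect_equal(abs(ax@uPar), c(1, 0), tolerance = 1e-9)
  expect_equal(sum(ax@uPar * ax@uPerp), 0)

  # no extrameatal label -> undefined
  a2 <- array(0L, c(10, 10, 4)); a2[3:6, 3:6, 2] <- 1L
  expect_null(meatalAxis(LabeledVolume(a2)))

  # phantom with the porus plane rotated 30 degrees in-plane:
  # recovered direction within 5 degrees of truth
  ph <- makePhantom(coarsePhantomParams(canalAngle = 30))
  ax2 <- meatalAxis(ph$volume)
  cosang <- abs(sum(ax2@uPar * ph$truth@uPar))
  expect_lt(acos(min(1, cosang)) * 180 / pi, 5)
})

test_that("directional extents follow the pixel-centre range convention", {
  # extrameatal 6 mm x 2 mm rectangle aligned with uPar, intrameatal block
  a <- array(0L, c(20, 12, 3))
  a[3:5, 3:6, 2] <- 1L
  a[8:13, 4:5, 2] <- 2L     # 6 x 2 pixels at 1 mm
  v <- LabeledVolume(a)
  ax <- new("MeatalAxis", uPar = c(1, 0), uPerp = c(0, 1),
            nInterfaceVoxels = 2L)
  ext <- directionalExtents(v, ax, referenceSlice = 2L)
  expect_equal(ext[["dExtraPar"]], 6 - 1)   # max - min of pixel centres
  expect_equal(ext[["dExtraPerp"]], 2 - 1)
  expect_equal(ext[["dIntraPar"]], 3 - 1)

  # axis undefined is an error
  expect_error(directionalExtents(v, NULL), "no meatal axis")

  # intrameatal absent on the reference slice -> fallback slice used
  a2 <- array(0L, c(20, 12, 5))
  a2[3:5, 3:6, 2] <- 1L
  a2[6, 3:6, 2] <- 2L        # interface voxels live on slice 2
  a2[8:13, 4:5, 4] <- 2L     # reference slice (max D) has no intrameatal
  v2 <- LabeledVolume(a2)
  ext2 <- directionalExtents(v2, ax, referenceSlice = 4L)
  expect_gt(ext2[["dIntraPar"]], 0)
})

test_that("volumes are exact voxel counts and scale with spacing cubed", {
  a <- array(0L, c(10, 10, 10)); a[1:10, 1:10, 1:10] <- 1L
  expect_equal(regionVolumes(LabeledVolume(a, spacing = 1))[["vWhole"]], 1.0)
  expect_equal(unname(regionVolumes(LabeledVolume(array(0L, c(5, 5, 5))))),
               c(0, 0, 0))
  v1 <- regionVolumes(tinyTwoCompartment(spacing = c(1, 1, 1)))
  v2 <- regionVolumes(tinyTwoCompartment(spacing = c(2, 2, 2)))
  expect_equal(unname(v2), unname(v1) * 8)
  expect_identical(v1[["vWhole"]], v1[["vIntra"]] + v1[["vExtra"]])
})

test_that("measureSession populates every field consistently", {
  # empty mask
  m0 <- measureSession(LabeledVolume(array(0L, c(6, 6, 6))))
  expect_identical(m0@dWT, 0)
  expect_identical(m0@nAxialSlices, 0L)
  expect_true(m0@entirelyIntrameatal)
  expect_true(is.na(m0@dEM))

  # entirely intrameatal phantom: DEM and extents undefined, DWT > 0
  phI <- makePhantom(coarsePhantomParams(extraAxes = c(0, 0, 0)))
  mI <- measureSession(phI$volume)
  expect_true(mI@entirelyIntrameatal)
  expect_true(is.na(mI@dEM) && is.na(mI@dIntraPar))
  expect_gt(mI@dWT, 0)

  # two-compartment phantom: all fields defined, invariants hold
  ph <- makePhantom(coarsePhantomParams())
  m <- measureSession(ph$volume)
  expect_false(m@entirelyIntrameatal)
  expect_false(anyNA(c(m@dEM, m@dIntraPar, m@dExtraPar, m@dExtraPerp)))
  expect_gte(m@dWT, m@dEM)
  expect_identical(m@vWhole, m@vIntra + m@vExtra)
  expect_gt(m@nAxialSlices, 1L)
  expect_false(is.na(m@referenceSlice))
})
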