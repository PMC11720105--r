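test_that("global thresholding implements the inclusive rule", {
  v <- intensityVolume(array(c(300, 299.999, 500, -1000, 0, 300.0001, 42, 301),
                             c(2, 2, 2)))
  occ <- thresholdSegment(v, 300)
  expect_equal(as.vector(occ@values), c(1, 0, 1, 0, 0, 1, 0, 1))
  # all below threshold
  expect_equal(sum(thresholdSegment(intensityVolume(array(0, c(3, 3, 3))),
                                    300)@values), 0)
  # random grid matches the elementwise oracle
  withr::with_seed(21, {
    g <- array(runif(512, -1000, 2000), c(8, 8, 8))
    occ <- thresholdSegment(intensityVolume(g), 300)
    oracle <- array(0, c(8, 8, 8))
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      if (g[i, j, k] >= 300) oracle[i, j, k] <- 1
    expect_equal(occ@values, oracle)
  })
})

test_that("thresholding is idempotent on its own rescaled output", {
  withr::with_seed(3, {
    g <- array(runif(216, 0, 600), c(6, 6, 6))
    occ1 <- thresholdSegment(intensityVolume(g), 300)
    # re-express occupancy in HU (0 / 1000) and re-threshold between
    occ2 <- thresholdSegment(intensityVolume(occ1@values * 1000), 500)
    expect_equal(occ1@values, occ2@values)
  })
})

test_that("surface extraction recovers phantom geometry", {
  # solid cube: bounding box within one voxel of the voxel-centre extent
  cv <- array(0, c(20, 20, 20))
  cv[5:15, 5:15, 5:15] <- 1
  mesh <- extractSurface(occupancyVolume(cv))
  bb <- apply(meshVertices(mesh), 2, range)
  expect_true(all(abs(bb[1, ] - 4) <= 1))
  expect_true(all(abs(bb[2, ] - 14) <= 1))

  # solid ball: area within 5 percent of the sphere area
  n <- 41; r <- 14
  co <- seq_len(n) - (n + 1) / 2
  d2 <- outer(co^2, outer(co^2, co^2, `+`), `+`)
  ball <- extractSurface(thresholdSegment(
    intensityVolume(ifelse(d2 <= r^2, 1000, 0)), 300))
  expect_lt(abs(meshArea(ball) / (4 * pi * r^2) - 1), 0.05)

  # anisotropic spacing scales coordinates
  small <- array(0, c(10, 10, 10)); small[4:7, 4:7, 4:7] <- 1
  m2 <- extractSurface(occupancyVolume(small, spacing = c(2, 1, 1),
                                       origin = c(10, 0, 0)))
  bb2 <- apply(meshVertices(m2), 2, range)
  expect_gt(mean(bb2[, 1]), 10)  # origin offset applied on x
})

test_that("only the largest connected component is retained", {
  v <- array(0, c(24, 12, 12))
  v[3:10, 3:10, 3:10] <- 1    # large blob
  v[16:19, 5:8, 5:8] <- 1     # small blob
  both <- extractSurface(occupancyVolume(v), keepLargestOnly = FALSE)
  only <- extractSurface(occupancyVolume(v))
  expect_lt(nrow(meshFaces(only)), nrow(meshFaces(both)))
  # retained surface lies entirely in the large blob's half-space
  expect_lt(max(meshVertices(only)[, 1]), 12)
  expect_error(extractSurface(occupancyVolume(array(0, c(4, 4, 4)))),
               "empty segmentation")
})

test_that("surface sampling is area-uniform and seeded", {
  tri <- triangleMesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                      rbind(c(1L, 2L, 3L)))
  cl <- sampleSurface(tri, 1000, seed = 4)
  P <- cloudPoints(cl)
  expect_lt(max(abs(P[, 3])), 1e-9)          # in the triangle plane
  expect_true(all(P[, 1] >= -1e-9 & P[, 2] >= -1e-9 &
                  P[, 1] + P[, 2] <= 2 + 1e-9))
  # two triangles with area ratio 3:1 get hits in ratio 3:1 (within 5%)
  two <- triangleMesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0),
                            c(10, 0, 0), c(11, 0, 0), c(10, 2, 0)),
                      rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  Q <- cloudPoints(sampleSurface(two, 40000, seed = 9))
  hitsBig <- sum(Q[, 1] < 5)
  expect_lt(abs(hitsBig / (40000 - hitsBig) - 3), 0.15)
  # seeded determinism
  expect_identical(cloudPoints(sampleSurface(two, 100, seed = 1)),
                   cloudPoints(sampleSurface(two, 100, seed = 1)))
  expect_error(sampleSurface(triangleMesh(matrix(0, 3, 3),
                                          rbind(c(1L, 2L, 3L))), 10),
               "zero total area")
})

test_that("point density per unit area is uniform across triangles", {
  # flat two-triangle mesh with equal areas: chi-square should not reject
  mesh <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                       rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  P <- cloudPoints(sampleSurface(mesh, 40000, seed = 2))
  inUpper <- sum(P[, 2] > P[, 1])   # triangle 2 is above the diagonal
  pval <- stats::chisq.test(c(inUpper, 40000 - inUpper),
                            p = c(0.5, 0.5))$p.value
  expect_gt(pval, 0.01)
})

test_that("unit-sphere normalization is exact, invertible and idempotent", {
  cl <- pointCloud(rbind(c(1, 0, 0), c(-1, 0, 0)))
  nc <- normalizeCloud(cl)
  expect_equal(cloudPoints(nc), rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(cloudCentroid(nc), c(0, 0, 0))
  expect_equal(cloudScale(nc), 1)
  withr::with_seed(12, {
    raw <- pointCloud(matrix(rnorm(300, sd = 40), 100, 3) + 25)
    ncl <- normalizeCloud(raw)
    expect_lt(max(abs(colMeans(cloudPoints(ncl)))), 1e-9)
    expect_equal(max(sqrt(rowSums(cloudPoints(ncl)^2))), 1, tolerance = 1e-9)
    # inverse mapping recovers the input
    back <- denormalizeCloud(ncl)
    expect_lt(max(abs(cloudPoints(back) - cloudPoints(raw))), 1e-9)
    # idempotence
    n2 <- normalizeCloud(ncl)
    expect_lt(max(abs(cloudPoints(n2) - cloudPoints(ncl))), 1e-12)
  })
  expect_error(normalizeCloud(pointCloud(rbind(c(1, 1, 1), c(1, 1, 1)))),
               "zero scale")
})

test_that("STL write/read round-trips both dialects", {
  tet <- triangleMesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10)),
                      rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L),
                            c(2L, 3L, 4L)))
  bin <- tempfile(fileext = ".stl")
  asc <- tempfile(fileext = ".stl")
  writeSTL(tet, bin)
  writeSTLAscii(tet, asc)
  mb <- readSTL(bin)
  ma <- readSTL(asc)
  expect_equal(nrow(meshVertices(mb)), 4L)  # soup de-duplicated
  expect_equal(nrow(meshFaces(mb)), 4L)
  # binary and ASCII encodings agree as vertex sets
  sortV <- function(V) V[order(V[, 1], V[, 2], V[, 3]), ]
  expect_equal(sortV(meshVertices(mb)), sortV(meshVertices(ma)),
               tolerance = 1e-6)
  # float32 precision on a non-integer mesh
  irr <- triangleMesh(matrix(c(pi, exp(1), sqrt(2), 10.1, 0.3, 7.7,
                               1.23, 4.56, 7.89), 3, 3, byrow = TRUE),
                      rbind(c(1L, 2L, 3L)))
  writeSTL(irr, bin)
  expect_lt(max(abs(sortV(meshVertices(readSTL(bin))) -
                    sortV(meshVertices(irr)))), 1e-5)
})

test_that("malformed STL files raise format errors", {
  f <- tempfile(fileext = ".stl")
  file.create(f)
  expect_error(readSTL(f), "too short")
  writeLines(c("solid junk", "facet normal 0 0 0", "vertex 1 2"), f)
  expect_error(readSTL(f))
  # binary header with wrong facet count
  con <- file(f, "wb")
  writeBin(raw(80), con)
  writeBin(5L, con, size = 4, endian = "little")
  close(con)
  expect_error(readSTL(f), "malformed")
  expect_error(readSTL(tempfile()), "no such file")
})

test_that("volume files round-trip through both on-disk forms", {
  withr::with_seed(33, {
    vol <- intensityVolume(array(round(runif(60, -100, 900), 3), c(3, 4, 5)),
                           spacing = c(0.75, 0.75, 1), origin = c(-20, 5, 0))
    # plain-text JSON + data sidecar
    j <- file.path(tempdir(), "vol.json")
    writeVolume(vol, j)
    back <- readVolume(j)
    expect_equal(back@values, vol@values, tolerance = 1e-9)
    expect_equal(back@spacing, vol@spacing)
    expect_equal(back@origin, vol@origin)
    # NIfTI via RNifti
    nii <- file.path(tempdir(), "vol.nii.gz")
    img <- RNifti::asNifti(vol@values, reference = NULL)
    RNifti::pixdim(img) <- vol@spacing
    RNifti::writeNifti(img, nii)
    fromNifti <- readVolume(nii)
    expect_equal(fromNifti@values, vol@values, tolerance = 1e-4)
    expect_equal(fromNifti@spacing, vol@spacing, tolerance = 1e-6)
    expect_error(readVolume(tempfile()), "no such file")
  })
})
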