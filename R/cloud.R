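#' Area-uniform point sampling of a triangle mesh
#'
#' Draws `n` points uniformly over the surface: a triangle is chosen with
#' probability proportional to its area and the position within it is
#' uniform in barycentric coordinates (the square-root-free reflection
#' trick). Sampling is reproducible for a fixed seed and leaves the global
#' RNG state untouched.
#'
#' @param mesh A [TriangleMesh-class] with positive total area.
#' @param n Number of points (default 2048, the size used throughout the
#'   pipeline).
#' @param seed Integer seed for reproducible sampling.
#' @return An un-normalized [PointCloud-class] with `n` points.
#' @export
sampleSurface <- function(mesh, n = 2048, seed = 1L) {
  stopifnot(n >= 1)
  V <- meshVertices(mesh)
  Fc <- meshFaces(mesh)
  if (nrow(Fc) == 0) stop("sampleSurface: mesh has no faces")
  A <- V[Fc[, 1], , drop = FALSE]
  B <- V[Fc[, 2], , drop = FALSE]
  C <- V[Fc[, 3], , drop = FALSE]
  e1 <- B - A; e2 <- C - A
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  areas <- sqrt(rowSums(cr^2)) / 2
  if (sum(areas) <= 0) stop("sampleSurface: mesh has zero total area")
  pts <- withr::with_seed(as.integer(seed), {
    tri <- sample.int(nrow(Fc), n, replace = TRUE, prob = areas)
    u <- runif(n); v <- runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]
    v[flip] <- 1 - v[flip]
    A[tri, , drop = FALSE] + u * e1[tri, , drop = FALSE] +
      v * e2[tri, , drop = FALSE]
  })
  pointCloud(pts)
}

#' Normalize a point cloud into the unit sphere
#'
#' Shifts the centroid to the origin and divides by the maximum Euclidean
#' norm of the centred points, so the cloud fits exactly within the unit
#' sphere. The centroid (mm) and scale (mm) are recorded on the returned
#' object so the mapping can be inverted with [denormalizeCloud()].
#' Normalization is idempotent.
#'
#' @param cloud A [PointCloud-class] with at least one point.
#' @return A normalized [PointCloud-class].
#' @export
normalizeCloud <- function(cloud) {
  P <- cloudPoints(cloud)
  if (nrow(P) < 1) stop("normalizeCloud: empty cloud")
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  s <- sqrt(max(rowSums(Q^2)))
  if (s <= 0) stop("normalizeCloud: all points coincide (zero scale)")
  # compose with any normalization already applied
  pointCloud(Q / s,
             centroid = cloud@centroid + ctr * cloud@scale,
             scale = cloud@scale * s,
             normalized = TRUE)
}

#' Invert unit-sphere normalization
#'
#' @param cloud A normalized [PointCloud-class].
#' @return The cloud mapped back to its original mm coordinates.
#' @export
denormalizeCloud <- function(cloud) {
  P <- sweep(cloudPoints(cloud) * cloud@scale, 2, cloud@centroid, `+`)
  pointCloud(P)
}
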