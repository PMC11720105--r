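#' Rotation conventions
#'
#' All rotations in nhpnet use a fixed anatomical frame: +x anterior,
#' +y left, +z superior, millimetre units. Euler angles are given in degrees
#' as (roll, pitch, yaw) = rotations about +x, +y, +z, composed as
#' R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll). Pitch is restricted to
#' \[-90, 90\] degrees; roll and yaw to (-180, 180\]. At gimbal lock
#' (|pitch| = 90 deg) roll is reported as 0 and yaw absorbs the remaining
#' freedom.
#'
#' @name rotation-conventions
NULL

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.Rx <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
.Ry <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
.Rz <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Convert Euler angles (degrees) to a rotation matrix
#'
#' @param angles Numeric length-3 vector `c(roll, pitch, yaw)` in degrees
#'   (see [rotation-conventions]).
#' @return 3 x 3 rotation matrix.
#' @examples
#' eulerToMatrix(c(0, 0, 90)) %*% c(1, 0, 0)  # +x maps to +y
#' @export
eulerToMatrix <- function(angles) {
  stopifnot(is.numeric(angles), length(angles) == 3L, all(is.finite(angles)))
  a <- .deg2rad(angles)
  .Rz(a[3]) %*% .Ry(a[2]) %*% .Rx(a[1])
}

#' Check that a matrix is a proper rotation
#'
#' @param R 3 x 3 matrix.
#' @param tol Orthonormality/determinant tolerance.
#' @return Logical scalar.
#' @export
isRotationMatrix <- function(R, tol = .EPS_ORTHO) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Recover Euler angles (degrees) from a rotation matrix
#'
#' Inverse of [eulerToMatrix()] under the package convention. At gimbal lock
#' (|pitch| = 90 degrees within ~1e-7) roll is set to 0 and yaw absorbs the
#' remaining degree of freedom.
#'
#' @param R 3 x 3 rotation matrix.
#' @return Numeric `c(roll, pitch, yaw)` in degrees.
#' @export
matrixToEuler <- function(R) {
  if (!isRotationMatrix(R))
    stop("matrixToEuler: input is not a valid rotation matrix")
  s <- max(-1, min(1, -R[3, 1]))
  pitch <- asin(s)
  if (abs(abs(s) - 1) < 1e-7) {
    # gimbal lock: only roll +/- yaw is determined; report roll = 0
    roll <- 0
    yaw <- atan2(-R[1, 2], R[2, 2])
  } else {
    roll <- atan2(R[3, 2], R[3, 3])
    yaw <- atan2(R[2, 1], R[1, 1])
  }
  out <- .rad2deg(c(roll, pitch, yaw))
  names(out) <- c("roll", "pitch", "yaw")
  out
}

#' Project an arbitrary 3 x 3 matrix onto SO(3)
#'
#' Computes the singular value decomposition A = U S V' and returns
#' U diag(1, 1, det(UV')) V', the Frobenius-nearest proper rotation to A.
#' The determinant correction guarantees det = +1 even for inputs with
#' negative determinant, where the plain product UV' would be a reflection.
#'
#' @param A 3 x 3 numeric matrix (finite entries; need not be orthogonal).
#' @return 3 x 3 rotation matrix. If the nearest rotation is ambiguous (two
#'   tied smallest singular values with a reflective input) the result
#'   carries attribute `degenerate = TRUE`; the SVD's column order makes the
#'   tie-break deterministic.
#' @export
projectToSO3 <- function(A) {
  stopifnot(is.matrix(A), all(dim(A) == c(3L, 3L)))
  if (!all(is.finite(A))) stop("projectToSO3: matrix has non-finite entries")
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  if (d < 0 && abs(sv$d[2] - sv$d[3]) < 1e-9 * max(sv$d[1], 1))
    attr(R, "degenerate") <- TRUE
  R
}

#' Geodesic rotation error in degrees
#'
#' The angular difference between two rotations,
#' RE = arccos((Tr(Rhat R') - 1) / 2), in degrees, range \[0, 180\]. The
#' arccos argument is clamped to \[-1, 1\] to absorb floating-point error.
#'
#' @param Rhat,R 3 x 3 rotation matrices (predicted and ground truth).
#' @return Rotation error in degrees.
#' @export
rotationError <- function(Rhat, R) {
  if (!isRotationMatrix(Rhat) || !isRotationMatrix(R))
    stop("rotationError: both arguments must be rotation matrices")
  arg <- (sum(diag(Rhat %*% t(R))) - 1) / 2
  .rad2deg(acos(max(-1, min(1, arg))))
}

#' Per-angle mean absolute error between two sets of Euler angles
#'
#' MAE is computed independently for roll, pitch and yaw:
#' MAE = (1/n) sum |predicted_i - truth_i|. The per-sample absolute errors
#' and their standard deviation are returned as well, supporting the
#' mean +/- SD reporting style.
#'
#' @param predicted,truth n x 3 matrices or data.frames of (roll, pitch,
#'   yaw) in degrees, equal number of rows.
#' @return List with `mae` (length-3), `sd` (length-3) and `absErrors`
#'   (n x 3 matrix).
#' @export
angleMAE <- function(predicted, truth) {
  predicted <- as.matrix(predicted)
  truth <- as.matrix(truth)
  if (!all(dim(predicted) == dim(truth)) || ncol(predicted) != 3L)
    stop("angleMAE: inputs must be n x 3 with equal dimensions")
  if (nrow(predicted) < 1L) stop("angleMAE: need at least one sample")
  ae <- abs(predicted - truth)
  colnames(ae) <- c("roll", "pitch", "yaw")
  list(mae = colMeans(ae),
       sd = apply(ae, 2, sd),
       absErrors = ae)
}

#' Rotate a mesh, point cloud or coordinate matrix about a centre
#'
#' Applies v' = R (v - center) + center to every vertex/point. The default
#' centre is the vertex centroid, consistent with the centroid-at-origin
#' normalization used throughout the pipeline.
#'
#' @param x A [TriangleMesh-class], [PointCloud-class] or n x 3 matrix.
#' @param R 3 x 3 rotation matrix.
#' @param center Length-3 rotation centre; `NULL` means the centroid of `x`.
#' @return Object of the same class as `x`, rotated.
#' @export
setGeneric("applyRotation", function(x, R, center = NULL)
  standardGeneric("applyRotation"))

.rotatePoints <- function(P, R, center) {
  if (is.null(center)) center <- colMeans(P)
  sweep(sweep(P, 2, center) %*% t(R), 2, center, `+`)
}

#' @rdname applyRotation
setMethod("applyRotation", "matrix", function(x, R, center = NULL) {
  stopifnot(ncol(x) == 3L)
  .rotatePoints(x, R, center)
})

#' @rdname applyRotation
setMethod("applyRotation", "TriangleMesh", function(x, R, center = NULL) {
  triangleMesh(.rotatePoints(x@vertices, R, center), x@faces)
})

#' @rdname applyRotation
setMethod("applyRotation", "PointCloud", function(x, R, center = NULL) {
  pointCloud(.rotatePoints(x@points, R, center),
             centroid = x@centroid, scale = x@scale,
             normalized = x@normalized)
})

#' Per-vertex surface distance between two orientations of a mesh
#'
#' Rotates the same mesh by a predicted and a ground-truth rotation about a
#' shared centre and returns the Euclidean distance per vertex, the standard
#' way of visualising how far a mis-predicted orientation displaces the
#' skull surface.
#'
#' @param mesh A [TriangleMesh-class].
#' @param Rhat,R Predicted and ground-truth rotation matrices.
#' @param center Shared rotation centre; `NULL` = vertex centroid.
#' @return List with `distances` (per vertex, mm), `mean` and `max`.
#' @export
surfaceDistance <- function(mesh, Rhat, R, center = NULL) {
  V <- meshVertices(mesh)
  if (is.null(center)) center <- colMeans(V)
  d <- sqrt(rowSums((.rotatePoints(V, Rhat, center) -
                     .rotatePoints(V, R, center))^2))
  list(distances = d, mean = mean(d), max = max(d))
}
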