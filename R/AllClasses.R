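#' TriangleMesh: a triangulated surface in millimetre coordinates
#'
#' Vertices are an n x 3 numeric matrix (mm); faces an m x 3 integer matrix of
#' 1-based vertex indices. Degenerate (zero-area) faces are disallowed after
#' construction-time cleaning.
#'
#' @slot vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must have 3 columns")
    if (ncol(object@faces) != 3L) msg <- c(msg, "faces must have 3 columns")
    if (nrow(object@faces) > 0L) {
      f <- object@faces
      if (any(f < 1L) || any(f > nrow(object@vertices)))
        msg <- c(msg, "face indices out of range")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a TriangleMesh
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @return A [TriangleMesh-class] object.
#' @export
triangleMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  new("TriangleMesh", vertices = vertices, faces = faces)
}

#' @describeIn triangleMesh vertex coordinate matrix
#' @param mesh A TriangleMesh.
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @describeIn triangleMesh face index matrix
#' @export
meshFaces <- function(mesh) mesh@faces

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
  bb <- apply(object@vertices, 2, range)
  cat(sprintf("  bbox (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
})

#' PointCloud: a fixed-size set of 3D points
#'
#' Holds the points together with the centroid and scale recorded before
#' normalization, so the unit-sphere mapping is invertible.
#'
#' @slot points n x 3 numeric matrix.
#' @slot centroid length-3 numeric, centroid subtracted at normalization (mm).
#' @slot scale length-1 numeric, max centred norm divided out at
#'   normalization (mm).
#' @slot normalized logical scalar.
#' @export
setClass("PointCloud",
  representation(points = "matrix", centroid = "numeric", scale = "numeric",
                 normalized = "logical"),
  prototype(centroid = c(0, 0, 0), scale = 1, normalized = FALSE),
  validity = function(object) {
    msg <- character()
    if (ncol(object@points) != 3L) msg <- c(msg, "points must have 3 columns")
    if (length(object@centroid) != 3L) msg <- c(msg, "centroid must have length 3")
    if (length(object@scale) != 1L || object@scale <= 0)
      msg <- c(msg, "scale must be a positive scalar")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a PointCloud
#'
#' @param points n x 3 numeric matrix of coordinates.
#' @param centroid,scale Pre-normalization centroid and scale (used by
#'   [normalizeCloud()]; defaults mark the cloud as un-normalized raw data).
#' @param normalized Whether the points already live in the unit sphere.
#' @return A [PointCloud-class] object.
#' @export
pointCloud <- function(points, centroid = c(0, 0, 0), scale = 1,
                       normalized = FALSE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  new("PointCloud", points = points, centroid = as.numeric(centroid),
      scale = as.numeric(scale), normalized = isTRUE(normalized))
}

#' @describeIn pointCloud coordinate matrix
#' @param cloud A PointCloud.
#' @export
cloudPoints <- function(cloud) cloud@points

#' @describeIn pointCloud pre-normalization centroid (mm)
#' @export
cloudCentroid <- function(cloud) cloud@centroid

#' @describeIn pointCloud pre-normalization scale (mm)
#' @export
cloudScale <- function(cloud) cloud@scale

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points (%s)\n", nrow(object@points),
              if (object@normalized) "normalized to unit sphere" else "raw mm"))
})

#' Volumetric image classes
#'
#' `IntensityVolume` holds CT intensities in Hounsfield units on a voxel grid;
#' `OccupancyVolume` holds a binary segmentation of the same grid. Voxel
#' (1,1,1) is centred at `origin`; voxel centres advance by `spacing` (mm)
#' along each axis.
#'
#' @slot values 3D numeric array (HU) or binary array.
#' @slot spacing length-3 positive numeric, voxel size per axis (mm).
#' @slot origin length-3 numeric, position of the first voxel centre (mm).
#' @name volumes
NULL

.validVolume <- function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L) msg <- c(msg, "values must be a 3D array")
  if (length(object@values) == 0L) msg <- c(msg, "grid must be non-empty")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers")
  if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
  if (length(msg)) msg else TRUE
}

#' @rdname volumes
#' @export
setClass("IntensityVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = .validVolume)

#' @rdname volumes
#' @export
setClass("OccupancyVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    base <- .validVolume(object)
    if (!isTRUE(base)) return(base)
    if (!all(object@values %in% c(0, 1))) return("occupancy values must be 0/1")
    TRUE
  })

#' @rdname volumes
#' @param values 3D array.
#' @param spacing Voxel size per axis (mm).
#' @param origin Coordinates of the first voxel centre (mm).
#' @export
intensityVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("IntensityVolume", values = as.array(values),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' @rdname volumes
#' @export
occupancyVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("OccupancyVolume", values = as.array(values),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("IntensityVolume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range: [%.1f, %.1f] HU\n",
              min(object@values), max(object@values)))
})

setMethod("show", "OccupancyVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("OccupancyVolume: %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(object@values)))
})

#' SkullCohort: a labelled synthetic dataset
#'
#' Each sample couples a canonical (NHP-frame) mesh, the acquired
#' (misaligned) mesh, and the ground-truth NHP-restoring rotation. The
#' ground-truth table mirrors what [generateCohort()] writes to disk.
#'
#' @slot samples List of labelled samples (see [generateCohort()]).
#' @slot table data.frame with subject_id, split, roll, pitch, yaw, r11..r33.
#' @slot spec The cohort specification list used to generate the data.
#' @export
setClass("SkullCohort",
  representation(samples = "list", table = "data.frame", spec = "list"),
  validity = function(object) {
    if (nrow(object@table) != length(object@samples))
      return("table rows must match number of samples")
    TRUE
  })

#' @describeIn generateCohort list of all labelled samples
#' @param cohort A SkullCohort.
#' @export
cohortSamples <- function(cohort) cohort@samples

#' @describeIn generateCohort the ground-truth table (one row per sample)
#' @export
cohortTable <- function(cohort) cohort@table

#' @describeIn generateCohort samples belonging to one split
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @export
cohortSplit <- function(cohort, split) {
  stopifnot(split %in% c("train", "val", "test"))
  cohort@samples[cohort@table$split == split]
}

setMethod("show", "SkullCohort", function(object) {
  tab <- table(factor(object@table$split, levels = c("train", "val", "test")))
  cat(sprintf("SkullCohort: %d samples (train %d / val %d / test %d)\n",
              length(object@samples), tab[["train"]], tab[["val"]], tab[["test"]]))
})

setMethod("length", "SkullCohort", function(x) length(x@samples))

#' NHPModel: trained network parameters plus their architecture
#'
#' @slot params Nested list of weight matrices and bias vectors.
#' @slot config The [networkConfig()] list the parameters were built from.
#' @export
setClass("NHPModel", representation(params = "list", config = "list"))

#' @describeIn initModel the parameter list of a model
#' @param model An NHPModel.
#' @export
modelParams <- function(model) model@params

#' @describeIn initModel the network configuration of a model
#' @export
modelConfig <- function(model) model@config

setMethod("show", "NHPModel", function(object) {
  cat(sprintf("NHPModel: %s learnable parameters\n",
              format(countParameters(object@config), big.mark = ",")))
  cat(sprintf("  SAB1: %d centroids, r=%.2f -> %d ch; SAB2: %d centroids, r=%.2f -> %d ch; head: %s\n",
              object@config$sab1$nCentroids, object@config$sab1$radius,
              object@config$sab1$outChannels, object@config$sab2$nCentroids,
              object@config$sab2$radius, object@config$sab2$outChannels,
              paste(object@config$headWidths, collapse = "-")))
})

#' EvalReport: per-sample and aggregate orientation errors
#'
#' @slot perSample data.frame with one row per test subject: predicted and
#'   ground-truth roll/pitch/yaw (degrees), per-angle absolute errors, and
#'   geodesic rotation error (degrees).
#' @slot summary data.frame of mean and SD for each metric.
#' @export
setClass("EvalReport",
  representation(perSample = "data.frame", summary = "data.frame"))

#' @describeIn evaluateNHP per-sample rows of a report
#' @param report An EvalReport.
#' @export
reportPerSample <- function(report) report@perSample

#' @describeIn evaluateNHP aggregate mean/SD rows of a report
#' @export
reportSummary <- function(report) report@summary

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d samples\n", nrow(object@perSample)))
  s <- object@summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %6.3f +/- %.3f deg\n", s$metric[i], s$mean[i], s$sd[i]))
  }
})
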