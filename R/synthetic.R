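#' Shape parameters for a synthetic skull proxy
#'
#' The proxy is a star-shaped closed surface built from three ingredients,
#' the minimal geometry that breaks all three rotational symmetries so the
#' canonical orientation is identifiable from shape alone:
#' a superellipsoid cranium, a jaw lobe fused anterior-inferiorly, and a
#' single lateral bump breaking left-right symmetry.
#'
#' @param craniumSemiaxes Length-3 positive semiaxes (mm) along +x anterior,
#'   +y left, +z superior.
#' @param craniumExponent Superellipsoid shape exponent (2 = ellipsoid;
#'   larger = boxier).
#' @param jawOffset Length-3 vector (mm): direction of the jaw lobe centre
#'   (anterior-inferior by default); its norm sets the lobe's radial reach.
#' @param jawScale Dimensionless lobe strength; lobe height is
#'   `jawScale * |jawOffset|` mm. Zero removes the jaw.
#' @param asymmetryBumpPosition Unit direction of the lateral bump.
#' @param asymmetryBumpAmplitude Bump height in mm; must be > 0 for the
#'   default proxy so no rotation maps the shape onto itself.
#' @param meshResolution Integer >= 1 controlling tessellation density
#'   (resolution r gives a 16r x 8r longitude/latitude grid).
#' @return A validated parameter list of class `ShapeParams`.
#' @export
shapeParams <- function(craniumSemiaxes = c(80, 65, 70),
                        craniumExponent = 2.5,
                        jawOffset = c(60, 0, -55),
                        jawScale = 0.35,
                        asymmetryBumpPosition = c(0.25, 0.93, 0.27),
                        asymmetryBumpAmplitude = 6,
                        meshResolution = 3L) {
  if (any(craniumSemiaxes <= 0)) stop("shapeParams: semiaxes must be positive")
  if (craniumExponent <= 0) stop("shapeParams: exponent must be positive")
  if (jawScale < 0) stop("shapeParams: jawScale must be >= 0")
  if (asymmetryBumpAmplitude < 0)
    stop("shapeParams: bump amplitude must be >= 0")
  if (meshResolution < 1) stop("shapeParams: meshResolution must be >= 1")
  p <- asymmetryBumpPosition / sqrt(sum(asymmetryBumpPosition^2))
  structure(list(craniumSemiaxes = craniumSemiaxes,
                 craniumExponent = craniumExponent,
                 jawOffset = jawOffset,
                 jawScale = jawScale,
                 asymmetryBumpPosition = p,
                 asymmetryBumpAmplitude = asymmetryBumpAmplitude,
                 meshResolution = as.integer(meshResolution)),
            class = "ShapeParams")
}

# Radius of the superellipsoid |x/a|^p + |y/b|^p + |z/c|^p = 1 along unit
# direction u: scale t with sum |t u_i / a_i|^p = 1.
.superellipsoidRadius <- function(U, semiaxes, p) {
  s <- (abs(U[, 1]) / semiaxes[1])^p + (abs(U[, 2]) / semiaxes[2])^p +
    (abs(U[, 3]) / semiaxes[3])^p
  s^(-1 / p)
}

#' Generate a synthetic skull-proxy mesh in the canonical (NHP) frame
#'
#' Builds a watertight closed triangle mesh (Euler characteristic 2) by
#' radially deforming a UV sphere: the base radius follows the
#' superellipsoid cranium, a Gaussian angular lobe adds the jaw
#' anterior-inferiorly, and a second, smaller Gaussian lobe off the midline
#' breaks left-right symmetry. The construction is deterministic: identical
#' parameters give bit-identical vertex arrays. With the jaw and the bump
#' switched off the surface is exactly mirror-symmetric in y, which the test
#' suite uses as a symmetry oracle.
#'
#' @param params A [shapeParams()] list.
#' @return A [TriangleMesh-class] centred near the origin, mm units.
#' @export
makeSkullProxy <- function(params = shapeParams()) {
  stopifnot(inherits(params, "ShapeParams"))
  res <- params$meshResolution
  nSeg <- 16L * res              # longitudes
  nRing <- 8L * res              # latitude rings between the poles
  phi <- 2 * pi * (seq_len(nSeg) - 1L) / nSeg
  theta <- pi * seq_len(nRing) / (nRing + 1L)
  # unit directions: rings x segments, plus 2 poles
  dirRing <- do.call(rbind, lapply(theta, function(th)
    cbind(sin(th) * cos(phi), sin(th) * sin(phi), rep(cos(th), nSeg))))
  U <- rbind(c(0, 0, 1), dirRing, c(0, 0, -1))

  r <- .superellipsoidRadius(U, params$craniumSemiaxes, params$craniumExponent)
  if (params$jawScale > 0) {
    jd <- params$jawOffset / sqrt(sum(params$jawOffset^2))
    ang <- acos(pmax(-1, pmin(1, U %*% jd)))
    r <- r + params$jawScale * sqrt(sum(params$jawOffset^2)) *
      exp(-ang^2 / (2 * 0.45^2))
  }
  if (params$asymmetryBumpAmplitude > 0) {
    angB <- acos(pmax(-1, pmin(1, U %*% params$asymmetryBumpPosition)))
    r <- r + params$asymmetryBumpAmplitude * exp(-angB^2 / (2 * 0.30^2))
  }
  V <- U * as.vector(r)

  # faces: pole fans + quad strips between rings (all 1-based)
  ringIdx <- function(i, j) 1L + (i - 1L) * nSeg + (j - 1L) %% nSeg + 1L
  top <- 1L
  bottom <- nrow(V)
  faces <- vector("list", nRing + 1L)
  faces[[1L]] <- cbind(top, ringIdx(1L, 1:nSeg), ringIdx(1L, 2:(nSeg + 1L)))
  for (i in seq_len(nRing - 1L)) {
    a <- ringIdx(i, 1:nSeg);      b <- ringIdx(i, 2:(nSeg + 1L))
    cc <- ringIdx(i + 1L, 1:nSeg); d <- ringIdx(i + 1L, 2:(nSeg + 1L))
    faces[[i + 1L]] <- rbind(cbind(a, cc, b), cbind(b, cc, d))
  }
  faces[[nRing + 1L]] <- cbind(bottom, ringIdx(nRing, 2:(nSeg + 1L)),
                               ringIdx(nRing, 1:nSeg))
  triangleMesh(V, do.call(rbind, faces))
}

#' Acquisition misalignment model
#'
#' Models the deviation of the CT-acquired head posture from NHP as small
#' independent roll/pitch/yaw angles drawn from zero-mean truncated normal
#' distributions. Defaults (sd 5 degrees per axis, hard bound 15 degrees)
#' are a plausible magnitude for head deviation in a CT headrest.
#'
#' @param sdRoll,sdPitch,sdYaw Standard deviations in degrees (>= 0).
#' @param truncation Hard bound in degrees (> 0); samples are rejected
#'   outside +/- truncation.
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream (as [generateCohort()] does).
#' @return A validated list of class `MisalignmentModel`.
#' @export
misalignmentModel <- function(sdRoll = 5, sdPitch = 5, sdYaw = 5,
                              truncation = 15, seed = NULL) {
  if (any(c(sdRoll, sdPitch, sdYaw) < 0))
    stop("misalignmentModel: standard deviations must be >= 0")
  if (truncation <= 0) stop("misalignmentModel: truncation must be > 0")
  structure(list(sdRoll = sdRoll, sdPitch = sdPitch, sdYaw = sdYaw,
                 truncation = truncation, seed = seed),
            class = "MisalignmentModel")
}

.rtruncnorm <- function(k, sdv, bound) {
  if (sdv == 0) return(rep(0, k))
  out <- numeric(0)
  while (length(out) < k) {
    x <- rnorm(k, 0, sdv)
    out <- c(out, x[abs(x) <= bound])
  }
  out[seq_len(k)]
}

#' Sample acquisition misalignment angles
#'
#' @param model A [misalignmentModel()].
#' @param k Number of triples to draw (>= 0).
#' @return `k` x 3 data.frame with columns roll, pitch, yaw (degrees), every
#'   entry within +/- truncation.
#' @export
sampleMisalignment <- function(model, k) {
  stopifnot(inherits(model, "MisalignmentModel"), k >= 0)
  draw <- function() data.frame(
    roll = .rtruncnorm(k, model$sdRoll, model$truncation),
    pitch = .rtruncnorm(k, model$sdPitch, model$truncation),
    yaw = .rtruncnorm(k, model$sdYaw, model$truncation))
  if (is.null(model$seed)) draw()
  else withr::with_seed(as.integer(model$seed), draw())
}

#' Cohort specification for synthetic data generation
#'
#' @param nTrain,nVal,nTest Split sizes (>= 0). The defaults reproduce the
#'   90/30/30 patient split used for the clinical experiments.
#' @param shapeVariability Relative spread (fraction) applied per subject to
#'   the proxy lengths (default 0.10).
#' @param misalignment A [misalignmentModel()] (its own seed is ignored; the
#'   cohort seed drives one reproducible stream).
#' @param seed Integer seed; generation is bit-reproducible for a fixed
#'   seed.
#' @return A validated list of class `CohortSpec`.
#' @export
cohortSpec <- function(nTrain = 90L, nVal = 30L, nTest = 30L,
                       shapeVariability = 0.10,
                       misalignment = misalignmentModel(),
                       seed = 1L) {
  if (any(c(nTrain, nVal, nTest) < 0)) stop("cohortSpec: counts must be >= 0")
  if (shapeVariability < 0 || shapeVariability >= 1)
    stop("cohortSpec: shapeVariability must be in [0, 1)")
  structure(list(nTrain = as.integer(nTrain), nVal = as.integer(nVal),
                 nTest = as.integer(nTest),
                 shapeVariability = shapeVariability,
                 misalignment = misalignment, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Generate a labelled synthetic cohort
#'
#' For each subject a canonical-frame proxy mesh is generated with
#' per-subject shape variability, a misalignment Euler triple `e` is drawn,
#' and the "acquired" mesh is produced by rotating the canonical mesh by
#' `eulerToMatrix(e)` about its centroid. The stored ground truth is the
#' NHP-restoring rotation — the transpose of the applied misalignment — so
#' applying it to the acquired mesh reproduces the canonical mesh exactly.
#'
#' Each sample is a list with `subjectId`, `split`, `canonical` and
#' `acquired` ([TriangleMesh-class]), `gtRotation` (3 x 3), and `gtAngles`
#' (degrees). When `outDir` is given, the acquired meshes are written as
#' binary STL (one per subject) and the ground truth as
#' `ground_truth.csv` with columns subject_id, split, roll, pitch, yaw,
#' r11..r33 (row-major).
#'
#' @param spec A [cohortSpec()].
#' @param baseShape Base [shapeParams()] that per-subject variability
#'   perturbs.
#' @param outDir Optional output directory for STL + CSV artifacts.
#' @return A [SkullCohort-class].
#' @export
generateCohort <- function(spec = cohortSpec(), baseShape = shapeParams(),
                           outDir = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$nTrain + spec$nVal + spec$nTest
  splits <- rep(c("train", "val", "test"),
                times = c(spec$nTrain, spec$nVal, spec$nTest))
  mis <- spec$misalignment
  samples <- withr::with_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      sv <- spec$shapeVariability
      jitter <- function(x) x * pmax(0.5, 1 + rnorm(length(x), 0, sv))
      p <- shapeParams(
        craniumSemiaxes = jitter(baseShape$craniumSemiaxes),
        craniumExponent = baseShape$craniumExponent,
        # lengths vary per subject; directions are anatomy, not noise:
        # the jaw offset is scaled in norm only
        jawOffset = baseShape$jawOffset * jitter(1),
        jawScale = jitter(baseShape$jawScale),
        asymmetryBumpPosition = baseShape$asymmetryBumpPosition,
        asymmetryBumpAmplitude = jitter(baseShape$asymmetryBumpAmplitude),
        meshResolution = baseShape$meshResolution)
      e <- c(roll = .rtruncnorm(1, mis$sdRoll, mis$truncation),
             pitch = .rtruncnorm(1, mis$sdPitch, mis$truncation),
             yaw = .rtruncnorm(1, mis$sdYaw, mis$truncation))
      canonical <- makeSkullProxy(p)
      Rmis <- eulerToMatrix(e)
      acquired <- applyRotation(canonical, Rmis)   # about centroid
      gt <- t(Rmis)
      list(subjectId = sprintf("S%03d", i), split = splits[i],
           canonical = canonical, acquired = acquired,
           gtRotation = gt, gtAngles = matrixToEuler(gt))
    })
  })
  tab <- .cohortTable(samples)
  cohort <- new("SkullCohort", samples = samples, table = tab,
                spec = unclass(spec))
  if (!is.null(outDir)) writeCohort(cohort, outDir)
  cohort
}

.cohortTable <- function(samples) {
  rows <- lapply(samples, function(s) {
    g <- s$gtRotation
    data.frame(subject_id = s$subjectId, split = s$split,
               roll = s$gtAngles[["roll"]], pitch = s$gtAngles[["pitch"]],
               yaw = s$gtAngles[["yaw"]],
               r11 = g[1, 1], r12 = g[1, 2], r13 = g[1, 3],
               r21 = g[2, 1], r22 = g[2, 2], r23 = g[2, 3],
               r31 = g[3, 1], r32 = g[3, 2], r33 = g[3, 3])
  })
  do.call(rbind, rows)
}

#' @describeIn generateCohort write the STL files and ground-truth CSV
#' @export
writeCohort <- function(cohort, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort@samples)
    writeSTL(s$acquired, file.path(outDir, paste0(s$subjectId, ".stl")))
  write.csv(cohort@table, file.path(outDir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(outDir)
}
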