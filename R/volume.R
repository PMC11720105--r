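#' Global thresholding of a CT volume
#'
#' Segments bone by the inclusive rule S(x,y,z) = 1 if I(x,y,z) >= T, else 0.
#' The default threshold of 300 HU is a conventional bone threshold for
#' adult CT; clinical pipelines tune it per scanner, so it is exposed as a
#' parameter.
#'
#' @param volume An [IntensityVolume-class].
#' @param threshold Threshold T in Hounsfield units (default 300).
#' @return An [OccupancyVolume-class] on the same grid.
#' @export
thresholdSegment <- function(volume, threshold = 300) {
  stopifnot(is(volume, "IntensityVolume"), is.numeric(threshold),
            length(threshold) == 1L)
  occ <- array(0, dim = dim(volume@values))
  occ[volume@values >= threshold] <- 1
  occupancyVolume(occ, spacing = volume@spacing, origin = volume@origin)
}

# Separable 3^3 box smoothing with replicate padding, applied `iter` times.
# Anti-aliases the binary occupancy so the interpolated isosurface tracks the
# true object boundary instead of the voxel staircase.
.boxSmooth3 <- function(a, iter = 2) {
  smooth1 <- function(x, axis) {
    d <- dim(x)
    idx <- function(shift) {
      i <- pmin(pmax(seq_len(d[axis]) + shift, 1L), d[axis])
      switch(axis, x[i, , , drop = FALSE], x[, i, , drop = FALSE],
             x[, , i, drop = FALSE])
    }
    (idx(-1L) + idx(0L) + idx(1L)) / 3
  }
  for (k in seq_len(iter)) for (ax in 1:3) a <- smooth1(a, ax)
  a
}

# Tetrahedral decomposition of the unit cube (all 6 share diagonal v1-v7).
# Cube corners in (dx,dy,dz) offset order:
.CUBE_CORNERS <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                       c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
.CUBE_TETS <- rbind(c(1,2,3,7), c(1,3,4,7), c(1,4,8,7),
                    c(1,8,5,7), c(1,5,6,7), c(1,6,2,7))

#' Extract an isosurface mesh from a binary occupancy volume
#'
#' Marches a tetrahedral decomposition of the voxel grid at level 0.5. The
#' binary field is first lightly box-smoothed (`smoothIter` passes) so edge
#' interpolation places vertices on a faithful, anti-aliased boundary rather
#' than at voxel midpoints; with `smoothIter = 0` the raw binary field is
#' contoured. Vertices are returned in mm using the volume spacing and
#' origin, and only the largest connected surface component is retained
#' (small speckle components are the isosurface analogue of segmentation
#' noise a clinician would remove by hand).
#'
#' @param occ An [OccupancyVolume-class] with at least one foreground voxel.
#' @param smoothIter Box-smoothing passes before contouring (default 2).
#' @param keepLargestOnly Keep only the largest connected component
#'   (default TRUE).
#' @return A [TriangleMesh-class] in mm.
#' @export
extractSurface <- function(occ, smoothIter = 2, keepLargestOnly = TRUE) {
  stopifnot(is(occ, "OccupancyVolume"))
  if (sum(occ@values) == 0)
    stop("extractSurface: empty segmentation (no foreground voxels)")
  # zero-pad one voxel so objects touching the grid boundary still close
  d <- dim(occ@values)
  a <- array(0, d + 2L)
  a[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- occ@values
  a <- .boxSmooth3(a, iter = smoothIter)
  tri <- .marchingTetrahedra(a, level = 0.5)
  if (nrow(tri) == 0)
    stop("extractSurface: no isosurface crossing found")
  # padded voxel (i,j,k) center -> mm: origin + (i-2)*spacing
  tri <- sweep(sweep(tri, 2, c(2, 2, 2)) %*% diag(occ@spacing), 2,
               occ@origin, `+`)
  mesh <- .soupToMesh(tri, mergeTol = 1e-6 * max(occ@spacing))
  if (keepLargestOnly) mesh <- .largestComponent(mesh)
  mesh
}

# Vectorized marching tetrahedra on a 3D array; returns a triangle soup
# (3t x 3 matrix of vertex rows) in 1-based voxel-index coordinates.
.marchingTetrahedra <- function(a, level = 0.5) {
  d <- dim(a)
  nc <- d - 1L
  # restrict to cubes whose 2x2x2 block straddles the level
  lin <- function(i, j, k) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
  ii <- rep(seq_len(nc[1]), times = nc[2] * nc[3])
  jj <- rep(rep(seq_len(nc[2]), each = nc[1]), times = nc[3])
  kk <- rep(seq_len(nc[3]), each = nc[1] * nc[2])
  base <- lin(ii, jj, kk)
  off <- .CUBE_CORNERS
  cornerLin <- sapply(1:8, function(c8)
    base + off[c8, 1] + off[c8, 2] * d[1] + off[c8, 3] * d[1] * d[2])
  vals <- matrix(a[cornerLin], ncol = 8)
  inside <- vals >= level
  active <- which(rowSums(inside) > 0 & rowSums(inside) < 8)
  if (length(active) == 0) return(matrix(numeric(0), 0, 3))
  vals <- vals[active, , drop = FALSE]
  ii <- ii[active]; jj <- jj[active]; kk <- kk[active]

  soup <- vector("list", 6 * 15)
  sn <- 0L
  for (t6 in 1:6) {
    tc <- .CUBE_TETS[t6, ]
    tv <- vals[, tc, drop = FALSE]               # tet corner values
    tin <- tv >= level
    caseId <- tin[, 1] + 2L * tin[, 2] + 4L * tin[, 3] + 8L * tin[, 4]
    for (cs in 1:14) {
      rows <- which(caseId == cs)
      if (length(rows) == 0) next
      insideIdx <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0)
      # edge interpolation between tet corners p, q for the selected rows
      interp <- function(p, q) {
        vp <- tv[rows, p]; vq <- tv[rows, q]
        tt <- (level - vp) / (vq - vp)
        cp <- off[tc[p], ]; cq <- off[tc[q], ]
        cbind(ii + cp[1], jj + cp[2], kk + cp[3])[rows, , drop = FALSE] +
          tt * (cbind(cq[1] - cp[1], cq[2] - cp[2], cq[3] - cp[3])[
            rep(1, length(rows)), , drop = FALSE])
      }
      if (length(insideIdx) == 1L || length(insideIdx) == 3L) {
        one <- if (length(insideIdx) == 1L) insideIdx else setdiff(1:4, insideIdx)
        others <- setdiff(1:4, one)
        e1 <- interp(one, others[1])
        e2 <- interp(one, others[2])
        e3 <- interp(one, others[3])
        sn <- sn + 1L
        soup[[sn]] <- .interleave3(e1, e2, e3)
      } else {  # two inside, two outside: quad -> two triangles
        ins <- insideIdx; outs <- setdiff(1:4, ins)
        eA <- interp(ins[1], outs[1])
        eB <- interp(ins[1], outs[2])
        eC <- interp(ins[2], outs[2])
        eD <- interp(ins[2], outs[1])
        sn <- sn + 1L
        soup[[sn]] <- .interleave3(eA, eB, eC)
        sn <- sn + 1L
        soup[[sn]] <- .interleave3(eA, eC, eD)
      }
    }
  }
  do.call(rbind, soup[seq_len(sn)])
}

# Stack per-triangle corner matrices (t x 3 each) into a 3t x 3 soup with
# consecutive rows per triangle.
.interleave3 <- function(e1, e2, e3) {
  t3 <- nrow(e1)
  out <- matrix(0, 3 * t3, 3)
  out[seq(1, 3 * t3, by = 3), ] <- e1
  out[seq(2, 3 * t3, by = 3), ] <- e2
  out[seq(3, 3 * t3, by = 3), ] <- e3
  out
}

# Keep faces of the largest connected component (connectivity via shared
# vertices after merging).
.largestComponent <- function(mesh) {
  Fc <- meshFaces(mesh)
  if (nrow(Fc) <= 1) return(mesh)
  edges <- rbind(Fc[, 1:2], Fc[, 2:3], Fc[, c(1, 3)])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  keep <- comp$membership[Fc[, 1]] == big
  sub <- Fc[keep, , drop = FALSE]
  used <- sort(unique(as.vector(sub)))
  remap <- integer(nrow(meshVertices(mesh)))
  remap[used] <- seq_along(used)
  triangleMesh(meshVertices(mesh)[used, , drop = FALSE],
               matrix(remap[sub], ncol = 3))
}

#' Total surface area of a mesh
#'
#' @param mesh A [TriangleMesh-class].
#' @return Area in mm^2.
#' @export
meshArea <- function(mesh) {
  V <- meshVertices(mesh)
  Fc <- meshFaces(mesh)
  a <- V[Fc[, 2], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 3], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}
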