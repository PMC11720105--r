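#' Read a triangle mesh from an STL file
#'
#' Both binary and ASCII STL dialects are supported; the dialect is detected
#' from the file content (the `solid` keyword plus a `facet` token), not the
#' extension. STL stores a triangle soup, so coincident corner vertices are
#' merged within a tolerance to recover shared connectivity.
#'
#' @param path Path to an STL file.
#' @param mergeTol Vertices closer than this (mm) are merged; default 1e-6.
#' @return A [TriangleMesh-class].
#' @export
readSTL <- function(path, mergeTol = 1e-6) {
  if (!file.exists(path)) stop("readSTL: no such file: ", path)
  size <- file.info(path)$size
  if (is.na(size) || size < 15)
    stop("readSTL: malformed STL (file too short, ", size, " bytes at offset 0)")
  con <- file(path, "rb")
  on.exit(close(con))
  headRaw <- readBin(con, "raw", n = min(size, 512))
  isAscii <- length(grepRaw("solid", headRaw, fixed = TRUE)) > 0 &&
    length(grepRaw("facet", headRaw, fixed = TRUE)) > 0
  tri <- if (isAscii) .readSTLAscii(path) else .readSTLBinary(path, size)
  .soupToMesh(tri, mergeTol)
}

.readSTLBinary <- function(path, size) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + n * 50
  if (n < 0 || expected != size)
    stop(sprintf("readSTL: malformed binary STL (declared %d facets at offset 80, expected %d bytes, file has %d)",
                 n, expected, size))
  if (n == 0) return(matrix(numeric(0), 0, 3))
  body <- readBin(con, "raw", n = n * 50)
  # Each 50-byte record: 12 float32 (normal + 3 vertices) + uint16 attribute
  rec <- matrix(body, nrow = 50)
  floats <- readBin(as.vector(rec[1:48, ]), "numeric", n = n * 12, size = 4,
                    endian = "little")
  fl <- matrix(floats, nrow = 12)   # cols = facets
  tri <- t(fl[4:12, , drop = FALSE])  # drop normals
  matrix(t(tri), ncol = 3, byrow = TRUE)  # 3n x 3, vertex rows
}

.readSTLAscii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0)
    stop("readSTL: malformed ASCII STL (no vertex lines found at offset 0)")
  if (length(vl) %% 3 != 0)
    stop("readSTL: malformed ASCII STL (vertex count not a multiple of 3)")
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v)) stop("readSTL: malformed ASCII STL vertex line: ",
                       paste(tok, collapse = " "))
    v
  })
  do.call(rbind, nums)
}

# Merge soup vertices within tolerance and drop degenerate faces
.soupToMesh <- function(tri, mergeTol) {
  if (nrow(tri) == 0) return(triangleMesh(matrix(numeric(0), 0, 3),
                                          matrix(integer(0), 0, 3)))
  key <- apply(round(tri / mergeTol), 1, paste, collapse = ",")
  idx <- match(key, key)               # first occurrence per unique vertex
  keep <- !duplicated(idx)
  remap <- cumsum(keep)[idx]
  V <- tri[keep, , drop = FALSE]
  Fc <- matrix(remap, ncol = 3, byrow = TRUE)
  # degenerate faces: repeated indices or numerically zero area
  a <- V[Fc[, 2], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 3], , drop = FALSE] - V[Fc[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- sqrt(rowSums(cr^2))
  ok <- Fc[, 1] != Fc[, 2] & Fc[, 2] != Fc[, 3] & Fc[, 1] != Fc[, 3] &
    area2 > 1e-12
  triangleMesh(V, Fc[ok, , drop = FALSE])
}

#' Write a triangle mesh to binary STL
#'
#' Coordinates are stored as little-endian float32, the binary STL payload
#' type, so a write/read round trip preserves vertices to single precision.
#'
#' @param mesh A [TriangleMesh-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSTL <- function(mesh, path) {
  V <- meshVertices(mesh)
  Fc <- meshFaces(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "nhpnet binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(Fc)), con, size = 4, endian = "little")
  if (nrow(Fc) > 0) {
    p1 <- V[Fc[, 1], , drop = FALSE]
    p2 <- V[Fc[, 2], , drop = FALSE]
    p3 <- V[Fc[, 3], , drop = FALSE]
    e1 <- p2 - p1; e2 <- p3 - p1
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    # 12 float32 per facet, row-wise: normal, v1, v2, v3
    fl <- t(cbind(nrm, p1, p2, p3))
    raw12 <- writeBin(as.numeric(fl), raw(), size = 4, endian = "little")
    recs <- matrix(as.raw(0), nrow = 50, ncol = nrow(Fc))
    recs[1:48, ] <- matrix(raw12, nrow = 48)
    writeBin(as.vector(recs), con)
  }
  invisible(path)
}

#' Write a triangle mesh to ASCII STL
#'
#' Mostly useful for small, human-readable fixtures; [writeSTL()] is the
#' production writer.
#'
#' @inheritParams writeSTL
#' @export
writeSTLAscii <- function(mesh, path) {
  V <- meshVertices(mesh)
  Fc <- meshFaces(mesh)
  out <- c("solid nhpnet")
  for (i in seq_len(nrow(Fc))) {
    tri <- V[Fc[i, ], , drop = FALSE]
    out <- c(out,
             "  facet normal 0 0 0",
             "    outer loop",
             sprintf("      vertex %.9g %.9g %.9g", tri[1, 1], tri[1, 2], tri[1, 3]),
             sprintf("      vertex %.9g %.9g %.9g", tri[2, 1], tri[2, 2], tri[2, 3]),
             sprintf("      vertex %.9g %.9g %.9g", tri[3, 1], tri[3, 2], tri[3, 3]),
             "    endloop",
             "  endfacet")
  }
  writeLines(c(out, "endsolid nhpnet"), path)
  invisible(path)
}
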