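#' Read / write intensity volumes
#'
#' Two on-disk forms are supported. NIfTI (`.nii` / `.nii.gz`, via the
#' RNifti package) covers exports from clinical toolchains; voxel spacing
#' is taken from the header pixel dimensions and the origin from the
#' stored spatial transform's translation. The plain-text form is a JSON
#' header carrying `dim`, `spacing`, `origin` and `data_file`, the latter
#' naming a sidecar text file of intensities in column-major (R array)
#' order — convenient for fixtures and language-agnostic pipelines.
#'
#' @param path Path to a `.nii`/`.nii.gz` file or a `.json` header.
#' @return An [IntensityVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("readVolume: no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    hdr <- jsonlite::fromJSON(path)
    need <- c("dim", "spacing", "origin", "data_file")
    if (!all(need %in% names(hdr)))
      stop("readVolume: JSON header must contain ",
           paste(need, collapse = ", "))
    dataPath <- file.path(dirname(path), hdr$data_file)
    vals <- scan(dataPath, what = numeric(), quiet = TRUE)
    if (length(vals) != prod(hdr$dim))
      stop("readVolume: data file has ", length(vals),
           " values, header expects ", prod(hdr$dim))
    intensityVolume(array(vals, dim = hdr$dim), spacing = hdr$spacing,
                    origin = hdr$origin)
  } else {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("readVolume: the RNifti package is required for NIfTI input")
    img <- RNifti::readNifti(path)
    xf <- RNifti::xform(img)
    intensityVolume(array(as.numeric(img), dim = dim(img)),
                    spacing = abs(RNifti::pixdim(img))[1:3],
                    origin = as.numeric(xf[1:3, 4]))
  }
}

#' @describeIn readVolume write the plain-text JSON + data form
#' @param volume An [IntensityVolume-class] or [OccupancyVolume-class].
#' @param path Output path for the `.json` header; the data file is written
#'   alongside it with extension `.dat.txt`.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(grepl("\\.json$", path, ignore.case = TRUE))
  dataFile <- sub("\\.json$", ".dat.txt", basename(path), ignore.case = TRUE)
  hdr <- list(dim = dim(volume@values), spacing = volume@spacing,
              origin = volume@origin, data_file = dataFile)
  jsonlite::write_json(hdr, path, auto_unbox = FALSE, digits = NA)
  writeLines(format(as.vector(volume@values), scientific = FALSE,
                    trim = TRUE),
             file.path(dirname(path), dataFile))
  invisible(path)
}
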