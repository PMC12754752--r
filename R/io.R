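#' Write / read a skull slice as NIfTI plus JSON sidecar
#'
#' The HU raster is stored as a NIfTI volume; pixel spacing, bone
#' threshold and provenance seed go to a `.json` sidecar next to it.
#'
#' @param slice A [skull_slice()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_slice_nifti <- function(slice, path) {
  img <- RNifti::asNifti(slice$hu_grid,
                         pixdim = rep(slice$pixel_spacing_mm, 2L))
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(pixel_spacing_mm = slice$pixel_spacing_mm,
                            bone_threshold_hu = slice$bone_threshold_hu,
                            provenance_seed = slice$provenance_seed),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_slice_nifti
#' @export
read_slice_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  skull_slice(matrix(as.numeric(img), nrow = dim(img)[1L]),
              meta$pixel_spacing_mm,
              bone_threshold_hu = meta$bone_threshold_hu,
              provenance_seed = meta$provenance_seed)
}

#' Export a raster to an 8-bit grayscale PNG for visualization
#'
#' @param x Numeric matrix (e.g. a normalized field or canvas image);
#'   values are rescaled to `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(x, path) {
  if (inherits(x, "pressure_field")) x <- x$normalized
  rng <- range(x)
  z <- if (diff(rng) > 0) (x - rng[1L]) / diff(rng) else x * 0
  png::writePNG(z, path)
  invisible(path)
}

#' Serialize a phase vector to JSON
#'
#' @param v A [phase_vector()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phase_json <- function(v, path) {
  jsonlite::write_json(list(f0_hz = v$f0_hz, delays_s = v$delays_s),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phase_json
#' @export
read_phase_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  phase_vector(d$delays_s, d$f0_hz)
}
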