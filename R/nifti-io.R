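#' Read and write PET volumes as NIfTI
#'
#' Volumes are stored as 3D NIfTI images (`.nii` / `.nii.gz`); voxel spacing
#' lives in `pixdim` and the origin in the qform translation. An optional
#' JSON sidecar (`<path>.json`) carries the acquisition metadata needed for
#' SUV conversion (`injected_activity_kBq`, `body_weight_g`) plus the value
#' units.
#'
#' @param path File path of a 3D NIfTI image.
#' @param units Units to assume when no sidecar is present.
#' @return `read_pet_volume()` returns a [pet_volume()] with, if a sidecar
#'   was found, an `acquisition` attribute holding the metadata list.
#' @export
read_pet_volume <- function(path, units = c("suv", "kBq/mL")) {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    abort(sprintf("Expected a 3D image, got %d dimensions.", length(d)),
          class = "petefs_format_error")
  }
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) {
    abort("Image is missing a valid voxel spacing.",
          class = "petefs_format_error")
  }
  xf <- RNifti::xform(img)
  org <- as.numeric(xf[1:3, 4])
  sidecar <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$units)) units <- meta$units
  }
  vals <- array(as.numeric(img), dim = d)  # drop niftiImage attributes
  out <- pet_volume(vals, spacing = sp[1:3], origin = org, units = units)
  if (!is.null(meta)) attr(out, "acquisition") <- meta
  out
}

#' @rdname read_pet_volume
#' @param volume A [pet_volume()].
#' @param acquisition Optional named list written to the JSON sidecar (e.g.
#'   `list(injected_activity_kBq = 370000, body_weight_g = 74000)`).
#' @return `write_pet_volume()` invisibly returns `path`.
#' @export
write_pet_volume <- function(volume, path, acquisition = NULL) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$values)
  aff <- diag(c(volume$spacing, 1))
  aff[1:3, 4] <- volume$origin
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  if (!is.null(acquisition) || volume$units != "suv") {
    meta <- c(acquisition, list(units = volume$units))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}
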