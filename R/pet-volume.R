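#' PET volume objects
#'
#' A `pet_volume` is a 3D array of voxel values (usually standardized uptake
#' values, SUV) together with the voxel spacing in mm and the scanner-space
#' position of the first voxel. It is the raster object every downstream
#' operation (segmentation, intensity indices, texture) reads.
#'
#' @param values Numeric 3D array of finite, non-negative voxel values.
#' @param spacing Numeric length-3 vector, voxel edge lengths in mm (all > 0).
#' @param origin Numeric length-3 vector, mm position of voxel (1,1,1).
#' @param units Either `"suv"` (dimensionless standardized uptake values) or
#'   `"kBq/mL"` (activity concentration prior to SUV conversion).
#'
#' @return An object of class `pet_volume`.
#' @examples
#' v <- pet_volume(array(1, dim = c(4, 4, 4)), spacing = c(4, 4, 4))
#' voxel_volume_ml(v)
#' @export
pet_volume <- function(values, spacing = c(4, 4, 4), origin = c(0, 0, 0),
                       units = c("suv", "kBq/mL")) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.", class = "petefs_format_error")
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    abort("Voxel values must be finite.", class = "petefs_format_error")
  }
  if (any(values < 0)) {
    abort("Voxel values must be non-negative.", class = "petefs_format_error")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive values (mm).",
          class = "petefs_format_error")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be 3 finite values (mm).",
          class = "petefs_format_error")
  }
  structure(list(values = values, spacing = spacing, origin = origin,
                 units = units),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pet_volume> %d x %d x %d voxels, spacing %s mm, units %s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "), x$units))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$values)

#' Voxel volume in millilitres
#'
#' @param volume A [pet_volume()].
#' @return Voxel volume in mL (`dx * dy * dz / 1000` with spacing in mm).
#' @export
voxel_volume_ml <- function(volume) {
  stopifnot(inherits(volume, "pet_volume"))
  prod(volume$spacing) / 1000
}

#' Convert activity concentration to standardized uptake values
#'
#' SUV normalises the tissue tracer concentration by the injected activity
#' per unit body weight: `SUV = concentration (kBq/mL) /
#' (injected_activity_kbq / body_weight_g)`. The result is dimensionless.
#'
#' @param volume A [pet_volume()] holding activity concentration in kBq/mL.
#' @param injected_activity_kbq Injected activity in kBq (> 0).
#' @param body_weight_g Patient body weight in grams (> 0).
#' @return A [pet_volume()] in SUV units with spacing and origin preserved.
#' @examples
#' conc <- pet_volume(array(5, dim = c(2, 2, 2)), units = "kBq/mL")
#' suv <- activity_to_suv(conc, injected_activity_kbq = 370000,
#'                        body_weight_g = 74000)
#' max(suv$values) # 1
#' @export
activity_to_suv <- function(volume, injected_activity_kbq, body_weight_g) {
  stopifnot(inherits(volume, "pet_volume"))
  if (!is.numeric(injected_activity_kbq) || length(injected_activity_kbq) != 1 ||
      !is.finite(injected_activity_kbq) || injected_activity_kbq <= 0) {
    abort("`injected_activity_kbq` must be a single positive number.",
          class = "petefs_metadata_error")
  }
  if (!is.numeric(body_weight_g) || length(body_weight_g) != 1 ||
      !is.finite(body_weight_g) || body_weight_g <= 0) {
    abort("`body_weight_g` must be a single positive number.",
          class = "petefs_metadata_error")
  }
  out <- volume
  out$values <- volume$values / (injected_activity_kbq / body_weight_g)
  out$units <- "suv"
  out
}

#' Region-of-interest box
#'
#' A rectangular voxel-index box standing in for the manual delineation of a
#' large region encompassing the tumor and surrounding tissue. Bounds are
#' 1-based and inclusive on each axis.
#'
#' @param lower,upper Integer length-3 vectors of voxel indices with
#'   `lower <= upper` componentwise.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(lower, upper) {
  lower <- as.integer(lower)
  upper <- as.integer(upper)
  if (length(lower) != 3L || length(upper) != 3L || anyNA(lower) ||
      anyNA(upper)) {
    abort("`lower` and `upper` must be 3 integer indices.",
          class = "petefs_bounds_error")
  }
  if (any(lower < 1L) || any(lower > upper)) {
    abort("Need 1 <= lower <= upper on every axis.",
          class = "petefs_bounds_error")
  }
  structure(list(lower = lower, upper = upper), class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> [%s] .. [%s]\n",
              paste(x$lower, collapse = ", "),
              paste(x$upper, collapse = ", ")))
  invisible(x)
}

#' Crop a PET volume to a region-of-interest box
#'
#' @param volume A [pet_volume()].
#' @param box A [roi_box()] lying entirely inside the volume.
#' @return A [pet_volume()] containing exactly the voxels inside the box;
#'   origin is shifted so cropped voxels keep their scanner-space position.
#' @export
crop_roi <- function(volume, box) {
  stopifnot(inherits(volume, "pet_volume"), inherits(box, "roi_box"))
  d <- dim(volume$values)
  if (any(box$upper > d)) {
    abort("ROI box exceeds the volume extent.", class = "petefs_bounds_error")
  }
  vals <- volume$values[box$lower[1]:box$upper[1],
                        box$lower[2]:box$upper[2],
                        box$lower[3]:box$upper[3], drop = FALSE]
  pet_volume(vals, spacing = volume$spacing,
             origin = volume$origin + (box$lower - 1L) * volume$spacing,
             units = volume$units)
}
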