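#' Per-lesion metabolic intensity indices
#'
#' Computes the standard FDG-PET intensity indices over a segmented tumor:
#' SUVmax (hottest voxel), SUVmean (mean over the mask), SUVpeak (mean over
#' the hottest 1 cm^3 spherical neighbourhood, see [suv_peak()]), MATV
#' (mask voxel count times voxel volume, in mL) and TLG (MATV x SUVmean).
#'
#' @param volume A [pet_volume()] in SUV units.
#' @param mask A `seg_mask` from [segment_adaptive()] / [segment_fixed()],
#'   or a logical array congruent with `volume`.
#' @return A one-row tibble with columns `suv_max`, `suv_mean`, `suv_peak`,
#'   `matv_ml`, `tlg`.
#' @examples
#' v <- pet_volume(array(4, dim = c(5, 5, 4)), spacing = c(4, 4, 4))
#' m <- array(TRUE, dim(v))
#' metabolic_indices(v, m)
#' @export
metabolic_indices <- function(volume, mask) {
  stopifnot(inherits(volume, "pet_volume"))
  m <- as_mask_array(mask, dim(volume$values))
  if (!any(m)) abort("Empty mask.", class = "petefs_empty_segmentation")
  vox <- volume$values[m]
  suv_mean <- mean(vox)
  matv <- sum(m) * voxel_volume_ml(volume)
  tibble(
    suv_max = max(vox),
    suv_mean = suv_mean,
    suv_peak = suv_peak(volume, m),
    matv_ml = matv,
    tlg = matv * suv_mean
  )
}

#' SUVpeak: mean uptake over the hottest 1 cm^3 sphere
#'
#' For every voxel center inside the mask, a sphere of volume `sphere_ml`
#' (1 cm^3 by default, radius 6.2035 mm) is centred there and the mean SUV of
#' all voxels whose centers fall strictly within the sphere is taken; the
#' maximum of these means is SUVpeak. The sphere may extend beyond the mask
#' into surrounding tissue, but not beyond the volume.
#'
#' @inheritParams metabolic_indices
#' @param sphere_ml Sphere volume in mL.
#' @return A single SUV value (always `<= suv_max`).
#' @export
suv_peak <- function(volume, mask, sphere_ml = 1) {
  stopifnot(inherits(volume, "pet_volume"))
  m <- as_mask_array(mask, dim(volume$values))
  if (!any(m)) abort("Empty mask.", class = "petefs_empty_segmentation")
  r_mm <- (3 * sphere_ml * 1000 / (4 * pi))^(1 / 3)  # mL -> mm^3
  sp <- volume$spacing
  d <- dim(volume$values)
  # voxel-index offsets whose center-to-center distance is < r
  reach <- floor(r_mm / sp)
  offs <- as.matrix(expand.grid(di = -reach[1]:reach[1],
                                dj = -reach[2]:reach[2],
                                dk = -reach[3]:reach[3]))
  dist2 <- (offs[, 1] * sp[1])^2 + (offs[, 2] * sp[2])^2 +
    (offs[, 3] * sp[3])^2
  offs <- offs[dist2 < r_mm^2, , drop = FALSE]
  centers <- which(m, arr.ind = TRUE)
  best <- -Inf
  for (i in seq_len(nrow(centers))) {
    nb <- sweep(offs, 2, centers[i, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    best <- max(best, mean(volume$values[lin]))
  }
  best
}

as_mask_array <- function(mask, dims) {
  m <- if (inherits(mask, "seg_mask")) mask$mask else mask
  if (!is.logical(m) || !identical(dim(m), dims)) {
    abort("Mask must be a logical array congruent with the volume.",
          class = "petefs_format_error")
  }
  m
}
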