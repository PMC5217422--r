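#' Segmentation of the metabolically active tumor volume
#'
#' Two threshold-based segmentations of an ROI-cropped SUV volume are
#' provided. Both keep only the 26-connected component containing the
#' hottest voxel, reflecting the single-primary-tumor setting.
#'
#' `segment_adaptive()` iterates a background-adapted threshold: starting
#' from `T0 = init_fraction * SUVmax`, the mask at step k is the connected
#' component (seeded at the SUVmax voxel) of voxels at or above `T_k`, and
#' the next threshold is `alpha * mean(SUV over mask_k) +
#' (1 - alpha) * background`. Iteration stops when the mask no longer
#' changes.
#'
#' `segment_fixed()` thresholds at a fixed fraction of SUVmax.
#'
#' @param volume An ROI-cropped [pet_volume()] in SUV units.
#' @param background Background SUV level, or `"auto"` to estimate it as the
#'   median SUV of ROI voxels outside the 40%-of-max region (the ROI is
#'   assumed to contain healthy tissue around the tumor).
#' @param alpha Weight of the mask mean in the threshold update (default 0.5).
#' @param init_fraction Initial threshold as a fraction of SUVmax.
#' @param max_iter Iteration cap before a convergence error is raised.
#' @return A `seg_mask`: list with `mask` (logical array congruent with the
#'   volume), `method`, `threshold_used` (SUV), and `n_iter`.
#' @examples
#' ph <- make_phantom(radius_mm = 10, spacing_mm = 2, psf_fwhm_mm = 0,
#'                    noise_sd = 0, heterogeneity = 0, seed = 1)
#' m <- segment_adaptive(ph$volume)
#' sum(m$mask) * voxel_volume_ml(ph$volume) # ~ analytic sphere volume
#' @export
segment_adaptive <- function(volume, background = "auto", alpha = 0.5,
                             init_fraction = 0.4, max_iter = 100L) {
  stopifnot(inherits(volume, "pet_volume"))
  vals <- volume$values
  suv_max <- max(vals)
  bg <- if (identical(background, "auto")) {
    estimate_background(volume)
  } else {
    as.numeric(background)
  }
  if (suv_max <= bg) {
    abort("No voxel above background: nothing to segment.",
          class = "petefs_empty_segmentation")
  }
  seed <- which.max(vals)
  thr <- init_fraction * suv_max
  if (!any(vals >= thr)) {
    abort("No voxel above the initial threshold.",
          class = "petefs_empty_segmentation")
  }
  mask <- connected_component(vals >= thr, seed)
  for (k in seq_len(max_iter)) {
    thr <- alpha * mean(vals[mask]) + (1 - alpha) * bg
    if (thr >= suv_max) thr <- suv_max  # never lose the seed voxel
    mask_new <- connected_component(vals >= thr, seed)
    if (identical(mask_new, mask)) {
      return(new_seg_mask(mask, "adaptive", thr, k))
    }
    mask <- mask_new
  }
  abort("Adaptive threshold did not converge.",
        class = "petefs_convergence_error",
        last_mask = mask, threshold = thr)
}

#' @rdname segment_adaptive
#' @param fraction Fixed threshold as a fraction of SUVmax, in (0, 1).
#' @export
segment_fixed <- function(volume, fraction = 0.4) {
  stopifnot(inherits(volume, "pet_volume"))
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction <= 0 ||
      fraction >= 1) {
    abort("`fraction` must lie in (0, 1).", class = "petefs_format_error")
  }
  vals <- volume$values
  suv_max <- max(vals)
  if (suv_max <= 0) {
    abort("Volume has no positive uptake.",
          class = "petefs_empty_segmentation")
  }
  thr <- fraction * suv_max
  mask <- connected_component(vals >= thr, which.max(vals))
  new_seg_mask(mask, "fixed", thr, 1L)
}

new_seg_mask <- function(mask, method, threshold, n_iter) {
  structure(list(mask = mask, method = method,
                 threshold_used = threshold, n_iter = as.integer(n_iter)),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s threshold %.4g SUV, %d voxels, %d iteration(s)\n",
              x$method, x$threshold_used, sum(x$mask), x$n_iter))
  invisible(x)
}

#' Background SUV estimate inside an ROI
#'
#' Median SUV over voxels outside the 40%-of-max region; falls back to the
#' global median when every voxel exceeds that level.
#'
#' @param volume A [pet_volume()].
#' @return A single SUV value.
#' @export
estimate_background <- function(volume) {
  vals <- volume$values
  out <- vals[vals < 0.4 * max(vals)]
  if (length(out) == 0) return(median(vals))
  median(out)
}

# 26 neighbour offsets (Chebyshev distance 1) as a 26 x 3 integer matrix
neighbour_offsets_26 <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Connected component of `keep` (logical 3D array) containing linear index
# `seed`, under 26-connectivity. Breadth-first frontier expansion.
connected_component <- function(keep, seed) {
  d <- dim(keep)
  if (!keep[seed]) {
    out <- array(FALSE, d)
    return(out)
  }
  offs <- neighbour_offsets_26()
  visited <- array(FALSE, d)
  visited[seed] <- TRUE
  frontier <- matrix(arrayInd(seed, d), ncol = 3)
  while (nrow(frontier) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r) {
      sweep(frontier, 2, offs[r, ], `+`)
    }))
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) break
    lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
    new <- keep[lin] & !visited[lin]
    if (!any(new)) break
    lin_new <- unique(lin[new])
    visited[lin_new] <- TRUE
    frontier <- matrix(arrayInd(lin_new, d), ncol = 3)
  }
  visited
}
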