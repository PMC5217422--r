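#' 64-bin intensity quantization over a tumor mask
#'
#' SUVs inside the mask are rescaled to `n_bins` discrete gray levels using
#' the in-mask minimum and maximum: `bin(v) = ceil(n_bins * (v - min) /
#' (max - min))`, clamped to `[1, n_bins]`; a constant region maps to bin 1.
#' Texture features built on this quantization are therefore invariant to
#' affine rescaling of the SUVs.
#'
#' @param volume A [pet_volume()] in SUV units.
#' @param mask A `seg_mask` or logical array congruent with `volume`.
#' @param n_bins Number of gray levels (64 by default).
#' @return Integer array congruent with the volume; `NA` outside the mask.
#' @export
quantize_suv <- function(volume, mask, n_bins = 64L) {
  stopifnot(inherits(volume, "pet_volume"))
  m <- as_mask_array(mask, dim(volume$values))
  if (!any(m)) abort("Empty mask.", class = "petefs_empty_segmentation")
  v <- volume$values[m]
  lo <- min(v)
  hi <- max(v)
  bins <- if (hi == lo) {
    rep(1L, length(v))
  } else {
    pmin(pmax(ceiling(n_bins * (v - lo) / (hi - lo)), 1L), n_bins)
  }
  q <- array(NA_integer_, dim(volume$values))
  q[m] <- as.integer(bins)
  attr(q, "n_bins") <- as.integer(n_bins)
  q
}

#' 3D gray-level co-occurrence matrix at distance one
#'
#' Counts unordered pairs of in-mask voxels at Chebyshev distance 1
#' (26-neighbourhood; the 13 unique directions are pooled into a single
#' symmetric matrix). Each pair with bins (i, j) increments both `P[i, j]`
#' and `P[j, i]`; pairs with a voxel outside the mask are discarded. By
#' default the matrix is normalized to sum to 1.
#'
#' @param quantized Integer array from [quantize_suv()] (`NA` outside mask).
#' @param n_bins Number of gray levels; taken from `quantized` if present.
#' @param normalize Normalize counts to probabilities (default `TRUE`).
#' @return `n_bins x n_bins` numeric matrix with attribute `normalized`.
#' @export
glcm_3d <- function(quantized, n_bins = NULL, normalize = TRUE) {
  n_bins <- n_bins %||% attr(quantized, "n_bins") %||% 64L
  d <- dim(quantized)
  stopifnot(length(d) == 3L)
  P <- matrix(0, n_bins, n_bins)
  dirs <- neighbour_offsets_26()
  dirs <- dirs[dirs[, 3] > 0 | (dirs[, 3] == 0 & dirs[, 2] > 0) |
                 (dirs[, 3] == 0 & dirs[, 2] == 0 & dirs[, 1] > 0), ,
               drop = FALSE]  # 13 unique directions
  for (r in seq_len(nrow(dirs))) {
    o <- dirs[r, ]
    ia <- seq_len(d[1] - abs(o[1])) + max(-o[1], 0)
    ja <- seq_len(d[2] - abs(o[2])) + max(-o[2], 0)
    ka <- seq_len(d[3] - abs(o[3])) + max(-o[3], 0)
    a <- quantized[ia, ja, ka, drop = FALSE]
    b <- quantized[ia + o[1], ja + o[2], ka + o[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = seq_len(n_bins)),
                 factor(b[ok], levels = seq_len(n_bins)))
    P <- P + tab + t(tab)
  }
  if (sum(P) == 0) {
    abort("Mask has no adjacent voxel pairs.", class = "petefs_format_error")
  }
  if (normalize) P <- P / sum(P)
  P <- matrix(as.numeric(P), n_bins, n_bins)
  attr(P, "normalized") <- normalize
  P
}

#' Haralick entropy of a co-occurrence matrix
#'
#' `E = -sum_ij P[i,j] log P[i,j]` in nats, with `0 log 0 := 0`. High when
#' adjacent-voxel intensity pairs are spread over many bin combinations.
#'
#' @param P Normalized co-occurrence matrix from [glcm_3d()].
#' @return Entropy in nats, in `[0, log(n_bins^2)]`.
#' @export
glcm_entropy <- function(P) {
  check_normalized(P)
  p <- P[P > 0]
  -sum(p * log(p))
}

#' Haralick homogeneity of a co-occurrence matrix
#'
#' `H = sum_ij P[i,j] / (1 + |i - j|)`. High when adjacent voxels fall in
#' similar intensity bins; equals 1 for a purely diagonal matrix.
#'
#' @inheritParams glcm_entropy
#' @return Homogeneity in `(0, 1]`.
#' @export
glcm_homogeneity <- function(P) {
  check_normalized(P)
  n <- nrow(P)
  w <- 1 / (1 + abs(outer(seq_len(n), seq_len(n), `-`)))
  sum(P * w)
}

check_normalized <- function(P) {
  if (!isTRUE(attr(P, "normalized")) ||
      abs(sum(P) - 1) > 1e-8) {
    abort("Co-occurrence matrix must be normalized to sum 1.",
          class = "petefs_format_error")
  }
  invisible(P)
}

#' Texture features of a segmented tumor
#'
#' Convenience wrapper: quantize, build the 3D co-occurrence matrix at
#' distance one, and return the two texture indices.
#'
#' @inheritParams quantize_suv
#' @return One-row tibble with `entropy_nats` and `homogeneity`.
#' @export
texture_features <- function(volume, mask, n_bins = 64L) {
  q <- quantize_suv(volume, mask, n_bins)
  P <- glcm_3d(q, n_bins)
  tibble(entropy_nats = glcm_entropy(P), homogeneity = glcm_homogeneity(P))
}
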