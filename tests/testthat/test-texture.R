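test_that("quantization maps the in-mask range onto 1..n_bins", {
  # constant region -> bin 1
  v <- pet_volume(array(3, c(3, 3, 3)))
  m <- array(TRUE, c(3, 3, 3))
  expect_true(all(quantize_suv(v, m)[m] == 1L))

  # endpoints map to 1 and n_bins
  vals <- array(5, c(4, 4, 4))
  vals[1] <- 1
  vals[2] <- 9
  v2 <- pet_volume(vals)
  q2 <- quantize_suv(v2, array(TRUE, c(4, 4, 4)))
  expect_equal(q2[1], 1L)
  expect_equal(q2[2], 64L)

  # 64 evenly spaced values over (1, 65] hit each bin exactly once
  vals3 <- array(seq(2, 65, by = 1), c(4, 4, 4))
  vals3[1] <- 1  # min
  q3 <- quantize_suv(pet_volume(vals3), array(TRUE, c(4, 4, 4)))
  expect_equal(sort(unique(as.vector(q3))), 1:64)
  expect_equal(as.vector(table(q3)), rep(1L, 64))
})

test_that("co-occurrence matrix matches the pair-enumeration oracle", {
  set.seed(12)
  for (k in 1:4) {
    n_bins <- c(4L, 8L)[(k %% 2) + 1]
    d <- c(4, 5, 3)
    m <- array(runif(prod(d)) < 0.6, d)
    m[2, 2, 2] <- TRUE
    v <- pet_volume(array(runif(prod(d), 0, 10), d))
    q <- quantize_suv(v, m, n_bins = n_bins)
    P <- glcm_3d(q, n_bins)
    expect_equal(matrix(P, n_bins, n_bins), oracle_glcm(q, n_bins))
    expect_equal(P, t(P))        # symmetry
    expect_equal(sum(P), 1)      # normalization
  }
})

test_that("two adjacent voxels with distinct bins give P[1,2] = P[2,1] = 0.5", {
  vals <- array(0, c(3, 3, 3))
  vals[1, 1, 1] <- 1
  vals[2, 1, 1] <- 5
  m <- array(FALSE, c(3, 3, 3))
  m[1:2, 1, 1] <- TRUE
  q <- quantize_suv(pet_volume(vals), m, n_bins = 2)
  P <- glcm_3d(q, 2)
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(P[1, 1] + P[2, 2], 0)
})

test_that("entropy and homogeneity match closed forms", {
  # all mass in one diagonal cell
  P <- matrix(0, 64, 64)
  P[5, 5] <- 1
  attr(P, "normalized") <- TRUE
  expect_equal(glcm_entropy(P), 0)
  expect_equal(glcm_homogeneity(P), 1)

  # uniform mass over all 64^2 cells
  U <- matrix(1 / 4096, 64, 64)
  attr(U, "normalized") <- TRUE
  expect_equal(glcm_entropy(U), log(4096))
  idx <- abs(outer(1:64, 1:64, `-`))
  expect_equal(glcm_homogeneity(U), sum(1 / (1 + idx)) / 4096)

  # 2-bin toy matrix, hand evaluation
  M <- matrix(c(0.5, 0.25, 0.25, 0), 2, 2)
  attr(M, "normalized") <- TRUE
  expect_equal(glcm_entropy(M), 1.5 * log(2))
  expect_equal(M[1, 2], 0.25)
  expect_equal(glcm_homogeneity(M), 0.5 + 0.25 / 2 + 0.25 / 2)

  # extreme off-diagonal mass
  O <- matrix(0, 64, 64)
  O[1, 64] <- 0.5
  O[64, 1] <- 0.5
  attr(O, "normalized") <- TRUE
  expect_equal(glcm_homogeneity(O), 1 / 64)

  # unnormalized input is rejected
  bad <- matrix(1, 4, 4)
  attr(bad, "normalized") <- FALSE
  expect_error(glcm_entropy(bad), class = "petefs_format_error")
  expect_error(glcm_homogeneity(bad), class = "petefs_format_error")
})

test_that("texture bounds hold and a constant tumor is the degenerate limit", {
  set.seed(13)
  for (k in 1:10) {
    d <- c(5, 5, 5)
    m <- array(runif(prod(d)) < 0.7, d)
    m[2:3, 2:3, 2:3] <- TRUE
    v <- pet_volume(array(runif(prod(d), 0, 15), d))
    q <- quantize_suv(v, m)
    P <- glcm_3d(q, 64)
    E <- glcm_entropy(P)
    H <- glcm_homogeneity(P)
    expect_gte(E, 0)
    expect_lte(E, log(64^2))
    expect_gt(H, 0)
    expect_lte(H, 1)
  }
  ph <- make_phantom(radius_mm = 10, spacing_mm = 2)
  tf <- texture_features(ph$volume, ph$truth_mask)
  expect_equal(tf$entropy_nats, 0)
  expect_equal(tf$homogeneity, 1)
})

test_that("texture is invariant to affine SUV rescaling", {
  ph <- make_phantom(radius_mm = 10, spacing_mm = 2, heterogeneity = 1.5,
                     seed = 6)
  t1 <- texture_features(ph$volume, ph$truth_mask)
  v2 <- ph$volume
  v2$values <- 2.5 * v2$values + 1
  t2 <- texture_features(v2, ph$truth_mask)
  expect_equal(t1, t2)
})

test_that("heterogeneous tumors score higher entropy / lower homogeneity than homogeneous ones", {
  # Min-max quantization makes texture scale-free in the field amplitude
  # (see the affine-invariance test), so heterogeneity is detected as
  # presence of spatial structure, not as its amplitude.
  e <- h <- numeric(8)
  for (i in 1:8) {
    ph <- make_phantom(radius_mm = 12, spacing_mm = 2, heterogeneity = 1.5,
                       correlation_mm = 4, seed = i)
    tf <- texture_features(ph$volume, ph$truth_mask)
    e[i] <- tf$entropy_nats
    h[i] <- tf$homogeneity
  }
  hom <- texture_features(make_phantom(radius_mm = 12, spacing_mm = 2)$volume,
                          make_phantom(radius_mm = 12, spacing_mm = 2)$truth_mask)
  expect_true(all(e > hom$entropy_nats))   # 0 for the constant tumor
  expect_true(all(h < hom$homogeneity))    # 1 for the constant tumor
  # and identically-seeded fields at different amplitudes tie exactly
  p1 <- make_phantom(radius_mm = 12, spacing_mm = 2, heterogeneity = 0.5,
                     correlation_mm = 8, seed = 3)
  p2 <- make_phantom(radius_mm = 12, spacing_mm = 2, heterogeneity = 1,
                     correlation_mm = 8, seed = 3)
  expect_equal(texture_features(p1$volume, p1$truth_mask),
               texture_features(p2$volume, p2$truth_mask))
})
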