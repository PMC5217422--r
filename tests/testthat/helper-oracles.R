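# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and no code from R/.

# Mean-in-sphere search over all mask voxels, testing every voxel of the
# volume for strict center-in-sphere inclusion.
oracle_suv_peak <- function(vals, spacing, mask, sphere_ml = 1) {
  r <- (3 * sphere_ml * 1000 / (4 * pi))^(1 / 3)
  d <- dim(vals)
  coords <- arrayInd(seq_len(prod(d)), d)
  mm <- sweep(coords, 2, spacing, `*`)
  centers <- which(mask)
  best <- -Inf
  for (c0 in centers) {
    d2 <- rowSums(sweep(mm, 2, mm[c0, ], `-`)^2)
    best <- max(best, mean(vals[d2 < r^2]))
  }
  best
}

# Pair enumeration GLCM: every ordered pair of voxels at Chebyshev distance 1
# with both bins defined contributes one count.
oracle_glcm <- function(q, n_bins) {
  d <- dim(q)
  P <- matrix(0, n_bins, n_bins)
  idx <- arrayInd(seq_len(prod(d)), d)
  for (a in seq_len(nrow(idx))) {
    if (is.na(q[a])) next
    for (b in seq_len(nrow(idx))) {
      if (a == b || is.na(q[b])) next
      if (max(abs(idx[a, ] - idx[b, ])) == 1) {
        P[q[a], q[b]] <- P[q[a], q[b]] + 1
      }
    }
  }
  P / sum(P)
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all rank assignments.
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # Mann-Whitney U
  all_r <- seq_len(nx + length(y))
  combos <- utils::combn(all_r, nx)
  w_all <- colSums(matrix(all_r[combos], nrow = nx)) - nx * (nx + 1) / 2
  mu <- nx * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Brute-force Cox partial likelihood (no ties) maximized by grid/optimize.
oracle_cox_beta <- function(time, event, x) {
  loglik <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  stats::optimize(loglik, c(-8, 8), maximum = TRUE)$maximum
}

# small helper: uniform two-level cube phantom
make_two_level_cube <- function(core = 10, shell = 2, background = 0) {
  vals <- array(background, c(9, 9, 9))
  vals[3:7, 3:7, 3:7] <- shell
  vals[4:6, 4:6, 4:6] <- core
  petefs::pet_volume(vals, spacing = c(4, 4, 4))
}
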