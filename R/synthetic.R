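#' Simulated PET tumor phantom
#'
#' Builds a 3D SUV volume containing one ellipsoidal lesion with known
#' ground truth, emulating the scale of locally advanced breast lesions on
#' 4 mm isotropic PET (median tumor volume around 10 mL): uniform background,
#' tumor uptake plus an optional spatially correlated heterogeneity field,
#' optional Gaussian point-spread blurring, and additive Gaussian noise,
#' clipped at zero.
#'
#' Ground truth is the analytic ellipsoid volume and the voxel-center
#' indicator mask before blurring.
#'
#' @param radius_mm Sphere radius in mm, or length-3 semi-axes for an
#'   ellipsoid.
#' @param mean_suv Tumor mean SUV (must exceed `background_suv`).
#' @param background_suv Background SUV.
#' @param heterogeneity SD (SUV units) of the correlated intratumor field.
#' @param correlation_mm Correlation length (Gaussian smoothing sigma, mm) of
#'   the heterogeneity field.
#' @param psf_fwhm_mm Full width at half maximum of the Gaussian
#'   point-spread function; 0 disables blurring.
#' @param noise_sd SD of additive Gaussian voxel noise (SUV units).
#' @param spacing_mm Voxel spacing in mm (scalar or length 3); 4 mm isotropic
#'   by default.
#' @param margin_mm Background margin around the lesion on every side.
#' @param seed Integer seed; the heterogeneity field and the noise use
#'   separate streams derived from it, so disabling one does not perturb the
#'   other.
#' @return List with `volume` (a [pet_volume()]), `truth_matv_ml` (analytic
#'   ellipsoid volume in mL) and `truth_mask` (logical array of voxel centers
#'   inside the ellipsoid).
#' @examples
#' ph <- make_phantom(radius_mm = 13.4, seed = 7)
#' ph$truth_matv_ml # ~ 10.1 mL
#' @export
make_phantom <- function(radius_mm = 13.4, mean_suv = 8, background_suv = 0.5,
                         heterogeneity = 0, correlation_mm = 8,
                         psf_fwhm_mm = 0, noise_sd = 0, spacing_mm = 4,
                         margin_mm = 16, seed = NULL) {
  semi <- if (length(radius_mm) == 1) rep(radius_mm, 3) else as.numeric(radius_mm)
  stopifnot(length(semi) == 3, all(semi > 0))
  if (mean_suv <= background_suv) {
    abort("Tumor SUV must exceed background SUV.",
          class = "petefs_config_error")
  }
  sp <- if (length(spacing_mm) == 1) rep(spacing_mm, 3) else as.numeric(spacing_mm)
  stopifnot(all(sp > 0))
  extent <- 2 * (semi + margin_mm)
  d <- pmax(ceiling(extent / sp), 3L)
  if (any(2 * semi > d * sp)) {
    abort("Tumor larger than the field of view.",
          class = "petefs_config_error")
  }
  center <- (d + 1) / 2  # voxel-index center
  # voxel-center coordinates relative to lesion center, in mm
  xs <- (seq_len(d[1]) - center[1]) * sp[1]
  ys <- (seq_len(d[2]) - center[2]) * sp[2]
  zs <- (seq_len(d[3]) - center[3]) * sp[3]
  r2 <- outer(outer((xs / semi[1])^2, (ys / semi[2])^2, `+`),
              (zs / semi[3])^2, `+`)
  inside <- r2 <= 1
  vals <- array(background_suv, d)
  vals[inside] <- mean_suv
  if (heterogeneity > 0) {
    field <- with_seed(seed, array(rnorm(prod(d)), d))
    field <- gaussian_smooth(field, correlation_mm / sp)
    field <- field / max(sd(field[inside]), .Machine$double.eps)
    vals[inside] <- vals[inside] + heterogeneity * field[inside]
  }
  if (psf_fwhm_mm > 0) {
    sigma_vox <- (psf_fwhm_mm / 2.354820045) / sp
    vals <- gaussian_smooth(vals, sigma_vox)
  }
  if (noise_sd > 0) {
    noise_seed <- if (is.null(seed)) NULL else seed + 500009L
    vals <- vals + with_seed(noise_seed, array(rnorm(prod(d), sd = noise_sd), d))
  }
  vals[vals < 0] <- 0
  list(
    volume = pet_volume(vals, spacing = sp),
    truth_matv_ml = 4 / 3 * pi * prod(semi) / 1000,
    truth_mask = inside
  )
}

# separable Gaussian smoothing with truncated, renormalized kernels
gaussian_smooth <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-half:half) / s)^2)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

convolve_axis <- function(arr, k, ax) {
  d <- dim(arr)
  half <- (length(k) - 1L) / 2L
  out <- array(0, d)
  wt <- array(0, d)
  for (t in seq_along(k)) {
    o <- t - half - 1L
    src <- seq(max(1L, 1L + o), min(d[ax], d[ax] + o))
    dst <- src - o
    idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_src[[ax]] <- src
    idx_dst[[ax]] <- dst
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      k[t] * arr[idx_src[[1]], idx_src[[2]], idx_src[[3]], drop = FALSE]
    wt[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      wt[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] + k[t]
  }
  out / wt
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Covariate specifications for the cohort simulator
#'
#' Helpers building one covariate row each: a Bernoulli indicator
#' (`covariate_binary()`), a log-normal positive variable parameterised by
#' its median (`covariate_lognormal()`), or a Gaussian variable
#' (`covariate_normal()`). `hr` is the true hazard ratio per unit (per 1 for
#' binaries, per unit of the variable otherwise).
#'
#' `default_covariates()` mirrors the multivariate prognostic structure of an
#' ER+/HER2- neoadjuvant cohort: a skewed metabolic tumor volume (median
#' 10 mL, HR 1.01 per mL), a progesterone-receptor-negative indicator
#' (prevalence 0.38, HR 2.90) and a lobular-histology indicator (prevalence
#' 0.05, HR 3.80).
#'
#' @param name Column name in the simulated cohort.
#' @param prevalence Probability of 1 for a binary covariate.
#' @param median_value,sdlog Log-normal median and log-scale SD.
#' @param mean,sd Normal mean and SD.
#' @param hr True hazard ratio per unit.
#' @return One-row (or, for `default_covariates()`, three-row) tibble.
#' @export
covariate_binary <- function(name, prevalence, hr) {
  tibble(name = name, type = "binary", p1 = prevalence, p2 = NA_real_,
         hr = hr)
}

#' @rdname covariate_binary
#' @export
covariate_lognormal <- function(name, median_value, sdlog, hr) {
  tibble(name = name, type = "lognormal", p1 = log(median_value), p2 = sdlog,
         hr = hr)
}

#' @rdname covariate_binary
#' @export
covariate_normal <- function(name, mean, sd, hr) {
  tibble(name = name, type = "normal", p1 = mean, p2 = sd, hr = hr)
}

#' @rdname covariate_binary
#' @export
default_covariates <- function() {
  dplyr::bind_rows(
    covariate_lognormal("matv_ml", median_value = 10, sdlog = 0.8, hr = 1.01),
    covariate_binary("pr_negative", prevalence = 0.38, hr = 2.90),
    covariate_binary("lobular", prevalence = 0.05, hr = 3.80)
  )
}

#' Simulate an event-free-survival cohort
#'
#' Generates a proportional-hazards cohort: covariates per
#' [default_covariates()]-style specs, exponential event times with hazard
#' `baseline_rate * exp(sum(log(hr) * x))` per month, independent exponential
#' random censoring, and administrative censoring at a follow-up horizon.
#' Defaults emulate the study conditions of a 143-patient ER+/HER2-
#' neoadjuvant cohort: 44-month median follow-up and roughly 14% events.
#'
#' @param n Number of patients.
#' @param covariates Covariate spec tibble (see [covariate_binary()]).
#' @param baseline_rate Baseline hazard, events per month at covariates 0.
#' @param admin_horizon_months Administrative censoring time (months).
#' @param censor_rate Rate of the random-censoring exponential (per month).
#' @param seed Integer seed for reproducibility.
#' @return Tibble with `id`, one column per covariate, `efs_months` and
#'   `event` (1 = relapse/death observed, 0 = censored).
#' @examples
#' co <- make_cohort(n = 143, seed = 1)
#' mean(co$event)
#' @export
make_cohort <- function(n = 143, covariates = default_covariates(),
                        baseline_rate = 0.00175,
                        admin_horizon_months = 44, censor_rate = 0.004,
                        seed = NULL) {
  stopifnot(n >= 2, baseline_rate > 0, censor_rate >= 0,
            admin_horizon_months > 0)
  with_seed(seed, {
    x <- purrr::pmap(covariates, function(name, type, p1, p2, hr) {
      switch(type,
        binary = rbinom(n, 1, p1),
        lognormal = rlnorm(n, meanlog = p1, sdlog = p2),
        normal = rnorm(n, mean = p1, sd = p2),
        abort(sprintf("Unknown covariate type '%s'.", type),
              class = "petefs_config_error")
      )
    })
    names(x) <- covariates$name
    degenerate <- vapply(x, function(v) stats::var(v) == 0, logical(1))
    if (any(degenerate)) {
      warn(paste("Degenerate (zero-variance) covariate(s):",
                 paste(names(x)[degenerate], collapse = ", ")))
    }
    lp <- Reduce(`+`, purrr::map2(x, covariates$hr, ~ .x * log(.y)))
    t_event <- rexp(n, rate = baseline_rate * exp(lp))
    t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
    t_cens <- pmin(t_cens, admin_horizon_months)
    tibble(id = seq_len(n), !!!x,
           efs_months = pmax(pmin(t_event, t_cens), 1e-6),
           event = as.integer(t_event <= t_cens))
  })
}

#' Expected event fraction of a simulated cohort
#'
#' For a subject with hazard `lambda`, exponential random censoring at rate
#' `c` and administrative horizon `H`, the event probability is
#' `lambda / (lambda + c) * (1 - exp(-(lambda + c) * H))`. This conditional
#' closed form is averaged over the covariate distribution by Monte Carlo.
#'
#' @inheritParams make_cohort
#' @param n_mc Monte Carlo draws over the covariate distribution.
#' @return Expected fraction of subjects with an observed event.
#' @export
expected_event_fraction <- function(covariates = default_covariates(),
                                    baseline_rate = 0.00175,
                                    admin_horizon_months = 44,
                                    censor_rate = 0.004,
                                    n_mc = 100000, seed = 1) {
  with_seed(seed, {
    x <- purrr::pmap(covariates, function(name, type, p1, p2, hr) {
      switch(type,
        binary = rbinom(n_mc, 1, p1),
        lognormal = rlnorm(n_mc, meanlog = p1, sdlog = p2),
        normal = rnorm(n_mc, mean = p1, sd = p2)
      )
    })
    lp <- Reduce(`+`, purrr::map2(x, covariates$hr, ~ .x * log(.y)))
    lam <- baseline_rate * exp(lp)
    tot <- lam + censor_rate
    mean(lam / tot * (1 - exp(-tot * admin_horizon_months)))
  })
}

#' Simulate a cohort with a step in 3-year event risk at a known cutoff
#'
#' One continuous feature is drawn uniformly; the probability of an event
#' within `horizon_months` steps from `p_below` to `p_above` at
#' `true_cutoff`. Event times are exponential with the rate calibrated so
#' the event probability at the horizon is exact; follow-up is
#' administratively censored. Used to check that the Youden-index cutoff
#' search recovers a known threshold.
#'
#' @param n Cohort size.
#' @param true_cutoff Feature value where the risk steps.
#' @param p_below,p_above Event probability by the horizon on either side.
#' @param feature_range Range of the uniform feature.
#' @param horizon_months Risk-definition horizon (36 = 3 years).
#' @param admin_horizon_months Administrative censoring time.
#' @param seed Integer seed.
#' @return Tibble with `id`, `feature`, `efs_months`, `event`.
#' @export
make_cutoff_cohort <- function(n = 5000, true_cutoff = 8.3, p_below = 0.06,
                               p_above = 0.22, feature_range = c(2, 15),
                               horizon_months = 36,
                               admin_horizon_months = 44, seed = NULL) {
  stopifnot(p_below > 0, p_above < 1, p_below < p_above,
            true_cutoff > feature_range[1], true_cutoff < feature_range[2])
  with_seed(seed, {
    f <- runif(n, feature_range[1], feature_range[2])
    p <- ifelse(f > true_cutoff, p_above, p_below)
    rate <- -log(1 - p) / horizon_months
    t_event <- rexp(n, rate)
    tibble(id = seq_len(n), feature = f,
           efs_months = pmin(t_event, admin_horizon_months),
           event = as.integer(t_event <= admin_horizon_months))
  })
}
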