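#' Extract per-lesion PET features from volumes
#'
#' Runs segmentation, intensity indices and texture features over a batch of
#' lesions. Lesions whose segmentation is empty (slight or no uptake) are not
#' dropped silently: the row is kept with `excluded = TRUE` and a
#' machine-readable reason, mirroring clinical pipelines that exclude
#' non-avid tumors while logging them.
#'
#' @param volumes List of [pet_volume()] objects or character vector of NIfTI
#'   paths (read with [read_pet_volume()]).
#' @param roi_boxes Optional list of [roi_box()] (one per volume, or `NULL`
#'   entries for whole-volume ROIs).
#' @param ids Lesion identifiers (defaults to sequence or file names).
#' @param method `"adaptive"` (default) or `"fixed"` segmentation.
#' @param fraction Fixed-threshold fraction when `method = "fixed"`.
#' @param background Background for adaptive segmentation (`"auto"` or SUV).
#' @param n_bins Gray levels for texture quantization.
#' @return Tibble, one row per lesion: `id`, `suv_max`, `suv_mean`,
#'   `suv_peak`, `matv_ml`, `tlg`, `entropy_nats`, `homogeneity`,
#'   `threshold_used`, `n_voxels`, `excluded`, `exclude_reason`.
#' @examples
#' phs <- lapply(1:2, function(s) make_phantom(seed = s)$volume)
#' extract_features(phs)
#' @export
extract_features <- function(volumes, roi_boxes = NULL, ids = NULL,
                             method = c("adaptive", "fixed"), fraction = 0.4,
                             background = "auto", n_bins = 64L) {
  method <- match.arg(method)
  if (is.character(volumes)) {
    if (is.null(ids)) ids <- basename(volumes)
    volumes <- lapply(volumes, read_pet_volume)
  }
  if (inherits(volumes, "pet_volume")) volumes <- list(volumes)
  n <- length(volumes)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (!is.null(roi_boxes)) stopifnot(length(roi_boxes) == n)
  purrr::map_dfr(seq_len(n), function(i) {
    v <- volumes[[i]]
    if (!is.null(roi_boxes) && !is.null(roi_boxes[[i]])) {
      v <- crop_roi(v, roi_boxes[[i]])
    }
    na_row <- tibble(id = ids[i], suv_max = NA_real_, suv_mean = NA_real_,
                     suv_peak = NA_real_, matv_ml = NA_real_, tlg = NA_real_,
                     entropy_nats = NA_real_, homogeneity = NA_real_,
                     threshold_used = NA_real_, n_voxels = NA_integer_,
                     excluded = TRUE, exclude_reason = NA_character_)
    seg <- tryCatch(
      switch(method,
             adaptive = segment_adaptive(v, background = background),
             fixed = segment_fixed(v, fraction = fraction)),
      petefs_empty_segmentation = function(e) e,
      petefs_convergence_error = function(e) e
    )
    if (inherits(seg, "condition")) {
      na_row$exclude_reason <- if (inherits(seg, "petefs_empty_segmentation"))
        "no_uptake" else "no_convergence"
      return(na_row)
    }
    ind <- metabolic_indices(v, seg)
    tex <- texture_features(v, seg, n_bins = n_bins)
    dplyr::bind_cols(tibble(id = ids[i]), ind, tex,
                     tibble(threshold_used = seg$threshold_used,
                            n_voxels = sum(seg$mask),
                            excluded = FALSE,
                            exclude_reason = NA_character_))
  })
}

#' Full prognostic analysis of a feature/cohort table
#'
#' Reproduces the analysis plan of a baseline-PET prognostic study on one
#' table: (1) association of each image feature with binary
#' clinicopathological groupings (Wilcoxon + Benjamini-Hochberg), (2)
#' Youden-index cutoffs for each feature at a fixed horizon, (3) Kaplan-Meier
#' curves and log-rank tests for each feature dichotomized at its cutoff and
#' for each binary factor, with Hochberg control across the log-rank family,
#' (4) univariate Cox on continuous features and binary factors, and (5)
#' stepwise forward multivariate Cox over the univariately significant
#' candidates.
#'
#' @param data Data frame with one row per patient: feature columns, binary
#'   factor columns, plus follow-up columns.
#' @param features Character vector of continuous image-feature columns.
#' @param factors Character vector of binary clinicopathological columns.
#' @param time,event Follow-up column names.
#' @param horizon_months Youden/ROC horizon (36 = 3 years).
#' @param alpha Significance level for univariate screening and stepwise
#'   entry/stay.
#' @return List of class `efs_report`: `association`, `cutoffs`, `logrank`,
#'   `km` (named list of `efs_km`), `univariate` (tibble), `multivariate`
#'   (`efs_cox`), `n`, `n_event`.
#' @examples
#' co <- make_cohort(n = 120, seed = 6)
#' rep <- analyze_cohort(co, features = "matv_ml",
#'                       factors = c("pr_negative", "lobular"))
#' tidy(rep$multivariate)
#' @export
analyze_cohort <- function(data, features, factors = character(0),
                           time = "efs_months", event = "event",
                           horizon_months = 36, alpha = 0.05) {
  sv <- check_survival_cols(data, time, event)
  if (sum(sv$event) < 2) {
    abort("Fewer than 2 events: survival analysis aborted.",
          class = "petefs_no_events")
  }
  association <- if (length(factors) > 0) {
    compare_features(data, features, factors)
  } else {
    NULL
  }
  cutoffs <- purrr::map_dfr(features, function(fn) {
    tryCatch(
      youden_cutoff(data, fn, time = time, event = event,
                    horizon_months = horizon_months),
      error = function(e) {
        warn(sprintf("Cutoff for '%s' skipped: %s", fn,
                     conditionMessage(e)))
        tibble()
      })
  })
  work <- as_tibble(data)
  strat_cols <- character(0)
  for (k in seq_len(nrow(cutoffs))) {
    cn <- paste0(cutoffs$feature[k], "_high")
    work[[cn]] <- as.integer(work[[cutoffs$feature[k]]] > cutoffs$cutoff[k])
    strat_cols <- c(strat_cols, cn)
  }
  lr_groups <- c(factors, strat_cols)
  logrank <- purrr::map_dfr(lr_groups, function(gn) {
    tryCatch(logrank_test(work, gn, time = time, event = event),
             error = function(e) tibble())
  })
  if (nrow(logrank) > 0) logrank$p_hochberg <- adjust_hochberg(logrank$p_value)
  km <- setNames(
    lapply(lr_groups, function(gn) km_curve(work, time, event, group = gn)),
    lr_groups
  )
  univariate <- cox_univariate(work, c(features, factors), time = time,
                               event = event)
  candidates <- univariate$term[!is.na(univariate$p_value) &
                                  univariate$p_value <= alpha]
  multivariate <- cox_stepwise(work, candidates, time = time, event = event,
                               alpha_enter = alpha, alpha_stay = alpha)
  structure(list(association = association, cutoffs = cutoffs,
                 logrank = logrank, km = km, univariate = univariate,
                 multivariate = multivariate,
                 n = nrow(work), n_event = sum(sv$event)),
            class = "efs_report")
}

#' @export
print.efs_report <- function(x, ...) {
  cat(sprintf("<efs_report> %d patients, %d events\n", x$n, x$n_event))
  cat("Univariate Cox:\n")
  print(x$univariate)
  cat("Multivariate (stepwise) Cox:\n")
  print(x$multivariate$table)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes the tables of an `efs_report` as TSV/CSV/JSON under `dir`:
#' `association.tsv`, `univariate.tsv`, `multivariate.tsv`,
#' `stepwise_trace.tsv`, `logrank.tsv`, `cutoffs.json` and one
#' `km_<group>.csv` per stratification.
#'
#' @param report An `efs_report` from [analyze_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "efs_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_tsv(df, p)
    written <<- c(written, p)
  }
  if (!is.null(report$association)) wr(report$association, "association.tsv")
  wr(report$univariate, "univariate.tsv")
  wr(report$multivariate$table, "multivariate.tsv")
  if (!is.null(report$multivariate$trace)) {
    wr(report$multivariate$trace, "stepwise_trace.tsv")
  }
  if (nrow(report$logrank) > 0) wr(report$logrank, "logrank.tsv")
  cj <- file.path(dir, "cutoffs.json")
  jsonlite::write_json(report$cutoffs, cj, digits = NA)
  written <- c(written, cj)
  for (gn in names(report$km)) {
    p <- file.path(dir, paste0("km_", gn, ".csv"))
    readr::write_csv(as_tibble(report$km[[gn]]), p)
    written <- c(written, p)
  }
  invisible(written)
}
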