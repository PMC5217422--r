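#' Wilcoxon rank-sum comparison of a feature between two groups
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test: exact distribution for a
#' combined sample size up to 20 without ties, normal approximation with
#' mid-ranks and tie-corrected variance otherwise (via
#' [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples (each non-empty).
#' @return One-row tibble: `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `exact` (whether the exact distribution was used).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0 || anyNA(x) || anyNA(y)) {
    abort("Both samples must be non-empty and free of NA.",
          class = "petefs_format_error")
  }
  use_exact <- (length(x) + length(y)) <= 20 &&
    !any(duplicated(c(x, y)))
  wt <- wilcox.test(x, y, exact = use_exact, correct = !use_exact)
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         exact = use_exact)
}

#' Feature-by-group association table with FDR correction
#'
#' For each (feature, grouping) pair, compares the feature between the two
#' arms of the grouping with the Wilcoxon rank-sum test and reports the
#' per-arm medians; Benjamini-Hochberg adjustment is applied across the whole
#' table. Groupings must be binary columns (logical or 0/1 or two-level
#' factors); a grouping with an empty arm is skipped with a warning.
#'
#' @param data Data frame, one row per patient.
#' @param features Character vector of numeric feature column names.
#' @param groupings Character vector of binary grouping column names.
#' @return Tibble with one row per feature x grouping: `feature`, `grouping`,
#'   `median_a`, `median_b` (arms in sorted level order), `n_a`, `n_b`,
#'   `statistic`, `p_raw`, `p_bh`.
#' @examples
#' co <- make_cohort(n = 80, seed = 5)
#' co$suv_high <- as.integer(co$matv_ml > stats::median(co$matv_ml))
#' compare_features(co, "matv_ml", "pr_negative")
#' @export
compare_features <- function(data, features, groupings) {
  missing_cols <- setdiff(c(features, groupings), names(data))
  if (length(missing_cols)) {
    abort(paste("Missing column(s):", paste(missing_cols, collapse = ", ")),
          class = "petefs_format_error")
  }
  rows <- purrr::map_dfr(groupings, function(gn) {
    g <- factor(data[[gn]])
    if (nlevels(g) != 2 || any(table(g) == 0)) {
      warn(sprintf("Grouping '%s' does not split into two non-empty arms; skipped.",
                   gn))
      return(tibble())
    }
    a <- g == levels(g)[1]
    purrr::map_dfr(features, function(fn) {
      x <- data[[fn]]
      wt <- wilcoxon_rank_sum(x[a], x[!a])
      tibble(feature = fn, grouping = gn,
             median_a = median(x[a]), median_b = median(x[!a]),
             n_a = sum(a), n_b = sum(!a),
             statistic = wt$statistic, p_raw = wt$p_value)
    })
  })
  if (nrow(rows) == 0) {
    abort("No valid feature/grouping pair.", class = "petefs_format_error")
  }
  rows$p_bh <- adjust_bh(rows$p_raw)
  rows
}
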