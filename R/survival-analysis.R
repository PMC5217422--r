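#' Kaplan-Meier event-free-survival curve
#'
#' Product-limit estimate of the survivor function, optionally stratified by
#' a grouping column. Thin tabular wrapper around [survival::survfit()].
#'
#' @param data Data frame with one row per patient.
#' @param time,event Column names (strings) of follow-up time (months, > 0)
#'   and event indicator (1 = event, 0 = censored).
#' @param group Optional column name to stratify by.
#' @return Tibble of class `efs_km` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (and `group` when stratified),
#'   including the `time = 0, survival = 1` anchor per stratum.
#' @examples
#' co <- make_cohort(n = 60, seed = 2)
#' km_curve(co, group = "pr_negative")
#' @export
km_curve <- function(data, time = "efs_months", event = "event",
                     group = NULL) {
  sv <- check_survival_cols(data, time, event)
  if (nrow(data) == 0) abort("No records.", class = "petefs_format_error")
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(sv$time, sv$event) ~ 1)
    out <- tibble(time = c(0, fit$time),
                  n_risk = c(fit$n, fit$n.risk),
                  n_event = c(0, fit$n.event),
                  n_censor = c(0, fit$n.censor),
                  survival = c(1, fit$surv))
  } else {
    g <- data[[group]]
    fit <- survival::survfit(survival::Surv(sv$time, sv$event) ~ g)
    strata <- if (is.null(fit$strata)) {
      rep(levels(factor(g))[1], length(fit$time))
    } else {
      rep(sub("^g=", "", names(fit$strata)), fit$strata)
    }
    out <- tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, n_censor = fit$n.censor,
                  survival = fit$surv) |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(~ dplyr::bind_rows(
        tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0,
               n_censor = 0, survival = 1), .x)) |>
      dplyr::ungroup()
  }
  class(out) <- c("efs_km", class(out))
  out
}

#' Survival probability at a time point from a KM curve
#'
#' @param km An `efs_km` tibble from [km_curve()].
#' @param at Time (months) at which to read the step function.
#' @return Tibble with the survival probability at `at` (per group if the
#'   curve is stratified).
#' @export
km_survival_at <- function(km, at) {
  step_val <- function(tm, sv) {
    i <- findInterval(at, tm)
    if (i == 0) 1 else sv[i]
  }
  if ("group" %in% names(km)) {
    km |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(survival = step_val(.data$time, .data$survival),
                       .groups = "drop") |>
      dplyr::mutate(at = at, .before = 1)
  } else {
    tibble(at = at, survival = step_val(km$time, km$survival))
  }
}

#' Two-group log-rank test
#'
#' Standard 1-degree-of-freedom log-rank test via [survival::survdiff()].
#'
#' @inheritParams km_curve
#' @param group Column name of a two-level grouping.
#' @return One-row tibble: `group`, `n_a`, `n_b`, `chisq`, `p_value`.
#' @export
logrank_test <- function(data, group, time = "efs_months", event = "event") {
  sv <- check_survival_cols(data, time, event)
  g <- factor(data[[group]])
  if (nlevels(g) != 2) {
    abort("Log-rank grouping must have exactly 2 levels.",
          class = "petefs_format_error")
  }
  if (sum(sv$event) == 0) {
    abort("No events: log-rank statistic undefined.",
          class = "petefs_no_events")
  }
  sd <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ g)
  tibble(group = group,
         n_a = sum(g == levels(g)[1]), n_b = sum(g == levels(g)[2]),
         chisq = unname(sd$chisq),
         p_value = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Hochberg step-up adjustment
#'
#' Family-wise-error control for a family of log-rank (or other) p-values.
#' Wrapper around `stats::p.adjust(method = "hochberg")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, clipped at 1, same order as the input.
#' @export
adjust_hochberg <- function(p) {
  check_pvalues(p)
  p.adjust(p, method = "hochberg")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @inheritParams adjust_hochberg
#' @return BH step-up adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  check_pvalues(p)
  p.adjust(p, method = "BH")
}

check_pvalues <- function(p) {
  if (length(p) == 0 || anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].", class = "petefs_format_error")
  }
  invisible(p)
}

#' Youden-index optimal cutoff at a fixed horizon
#'
#' Dichotomizes the outcome at `horizon_months`: patients with an event at or
#' before the horizon are positives; patients event-free with follow-up
#' reaching the horizon are negatives; patients censored before the horizon
#' are excluded. The cutoff maximizing the Youden index
#' `J = sensitivity + specificity - 1` (positives predicted by
#' `feature > cutoff`) is searched over midpoints between consecutive sorted
#' unique feature values, ties broken toward the lower cutoff.
#'
#' @inheritParams km_curve
#' @param feature Column name of the continuous marker.
#' @param horizon_months Classification horizon (36 = 3 years).
#' @return One-row tibble: `feature`, `cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`, `n_pos`, `n_neg`, `n_excluded`.
#' @examples
#' co <- make_cutoff_cohort(n = 400, seed = 3)
#' youden_cutoff(co, "feature")
#' @export
youden_cutoff <- function(data, feature, time = "efs_months",
                          event = "event", horizon_months = 36) {
  sv <- check_survival_cols(data, time, event)
  f <- data[[feature]]
  if (is.null(f)) abort(sprintf("No column '%s'.", feature),
                        class = "petefs_format_error")
  pos <- sv$event == 1 & sv$time <= horizon_months
  neg <- sv$time >= horizon_months
  keep <- pos | neg
  if (!any(pos) || !any(neg)) {
    abort("Need at least one positive and one negative at the horizon.",
          class = "petefs_degenerate_outcome")
  }
  f <- f[keep]
  y <- pos[keep]
  u <- sort(unique(f))
  if (length(u) < 2) {
    abort("Feature is constant among evaluable subjects.",
          class = "petefs_degenerate_feature")
  }
  grid <- (u[-length(u)] + u[-1]) / 2
  sens <- vapply(grid, function(c) mean(f[y] > c), numeric(1))
  spec <- vapply(grid, function(c) mean(f[!y] <= c), numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)  # which.max returns the first (lowest-cutoff) maximum
  tibble(feature = feature, cutoff = grid[best], sensitivity = sens[best],
         specificity = spec[best], youden_j = j[best],
         n_pos = sum(y), n_neg = sum(!y), n_excluded = sum(!keep))
}

#' Cox proportional-hazards fits for event-free survival
#'
#' `cox_fit()` fits one multivariate Cox model (Efron tie handling) and
#' returns an `efs_cox` object with [tidy()] / [glance()] methods;
#' `cox_univariate()` fits a separate model per covariate and returns the
#' screening table. Covariates with essentially infinite estimates (complete
#' separation, e.g. a level with zero events) are flagged non-estimable
#' rather than reported with meaningless confidence bounds.
#'
#' @inheritParams km_curve
#' @param covariates Character vector of covariate column names; continuous
#'   columns enter as continuous, per the reporting convention for age and
#'   PET parameters.
#' @return `cox_fit()`: an `efs_cox` object. `cox_univariate()`: a tibble
#'   with one row per covariate (`term`, `hr`, `conf_low`, `conf_high`,
#'   `p_value`, `estimable`).
#' @examples
#' co <- make_cohort(n = 200, seed = 4)
#' tidy(cox_fit(co, c("matv_ml", "pr_negative")))
#' @export
cox_fit <- function(data, covariates, time = "efs_months", event = "event") {
  sv <- check_survival_cols(data, time, event)
  if (sum(sv$event) < 2) {
    abort("Need at least 2 events to fit a Cox model.",
          class = "petefs_no_events")
  }
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols)) {
    abort(paste("Missing covariate column(s):",
                paste(missing_cols, collapse = ", ")),
          class = "petefs_format_error")
  }
  df <- as.data.frame(data[, covariates, drop = FALSE])
  df$.time <- sv$time
  df$.event <- sv$event
  fml <- stats::reformulate(sprintf("`%s`", covariates),
                            response = quote(survival::Surv(.time, .event)))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit)
  co <- s$coefficients
  term <- sub("^`|`$", "", rownames(co))
  se <- co[, "se(coef)"]
  estimable <- is.finite(co[, "coef"]) & se < 50
  tab <- tibble(
    term = term,
    hr = unname(exp(co[, "coef"])),
    conf_low = unname(exp(co[, "coef"] - qnorm(0.975) * se)),
    conf_high = unname(exp(co[, "coef"] + qnorm(0.975) * se)),
    p_value = unname(co[, "Pr(>|z|)"]),
    estimable = unname(estimable)
  )
  tab[!tab$estimable, c("hr", "conf_low", "conf_high", "p_value")] <- NA_real_
  structure(list(fit = fit, table = tab, n = s$n, n_event = s$nevent,
                 covariates = covariates),
            class = "efs_cox")
}

#' @rdname cox_fit
#' @export
cox_univariate <- function(data, covariates, time = "efs_months",
                           event = "event") {
  purrr::map_dfr(covariates, function(cv) {
    tidy(cox_fit(data, cv, time = time, event = event))
  })
}

#' Stepwise forward Cox model selection
#'
#' Builds a multivariate Cox model by forward selection on Wald p-values:
#' at each step the candidate with the smallest p-value (when added to the
#' current model) enters if `p <= alpha_enter`; after each entry, included
#' variables whose p-value has risen above `alpha_stay` are removed.
#' Candidates should be pre-screened for univariate significance (see
#' [cox_univariate()]). Stops when no addition or removal changes the model.
#'
#' @inheritParams cox_fit
#' @param candidates Character vector of candidate covariate names.
#' @param alpha_enter,alpha_stay Entry and stay significance thresholds.
#' @return An `efs_cox` for the final model (empty `table` if nothing
#'   enters), with a `trace` tibble (`step`, `action`, `term`, `p_value`)
#'   recording every entry and removal.
#' @export
cox_stepwise <- function(data, candidates, time = "efs_months",
                         event = "event", alpha_enter = 0.05,
                         alpha_stay = 0.05) {
  included <- character(0)
  trace <- tibble(step = integer(0), action = character(0),
                  term = character(0), p_value = numeric(0))
  step_no <- 0L
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, included)
    if (length(pool) > 0 && alpha_enter > 0) {
      trial <- purrr::map_dfr(pool, function(cv) {
        ft <- cox_fit(data, c(included, cv), time = time, event = event)
        row <- ft$table[ft$table$term == cv, ]
        tibble(term = cv, p_value = row$p_value)
      })
      trial <- trial[!is.na(trial$p_value), , drop = FALSE]
      if (nrow(trial) > 0 && min(trial$p_value) <= alpha_enter) {
        add <- trial$term[which.min(trial$p_value)]
        included <- c(included, add)
        step_no <- step_no + 1L
        trace <- dplyr::add_row(trace, step = step_no, action = "add",
                                term = add, p_value = min(trial$p_value))
        changed <- TRUE
      }
    }
    # backward pruning of variables that became nonsignificant
    repeat {
      if (length(included) == 0) break
      ft <- cox_fit(data, included, time = time, event = event)
      pv <- ft$table$p_value
      worst <- which.max(ifelse(is.na(pv), Inf, pv))
      worst_p <- pv[worst]
      if (is.na(worst_p) || worst_p > alpha_stay) {
        drop_term <- ft$table$term[worst]
        included <- setdiff(included, drop_term)
        step_no <- step_no + 1L
        trace <- dplyr::add_row(trace, step = step_no, action = "remove",
                                term = drop_term, p_value = worst_p)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (length(included) == 0) {
    out <- structure(list(fit = NULL,
                          table = tibble(term = character(0), hr = numeric(0),
                                         conf_low = numeric(0),
                                         conf_high = numeric(0),
                                         p_value = numeric(0),
                                         estimable = logical(0)),
                          n = nrow(data), n_event = sum(data[[event]]),
                          covariates = character(0)),
                     class = "efs_cox")
  } else {
    out <- cox_fit(data, included, time = time, event = event)
  }
  out$trace <- trace
  out
}

#' @export
print.efs_cox <- function(x, ...) {
  cat(sprintf("<efs_cox> n = %d, events = %d\n", x$n, x$n_event))
  print(x$table)
  invisible(x)
}

#' Tidy a fitted Cox model
#'
#' @param x An `efs_cox` object.
#' @param ... Unused.
#' @return Tibble with `term`, `hr`, `conf_low`, `conf_high`, `p_value`,
#'   `estimable`.
#' @export
tidy.efs_cox <- function(x, ...) x$table

#' @rdname tidy.efs_cox
#' @return For `glance()`: one-row tibble with `n`, `n_event`, `logLik`,
#'   `concordance` and `n_terms`.
#' @export
glance.efs_cox <- function(x, ...) {
  tibble(
    n = x$n,
    n_event = x$n_event,
    logLik = if (is.null(x$fit)) NA_real_ else unname(x$fit$loglik[2]),
    concordance = if (is.null(x$fit)) NA_real_ else
      unname(x$fit$concordance["concordance"]),
    n_terms = nrow(x$table)
  )
}

check_survival_cols <- function(data, time, event) {
  tm <- data[[time]]
  ev <- data[[event]]
  if (is.null(tm) || is.null(ev)) {
    abort(sprintf("Data must contain '%s' and '%s' columns.", time, event),
          class = "petefs_format_error")
  }
  if (any(!is.finite(tm)) || any(tm <= 0)) {
    abort("Follow-up times must be positive.", class = "petefs_format_error")
  }
  if (!all(ev %in% c(0, 1))) {
    abort("Event indicator must be 0/1.", class = "petefs_format_error")
  }
  list(time = as.numeric(tm), event = as.integer(ev))
}
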