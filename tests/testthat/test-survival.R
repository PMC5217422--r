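test_that("Kaplan-Meier matches the hand product-limit computation", {
  # 5 subjects: events at 2, 6, 8, 10; censored at 4
  dat <- tibble::tibble(efs_months = c(2, 4, 6, 8, 10),
                        event = c(1, 0, 1, 1, 1))
  km <- km_curve(dat)
  expect_equal(km$survival[km$time == 0], 1)
  expect_equal(km$survival[km$time == 2], 4 / 5)
  expect_equal(km$survival[km$time == 6], 4 / 5 * 2 / 3)
  expect_equal(km$survival[km$time == 8], 4 / 5 * 2 / 3 * 1 / 2)
  expect_equal(km$survival[km$time == 10], 0)
  expect_true(all(diff(km$survival) <= 0))
})

test_that("KM equals the empirical survivor function without censoring", {
  set.seed(40)
  t <- round(rexp(60, 0.05) + 0.5, 1)
  dat <- tibble::tibble(efs_months = t, event = 1)
  km <- km_curve(dat)
  for (tt in sort(unique(t))) {
    expect_equal(km_survival_at(km, tt)$survival, mean(t > tt))
  }
  # all censored -> S = 1 everywhere
  km1 <- km_curve(tibble::tibble(efs_months = t, event = 0))
  expect_true(all(km1$survival == 1))
  expect_error(km_curve(tibble::tibble(efs_months = numeric(0),
                                       event = integer(0))),
               class = "petefs_format_error")
})

test_that("log-rank matches the hand O-E computation and null symmetry", {
  # 6 subjects: A = 1(e), 3(e), 5(c); B = 2(e), 4(c), 6(e)
  dat <- tibble::tibble(efs_months = 1:6, event = c(1, 1, 1, 0, 0, 1),
                        grp = c("A", "B", "A", "B", "A", "B"))
  lr <- logrank_test(dat, "grp")
  # event times 1, 2, 3, 6; A's last subject is censored at 5, so A is no
  # longer at risk at t = 6:
  #   O_A = 2;  E_A = 3/6 + 2/5 + 2/4 + 0 = 1.4
  #   V = 3*3*5/(36*5) + 2*3*4/(25*4) + 2*2*3/(16*3) + 0 = 0.74
  expect_equal(lr$chisq, (2 - 1.4)^2 / 0.74, tolerance = 1e-10)

  # two identical groups -> chi2 = 0, p = 1
  one <- tibble::tibble(efs_months = c(3, 7, 12, 20), event = c(1, 0, 1, 1))
  both <- dplyr::bind_rows(dplyr::mutate(one, g = 0),
                           dplyr::mutate(one, g = 1))
  lr0 <- logrank_test(both, "g")
  expect_equal(lr0$chisq, 0)
  expect_equal(lr0$p_value, 1)

  expect_error(
    logrank_test(tibble::tibble(efs_months = c(1, 2), event = c(0, 0),
                                g = c(0, 1)), "g"),
    class = "petefs_no_events")
})

test_that("log-rank power under a strong simulated hazard ratio", {
  co <- make_cohort(n = 2000, covariates = covariate_binary("x", 0.4, 3.5),
                    seed = 41)
  expect_lt(logrank_test(co, "x")$p_value, 0.001)
})

test_that("log-rank equals the Cox score test at beta = 0 (no ties)", {
  set.seed(42)
  for (k in 1:5) {
    n <- 30
    dat <- tibble::tibble(efs_months = rexp(n, 0.02) + 0.01,
                          event = rbinom(n, 1, 0.7),
                          g = rbinom(n, 1, 0.5))
    if (sum(dat$event) == 0 || length(unique(dat$g)) < 2) next
    lr <- logrank_test(dat, "g")
    sc <- summary(survival::coxph(
      survival::Surv(efs_months, event) ~ g, data = dat))$sctest["test"]
    expect_equal(lr$chisq, unname(sc), tolerance = 1e-8)
  }
})

test_that("Hochberg adjustment follows the step-up rule and dominates Bonferroni", {
  expect_equal(adjust_hochberg(0.03), 0.03)
  expect_equal(adjust_hochberg(c(0.04, 0.04)), c(0.04, 0.04))
  set.seed(43)
  p <- runif(12)^2
  expect_true(all(adjust_hochberg(p) <= pmin(length(p) * p, 1) + 1e-15))
  expect_true(all(adjust_hochberg(p) <= 1))
  expect_error(adjust_hochberg(c(-0.1, 0.5)), class = "petefs_format_error")
})

test_that("Youden cutoff: separation, exclusions and degenerate input", {
  dat <- tibble::tibble(
    feature = c(1, 2, 3, 9, 10, 11, 5),
    efs_months = c(40, 44, 41, 10, 20, 30, 20),
    event = c(0, 0, 0, 1, 1, 1, 0))  # last subject censored pre-horizon
  yc <- youden_cutoff(dat, "feature")
  expect_equal(yc$youden_j, 1)
  expect_equal(yc$cutoff, 6)  # midpoint of the separating gap
  expect_equal(yc$n_excluded, 1)
  expect_equal(yc$n_pos, 3)
  expect_equal(yc$n_neg, 3)

  # subjects with events after the horizon count as negatives
  dat2 <- dat
  dat2$efs_months[5] <- 40  # event at 40 months -> event-free at 36
  yc2 <- youden_cutoff(dat2, "feature")
  expect_equal(yc2$n_pos, 2)
  expect_equal(yc2$n_neg, 4)

  const <- tibble::tibble(feature = 1, efs_months = c(10, 40),
                          event = c(1, 0))
  expect_error(youden_cutoff(const, "feature"),
               class = "petefs_degenerate_feature")
  nopos <- tibble::tibble(feature = c(1, 2), efs_months = c(40, 44),
                          event = c(0, 0))
  expect_error(youden_cutoff(nopos, "feature"),
               class = "petefs_degenerate_outcome")
})

test_that("Youden cutoff recovers a generative risk step and ties go low", {
  cc <- make_cutoff_cohort(n = 4000, seed = 44)
  yc <- youden_cutoff(cc, "feature")
  expect_lt(abs(yc$cutoff - 8.3), 0.5)

  # independent ROC cross-check on the dichotomized 36-month outcome
  pos <- cc$event == 1 & cc$efs_months <= 36
  keep <- pos | cc$efs_months >= 36
  roc <- pROC::roc(response = pos[keep], predictor = cc$feature[keep],
                   direction = "<", quiet = TRUE)
  best <- pROC::coords(roc, "best", best.method = "youden",
                       transpose = FALSE)
  expect_equal(yc$cutoff, best$threshold[1], tolerance = 1e-8)
  expect_equal(yc$sensitivity, best$sensitivity[1], tolerance = 1e-8)
  expect_equal(yc$specificity, best$specificity[1], tolerance = 1e-8)

  # tie toward the lower cutoff: symmetric two-point configuration
  tie <- tibble::tibble(feature = c(1, 2, 3, 4),
                        efs_months = c(40, 10, 40, 10),
                        event = c(0, 1, 0, 1))
  yt <- youden_cutoff(tie, "feature")
  expect_equal(yt$cutoff, 1.5)  # J identical at 1.5 and 3.5; lower one wins
})

test_that("Cox estimates match the brute-force partial-likelihood oracle", {
  # 4-subject binary-covariate case
  dat <- tibble::tibble(efs_months = c(2, 5, 7, 11), event = c(1, 1, 0, 1),
                        x = c(1, 0, 1, 0))
  b_hat <- log(tidy(cox_fit(dat, "x"))$hr)
  b_oracle <- oracle_cox_beta(dat$efs_months, dat$event, dat$x)
  expect_equal(b_hat, b_oracle, tolerance = 1e-3)

  set.seed(45)
  for (k in 1:8) {
    n <- sample(5:8, 1)
    dat <- tibble::tibble(efs_months = sample(seq(1, 50), n),
                          event = rbinom(n, 1, 0.8),
                          x = rnorm(n))
    if (sum(dat$event) < 2) next
    fit <- cox_fit(dat, "x")
    if (!fit$table$estimable) next
    expect_equal(log(fit$table$hr),
                 oracle_cox_beta(dat$efs_months, dat$event, dat$x),
                 tolerance = 1e-3)
  }
})

test_that("null covariate gives HR near 1 with covering CI", {
  co <- make_cohort(n = 8000, covariates = covariate_binary("x", 0.5, 1.0),
                    seed = 46)
  tab <- tidy(cox_fit(co, "x"))
  expect_equal(tab$hr, 1, tolerance = 0.15)
  expect_lt(tab$conf_low, 1)
  expect_gt(tab$conf_high, 1)
})

test_that("complete separation is flagged non-estimable", {
  # a pCR-like level with zero events
  set.seed(50)
  dat <- tibble::tibble(
    efs_months = c(rexp(30, 0.05) + 1, rep(44, 12)),
    event = c(rbinom(30, 1, 0.6), rep(0, 12)),
    pcr = c(rep(0, 30), rep(1, 12)))
  dat$event[1:3] <- 1  # ensure enough events
  tab <- tidy(cox_fit(dat, "pcr"))
  expect_false(tab$estimable)
  expect_true(is.na(tab$hr))
})

test_that("printed univariate hazard ratios are recovered within 10%", {
  # truths: binary uptake analog 3.51, PR analog 3.25, rare histology 3.74
  cases <- list(c(prev = 0.273, hr = 3.51),
                c(prev = 0.38, hr = 3.25),
                c(prev = 0.05, hr = 3.74))
  for (cs in cases) {
    loghr <- vapply(1:3, function(r) {
      co <- make_cohort(n = 10000,
                        covariates = covariate_binary("x", cs["prev"],
                                                      cs["hr"]),
                        seed = 100 * cs["hr"] + r)
      log(tidy(cox_fit(co, "x"))$hr)
    }, numeric(1))
    expect_equal(exp(mean(loghr)), unname(cs["hr"]),
                 tolerance = 0.1)
  }
})

test_that("stepwise forward selection keeps true effects and drops noise", {
  co <- make_cohort(n = 3000, seed = 47)  # matv_ml, pr_negative, lobular
  set.seed(48)
  co$noise1 <- rnorm(nrow(co))
  co$noise2 <- rbinom(nrow(co), 1, 0.5)
  # a redundant near-copy of a true covariate
  co$pr_copy <- ifelse(runif(nrow(co)) < 0.97, co$pr_negative,
                       1 - co$pr_negative)
  fit <- cox_stepwise(co, c("matv_ml", "pr_negative", "lobular", "noise1",
                            "noise2", "pr_copy"))
  expect_true(all(c("pr_negative", "lobular") %in% fit$table$term))
  expect_false(any(c("noise1", "noise2") %in% fit$table$term))
  expect_false("pr_copy" %in% fit$table$term)
  expect_true(all(c("add") %in% fit$trace$action))

  # alpha = 0 admits nothing
  empty <- cox_stepwise(co, c("matv_ml", "pr_negative"), alpha_enter = 0)
  expect_equal(nrow(empty$table), 0)
  expect_equal(glance(empty)$n_terms, 0)
})

test_that("tidy and glance expose the fit in broom style", {
  co <- make_cohort(n = 400, seed = 49)
  fit <- cox_fit(co, c("matv_ml", "pr_negative"))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("matv_ml", "pr_negative"))
  expect_true(all(td$conf_low <= td$hr & td$hr <= td$conf_high))
  gl <- glance(fit)
  expect_equal(gl$n, 400)
  expect_equal(gl$n_terms, 2)
  expect_true(gl$concordance > 0.5)
})
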