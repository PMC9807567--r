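# The ENHV equations: published coefficients, prediction arithmetic, and the
# model-building procedure (screening, interaction test, stratified OLS).

test_that("published-model predictions match hand arithmetic", {
  m <- published_model()
  expect_equal(predict_enhv(m, "medulla", icv = 1.5e6), 4675.0,
               tolerance = 1e-9)
  expect_equal(predict_enhv(m, "whole_brainstem", icv = 1.5e6, sex = 1),
               25250.0, tolerance = 1e-9)
  expect_equal(predict_enhv(m, "cerebrum", icv = 1.5e6, age = 30, sex = 0),
               991800.0, tolerance = 1e-9)
  forms <- purrr::map_int(m$equations, "form")
  expect_identical(forms[enhv_rois()],
                   c(whole_brainstem = 2L, medulla = 1L, pons = 2L,
                     midbrain = 2L, cerebrum = 3L))
})

test_that("sex dummy identity: prediction at sex 0/1 equals the sub-equation alone", {
  m <- published_model()
  icv <- c(1.3e6, 1.5e6, 1.7e6)
  age <- c(20, 40, 60)
  for (roi in c("whole_brainstem", "pons", "midbrain")) {
    cf <- m$equations[[roi]]$coefficients
    expect_identical(predict_enhv(m, roi, icv, sex = 1),
                     cf$a_m * icv + cf$b_m)
    expect_identical(predict_enhv(m, roi, icv, sex = 0),
                     cf$a_f * icv + cf$b_f)
  }
  cf <- m$equations$cerebrum$coefficients
  expect_identical(predict_enhv(m, "cerebrum", icv, age = age, sex = 1),
                   cf$a_m * icv + cf$b_m * age + cf$c_m)
})

test_that("published predictions are monotone: increasing in ICV, decreasing in age for the cerebrum", {
  m <- published_model()
  icv <- seq(1.2e6, 1.9e6, length.out = 25)
  for (roi in enhv_rois()) {
    for (sex in 0:1) {
      pred <- predict_enhv(m, roi, icv, age = 40, sex = sex)
      expect_true(all(diff(pred) > 0))
      expect_true(all(pred > 0))
    }
  }
  ages <- seq(18, 68, length.out = 25)
  for (sex in 0:1) {
    pred <- predict_enhv(m, "cerebrum", 1.5e6, age = ages, sex = sex)
    expect_true(all(diff(pred) < 0))
  }
})

test_that("prediction validates its inputs", {
  m <- published_model()
  expect_error(predict_enhv(m, "cerebrum", icv = 1.5e6, sex = 0),
               "age", class = "enhv_validation_error")
  expect_error(predict_enhv(m, "whole_brainstem", icv = 1.5e6, sex = 2),
               class = "enhv_validation_error")
  expect_error(predict_enhv(m, "medulla", icv = -1),
               class = "enhv_validation_error")
})

test_that("screening flags perfect ICV linearity and an age effect only where present", {
  cohort <- exact_cohort(published_model(), n = 80)
  cohort$medulla <- 2 * cohort$icv / 1000
  scr <- screen_variables(cohort, "medulla")
  expect_equal(scr$r_icv, 1.0, tolerance = 1e-12)
  expect_true(scr$include_icv)

  # volumes on the published equations: age matters for the cerebrum only
  cohort <- exact_cohort(published_model(), n = 120)
  scr_cer <- screen_variables(cohort, "cerebrum")
  expect_true(scr_cer$include_age)
  expect_lt(scr_cer$r_age, 0)
  scr_pons <- screen_variables(cohort, "pons")
  # pons depends on age only through nothing: expect a null-ish correlation
  expect_lt(abs(scr_pons$r_age), 0.4)
})

test_that("age inclusion has the nominal false-positive rate under the null", {
  cfg <- generator_config(seed = 42)
  hits <- purrr::map_lgl(1:40, function(i) {
    cohort <- generate_healthy_cohort(cfg, n = 120, seed = 5000 + i)
    screen_variables(cohort, "midbrain")$include_age
  })
  # strict p < 0.05 screening: ~5% false positives; allow generous slack
  expect_lte(mean(hits), 0.25)
})

test_that("zero-variance predictors are rejected in screening", {
  cohort <- tiny_cohort()
  cohort <- dplyr::bind_rows(purrr::map(1:4, ~ {
    x <- cohort
    x$subject_id <- paste0(x$subject_id, .x)
    x
  }))
  cohort$age <- 30
  expect_error(screen_variables(cohort, "pons"),
               class = "enhv_validation_error")
})

test_that("the sex-by-ICV interaction test detects distinct slopes and respects df (1, n - 4)", {
  cfg <- generator_config(seed = 11)
  cohort <- generate_healthy_cohort(cfg, n = 182, seed = 11)
  res <- test_sex_icv_interaction(cohort, "whole_brainstem")
  expect_identical(res$df1, 1L)
  expect_identical(res$df2, 178L)

  # slopes differ strongly (published male vs female) and noise is small
  low_noise <- generator_config(seed = 12,
                                residual_sd = setNames(rep(50, 5), enhv_rois()))
  cohort <- generate_healthy_cohort(low_noise, n = 100, seed = 12)
  expect_true(test_sex_icv_interaction(cohort, "whole_brainstem")$stratify)

  # a single common line: false-positive rate stays nominal
  common <- published_model()
  common$equations$whole_brainstem <- enhv:::new_roi_equation(
    "whole_brainstem", 2,
    c(a_f = 6e-3, b_f = 1.6e4, a_m = 6e-3, b_m = 1.6e4))
  cfg0 <- generator_config(seed = 13, true_model = common)
  hits <- purrr::map_lgl(1:40, function(i) {
    cohort <- generate_healthy_cohort(cfg0, n = 120, seed = 6000 + i)
    test_sex_icv_interaction(cohort, "whole_brainstem")$stratify
  })
  expect_lte(mean(hits), 0.25)

  single_sex <- generate_healthy_cohort(cfg, n = 30, seed = 14)
  single_sex$sex <- 1L
  expect_error(test_sex_icv_interaction(single_sex, "pons"), "pooled",
               class = "enhv_validation_error")
})

test_that("noise-free fitting recovers the generating coefficients to 1e-9 relative error", {
  m <- published_model()
  cohort <- exact_cohort(m, n = 60)

  eq1 <- fit_roi_equation(cohort, "medulla",
                          screening = tibble::tibble(
                            roi = "medulla", r_age = 0, p_age = 1,
                            r_icv = 1, p_icv = 0, include_age = FALSE,
                            include_icv = TRUE),
                          interaction = tibble::tibble(stratify = FALSE))
  expect_equal(eq1$form, 1L)
  expect_equal(eq1$coefficients$a, 1.35e-3, tolerance = 1e-9)
  expect_equal(eq1$coefficients$b, 2.65e3, tolerance = 1e-9)

  eq2 <- fit_roi_equation(cohort, "whole_brainstem",
                          screening = tibble::tibble(
                            roi = "whole_brainstem", r_age = 0, p_age = 1,
                            r_icv = 1, p_icv = 0, include_age = FALSE,
                            include_icv = TRUE),
                          interaction = tibble::tibble(stratify = TRUE))
  expect_equal(eq2$form, 2L)
  expect_equal(unlist(eq2$coefficients),
               c(a_f = 3.92e-3, b_f = 1.80e4, a_m = 9.50e-3, b_m = 1.10e4),
               tolerance = 1e-9)

  eq3 <- fit_roi_equation(cohort, "cerebrum",
                          screening = tibble::tibble(
                            roi = "cerebrum", r_age = 0, p_age = 0,
                            r_icv = 1, p_icv = 0, include_age = TRUE,
                            include_icv = TRUE),
                          interaction = tibble::tibble(stratify = TRUE))
  expect_equal(eq3$form, 3L)
  expect_equal(unlist(eq3$coefficients),
               c(a_f = 2.90e-1, b_f = -1.54e3, c_f = 6.03e5,
                 a_m = 4.41e-1, b_m = -2.01e3, c_m = 4.11e5),
               tolerance = 1e-9)
})

test_that("OLS matches the closed-form normal-equations solution on tiny instances", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      n <- 9
      cohort <- tiny_cohort()[rep(1, n), ]
      cohort$subject_id <- paste0("s", 1:n)
      cohort$sex <- rep_len(c(0L, 1L), n)
      cohort$age <- runif(n, 20, 60)
      cohort$icv <- runif(n, 1.3e6, 1.8e6)
      cohort$pons <- 4e-3 * cohort$icv + 500 + rnorm(n, 0, 300)
      eq <- fit_roi_equation(cohort, "pons",
                             screening = tibble::tibble(
                               roi = "pons", r_age = 0, p_age = 1, r_icv = 1,
                               p_icv = 0, include_age = FALSE,
                               include_icv = TRUE),
                             interaction = tibble::tibble(stratify = FALSE))
      oracle <- normal_equations_ols(cbind(1, cohort$icv), cohort$pons)
      expect_equal(eq$coefficients$a, oracle[2], tolerance = 1e-9,
                   ignore_attr = TRUE)
      expect_equal(eq$coefficients$b, oracle[1], tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
})

test_that("identical slopes in both sexes collapse to a pooled form-1 fit", {
  common <- published_model()
  common$equations$pons <- enhv:::new_roi_equation(
    "pons", 2, c(a_f = 4e-3, b_f = 8e3, a_m = 4e-3, b_m = 8e3))
  cfg <- generator_config(seed = 98, true_model = common,
                          residual_sd = setNames(rep(1, 5), enhv_rois()))
  cohort <- generate_healthy_cohort(cfg, n = 60, seed = 98)
  eq <- fit_roi_equation(cohort, "pons")
  expect_equal(eq$form, 1L)
  expect_equal(eq$coefficients$a, 4e-3, tolerance = 1e-4)
})

test_that("build_model assembles all five equations with full provenance and is deterministic", {
  cfg <- generator_config(seed = 21)
  cohort <- generate_healthy_cohort(cfg, seed = 21)
  fit1 <- build_model(cohort)
  fit2 <- build_model(cohort)
  expect_identical(fit1, fit2)
  expect_setequal(names(fit1$equations), enhv_rois())
  expect_identical(fit1$provenance$type, "fitted")
  expect_identical(fit1$provenance$n, 182L)
  expect_identical(nrow(fit1$provenance$screening), 5L)
  expect_identical(nrow(fit1$provenance$interaction), 5L)

  # ICV-only regressions keep positive intercepts (non-proportionality)
  for (roi in setdiff(enhv_rois(), "cerebrum")) {
    v <- cohort[[roi]]
    expect_gt(coef(lm(v ~ cohort$icv))[1], 0)
  }
})

test_that("a single-sex cohort falls back to pooled form-1 equations with a warning", {
  cfg <- generator_config(seed = 22)
  cohort <- generate_healthy_cohort(cfg, n = 60, seed = 22)
  cohort$sex <- 0L
  # re-generate volumes so they are consistent with an all-female cohort
  m <- published_model()
  withr::with_seed(23, {
    for (roi in enhv_rois()) {
      mu <- predict_enhv(m, roi, cohort$icv, cohort$age, cohort$sex)
      cohort[[roi]] <- mu + rnorm(60, 0, cfg$residual_sd[[roi]] / 10)
    }
  })
  warns <- testthat::capture_warnings(fit <- build_model(cohort))
  expect_true(any(grepl("pooled", warns)))
  expect_true(all(purrr::map_int(fit$equations, "form") %in% c(1L, 3L)))
  expect_false(fit$equations$pons$sex_stratified)
})

test_that("coefficient estimates are unbiased over replicates under default noise", {
  cfg <- generator_config(seed = 31)
  truth <- c(a_f = 3.92e-3, b_f = 1.80e4, a_m = 9.50e-3, b_m = 1.10e4)
  scr <- tibble::tibble(roi = "whole_brainstem", r_age = 0, p_age = 1,
                        r_icv = 1, p_icv = 0, include_age = FALSE,
                        include_icv = TRUE)
  est <- purrr::map(1:80, function(i) {
    cohort <- generate_healthy_cohort(cfg, n = 182, seed = 7000 + i)
    unlist(fit_roi_equation(cohort, "whole_brainstem", screening = scr,
                            interaction = tibble::tibble(stratify = TRUE))$coefficients)
  })
  est <- do.call(rbind, est)
  for (cf in colnames(est)) {
    err <- est[, cf] - truth[[cf]]
    # 99% Monte-Carlo CI of the mean error must cover zero
    expect_lt(abs(mean(err)), 2.58 * sd(err) / sqrt(nrow(est)))
  }
})

test_that("models round-trip through JSON exactly and tidy/glance describe them", {
  cfg <- generator_config(seed = 33)
  fit <- build_model(generate_healthy_cohort(cfg, seed = 33))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  for (roi in enhv_rois()) {
    expect_identical(back$equations[[roi]]$coefficients,
                     fit$equations[[roi]]$coefficients)
    expect_identical(back$equations[[roi]]$form, fit$equations[[roi]]$form)
  }
  td <- tidy(fit)
  expect_true(all(c("roi", "sex", "term", "estimate") %in% names(td)))
  expect_setequal(unique(td$roi), enhv_rois())
  gl <- glance(fit)
  expect_identical(gl$n, 182L)
})
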