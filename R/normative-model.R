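# The normative ENHV model.
#
# Each analysis ROI gets one of three equation forms, with sex coded
# male = 1 / female = 0:
#   form 1: ENHV = a*ICV + b                                (pooled sexes)
#   form 2: ENHV = (1-sex)*(a_f*ICV + b_f) + sex*(a_m*ICV + b_m)
#   form 3: ENHV = (1-sex)*(a_f*ICV + b_f*age + c_f)
#                  + sex*(a_m*ICV + b_m*age + c_m)
# The form is chosen per ROI by the building procedure: Pearson screening of
# age and ICV against volume (ICV is always retained), then an F-test of the
# sex-by-ICV interaction to decide pooled vs sex-stratified least squares.

new_roi_equation <- function(roi, form, coefficients, pooled_age = FALSE) {
  form <- as.integer(form)
  expected <- switch(as.character(form),
    "1" = c("a", "b"),
    "2" = c("a_f", "b_f", "a_m", "b_m"),
    "3" = c("a_f", "b_f", "c_f", "a_m", "b_m", "c_m"),
    abort("Equation form must be 1, 2, or 3.", class = "enhv_validation_error")
  )
  if (!setequal(names(coefficients), expected)) {
    abort(sprintf("Form %d equation for %s needs coefficients %s.",
                  form, roi, paste(expected, collapse = ", ")),
          class = "enhv_validation_error")
  }
  structure(
    list(roi = roi, form = form,
         coefficients = as.list(coefficients)[expected],
         uses_age = form == 3L,
         sex_stratified = form %in% c(2L, 3L),
         pooled_age = pooled_age),
    class = "enhv_roi_equation"
  )
}

new_enhv_model <- function(equations, provenance) {
  stopifnot(setequal(names(equations), enhv_rois()))
  structure(list(equations = equations[enhv_rois()], provenance = provenance),
            class = "enhv_model")
}

#' The published normative model
#'
#' Returns the normative model with the published coefficient set, exactly as
#' printed (three significant figures; predictions therefore carry that
#' rounding). Forms: medulla pooled ICV-only (form 1); whole brainstem, pons,
#' and midbrain sex-stratified ICV-only (form 2); cerebrum sex-stratified
#' ICV + age (form 3). The published equations were derived from 182 healthy
#' Japanese/East Asian adults, so they apply to comparable populations.
#'
#' @return An `enhv_model` object.
#' @export
#' @examples
#' m <- published_model()
#' predict_enhv(m, "medulla", icv = 1.5e6)
published_model <- function() {
  eqs <- list(
    medulla = new_roi_equation("medulla", 1,
      c(a = 1.35e-03, b = 2.65e+03)),
    whole_brainstem = new_roi_equation("whole_brainstem", 2,
      c(a_f = 3.92e-03, b_f = 1.80e+04, a_m = 9.50e-03, b_m = 1.10e+04)),
    pons = new_roi_equation("pons", 2,
      c(a_f = 2.01e-03, b_f = 1.08e+04, a_m = 5.74e-03, b_m = 6.06e+03)),
    midbrain = new_roi_equation("midbrain", 2,
      c(a_f = 1.19e-03, b_f = 3.55e+03, a_m = 2.20e-03, b_m = 2.30e+03)),
    cerebrum = new_roi_equation("cerebrum", 3,
      c(a_f = 2.90e-01, b_f = -1.54e+03, c_f = 6.03e+05,
        a_m = 4.41e-01, b_m = -2.01e+03, c_m = 4.11e+05))
  )
  new_enhv_model(eqs, provenance = list(type = "published"))
}

#' Predict the expected normal healthy volume of a region
#'
#' Evaluates an ROI's model equation at the given intracranial volume, age,
#' and sex. Arguments are vectorized and recycled. `age` is required only for
#' equations that use age (the cerebrum in the published model); `sex` is
#' required for any sex-stratified equation.
#'
#' @param model An `enhv_model` (e.g. [published_model()] or [build_model()]).
#' @param roi One of [enhv_rois()].
#' @param icv Intracranial volume in mm^3 (positive).
#' @param age Age in years (positive); needed only for age-using equations.
#' @param sex 1 for male, 0 for female; needed for sex-stratified equations.
#' @return Predicted ENHV in mm^3.
#' @export
#' @examples
#' predict_enhv(published_model(), "cerebrum", icv = 1.5e6, age = 30, sex = 0)
predict_enhv <- function(model, roi, icv, age = NULL, sex = NULL) {
  stopifnot(inherits(model, "enhv_model"))
  roi <- match.arg(roi, enhv_rois())
  eq <- model$equations[[roi]]
  if (any(!is.finite(icv) | icv <= 0)) {
    abort("icv must be positive and finite.", class = "enhv_validation_error")
  }
  if (eq$sex_stratified) {
    if (is.null(sex)) {
      abort(sprintf("The %s equation is sex-stratified; sex is required.", roi),
            class = "enhv_validation_error")
    }
    if (any(!sex %in% c(0, 1))) {
      abort("sex must be coded 1 (male) / 0 (female).",
            class = "enhv_validation_error")
    }
  }
  if (eq$uses_age) {
    if (is.null(age)) {
      abort(sprintf("The %s equation uses age; age is required.", roi),
            class = "enhv_validation_error")
    }
    if (any(!is.finite(age) | age <= 0)) {
      abort("age must be positive and finite.", class = "enhv_validation_error")
    }
  }
  cf <- eq$coefficients
  switch(as.character(eq$form),
    "1" = cf$a * icv + cf$b,
    "2" = (1 - sex) * (cf$a_f * icv + cf$b_f) +
          sex * (cf$a_m * icv + cf$b_m),
    "3" = (1 - sex) * (cf$a_f * icv + cf$b_f * age + cf$c_f) +
          sex * (cf$a_m * icv + cf$b_m * age + cf$c_m)
  )
}

#' Screen explanatory variables for one ROI
#'
#' Pearson correlation of the ROI volume against age and against ICV on the
#' pooled cohort (both sexes together), with two-sided p-values. A variable is
#' flagged for inclusion when p < 0.05 (strict). ICV is always retained as a
#' predictor downstream regardless of its flag; screening can only add age.
#'
#' @param data A healthy cohort table (see [validate_cohort()]).
#' @param roi One of [enhv_rois()].
#' @return A one-row tibble: `roi`, `r_age`, `p_age`, `r_icv`, `p_icv`,
#'   `include_age`, `include_icv`.
#' @export
screen_variables <- function(data, roi) {
  roi <- match.arg(roi, enhv_rois())
  data <- validate_cohort(data)
  if (nrow(data) < 10) {
    abort("Screening requires at least 10 subjects.",
          class = "enhv_validation_error")
  }
  v <- data[[roi]]
  for (p in list(data$age, data$icv, v)) {
    if (stats::sd(p) == 0) {
      abort("Zero-variance variable; correlations are undefined.",
            class = "enhv_validation_error")
    }
  }
  ct_age <- cor.test(v, data$age, alternative = "two.sided", method = "pearson")
  ct_icv <- cor.test(v, data$icv, alternative = "two.sided", method = "pearson")
  tibble::tibble(
    roi = roi,
    r_age = unname(ct_age$estimate), p_age = ct_age$p.value,
    r_icv = unname(ct_icv$estimate), p_icv = ct_icv$p.value,
    include_age = ct_age$p.value < 0.05,
    include_icv = ct_icv$p.value < 0.05
  )
}

#' Test the sex-by-ICV interaction for one ROI
#'
#' Fits the linear model `volume ~ sex + ICV + sex:ICV` with ICV continuous
#' and returns the F-test of the interaction term on (1, n - 4) degrees of
#' freedom. A significant interaction (p < 0.05) indicates that the ICV slope
#' differs between the sexes, so the ROI's equation should be fitted on each
#' sex subgroup separately.
#'
#' @inheritParams screen_variables
#' @return A one-row tibble: `roi`, `f_stat`, `df1`, `df2`, `p`, `stratify`.
#' @export
test_sex_icv_interaction <- function(data, roi) {
  roi <- match.arg(roi, enhv_rois())
  data <- validate_cohort(data)
  n_by_sex <- table(factor(data$sex, levels = c(0, 1)))
  if (any(n_by_sex < 5)) {
    abort("Both sexes must be represented with >= 5 subjects each; fit a pooled equation for single-sex cohorts.",
          class = "enhv_validation_error")
  }
  v <- data[[roi]]
  fit <- lm(v ~ sex * icv, data = data.frame(v = v, sex = data$sex,
                                             icv = data$icv))
  an <- anova(fit)
  row <- an["sex:icv", ]
  tibble::tibble(
    roi = roi,
    f_stat = row$`F value`,
    df1 = row$Df,
    df2 = an["Residuals", "Df"],
    p = row$`Pr(>F)`,
    stratify = row$`Pr(>F)` < 0.05
  )
}

# ordinary least squares for one subgroup; returns named slope/intercept set
ols_subgroup <- function(data, roi, use_age) {
  v <- data[[roi]]
  if (nrow(data) < (1 + use_age) + 2) {
    abort(sprintf("Subgroup of %d subjects is too small to fit %d predictor(s).",
                  nrow(data), 1 + use_age),
          class = "enhv_validation_error")
  }
  if (use_age) {
    fit <- lm(v ~ icv + age, data = data.frame(v = v, icv = data$icv,
                                               age = data$age))
    c(a = unname(coef(fit)["icv"]), b = unname(coef(fit)["age"]),
      c = unname(coef(fit)["(Intercept)"]))
  } else {
    fit <- lm(v ~ icv, data = data.frame(v = v, icv = data$icv))
    c(a = unname(coef(fit)["icv"]), b = unname(coef(fit)["(Intercept)"]))
  }
}

#' Fit one ROI's model equation
#'
#' Ordinary least squares per sex subgroup when the sex-by-ICV interaction is
#' significant, pooled otherwise; age enters as a second predictor when the
#' screening flagged it. The equation form follows: pooled ICV-only is form 1,
#' stratified ICV-only is form 2, stratified ICV + age is form 3. The pooled
#' ICV + age case (which does not occur in the published model) is stored as a
#' form 3 equation with identical female and male sub-equations, flagged
#' `pooled_age`.
#'
#' @inheritParams screen_variables
#' @param screening Result of [screen_variables()] for this ROI (computed if
#'   `NULL`).
#' @param interaction Result of [test_sex_icv_interaction()] for this ROI
#'   (computed if `NULL`); ignored (pooled fit, with a warning) when the
#'   cohort has fewer than 5 subjects of either sex.
#' @return An `enhv_roi_equation`.
#' @export
fit_roi_equation <- function(data, roi, screening = NULL, interaction = NULL) {
  roi <- match.arg(roi, enhv_rois())
  data <- validate_cohort(data)
  if (is.null(screening)) screening <- screen_variables(data, roi)
  single_sex <- any(table(factor(data$sex, levels = c(0, 1))) < 5)
  if (is.null(interaction)) {
    if (single_sex) {
      warn(sprintf("Fewer than 5 subjects of one sex; fitting a pooled equation for %s.", roi))
      stratify <- FALSE
    } else {
      stratify <- test_sex_icv_interaction(data, roi)$stratify
    }
  } else {
    stratify <- isTRUE(interaction$stratify)
    if (stratify && single_sex) {
      warn(sprintf("Fewer than 5 subjects of one sex; fitting a pooled equation for %s.", roi))
      stratify <- FALSE
    }
  }
  if (!screening$include_icv) {
    warn(sprintf("ICV not significantly correlated with %s volume (p = %.3g); ICV is retained as a predictor regardless.",
                 roi, screening$p_icv))
  }
  use_age <- screening$include_age

  if (stratify) {
    f <- ols_subgroup(data[data$sex == 0, ], roi, use_age)
    m <- ols_subgroup(data[data$sex == 1, ], roi, use_age)
    if (use_age) {
      new_roi_equation(roi, 3, c(a_f = f[["a"]], b_f = f[["b"]], c_f = f[["c"]],
                                 a_m = m[["a"]], b_m = m[["b"]], c_m = m[["c"]]))
    } else {
      new_roi_equation(roi, 2, c(a_f = f[["a"]], b_f = f[["b"]],
                                 a_m = m[["a"]], b_m = m[["b"]]))
    }
  } else {
    cf <- ols_subgroup(data, roi, use_age)
    if (use_age) {
      new_roi_equation(roi, 3, c(a_f = cf[["a"]], b_f = cf[["b"]], c_f = cf[["c"]],
                                 a_m = cf[["a"]], b_m = cf[["b"]], c_m = cf[["c"]]),
                       pooled_age = TRUE)
    } else {
      new_roi_equation(roi, 1, c(a = cf[["a"]], b = cf[["b"]]))
    }
  }
}

#' Build a normative model from a healthy cohort
#'
#' Runs the full model-building procedure on a healthy cohort: per ROI,
#' Pearson screening of age and ICV ([screen_variables()]), the sex-by-ICV
#' interaction test ([test_sex_icv_interaction()]), and the pooled or
#' sex-stratified least-squares fit ([fit_roi_equation()]). The result is
#' deterministic given the cohort and records the full decision provenance
#' (cohort sizes, screening statistics, interaction F-tests).
#'
#' @param data A healthy cohort table with all five analysis ROI volumes.
#' @return An `enhv_model` with `provenance$type == "fitted"`.
#' @export
#' @examples
#' cohort <- generate_healthy_cohort(generator_config(seed = 1), n = 60)
#' fit <- build_model(cohort)
#' glance(fit)
build_model <- function(data) {
  data <- validate_cohort(data)
  screening <- purrr::map_dfr(enhv_rois(), ~ screen_variables(data, .x))
  single_sex <- any(table(factor(data$sex, levels = c(0, 1))) < 5)
  interaction <- NULL
  if (!single_sex) {
    interaction <- purrr::map_dfr(enhv_rois(),
                                  ~ test_sex_icv_interaction(data, .x))
  }
  eqs <- purrr::map(enhv_rois(), function(roi) {
    fit_roi_equation(
      data, roi,
      screening = screening[screening$roi == roi, ],
      interaction = if (is.null(interaction)) NULL else
        interaction[interaction$roi == roi, ]
    )
  })
  names(eqs) <- enhv_rois()
  new_enhv_model(eqs, provenance = list(
    type = "fitted",
    n = nrow(data),
    n_female = sum(data$sex == 0),
    n_male = sum(data$sex == 1),
    screening = screening,
    interaction = interaction
  ))
}

#' @export
print.enhv_model <- function(x, ...) {
  cat("ENHV normative model (", x$provenance$type, ")\n", sep = "")
  if (x$provenance$type == "fitted") {
    cat(sprintf("  fitted on n = %d (%d F / %d M)\n", x$provenance$n,
                x$provenance$n_female, x$provenance$n_male))
  }
  for (eq in x$equations) {
    cat(sprintf("  %-16s form %d%s: %s\n", eq$roi, eq$form,
                if (isTRUE(eq$pooled_age)) " (pooled+age)" else "",
                paste(sprintf("%s=%.4g", names(eq$coefficients),
                              unlist(eq$coefficients)), collapse = ", ")))
  }
  invisible(x)
}

#' Tidy an ENHV model into a coefficient table
#'
#' @param x An `enhv_model`.
#' @param ... Unused.
#' @return A tibble with one row per ROI, sub-equation, and term: columns
#'   `roi`, `form`, `sex` (`pooled`, `female`, or `male`), `term`
#'   (`icv`, `age`, `intercept`), `estimate`.
#' @method tidy enhv_model
#' @export
tidy.enhv_model <- function(x, ...) {
  purrr::map_dfr(x$equations, function(eq) {
    cf <- eq$coefficients
    if (eq$form == 1L) {
      tibble::tibble(roi = eq$roi, form = eq$form, sex = "pooled",
                     term = c("icv", "intercept"),
                     estimate = c(cf$a, cf$b))
    } else if (eq$form == 2L) {
      tibble::tibble(roi = eq$roi, form = eq$form,
                     sex = rep(c("female", "male"), each = 2),
                     term = rep(c("icv", "intercept"), 2),
                     estimate = c(cf$a_f, cf$b_f, cf$a_m, cf$b_m))
    } else {
      tibble::tibble(roi = eq$roi, form = eq$form,
                     sex = rep(c("female", "male"), each = 3),
                     term = rep(c("icv", "age", "intercept"), 2),
                     estimate = c(cf$a_f, cf$b_f, cf$c_f,
                                  cf$a_m, cf$b_m, cf$c_m))
    }
  })
}

#' One-row summary of an ENHV model
#'
#' @param x An `enhv_model`.
#' @param ... Unused.
#' @return A one-row tibble: `provenance`, cohort sizes (NA for the published
#'   model), and the per-ROI equation forms.
#' @method glance enhv_model
#' @export
glance.enhv_model <- function(x, ...) {
  forms <- purrr::map_int(x$equations, "form")
  tibble::tibble(
    provenance = x$provenance$type,
    n = x$provenance$n %||% NA_integer_,
    n_female = x$provenance$n_female %||% NA_integer_,
    n_male = x$provenance$n_male %||% NA_integer_,
    form_whole_brainstem = forms[["whole_brainstem"]],
    form_medulla = forms[["medulla"]],
    form_pons = forms[["pons"]],
    form_midbrain = forms[["midbrain"]],
    form_cerebrum = forms[["cerebrum"]]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a normative model to JSON
#'
#' Serializes the equation set and provenance with full numeric precision so
#' that coefficients survive a round trip exactly.
#'
#' @param model An `enhv_model`.
#' @param path Output JSON path.
#' @return `model`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "enhv_model"))
  doc <- list(
    schema = "enhv-model",
    version = 1L,
    provenance = list(
      type = model$provenance$type,
      n = model$provenance$n %||% NULL,
      n_female = model$provenance$n_female %||% NULL,
      n_male = model$provenance$n_male %||% NULL
    ),
    equations = purrr::map(model$equations, function(eq) {
      # coefficients as full decimal text: %.17g survives the double ->
      # text -> double round trip bit-exactly
      list(roi = eq$roi, form = eq$form,
           coefficients = purrr::map(eq$coefficients,
                                     ~ sprintf("%.17g", .x)),
           uses_age = eq$uses_age, sex_stratified = eq$sex_stratified,
           pooled_age = isTRUE(eq$pooled_age))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(model)
}

#' Read a normative model from JSON
#'
#' @param path Path to a JSON file written by [write_model()].
#' @return An `enhv_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "enhv-model")) {
    abort(sprintf("%s is not an ENHV model document.", path),
          class = "enhv_parse_error")
  }
  eqs <- purrr::map(doc$equations, function(eq) {
    cf <- vapply(eq$coefficients, function(x) as.numeric(x), numeric(1))
    new_roi_equation(eq$roi, eq$form, cf,
                     pooled_age = isTRUE(eq$pooled_age))
  })
  names(eqs) <- purrr::map_chr(doc$equations, "roi")
  prov <- doc$provenance
  prov <- prov[!purrr::map_lgl(prov, is.null)]
  new_enhv_model(eqs, provenance = prov)
}
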