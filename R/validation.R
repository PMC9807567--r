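# Model validation by intraclass correlation.
#
# Agreement between measured volumes and model predictions is quantified with
# ICC(A,1) in McGraw & Wong's taxonomy: two-way model, single measures,
# absolute agreement. With n subjects and k = 2 "raters" (measurement vs
# model), the two-way crossed ANOVA decomposition gives row (subject), column
# (rater), and error mean squares, and
#   ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE)).
# Absolute agreement penalizes systematic offsets between the two columns,
# which mere correlation would not.

#' Intraclass correlation, two-way single-measure absolute agreement
#'
#' Computes ICC(A,1) between two equal-length measurement vectors, with the
#' standard F-based 95% confidence interval and a p-value for ICC > 0 from
#' `F = MSR / MSE` on `(n - 1, (n - 1)(k - 1))` degrees of freedom. Negative
#' estimates are reported as computed, not floored at zero.
#'
#' @param x,y Numeric vectors of equal length (n >= 5), e.g. measured volumes
#'   and model-predicted ENHVs across subjects.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A one-row tibble: `icc`, `ci_low`, `ci_high`, `p`.
#' @export
#' @examples
#' icc_absolute_single(c(1, 2, 3), c(2, 3, 4))
icc_absolute_single <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length.", class = "enhv_validation_error")
  }
  n <- length(x)
  k <- 2
  if (n < 3) {
    abort("ICC requires at least 3 paired observations (5 or more recommended).",
          class = "enhv_validation_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("ICC inputs must be finite.", class = "enhv_validation_error")
  }
  dat <- cbind(x, y)
  if (var(as.vector(dat)) == 0) {
    abort("Constant data; ICC is undefined.", class = "enhv_validation_error")
  }
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((dat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # F-based interval for ICC(A,1) (McGraw & Wong 1996, case 2A single)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  f0 <- msr / mse
  p <- pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  tibble::tibble(icc = icc, ci_low = ci_low, ci_high = ci_high, p = p)
}

#' Classify an ICC into a reliability band
#'
#' Bands: below 0.4 poor, [0.4, 0.6) fair, [0.6, 0.75) good, [0.75, 1] excellent
#' (left-closed intervals; the conventional band table's small gaps between
#' 0.59/0.6 and 0.74/0.75 are closed on the left). Vectorized.
#'
#' @param icc Numeric ICC estimate(s), each <= 1.
#' @return Character vector of bands.
#' @export
#' @examples
#' classify_icc(c(0.39, 0.4, 0.715, 0.922))
classify_icc <- function(icc) {
  if (any(icc > 1, na.rm = TRUE)) {
    abort("ICC cannot exceed 1.", class = "enhv_validation_error")
  }
  dplyr::case_when(
    icc < 0.4 ~ "poor",
    icc < 0.6 ~ "fair",
    icc < 0.75 ~ "good",
    TRUE ~ "excellent"
  )
}

#' Validate a normative model on an independent healthy cohort
#'
#' For each analysis ROI, computes ICC(A,1) between the measured volumes and
#' the model-predicted ENHVs across the cohort's subjects, classifies the
#' reliability band, and flags the equation as valid when ICC > 0.4. The
#' validation cohort must be disjoint from the cohort the model was fitted on
#' (the caller asserts this; it is not checkable from the data).
#'
#' @param model An `enhv_model`.
#' @param data A healthy cohort table.
#' @param conf_level Confidence level for the ICC intervals.
#' @return A tibble of class `enhv_validation` with one row per ROI: `roi`,
#'   `icc`, `ci_low`, `ci_high`, `p`, `band`, `valid`, `n`.
#' @export
#' @examples
#' cfg <- generator_config(seed = 7)
#' fit <- build_model(generate_healthy_cohort(cfg))
#' holdout <- generate_healthy_cohort(cfg, n = 47, seed = 8)
#' validate_model(fit, holdout)
validate_model <- function(model, data, conf_level = 0.95) {
  stopifnot(inherits(model, "enhv_model"))
  data <- validate_cohort(data)
  out <- purrr::map_dfr(enhv_rois(), function(roi) {
    enhv <- predict_enhv(model, roi, icv = data$icv, age = data$age,
                         sex = data$sex)
    res <- icc_absolute_single(data[[roi]], enhv, conf_level = conf_level)
    dplyr::bind_cols(tibble::tibble(roi = roi), res)
  })
  out$band <- classify_icc(out$icc)
  out$valid <- out$icc > 0.4
  out$n <- nrow(data)
  class(out) <- c("enhv_validation", class(out))
  out
}

#' Write a validation report to JSON
#'
#' @param validation Result of [validate_model()].
#' @param path Output JSON path.
#' @return `validation`, invisibly.
#' @export
write_validation <- function(validation, path) {
  jsonlite::write_json(
    list(schema = "enhv-validation", version = 1L,
         results = as.data.frame(validation)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(validation)
}
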