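# ENHV-adjusted volumes and the patient-vs-control analysis battery.
#
# The adjusted volume expresses a subject's measured regional volume as a
# percentage of the ENHV predicted for a healthy person of the same ICV, age,
# and sex:
#   adjusted (% of ENHV) = 100 * measured / ENHV,   percent loss = 100 - adjusted.
# The conventional "proportions" correction (measured / ICV) is carried along
# as a comparator.

#' ENHV-adjusted volume
#'
#' @param measured Measured regional volume, mm^3 (positive).
#' @param enhv Model-predicted expected normal healthy volume, mm^3 (positive).
#' @return Adjusted volume as a percent of ENHV (100 = exactly as expected,
#'   below 100 = volume loss). Vectorized.
#' @export
#' @examples
#' enhv_adjusted_volume(20000, 25000)
enhv_adjusted_volume <- function(measured, enhv) {
  if (any(!is.finite(measured) | measured <= 0) ||
      any(!is.finite(enhv) | enhv <= 0)) {
    abort("measured and enhv must be positive and finite.",
          class = "enhv_validation_error")
  }
  100 * measured / enhv
}

#' Conventional ICV-proportion volume
#'
#' The comparator head-size correction: regional volume divided by ICV.
#'
#' @param measured Measured regional volume, mm^3.
#' @param icv Intracranial volume, mm^3 (positive).
#' @return Dimensionless proportion. Vectorized.
#' @export
icv_proportion_volume <- function(measured, icv) {
  if (any(!is.finite(icv) | icv <= 0)) {
    abort("icv must be positive and finite.", class = "enhv_validation_error")
  }
  measured / icv
}

#' Compute per-subject adjusted volumes for a cohort
#'
#' Applies a normative model to every subject and ROI, returning a long table
#' of measured volume, predicted ENHV, ENHV-adjusted volume (percent of ENHV),
#' percent loss, and the ICV-proportion comparator. Subject-level clinical
#' covariates present in the cohort (`pta_weeks`, `time_since_injury_months`,
#' `group_label`) are carried through.
#'
#' @param data A cohort table (patients or controls).
#' @param model An `enhv_model` (default: [published_model()]).
#' @return A tibble with one row per subject x ROI.
#' @export
#' @examples
#' cfg <- generator_config(seed = 3)
#' dai <- generate_dai_cohort(cfg)
#' adj <- adjust_volumes(dai, published_model())
#' summarize_loss(adj)
adjust_volumes <- function(data, model = published_model()) {
  data <- validate_cohort(data)
  carry <- intersect(cohort_optional_cols(), names(data))
  long <- tidyr::pivot_longer(data, cols = dplyr::all_of(enhv_rois()),
                              names_to = "roi", values_to = "measured")
  long$enhv <- purrr::map_dbl(seq_len(nrow(long)), function(i) {
    predict_enhv(model, long$roi[i], icv = long$icv[i], age = long$age[i],
                 sex = long$sex[i])
  })
  long$adjusted <- enhv_adjusted_volume(long$measured, long$enhv)
  long$percent_loss <- 100 - long$adjusted
  long$icv_proportion <- icv_proportion_volume(long$measured, long$icv)
  long[, c("subject_id", carry, "roi", "measured", "enhv", "adjusted",
           "percent_loss", "icv_proportion")]
}

# two-sided Mann-Whitney U; exact when both groups are small and tie-free,
# normal approximation with tie correction otherwise
mw_test <- function(a, b, exact_max_n = 25) {
  use_exact <- length(a) <= exact_max_n && length(b) <= exact_max_n &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = !use_exact)
  )
  list(u = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal_approx")
}

#' Compare groups variable-by-variable with Mann-Whitney U tests
#'
#' Two-sided Mann-Whitney U test for each named column of two wide tables
#' (for example, a patient and a control cohort compared on ICV and the five
#' measured ROI volumes, or two groups of ENHV-adjusted volumes), with
#' Bonferroni correction over the declared family of tests. Exact p-values
#' are used when both groups have at most `exact_max_n` observations and
#' there are no ties; otherwise the normal approximation with tie correction.
#'
#' @param data_a,data_b Data frames holding the two groups.
#' @param vars Columns to compare (default: ICV plus the five analysis ROIs).
#' @param family_size Number of tests in the Bonferroni family (default
#'   `length(vars)`; the customary family for the measured-volume table is 6 =
#'   ICV + five ROIs).
#' @param exact_max_n Largest per-group n for which exact p-values are
#'   attempted (default 25).
#' @return A tibble with one row per variable: group means and SDs, `u_stat`,
#'   `p_raw`, `p_bonferroni` (`min(1, family_size * p_raw)`), `significant`
#'   (corrected p < 0.05), `method`, `family_size`.
#' @export
compare_groups <- function(data_a, data_b,
                           vars = c("icv", enhv_rois()),
                           family_size = length(vars),
                           exact_max_n = 25) {
  if (nrow(data_a) == 0 || nrow(data_b) == 0) {
    abort("Both groups must be non-empty.", class = "enhv_validation_error")
  }
  if (family_size < length(vars)) {
    abort("family_size must be at least the number of tests.",
          class = "enhv_validation_error")
  }
  purrr::map_dfr(vars, function(v) {
    a <- data_a[[v]]
    b <- data_b[[v]]
    if (is.null(a) || is.null(b)) {
      abort(sprintf("Column %s missing from one of the groups.", dQuote(v)),
            class = "enhv_validation_error")
    }
    res <- mw_test(a, b, exact_max_n = exact_max_n)
    p_bon <- min(1, family_size * res$p)
    tibble::tibble(
      variable = v,
      mean_a = mean(a), sd_a = sd(a), n_a = length(a),
      mean_b = mean(b), sd_b = sd(b), n_b = length(b),
      u_stat = res$u, p_raw = res$p, p_bonferroni = p_bon,
      significant = p_bon < 0.05, method = res$method,
      family_size = family_size
    )
  })
}

# paired two-sided Wilcoxon signed-rank; exact when tie- and zero-free and
# n <= exact_max_n. All-zero differences mean "no evidence of any effect",
# reported as p = 1.
signed_rank_test <- function(a, b, exact_max_n = 25) {
  d <- a - b
  if (all(d == 0)) {
    return(list(v = 0, p = 1, method = "degenerate_all_zero"))
  }
  use_exact <- sum(d != 0) <= exact_max_n && !any(d == 0) &&
    !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    wilcox.test(a, b, paired = TRUE, alternative = "two.sided",
                exact = use_exact, correct = !use_exact)
  )
  list(v = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal_approx")
}

#' Within-subject comparisons of adjusted volumes in a patient group
#'
#' Runs the within-subject battery on one group's ENHV-adjusted volumes:
#' (a) a related-samples Wilcoxon signed-rank test of whole brainstem vs
#' cerebrum; (b) a Friedman test across the three brainstem subfields
#' (medulla, pons, midbrain); and (c) the three pairwise signed-rank tests
#' among the subfields with Bonferroni correction (m = 3). All tests are
#' two-tailed. Subjects with incomplete ROI values are dropped with a warning.
#'
#' @param adjusted Long adjusted-volume table from [adjust_volumes()] (one
#'   group).
#' @param exact_max_n Largest n for exact signed-rank p-values.
#' @return A tibble with one row per test: `comparison`, `test`, `statistic`,
#'   `p_raw`, `p_bonferroni` (NA where no correction applies), `n`.
#' @export
within_subject_region_comparison <- function(adjusted, exact_max_n = 25) {
  wide <- tidyr::pivot_wider(
    adjusted[, c("subject_id", "roi", "adjusted")],
    names_from = "roi", values_from = "adjusted"
  )
  need <- c("whole_brainstem", "cerebrum", "medulla", "pons", "midbrain")
  missing_cols <- setdiff(need, names(wide))
  if (length(missing_cols) > 0) {
    abort(paste0("Adjusted table lacks ROI(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "enhv_validation_error")
  }
  complete <- stats::complete.cases(wide[, need])
  if (any(!complete)) {
    warn(sprintf("Dropping %d subject(s) with incomplete ROI values.",
                 sum(!complete)))
    wide <- wide[complete, ]
  }
  n <- nrow(wide)

  wb_cer <- signed_rank_test(wide$whole_brainstem, wide$cerebrum, exact_max_n)
  fr <- friedman.test(as.matrix(wide[, c("medulla", "pons", "midbrain")]))
  pairs <- list(
    pons_vs_midbrain = signed_rank_test(wide$pons, wide$midbrain, exact_max_n),
    pons_vs_medulla = signed_rank_test(wide$pons, wide$medulla, exact_max_n),
    midbrain_vs_medulla = signed_rank_test(wide$midbrain, wide$medulla,
                                           exact_max_n)
  )
  dplyr::bind_rows(
    tibble::tibble(comparison = "whole_brainstem_vs_cerebrum",
                   test = "wilcoxon_signed_rank", statistic = wb_cer$v,
                   p_raw = wb_cer$p, p_bonferroni = NA_real_, n = n),
    tibble::tibble(comparison = "medulla_pons_midbrain",
                   test = "friedman", statistic = unname(fr$statistic),
                   p_raw = fr$p.value, p_bonferroni = NA_real_, n = n),
    purrr::imap_dfr(pairs, function(res, nm) {
      tibble::tibble(comparison = nm, test = "wilcoxon_signed_rank",
                     statistic = res$v, p_raw = res$p,
                     p_bonferroni = min(1, 3 * res$p), n = n)
    })
  )
}

#' First-order partial correlation
#'
#' Pearson correlation between `x` and `y` after removing the linear effect of
#' a single covariate `z`, by the closed-form formula
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with a two-sided
#' p-value from the t distribution on n - 3 degrees of freedom. Identical to
#' the Pearson correlation of the OLS residuals of `x ~ z` and `y ~ z`.
#'
#' @param x,y,z Numeric vectors of equal length (n >= 5).
#' @return A one-row tibble: `r`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    abort("x, y, z must have equal length.", class = "enhv_validation_error")
  }
  if (n < 5) {
    abort("Partial correlation requires n >= 5.",
          class = "enhv_validation_error")
  }
  r_xy <- cor(x, y)
  r_xz <- cor(x, z)
  r_yz <- cor(y, z)
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  df <- n - 3
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  tibble::tibble(r = r, p = p, n = n)
}

#' Correlate PTA duration with regional volume measures
#'
#' For each analysis ROI, correlates the duration of posttraumatic amnesia
#' (integer weeks) with the ENHV-adjusted volume — plain Pearson correlation,
#' or a first-order partial correlation controlling for time since injury.
#' Setting `use_proportions = TRUE` substitutes the conventional
#' ICV-proportion volumes for the adjusted volumes. P-values are two-sided
#' and reported uncorrected.
#'
#' @param adjusted Long adjusted-volume table from [adjust_volumes()] for a
#'   patient group; must carry `pta_weeks` (and `time_since_injury_months`
#'   when controlling).
#' @param control_for_tsi Partial out time since injury? (default `TRUE`).
#' @param use_proportions Correlate ICV-proportion volumes instead of
#'   ENHV-adjusted volumes (default `FALSE`).
#' @return A tibble with one row per ROI: `roi`, `r`, `p`, `n`, `method`,
#'   `covariate`, `significant` (p < 0.05, uncorrected).
#' @export
pta_correlation <- function(adjusted, control_for_tsi = TRUE,
                            use_proportions = FALSE) {
  if (!"pta_weeks" %in% names(adjusted)) {
    abort("Adjusted table must carry pta_weeks.",
          class = "enhv_validation_error")
  }
  if (control_for_tsi && !"time_since_injury_months" %in% names(adjusted)) {
    abort("Controlling for time since injury requires time_since_injury_months.",
          class = "enhv_validation_error")
  }
  value_col <- if (use_proportions) "icv_proportion" else "adjusted"
  method <- if (control_for_tsi) {
    if (use_proportions) "proportions_partial" else "partial"
  } else "pearson"
  purrr::map_dfr(enhv_rois(), function(roi) {
    sub <- adjusted[adjusted$roi == roi, ]
    if (any(is.na(sub$pta_weeks))) {
      abort("pta_weeks must be present for all subjects.",
            class = "enhv_validation_error")
    }
    if (nrow(sub) < 5) {
      abort("PTA correlation requires at least 5 subjects.",
            class = "enhv_validation_error")
    }
    if (control_for_tsi) {
      res <- partial_correlation(sub$pta_weeks, sub[[value_col]],
                                 sub$time_since_injury_months)
    } else {
      ct <- cor.test(sub$pta_weeks, sub[[value_col]],
                     alternative = "two.sided", method = "pearson")
      res <- tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                            n = nrow(sub))
    }
    dplyr::bind_cols(
      tibble::tibble(roi = roi), res,
      tibble::tibble(method = method,
                     covariate = if (control_for_tsi)
                       "time_since_injury_months" else NA_character_,
                     significant = res$p < 0.05)
    )
  })
}

#' Summarize adjusted volumes and percent loss per ROI
#'
#' Arithmetic mean and SD of the per-subject ENHV-adjusted volumes for each
#' ROI (and group, when a `group_label` column is present), plus the mean
#' percent loss (100 minus the mean adjusted volume).
#'
#' @param adjusted Long adjusted-volume table from [adjust_volumes()].
#' @return A tibble with one row per (group x) ROI: `n`, `mean_adjusted`,
#'   `sd_adjusted`, `mean_percent_loss`.
#' @export
summarize_loss <- function(adjusted) {
  if (nrow(adjusted) == 0) {
    abort("Adjusted table is empty.", class = "enhv_validation_error")
  }
  keys <- intersect("group_label", names(adjusted))
  adjusted |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "roi")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_adjusted = mean(.data$adjusted),
      sd_adjusted = sd(.data$adjusted),
      mean_percent_loss = 100 - mean(.data$adjusted),
      .groups = "drop"
    )
}
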