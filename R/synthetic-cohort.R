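# Seeded synthetic cohorts.
#
# The generators emulate the statistical structure the normative model
# assumes: healthy regional volumes that follow the published equations with
# additive Gaussian residuals, sexes differing in mean ICV, and a patient
# group whose ENHV-adjusted volumes are shifted downward with a severity
# (PTA)-linked component. Residual SDs are not published, so they are solved
# analytically from the published ICV-volume correlations: for each ROI the
# mixture-of-sexes moments of (ICV, volume) give a closed form for the
# residual variance that reproduces a target pooled Pearson r.

#' Configuration of the synthetic cohort generators
#'
#' All distributional parameters of the synthetic healthy and DAI-like
#' cohorts. Defaults are calibrated to published healthy-adult and
#' diffuse-axonal-injury summary statistics: healthy n = 182 with 99 males,
#' ages uniform on 18-68, pooled ICV mean 1.544e6 mm^3 and SD 1.92e5 mm^3
#' with a male-female ICV offset of 10% of the mean; regional volumes
#' generated from the published equations with residual SDs solved to match
#' pooled ICV-volume Pearson correlations of 0.614 / 0.496 / 0.567 / 0.677 /
#' 0.828 (whole brainstem / medulla / pons / midbrain / cerebrum); a DAI
#' group of n = 22 (17 males), mean adjusted volumes 86.1 / 91.1 / 83.7 /
#' 88.1 / 92.6 percent with SDs 11.4 / 10.2 / 11.6 / 14.8 / 7.2, PTA drawn
#' from a discretized log-normal truncated to 1-26 weeks with median 7.5,
#' time since injury log-uniform on 5-355 months, and PTA-linked atrophy
#' targeting correlations of -0.528 / -0.283 / -0.537 / -0.572 / -0.313.
#'
#' @param seed Integer seed; every generator draw is reproducible given it.
#' @param n_healthy Healthy cohort size.
#' @param male_fraction Probability a healthy subject is male.
#' @param age_range Healthy age range in years (uniform).
#' @param icv_mean,icv_sd Pooled ICV mean and SD, mm^3.
#' @param icv_sex_offset Male-minus-female difference in mean ICV, mm^3.
#' @param true_model `enhv_model` used as the data-generating truth.
#' @param target_icv_r Named target pooled Pearson r of ICV vs volume per ROI;
#'   residual SDs are solved from these.
#' @param residual_sd Optional named per-ROI residual SD override, mm^3; when
#'   `NULL` (default) it is calibrated from `target_icv_r`.
#' @param n_dai DAI cohort size.
#' @param dai_male_fraction Probability a DAI subject is male.
#' @param dai_age_range DAI age range in years (uniform).
#' @param dai_adjusted_mean,dai_adjusted_sd Named per-ROI mean and SD of the
#'   DAI ENHV-adjusted volume, percent.
#' @param pta_range Integer PTA support in weeks (truncation bounds).
#' @param pta_median Target median PTA in weeks.
#' @param pta_sdlog Log-scale SD of the PTA log-normal.
#' @param pta_effect_r Named per-ROI target correlation between PTA and
#'   adjusted volume.
#' @param tsi_range Time since injury range in months (log-uniform).
#' @return A `generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(seed = 1)
#' round(cfg$residual_sd)
generator_config <- function(
    seed = 1L,
    n_healthy = 182L,
    male_fraction = 99 / 182,
    age_range = c(18, 68),
    icv_mean = 1.544e6,
    icv_sd = 1.92e5,
    icv_sex_offset = 0.1 * icv_mean,
    true_model = published_model(),
    target_icv_r = c(whole_brainstem = 0.614, medulla = 0.496, pons = 0.567,
                     midbrain = 0.677, cerebrum = 0.828),
    residual_sd = NULL,
    n_dai = 22L,
    dai_male_fraction = 17 / 22,
    dai_age_range = c(21, 61),
    dai_adjusted_mean = c(whole_brainstem = 86.1, medulla = 91.1, pons = 83.7,
                          midbrain = 88.1, cerebrum = 92.6),
    dai_adjusted_sd = c(whole_brainstem = 11.4, medulla = 10.2, pons = 11.6,
                        midbrain = 14.8, cerebrum = 7.2),
    pta_range = c(1L, 26L),
    pta_median = 7.5,
    pta_sdlog = 0.8,
    pta_effect_r = c(whole_brainstem = -0.528, medulla = -0.283, pons = -0.537,
                     midbrain = -0.572, cerebrum = -0.313),
    tsi_range = c(5, 355)) {
  stopifnot(icv_sd > 0, icv_mean > 0, male_fraction > 0, male_fraction < 1,
            all(dai_adjusted_sd >= 0), all(dai_adjusted_mean > 0),
            all(dai_adjusted_mean < 150), inherits(true_model, "enhv_model"))
  cfg <- list(
    seed = as.integer(seed), n_healthy = as.integer(n_healthy),
    male_fraction = male_fraction, age_range = age_range,
    icv_mean = icv_mean, icv_sd = icv_sd, icv_sex_offset = icv_sex_offset,
    true_model = true_model, target_icv_r = target_icv_r[enhv_rois()],
    n_dai = as.integer(n_dai), dai_male_fraction = dai_male_fraction,
    dai_age_range = dai_age_range,
    dai_adjusted_mean = dai_adjusted_mean[enhv_rois()],
    dai_adjusted_sd = dai_adjusted_sd[enhv_rois()],
    pta_range = pta_range, pta_median = pta_median, pta_sdlog = pta_sdlog,
    pta_effect_r = pta_effect_r[enhv_rois()], tsi_range = tsi_range
  )
  cfg$sigma_w <- sqrt(icv_sd^2 - male_fraction * (1 - male_fraction) *
                        icv_sex_offset^2)
  if (!is.finite(cfg$sigma_w) || cfg$sigma_w <= 0) {
    abort("icv_sex_offset is too large for the pooled icv_sd.",
          class = "enhv_validation_error")
  }
  cfg$residual_sd <- if (is.null(residual_sd)) {
    calibrate_residual_sd(cfg)
  } else {
    residual_sd[enhv_rois()]
  }
  structure(cfg, class = "generator_config")
}

# per-sex (icv slope, age slope, intercept) of an equation
equation_lines <- function(eq) {
  cf <- eq$coefficients
  switch(as.character(eq$form),
    "1" = list(f = c(a = cf$a, b_age = 0, c = cf$b),
               m = c(a = cf$a, b_age = 0, c = cf$b)),
    "2" = list(f = c(a = cf$a_f, b_age = 0, c = cf$b_f),
               m = c(a = cf$a_m, b_age = 0, c = cf$b_m)),
    "3" = list(f = c(a = cf$a_f, b_age = cf$b_f, c = cf$c_f),
               m = c(a = cf$a_m, b_age = cf$b_m, c = cf$c_m))
  )
}

# Solve, per ROI, the residual SD that makes the pooled ICV-volume Pearson
# correlation equal its target, from the exact mixture moments:
#   Cov(ICV,V)  = sigma_w^2 E[a_S] + p(1-p) (mu_m - mu_f)(m_m - m_f)
#   Var(ICV)    = sigma_w^2 + p(1-p) (mu_m - mu_f)^2
#   Var(V)      = E[a_S^2] sigma_w^2 + E[b_S^2] Var(age)
#                 + p(1-p) (m_m - m_f)^2 + tau^2
# where m_s is the sex-specific mean volume at the mean age, and the target
# fixes Var(V) = (Cov / (r * sd_ICV))^2.
calibrate_residual_sd <- function(cfg) {
  p <- cfg$male_fraction
  mu_f <- cfg$icv_mean - p * cfg$icv_sex_offset
  mu_m <- mu_f + cfg$icv_sex_offset
  var_w <- cfg$sigma_w^2
  mean_age <- mean(cfg$age_range)
  var_age <- diff(cfg$age_range)^2 / 12
  var_icv <- var_w + p * (1 - p) * (mu_m - mu_f)^2

  out <- purrr::map_dbl(enhv_rois(), function(roi) {
    ln <- equation_lines(cfg$true_model$equations[[roi]])
    e_a <- (1 - p) * ln$f[["a"]] + p * ln$m[["a"]]
    e_a2 <- (1 - p) * ln$f[["a"]]^2 + p * ln$m[["a"]]^2
    e_b2 <- (1 - p) * ln$f[["b_age"]]^2 + p * ln$m[["b_age"]]^2
    m_f <- ln$f[["a"]] * mu_f + ln$f[["b_age"]] * mean_age + ln$f[["c"]]
    m_m <- ln$m[["a"]] * mu_m + ln$m[["b_age"]] * mean_age + ln$m[["c"]]
    cov_iv <- var_w * e_a + p * (1 - p) * (mu_m - mu_f) * (m_m - m_f)
    var_v_target <- (cov_iv / (cfg$target_icv_r[[roi]] * sqrt(var_icv)))^2
    structural <- e_a2 * var_w + e_b2 * var_age +
      p * (1 - p) * (m_m - m_f)^2
    tau2 <- var_v_target - structural
    if (tau2 <= 0) {
      abort(sprintf("Target ICV correlation %.3f for %s is unattainably high given the equations.",
                    cfg$target_icv_r[[roi]], roi),
            class = "enhv_validation_error")
    }
    sqrt(tau2)
  })
  setNames(out, enhv_rois())
}

# demographics common to both generators
draw_demographics <- function(n, male_fraction, age_range, cfg, prefix) {
  sex <- rbinom(n, 1L, male_fraction)
  age <- runif(n, age_range[1], age_range[2])
  mu_f <- cfg$icv_mean - cfg$male_fraction * cfg$icv_sex_offset
  icv <- rnorm(n, mean = mu_f + sex * cfg$icv_sex_offset, sd = cfg$sigma_w)
  # truncate extreme tails (~0.1% of draws) so every subject stays anatomically
  # plausible (regional volumes must remain below the ICV)
  icv <- pmin(pmax(icv, cfg$icv_mean - 3.5 * cfg$icv_sd),
              cfg$icv_mean + 3.5 * cfg$icv_sd)
  tibble::tibble(
    subject_id = sprintf("%s%04d", prefix, seq_len(n)),
    age = age, sex = as.integer(sex), icv = icv
  )
}

#' Generate a synthetic healthy cohort
#'
#' Draws sex, age (uniform), and ICV (normal, sex-specific mean) per subject,
#' then generates each ROI volume from the configured true equations plus an
#' independent Gaussian residual whose SD is calibrated so the pooled
#' ICV-volume correlations match the configured targets. Volumes are clipped
#' to stay positive. Byte-identical output for a fixed seed.
#'
#' @param config A [generator_config()].
#' @param n Cohort size (default `config$n_healthy`).
#' @param seed Seed (default `config$seed`).
#' @param id_prefix Prefix of generated subject identifiers.
#' @return A validated cohort tibble with `group_label = "healthy"`.
#' @export
generate_healthy_cohort <- function(config = generator_config(),
                                    n = config$n_healthy,
                                    seed = config$seed,
                                    id_prefix = "HC") {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(seed, {
    demo <- draw_demographics(n, config$male_fraction, config$age_range,
                              config, id_prefix)
    for (roi in enhv_rois()) {
      mu <- predict_enhv(config$true_model, roi, icv = demo$icv,
                         age = demo$age, sex = demo$sex)
      v <- mu + rnorm(n, 0, config$residual_sd[[roi]])
      demo[[roi]] <- pmin(pmax(v, 1), 0.98 * demo$icv)
    }
    demo$group_label <- "healthy"
    validate_cohort(demo)
  })
}

#' Generate a synthetic DAI-like patient cohort
#'
#' Draws demographics as for healthy subjects (patient-specific sex fraction
#' and age range), PTA duration in integer weeks from a discretized truncated
#' log-normal, and time since injury log-uniformly. Each ROI's ENHV-adjusted
#' volume target is then drawn as
#' `mean + r * sd * z(PTA) + noise`, where `z(PTA)` is the sample-standardized
#' PTA and the noise SD is `sd * sqrt(1 - r^2)`, so the PTA-adjusted-volume
#' correlation targets the configured `pta_effect_r`. Finally the measured
#' volume is set to `adjusted/100` times the ENHV predicted by `model`.
#'
#' @param config A [generator_config()].
#' @param model `enhv_model` used to turn adjusted-volume targets into
#'   measured volumes (default [published_model()]).
#' @param n Cohort size (default `config$n_dai`).
#' @param seed Seed (default `config$seed`).
#' @param id_prefix Prefix of generated subject identifiers.
#' @return A validated cohort tibble with `group_label = "dai"`, `pta_weeks`,
#'   and `time_since_injury_months`.
#' @export
generate_dai_cohort <- function(config = generator_config(),
                                model = published_model(),
                                n = config$n_dai,
                                seed = config$seed,
                                id_prefix = "DAI") {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(seed, {
    demo <- draw_demographics(n, config$dai_male_fraction,
                              config$dai_age_range, config, id_prefix)
    pta <- round(exp(rnorm(n, log(config$pta_median), config$pta_sdlog)))
    pta <- as.integer(pmin(pmax(pta, config$pta_range[1]),
                           config$pta_range[2]))
    tsi <- exp(runif(n, log(config$tsi_range[1]), log(config$tsi_range[2])))
    z <- if (sd(pta) > 0) (pta - mean(pta)) / sd(pta) else rep(0, n)
    for (roi in enhv_rois()) {
      r <- config$pta_effect_r[[roi]]
      s <- config$dai_adjusted_sd[[roi]]
      adj <- config$dai_adjusted_mean[[roi]] + r * s * z +
        rnorm(n, 0, s * sqrt(1 - r^2))
      adj <- pmax(adj, 1)
      enhv <- predict_enhv(model, roi, icv = demo$icv, age = demo$age,
                           sex = demo$sex)
      demo[[roi]] <- adj / 100 * enhv
    }
    demo$pta_weeks <- pta
    demo$time_since_injury_months <- tsi
    demo$group_label <- "dai"
    validate_cohort(demo)
  })
}

#' Split a cohort into two groups with the permuted block method
#'
#' Age-controlled random split at an `a:b` ratio: subjects are sorted by age,
#' consecutive blocks of `a + b` subjects are formed, and within each block a
#' random permutation of the block's `a` A-roles and `b` B-roles assigns
#' members to the groups. A final short block of r subjects samples r of the
#' full block's roles without replacement, so group sizes deviate from the
#' exact ratio by at most the remainder block. Sorting by age is what makes
#' the groups age-matched; set `age_controlled = FALSE` for an unstratified
#' permuted-block split.
#'
#' @param data A cohort table.
#' @param ratio Integer pair, default `c(4, 1)`.
#' @param age_controlled Sort by age before blocking? (default `TRUE`).
#' @param seed Optional seed for the within-block permutations.
#' @return A list with elements `a` and `b` (cohort tibbles).
#' @export
split_permuted_block <- function(data, ratio = c(4, 1), age_controlled = TRUE,
                                 seed = NULL) {
  data <- validate_cohort(data)
  block <- sum(ratio)
  if (nrow(data) < block) {
    abort(sprintf("Cohort must have at least %d subjects for a %d:%d split.",
                  block, ratio[1], ratio[2]),
          class = "enhv_validation_error")
  }
  run <- function() {
    ord <- if (age_controlled) order(data$age) else sample.int(nrow(data))
    roles <- rep(c("a", "b"), times = ratio)
    assign <- character(nrow(data))
    i <- 1
    while (i <= nrow(data)) {
      take <- min(block, nrow(data) - i + 1)
      assign[ord[i:(i + take - 1)]] <- sample(roles, take)
      i <- i + take
    }
    list(a = data[assign == "a", ], b = data[assign == "b", ])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Select sex-matched controls by random-number ranking
#'
#' Assigns each subject in the pool an independent uniform random number on
#' (0, 1) and keeps the `n_male` males and `n_female` females with the
#' highest numbers.
#'
#' @param data Pool of healthy subjects.
#' @param n_male,n_female Requested counts per sex.
#' @param seed Optional seed.
#' @return A cohort tibble with exactly `n_male + n_female` rows.
#' @export
select_matched_controls <- function(data, n_male, n_female, seed = NULL) {
  data <- validate_cohort(data)
  if (sum(data$sex == 1) < n_male || sum(data$sex == 0) < n_female) {
    abort(sprintf("Pool (%d M / %d F) cannot supply %d M / %d F.",
                  sum(data$sex == 1), sum(data$sex == 0), n_male, n_female),
          class = "enhv_validation_error")
  }
  run <- function() {
    u <- runif(nrow(data))
    keep_m <- which(data$sex == 1)[order(u[data$sex == 1],
                                         decreasing = TRUE)][seq_len(n_male)]
    keep_f <- which(data$sex == 0)[order(u[data$sex == 0],
                                         decreasing = TRUE)][seq_len(n_female)]
    data[sort(c(keep_m, keep_f)), ]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

full_precision <- function(x) {
  format(x, digits = 17, scientific = FALSE, trim = TRUE)
}

#' Write FreeSurfer-format fixture files for one subject
#'
#' Writes a syntactically valid `aseg.stats` (summary `# Measure` lines plus a
#' token segmentation table) and `brainstemSsVolumes.v10.txt` under
#' `directory/<subject_id>/`, such that the package's readers round-trip the
#' subject's parse-level volumes exactly. Cohort tables carry only the
#' composed cerebrum, so it is decomposed into synthetic tissue components
#' (50% cortical gray, 44% cerebral white, remainder subcortical gray — the
#' three always sum back to the stored cerebrum exactly); likewise a synthetic
#' superior cerebellar peduncle of 2% of the whole brainstem is written, which
#' keeps it under the 3% share below which it is excluded from analysis.
#'
#' @param subject A one-row cohort tibble.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the paths of the two files written.
#' @export
write_fixture_subject <- function(subject, directory) {
  subject <- validate_cohort(subject)
  if (nrow(subject) != 1) {
    abort("write_fixture_subject expects exactly one subject.",
          class = "enhv_validation_error")
  }
  sub_dir <- file.path(directory, subject$subject_id)
  dir.create(sub_dir, recursive = TRUE, showWarnings = FALSE)

  cort <- 0.50 * subject$cerebrum
  wm <- 0.44 * subject$cerebrum
  subcort <- subject$cerebrum - cort - wm
  aseg <- c(
    "# Title Segmentation Statistics",
    sprintf("# subjectname %s", subject$subject_id),
    "# synthetic fixture written by the enhv package",
    sprintf("# Measure Cortex, CortexVol, Total cortical gray matter volume, %s, mm^3",
            full_precision(cort)),
    sprintf("# Measure CerebralWhiteMatter, CerebralWhiteMatterVol, Total cerebral white matter volume, %s, mm^3",
            full_precision(wm)),
    sprintf("# Measure SubCortGray, SubCortGrayVol, Subcortical gray matter volume, %s, mm^3",
            full_precision(subcort)),
    sprintf("# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, %s, mm^3",
            full_precision(subject$icv)),
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
    sprintf("  1  16  %d  %s  Brain-Stem",
            round(subject$whole_brainstem),
            full_precision(subject$whole_brainstem))
  )
  aseg_path <- file.path(sub_dir, "aseg.stats")
  writeLines(aseg, aseg_path)

  scp <- 0.02 * subject$whole_brainstem
  bs <- c(
    sprintf("Medulla %s", full_precision(subject$medulla)),
    sprintf("Pons %s", full_precision(subject$pons)),
    sprintf("SCP %s", full_precision(scp)),
    sprintf("Midbrain %s", full_precision(subject$midbrain)),
    sprintf("Whole_brainstem %s", full_precision(subject$whole_brainstem))
  )
  bs_path <- file.path(sub_dir, "brainstemSsVolumes.v10.txt")
  writeLines(bs, bs_path)

  invisible(c(aseg = aseg_path, brainstem = bs_path))
}
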