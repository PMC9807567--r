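#' Analysis regions of interest
#'
#' The five regions the normative model covers: the whole brainstem, its three
#' major subfields (medulla, pons, midbrain), and the cerebrum (cortical gray
#' matter + cerebral white matter + subcortical gray matter). The superior
#' cerebellar peduncle (`"scp"`) is parsed from FreeSurfer output but excluded
#' from analysis because it is a residual-like subfield amounting to less than
#' 3% of the whole brainstem.
#'
#' @return Character vector of the five analysis ROI identifiers.
#' @export
#' @examples
#' enhv_rois()
enhv_rois <- function() {
  c("whole_brainstem", "medulla", "pons", "midbrain", "cerebrum")
}

# raw-parse-only members that may appear in files but are not analysis ROIs
raw_rois <- function() {
  c("cortical_gm", "cerebral_wm", "subcortical_gm", "scp")
}

cohort_required_cols <- function() {
  c("subject_id", "age", "sex", "icv", enhv_rois())
}

cohort_optional_cols <- function() {
  c("pta_weeks", "time_since_injury_months", "group_label")
}

# documented aliases -> canonical column names (cohort CSV dialect)
cohort_col_aliases <- function() {
  c(id = "subject_id", subject = "subject_id",
    etiv = "icv", e_tiv = "icv",
    pta = "pta_weeks",
    tsi_months = "time_since_injury_months", tsi = "time_since_injury_months",
    group = "group_label")
}

#' Normalize sex codes to the model's dummy coding
#'
#' The model codes sex as male = 1, female = 0. Accepted input tokens are
#' `M`, `F`, `male`, `female` (case-insensitive), `0`, and `1`.
#'
#' @param sex Vector of sex codes (character, factor, or numeric).
#' @return Integer vector in `{0, 1}` (`NA` preserved).
#' @export
#' @examples
#' normalize_sex(c("M", "F", "male", 1, 0))
normalize_sex <- function(sex) {
  tok <- tolower(trimws(as.character(sex)))
  out <- dplyr::case_when(
    tok %in% c("m", "male", "1") ~ 1L,
    tok %in% c("f", "female", "0") ~ 0L,
    is.na(tok) ~ NA_integer_,
    TRUE ~ -1L
  )
  bad <- which(out == -1L)
  if (length(bad) > 0) {
    abort(sprintf("Unknown sex token %s at position %d (expected M/F/male/female/0/1).",
                  dQuote(tok[bad[1]]), bad[1]),
          class = "enhv_validation_error")
  }
  out
}

#' Validate a cohort table
#'
#' Checks the invariants of the subject-level data model: positive age and
#' ICV, positive regional volumes strictly below the ICV, sex coded 0/1, and
#' unique subject identifiers. Sex tokens are normalized with
#' [normalize_sex()]. Violations raise a validation error naming the first
#' offending row.
#'
#' @param data A data frame with columns `subject_id`, `age`, `sex`, `icv`,
#'   one column per analysis ROI (see [enhv_rois()]), and optionally
#'   `pta_weeks`, `time_since_injury_months`, `group_label`.
#' @return The validated cohort as a tibble with canonical column order.
#' @export
validate_cohort <- function(data) {
  data <- tibble::as_tibble(data)
  names(data) <- tolower(names(data))
  ali <- cohort_col_aliases()
  hit <- names(data) %in% names(ali)
  names(data)[hit] <- unname(ali[names(data)[hit]])

  missing <- setdiff(cohort_required_cols(), names(data))
  if (length(missing) > 0) {
    abort(paste0("Cohort table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "enhv_validation_error")
  }

  data$subject_id <- as.character(data$subject_id)
  data$sex <- normalize_sex(data$sex)

  dup <- duplicated(data$subject_id)
  if (any(dup)) {
    abort(sprintf("Duplicate subject_id %s at row %d.",
                  dQuote(data$subject_id[which(dup)[1]]), which(dup)[1]),
          class = "enhv_validation_error")
  }

  check_pos <- function(x, what) {
    bad <- which(!is.finite(x) | x <= 0)
    if (length(bad) > 0) {
      abort(sprintf("Non-positive or missing %s at row %d.", what, bad[1]),
            class = "enhv_validation_error")
    }
  }
  check_pos(data$age, "age")
  check_pos(data$icv, "icv")
  for (roi in enhv_rois()) {
    check_pos(data[[roi]], roi)
    over <- which(data[[roi]] >= data$icv)
    if (length(over) > 0) {
      abort(sprintf("%s volume >= icv at row %d.", roi, over[1]),
            class = "enhv_validation_error")
    }
  }
  if ("group_label" %in% names(data)) {
    bad <- which(!is.na(data$group_label) &
                   !data$group_label %in% c("healthy", "dai"))
    if (length(bad) > 0) {
      abort(sprintf("Unknown group_label %s at row %d (expected healthy/dai).",
                    dQuote(as.character(data$group_label[bad[1]])), bad[1]),
            class = "enhv_validation_error")
    }
  }
  keep <- intersect(c(cohort_required_cols(), cohort_optional_cols()), names(data))
  data[, keep]
}

#' Read a cohort table from CSV
#'
#' The exchange format is a UTF-8, comma-separated table with a header row,
#' `.` as the decimal mark, and all volumes in cubic millimetres. Required
#' columns: `subject_id`, `age` (years), `sex` (M/F/male/female/0/1), `icv`,
#' and one column per analysis ROI. Optional: `pta_weeks` (integer weeks),
#' `time_since_injury_months`, `group_label` (`healthy`/`dai`). A few common
#' header aliases (`id`, `etiv`, `pta`, `tsi`, `group`) are accepted and
#' mapped to the canonical names.
#'
#' @param path Path to a CSV file.
#' @return A validated cohort tibble (see [validate_cohort()]).
#' @export
read_cohort <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(data)
}

#' Write a cohort table to CSV
#'
#' Writes the canonical cohort CSV dialect (see [read_cohort()]). Doubles are
#' written with shortest round-trip precision so that
#' `read_cohort(write_cohort(x, p))` reproduces `x` exactly.
#'
#' @param data A cohort table (validated on the way out).
#' @param path Output file path.
#' @return `data`, invisibly.
#' @export
write_cohort <- function(data, path) {
  data <- validate_cohort(data)
  readr::write_csv(data, path)
  invisible(data)
}
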