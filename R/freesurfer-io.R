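# FreeSurfer stats readers.
#
# Both readers consume the text outputs of FreeSurfer's recon-all and
# brainstem-subfield pipelines; they never touch image data. Measure keys are
# matched case-sensitively against FreeSurfer's canonical names.

# canonical `# Measure` keys (either the short or the *Vol key may appear
# first on the line depending on FreeSurfer version)
aseg_measure_keys <- function() {
  list(
    icv = c("EstimatedTotalIntraCranialVol", "eTIV"),
    cortical_gm = c("Cortex", "CortexVol"),
    cerebral_wm = c("CerebralWhiteMatter", "CerebralWhiteMatterVol",
                    "CorticalWhiteMatter", "CorticalWhiteMatterVol"),
    subcortical_gm = c("SubCortGray", "SubCortGrayVol")
  )
}

# split one `# Measure ...` line into fields; accepts the comma-separated
# dialect and arbitrary-whitespace variants
split_measure_line <- function(line) {
  body <- sub("^#\\s*Measure\\s+", "", line)
  if (grepl(",", body, fixed = TRUE)) {
    trimws(strsplit(body, ",", fixed = TRUE)[[1]])
  } else {
    strsplit(trimws(body), "\\s+")[[1]]
  }
}

# numeric value of a measure line: last numeric-looking field before an
# optional unit field
measure_value <- function(fields, lineno, path) {
  num <- suppressWarnings(as.numeric(fields))
  idx <- which(!is.na(num))
  if (length(idx) == 0) {
    abort(sprintf("Non-numeric measure value at line %d of %s.", lineno, path),
          class = "enhv_parse_error")
  }
  num[max(idx)]
}

#' Read ICV and cerebral tissue volumes from a FreeSurfer aseg.stats file
#'
#' Extracts the `# Measure` summary lines for the estimated total intracranial
#' volume (eTIV) and the three cerebral tissue classes — total cortical gray
#' matter, cerebral white matter, and subcortical gray matter — and composes
#' the cerebrum as their sum. The segmentation table body of the file is
#' ignored: the cerebrum is deliberately built from the summary measures, not
#' from a sum over segmentation rows.
#'
#' @param path Path to an `aseg.stats` file.
#' @return A one-row tibble with columns `icv`, `cortical_gm`, `cerebral_wm`,
#'   `subcortical_gm`, and `cerebrum` (all mm^3).
#' @export
read_aseg_stats <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_measure <- grepl("^#\\s*Measure\\s", lines)
  found <- list()
  for (i in which(is_measure)) {
    fields <- split_measure_line(lines[i])
    for (key in names(aseg_measure_keys())) {
      if (any(fields[seq_len(min(2, length(fields)))] %in% aseg_measure_keys()[[key]])) {
        found[[key]] <- measure_value(fields, i, path)
      }
    }
  }
  labels <- c(icv = "EstimatedTotalIntraCranialVol", cortical_gm = "CortexVol",
              cerebral_wm = "CerebralWhiteMatterVol", subcortical_gm = "SubCortGrayVol")
  for (key in names(labels)) {
    if (is.null(found[[key]])) {
      abort(sprintf("Measure %s not found in %s.", dQuote(labels[[key]]), path),
            class = "enhv_parse_error")
    }
  }
  tibble::tibble(
    icv = found$icv,
    cortical_gm = found$cortical_gm,
    cerebral_wm = found$cerebral_wm,
    subcortical_gm = found$subcortical_gm,
    cerebrum = compose_cerebrum(found$cortical_gm, found$cerebral_wm,
                                found$subcortical_gm)
  )
}

#' Read brainstem subfield volumes from a FreeSurfer output file
#'
#' Parses the two-column `brainstemSsVolumes.v10.txt` format (structure name,
#' volume in mm^3) produced by the FreeSurfer brainstem-subfield pipeline.
#' The superior cerebellar peduncle (`scp`) is returned for completeness but
#' is not an analysis ROI (see [enhv_rois()]).
#'
#' @param path Path to a `brainstemSsVolumes.v10.txt` file.
#' @return A one-row tibble with columns `medulla`, `pons`, `midbrain`,
#'   `scp`, `whole_brainstem` (mm^3), plus `scp_excluded = TRUE` flagging
#'   that `scp` is excluded from analysis.
#' @export
read_brainstem_volumes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  name_map <- c(Medulla = "medulla", Pons = "pons", Midbrain = "midbrain",
                SCP = "scp", Whole_brainstem = "whole_brainstem")
  out <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2 || !f[1] %in% names(name_map)) next
    val <- suppressWarnings(as.numeric(f[2]))
    if (is.na(val)) {
      abort(sprintf("Non-numeric volume for %s at line %d of %s.",
                    f[1], i, path),
            class = "enhv_parse_error")
    }
    out[[name_map[[f[1]]]]] <- val
  }
  for (key in unname(name_map)) {
    if (is.null(out[[key]])) {
      abort(sprintf("Structure %s not found in %s.",
                    dQuote(names(name_map)[name_map == key]), path),
            class = "enhv_parse_error")
    }
  }
  tibble::tibble(medulla = out$medulla, pons = out$pons,
                 midbrain = out$midbrain, scp = out$scp,
                 whole_brainstem = out$whole_brainstem, scp_excluded = TRUE)
}

#' Compose the cerebrum volume from its three tissue classes
#'
#' The cerebrum is defined as the sum of total cortical gray matter, cerebral
#' white matter, and subcortical gray matter, i.e. the continuous supratentorial
#' tissue volume including deep gray structures but excluding the cerebellum
#' and brainstem.
#'
#' @param cortical_gm,cerebral_wm,subcortical_gm Tissue volumes in mm^3
#'   (vectors recycle; all must be strictly positive).
#' @return Cerebrum volume in mm^3.
#' @export
#' @examples
#' compose_cerebrum(500000, 450000, 60000)
compose_cerebrum <- function(cortical_gm, cerebral_wm, subcortical_gm) {
  for (x in list(cortical_gm, cerebral_wm, subcortical_gm)) {
    if (any(!is.finite(x) | x <= 0)) {
      abort("All cerebrum components must be positive and finite.",
            class = "enhv_validation_error")
    }
  }
  cortical_gm + cerebral_wm + subcortical_gm
}

#' Collect per-subject FreeSurfer stats files into one cohort table
#'
#' Walks a subjects directory in which every subdirectory holds one subject's
#' `aseg.stats` and `brainstemSsVolumes.v10.txt` (searched recursively within
#' the subject's folder), and assembles the morphometry columns of a cohort
#' table. Demographics (age, sex) are not present in FreeSurfer stats files
#' and must be supplied via `demographics` before the result passes cohort
#' validation.
#'
#' @param subjects_dir Directory with one subdirectory per subject.
#' @param demographics Optional data frame with `subject_id`, `age`, `sex`
#'   (and any optional cohort columns) to join onto the parsed volumes.
#' @return A tibble with one row per subject; validated when demographics are
#'   supplied, raw otherwise.
#' @export
collect_subjects <- function(subjects_dir, demographics = NULL) {
  subs <- list.dirs(subjects_dir, recursive = FALSE)
  if (length(subs) == 0) {
    abort(sprintf("No subject subdirectories found in %s.", subjects_dir),
          class = "enhv_parse_error")
  }
  rows <- purrr::map(subs, function(d) {
    aseg <- list.files(d, pattern = "^aseg\\.stats$", recursive = TRUE,
                       full.names = TRUE)
    bs <- list.files(d, pattern = "^brainstemSsVolumes", recursive = TRUE,
                     full.names = TRUE)
    if (length(aseg) == 0 || length(bs) == 0) {
      abort(sprintf("Subject folder %s is missing aseg.stats or brainstemSsVolumes files.", d),
            class = "enhv_parse_error")
    }
    dplyr::bind_cols(
      tibble::tibble(subject_id = basename(d)),
      read_aseg_stats(aseg[1]),
      read_brainstem_volumes(bs[1])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(demographics)) {
    out <- dplyr::inner_join(out, tibble::as_tibble(demographics),
                             by = "subject_id")
    out <- validate_cohort(out)
  }
  out
}
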