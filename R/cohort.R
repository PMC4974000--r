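# Cohort ingestion, validation and eligibility filtering.

# Canonical eye-level column set. `eye` and many clinical fields are optional
# on ingest; the three identity columns are mandatory.
EYE_COLUMNS <- c(
  "subject_id", "eye", "group", "age", "sex", "bcva_logmar", "iop",
  "spherical_equivalent", "cylinder", "axial_length", "md", "psd", "vfi",
  "disc_area_measured", "disc_area_corrected", "rnfl_avg", "gcipl_avg",
  "gcipl_min", "signal_strength_macula", "signal_strength_disc",
  "vf_fixation_loss", "vf_false_positive"
)
MANDATORY_COLUMNS <- c("subject_id", "group")
NUMERIC_COLUMNS <- setdiff(EYE_COLUMNS, c("subject_id", "eye", "group", "sex"))

#' Read an eye-level cohort table
#'
#' Reads a delimited text file with one row per eye, optionally renaming
#' source columns to the canonical names via `schema`, coerces measurement
#' columns to numeric, and validates range invariants (visual field index in
#' \[0, 100\], signal strengths in \[0, 10\], axial length > 1.82 mm,
#' thicknesses strictly positive). Unparseable or out-of-range cells raise an
#' error naming the row and field rather than being dropped.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Optional column mapping: either a named character vector
#'   mapping canonical column names to the names used in the file, e.g.
#'   `c(vfi = "VFI_percent")`, or the path of a JSON/YAML file holding the
#'   same key-value mapping.
#' @param delim Field delimiter, comma by default.
#' @return A tibble with canonical column names, one row per eye.
#' @export
read_cohort <- function(path, schema = NULL, delim = ",") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.character(schema) && length(schema) == 1L && is.null(names(schema))) {
    schema <- read_schema_file(schema)
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0L) abort("cohort file is empty")
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src)) {
      abort(paste0("schema maps absent column(s): ",
                   paste(missing_src, collapse = ", ")))
    }
    raw <- dplyr::rename(raw, !!!rlang::set_names(unname(schema), names(schema)))
  }
  missing <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing)) {
    abort(paste0("mandatory column(s) missing: ", paste(missing, collapse = ", ")))
  }
  cohort <- dplyr::select(raw, dplyr::any_of(EYE_COLUMNS))
  for (col in intersect(NUMERIC_COLUMNS, names(cohort))) {
    parsed <- suppressWarnings(as.numeric(cohort[[col]]))
    bad <- which(!is.na(cohort[[col]]) & is.na(parsed))
    if (length(bad)) {
      abort(paste0("column '", col, "' has unparseable value(s) in row(s) ",
                   paste(head(bad, 5L), collapse = ", ")))
    }
    cohort[[col]] <- parsed
  }
  cohort$group <- tolower(cohort$group)
  bad_group <- which(!cohort$group %in% c("glaucoma", "control"))
  if (length(bad_group)) {
    abort(paste0("column 'group' must be glaucoma/control; bad row(s) ",
                 paste(head(bad_group, 5L), collapse = ", ")))
  }
  validate_cohort(cohort)
  cohort
}

# key:value column mapping from a JSON or YAML sidecar file
read_schema_file <- function(path) {
  if (!file.exists(path)) abort(paste0("schema file not found: ", path))
  mapping <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading a YAML schema requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vapply(mapping, as.character, character(1))
}

#' Validate cohort range invariants
#'
#' Checks the range invariants of the eye-level record (VFI in \[0, 100\],
#' signal strengths integers in \[0, 10\], axial length > 1.82 mm, thickness
#' fields strictly positive, reliability indices in \[0, 100\]) and errors
#' with the offending rows and fields.
#'
#' @param cohort A cohort tibble.
#' @return `cohort`, invisibly, if all checks pass.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  checks <- list(
    vfi = function(x) x >= 0 & x <= 100,
    signal_strength_macula = function(x) x >= 0 & x <= 10,
    signal_strength_disc = function(x) x >= 0 & x <= 10,
    axial_length = function(x) x > 1.82,
    rnfl_avg = function(x) x > 0,
    gcipl_avg = function(x) x > 0,
    gcipl_min = function(x) x > 0,
    vf_fixation_loss = function(x) x >= 0 & x <= 100,
    vf_false_positive = function(x) x >= 0 & x <= 100
  )
  problems <- character(0)
  for (col in intersect(names(checks), names(cohort))) {
    ok <- checks[[col]](cohort[[col]])
    bad <- which(!is.na(cohort[[col]]) & !ok)
    if (length(bad)) {
      problems <- c(problems, paste0(col, " out of range in row(s) ",
                                     paste(head(bad, 5L), collapse = ", ")))
    }
  }
  dup <- duplicated(paste(cohort$subject_id,
                          if ("eye" %in% names(cohort)) cohort$eye else ""))
  if (any(dup)) {
    problems <- c(problems, paste0("duplicate subject_id/eye in row(s) ",
                                   paste(head(which(dup), 5L), collapse = ", ")))
  }
  if (length(problems)) {
    abort(paste0("cohort validation failed:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  invisible(cohort)
}

#' Eligibility thresholds for cohort exclusion
#'
#' Default thresholds mirror the study eligibility screen: best-corrected
#' visual acuity worse than 20/40 (logMAR > 0.30), intraocular pressure
#' exceeding 21 mmHg, cylinder correction outside \[-3, +3\] D, and any OCT
#' signal strength below 6. Boundaries are excluded per the stated wording:
#' an IOP of exactly 21 is retained, a signal strength of exactly 6 is
#' retained.
#'
#' @param bcva_logmar_max Maximum acceptable logMAR acuity (default 0.30,
#'   i.e. 20/40); exclusion is strict with a 1e-9 tolerance so 0.30 itself
#'   is retained.
#' @param iop_max Maximum acceptable IOP in mmHg (default 21; strict
#'   "exceeding" rule).
#' @param cylinder_range Acceptable cylinder interval in diopters.
#' @param min_signal_strength Minimum acceptable OCT signal strength (0-10).
#' @return A named list of thresholds of class `exclusion_criteria`.
#' @export
exclusion_criteria <- function(bcva_logmar_max = 0.30, iop_max = 21,
                               cylinder_range = c(-3, 3),
                               min_signal_strength = 6) {
  stopifnot(length(cylinder_range) == 2L, cylinder_range[1] <= cylinder_range[2])
  structure(
    list(bcva_logmar_max = bcva_logmar_max, iop_max = iop_max,
         cylinder_range = cylinder_range,
         min_signal_strength = min_signal_strength),
    class = "exclusion_criteria"
  )
}

#' Apply eligibility exclusions to a cohort
#'
#' Removes records violating the eligibility thresholds and accounts for
#' every removal in an exclusion report. Missing optional fields never
#' trigger exclusion; they raise a logged warning instead. Record order is
#' preserved, and the operation is idempotent.
#'
#' @param cohort A cohort tibble.
#' @param criteria An [exclusion_criteria()] list.
#' @return A list with elements `cohort` (retained rows), `report` (one row
#'   per violated rule: subject_id, eye, rule), and `counts` (removals per
#'   rule).
#' @export
apply_exclusions <- function(cohort, criteria = exclusion_criteria()) {
  stopifnot(is.data.frame(cohort), inherits(criteria, "exclusion_criteria"))
  n <- nrow(cohort)
  get_col <- function(col) {
    if (col %in% names(cohort)) cohort[[col]] else rep(NA_real_, n)
  }
  rules <- list(
    "visual acuity < 20/40" = get_col("bcva_logmar") >
      criteria$bcva_logmar_max + 1e-9,
    "IOP exceeding threshold" = get_col("iop") > criteria$iop_max,
    "cylinder outside range" = get_col("cylinder") < criteria$cylinder_range[1] |
      get_col("cylinder") > criteria$cylinder_range[2],
    "signal strength < 6" = get_col("signal_strength_macula") <
      criteria$min_signal_strength |
      get_col("signal_strength_disc") < criteria$min_signal_strength
  )
  fields <- list(
    "visual acuity < 20/40" = "bcva_logmar",
    "IOP exceeding threshold" = "iop",
    "cylinder outside range" = "cylinder",
    "signal strength < 6" = c("signal_strength_macula", "signal_strength_disc")
  )
  missing_fields <- unique(unlist(fields))[!unique(unlist(fields)) %in%
                                             names(cohort)]
  na_any <- Reduce(`|`, lapply(unlist(fields)[unlist(fields) %in% names(cohort)],
                               function(f) is.na(cohort[[f]])), rep(FALSE, n))
  if (length(missing_fields) || any(na_any)) {
    warn(paste0("missing eligibility field(s) treated as pass: ",
                paste(c(missing_fields,
                        if (any(na_any)) paste0(sum(na_any), " record(s) with NA")),
                      collapse = ", ")))
  }
  eye <- if ("eye" %in% names(cohort)) cohort$eye else rep(NA_character_, n)
  report <- purrr::imap_dfr(rules, function(flag, rule) {
    hit <- which(!is.na(flag) & flag)
    tibble::tibble(subject_id = cohort$subject_id[hit], eye = eye[hit],
                   rule = rep(rule, length(hit)))
  })
  excluded_idx <- sort(unique(unlist(lapply(rules, function(f) which(!is.na(f) & f)))))
  retained <- cohort[setdiff(seq_len(n), excluded_idx), , drop = FALSE]
  if (nrow(retained) == 0L && n > 0L) warn("no records retained after exclusions")
  counts <- if (nrow(report)) dplyr::count(report, .data$rule, name = "n") else
    tibble::tibble(rule = character(0), n = integer(0))
  list(cohort = retained, report = report, counts = counts)
}

#' Keep one eye per subject at random
#'
#' When both eyes of a subject are eligible, exactly one is chosen at
#' random; subjects contributing a single eye keep it regardless of the
#' seed. The selection is a pure function of the cohort and the seed, and
#' record order is preserved.
#'
#' @param cohort A cohort tibble.
#' @param seed Integer seed controlling the random choice.
#' @return A cohort tibble with at most one row per subject.
#' @export
select_one_eye <- function(cohort, seed) {
  stopifnot(is.data.frame(cohort))
  check_number(seed, "seed")
  keep <- with_seed(seed, {
    idx_by_subject <- split(seq_len(nrow(cohort)), cohort$subject_id)
    # iterate in first-appearance order for reproducibility
    ord <- idx_by_subject[unique(cohort$subject_id)]
    vapply(ord, function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }, integer(1))
  })
  cohort[sort(unname(keep)), , drop = FALSE]
}

#' Write a cohort back to delimited text
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  readr::write_delim(cohort, path, delim = delim)
  invisible(path)
}
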