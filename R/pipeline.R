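# End-to-end orchestration: ingest -> exclusions -> one eye per subject ->
# magnification correction -> characteristics table -> per-marker ROC
# regression -> AUC grids and ROC curve exports.

#' Reference ROC regression coefficients
#'
#' The packaged reference coefficient table for the three OCT markers
#' (average RNFL, average GCIPL, minimum GCIPL), each fitted with the five
#' covariates VFI, age, spherical equivalent, axial length and corrected
#' optic disc area. The average-RNFL age coefficient is stored with a
#' negative sign consistent with its confidence interval (-0.0311, -0.0009)
#' and flagged `sign_corrected`, since only the negative value is
#' consistent with the AUC grids the coefficients imply.
#'
#' @return A tibble with columns `marker`, `term`, `estimate`, `ci_lower`,
#'   `ci_upper`, `p_value`, `sign_corrected`.
#' @export
reference_coefficients <- function() {
  path <- system.file("extdata", "reference_coefficients.csv",
                      package = "octroc", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    estimate = "d", ci_lower = "d", ci_upper = "d",
                    sign_corrected = "l", .default = "c"
                  ))
}

#' Reference coefficients for one marker as a named vector
#'
#' @param marker One of `"rnfl_avg"`, `"gcipl_avg"`, `"gcipl_min"`.
#' @return Named numeric vector with `(Intercept)`, `probit_fpr` and the
#'   five covariate coefficients, directly usable by [roc_at()] and
#'   [roc_auc()].
#' @export
reference_coefficient_vector <- function(marker) {
  tab <- reference_coefficients()
  rows <- tab[tab$marker == marker, , drop = FALSE]
  if (nrow(rows) == 0L) {
    abort(paste0("unknown marker '", marker, "'; available: ",
                 paste(unique(tab$marker), collapse = ", ")))
  }
  rlang::set_names(rows$estimate, rows$term)
}

#' Baseline covariate profile for AUC evaluation
#'
#' The fixed profile at which covariate-specific accuracy is summarised:
#' age 55 years, spherical equivalent -2.15 D, axial length 24.5 mm,
#' corrected optic disc area 2 mm^2, and VFI 100% by default (VFI 92% is
#' the convention when axial length or disc area is varied instead).
#'
#' @param vfi,age,spherical_equivalent,axial_length,disc_area_corrected
#'   Profile values.
#' @return A one-row tibble.
#' @export
baseline_profile <- function(vfi = 100, age = 55, spherical_equivalent = -2.15,
                             axial_length = 24.5, disc_area_corrected = 2) {
  tibble::tibble(vfi = vfi, age = age,
                 spherical_equivalent = spherical_equivalent,
                 axial_length = axial_length,
                 disc_area_corrected = disc_area_corrected)
}

#' Desk-scale AUC grids from reference coefficients
#'
#' Evaluates the closed-form covariate-specific AUROC over the standard
#' profile grids without any fitting: AUROC by disease severity (VFI 100,
#' 90, 80, 70 at the baseline profile) for all three markers; AUROC by
#' axial length (23.0, 24.5, 26.0 mm at VFI 92%) for average RNFL and
#' average GCIPL; and AUROC by corrected disc area (1.5, 2.0, 2.5 mm^2 at
#' VFI 92%) for average RNFL.
#'
#' @param coefficients A coefficient table in the layout of
#'   [reference_coefficients()].
#' @param vfi_grid,al_grid,coda_grid Profile grids.
#' @return A list of tibbles: `auc_by_vfi`, `auc_by_axial_length`,
#'   `auc_by_disc_area`.
#' @export
reproduce_reference_tables <- function(coefficients = reference_coefficients(),
                                       vfi_grid = c(100, 90, 80, 70),
                                       al_grid = c(23.0, 24.5, 26.0),
                                       coda_grid = c(1.5, 2.0, 2.5)) {
  coef_vec <- function(marker) {
    rows <- coefficients[coefficients$marker == marker, , drop = FALSE]
    rlang::set_names(rows$estimate, rows$term)
  }
  markers <- unique(coefficients$marker)
  auc_by_vfi <- purrr::map_dfr(markers, function(mk) {
    profs <- baseline_profile(vfi = vfi_grid)
    out <- auc_profile_table(coef_vec(mk), profs)
    out$marker <- mk
    out
  })
  al_markers <- intersect(c("rnfl_avg", "gcipl_avg"), markers)
  auc_by_axial_length <- purrr::map_dfr(al_markers, function(mk) {
    profs <- baseline_profile(vfi = 92, axial_length = al_grid)
    out <- auc_profile_table(coef_vec(mk), profs)
    out$marker <- mk
    out
  })
  auc_by_disc_area <- purrr::map_dfr(intersect("rnfl_avg", markers),
                                     function(mk) {
    profs <- baseline_profile(vfi = 92, disc_area_corrected = coda_grid)
    out <- auc_profile_table(coef_vec(mk), profs)
    out$marker <- mk
    out
  })
  list(auc_by_vfi = auc_by_vfi,
       auc_by_axial_length = auc_by_axial_length,
       auc_by_disc_area = auc_by_disc_area)
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Supply either `input`
#' (path to a delimited cohort file) or `truth` (a [synthetic_truth()]) as
#' the data source.
#'
#' @param input Optional path to a cohort file.
#' @param truth Optional [synthetic_truth()] for a synthetic run.
#' @param schema Column mapping passed to [read_cohort()].
#' @param exclusions An [exclusion_criteria()] list.
#' @param markers Tibble with columns `marker`, `direction`.
#' @param covariates Covariate names entering every marker model.
#' @param grid_size FPR grid size.
#' @param bootstrap_B Bootstrap replicates per marker (0 disables).
#' @param seed Master seed; stage substreams fan out from it.
#' @param output_dir Optional directory to write the bundle to.
#' @param vfi_grid,al_grid,coda_grid AUC profile grids.
#' @param dists Covariate distributions for synthetic runs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, truth = NULL, schema = NULL,
                            exclusions = exclusion_criteria(),
                            markers = tibble::tibble(
                              marker = c("rnfl_avg", "gcipl_avg", "gcipl_min"),
                              direction = "lower_is_diseased"
                            ),
                            covariates = c("vfi", "age", "spherical_equivalent",
                                           "axial_length",
                                           "disc_area_corrected"),
                            grid_size = 100, bootstrap_B = 0, seed = 1,
                            output_dir = NULL,
                            vfi_grid = c(100, 90, 80, 70),
                            al_grid = c(23.0, 24.5, 26.0),
                            coda_grid = c(1.5, 2.0, 2.5),
                            dists = covariate_distributions()) {
  if (is.null(input) == is.null(truth)) {
    abort("supply exactly one of `input` (file) or `truth` (synthetic)")
  }
  stopifnot(is.data.frame(markers),
            all(c("marker", "direction") %in% names(markers)))
  bad_dir <- setdiff(markers$direction,
                     c("lower_is_diseased", "higher_is_diseased"))
  if (length(bad_dir)) {
    abort(paste0("unknown marker direction: ", paste(bad_dir, collapse = ", ")))
  }
  check_number(grid_size, "grid_size", lower = 2)
  check_number(seed, "seed")
  structure(
    list(input = input, truth = truth, schema = schema,
         exclusions = exclusions, markers = markers, covariates = covariates,
         grid_size = grid_size, bootstrap_B = bootstrap_B, seed = seed,
         output_dir = output_dir, vfi_grid = vfi_grid, al_grid = al_grid,
         coda_grid = coda_grid, dists = dists),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Ingests or generates the cohort, applies the eligibility exclusions,
#' keeps one eye per subject, adds the magnification-corrected disc area,
#' builds the group-characteristics table, fits the covariate-adjusted ROC
#' regression per marker (with optional bootstrap inference), and evaluates
#' the AUC profile grids and ROC curve point sets. Deterministic for a
#' fixed config and seed. If `output_dir` is set, the bundle is also
#' written as delimited text plus a JSON manifest.
#'
#' @param config A [pipeline_config()].
#' @return A list (the output bundle): `cohort`, `exclusion_report`,
#'   `table_one`, `fits` (named list of `roc_glm`), `coefficients` (tidy
#'   table across markers), `auc_by_vfi`, `auc_by_axial_length`,
#'   `auc_by_disc_area`, `roc_points`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  if (is.null(config$input)) {
    unknown <- setdiff(config$markers$marker,
                       c("rnfl_avg", "gcipl_avg", "gcipl_min"))
    if (length(unknown)) {
      abort(paste0("unknown marker(s) for a synthetic run: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  cohort0 <- stage("ingest", {
    if (!is.null(config$input)) {
      read_cohort(config$input, schema = config$schema)
    } else {
      generate_cohort(config$truth, config$dists,
                      seed = substream_seed(config$seed, "simulation"))
    }
  })
  if (length(setdiff(config$markers$marker, names(cohort0)))) {
    abort(paste0("marker column(s) absent from cohort: ",
                 paste(setdiff(config$markers$marker, names(cohort0)),
                       collapse = ", ")))
  }
  excl <- stage("exclusions", apply_exclusions(cohort0, config$exclusions))
  cohort <- stage("eye_selection",
                  select_one_eye(excl$cohort,
                                 substream_seed(config$seed, "eye_selection")))
  cohort <- stage("magnification", add_corrected_disc_area(cohort))
  tab1 <- stage("table_one", table_one(cohort))
  fits <- stage("roc_glm", {
    fits <- purrr::pmap(config$markers, function(marker, direction, ...) {
      fit <- roc_glm(cohort, marker, covariates = config$covariates,
                     direction = direction,
                     grid = fpr_grid(config$grid_size))
      if (config$bootstrap_B > 0) {
        fit <- roc_glm_boot(fit, B = config$bootstrap_B,
                            seed = substream_seed(config$seed, "bootstrap"))
      }
      fit
    })
    rlang::set_names(fits, config$markers$marker)
  })
  coef_tab <- purrr::imap_dfr(fits, function(f, mk) {
    out <- tidy(f)
    out$marker <- mk
    out
  })
  to_model_profile <- function(profs) {
    profs[, intersect(names(profs), config$covariates), drop = FALSE]
  }
  grids <- stage("auc_grids", {
    vfi_tab <- purrr::imap_dfr(fits, function(f, mk) {
      profs <- baseline_profile(vfi = config$vfi_grid)
      out <- auc_profile_table(f, to_model_profile(profs))
      dplyr::bind_cols(profs, auc = out$auc, marker = mk)
    })
    al_tab <- purrr::imap_dfr(fits[intersect(c("rnfl_avg", "gcipl_avg"),
                                             names(fits))], function(f, mk) {
      profs <- baseline_profile(vfi = 92, axial_length = config$al_grid)
      out <- auc_profile_table(f, to_model_profile(profs))
      dplyr::bind_cols(profs, auc = out$auc, marker = mk)
    })
    coda_tab <- purrr::imap_dfr(fits[intersect("rnfl_avg", names(fits))],
                                function(f, mk) {
      profs <- baseline_profile(vfi = 92, disc_area_corrected = config$coda_grid)
      out <- auc_profile_table(f, to_model_profile(profs))
      dplyr::bind_cols(profs, auc = out$auc, marker = mk)
    })
    list(vfi = vfi_tab, al = al_tab, coda = coda_tab)
  })
  roc_points <- purrr::imap_dfr(fits, function(f, mk) {
    profs <- to_model_profile(baseline_profile(vfi = config$vfi_grid))
    profs$label <- paste0("VFI ", config$vfi_grid)
    out <- roc_curve_points(f, profs)
    out$marker <- mk
    out
  })
  manifest <- list(
    seed = config$seed,
    source = if (is.null(config$input)) "synthetic" else config$input,
    n_input = nrow(cohort0),
    n_excluded = nrow(cohort0) - nrow(excl$cohort),
    n_analysis = nrow(cohort),
    markers = config$markers$marker,
    covariates = config$covariates,
    grid_size = config$grid_size,
    bootstrap_B = config$bootstrap_B,
    warnings = c(
      if (any(!vapply(fits, `[[`, TRUE, "converged"))) "non-convergent fit",
      if (any(vapply(fits, `[[`, TRUE, "separation"))) "quasi-separation"
    ),
    package_version = as.character(utils::packageVersion("octroc"))
  )
  bundle <- list(cohort = cohort, exclusion_report = excl$report,
                 table_one = tab1, fits = fits, coefficients = coef_tab,
                 auc_by_vfi = grids$vfi, auc_by_axial_length = grids$al,
                 auc_by_disc_area = grids$coda, roc_points = roc_points,
                 manifest = manifest)
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$cohort, file.path(dir, "cohort_analysis.csv"))
  readr::write_csv(bundle$exclusion_report, file.path(dir, "exclusions.csv"))
  readr::write_csv(bundle$table_one, file.path(dir, "table_one.csv"))
  readr::write_csv(bundle$coefficients, file.path(dir, "coefficients.csv"))
  readr::write_csv(bundle$auc_by_vfi, file.path(dir, "auc_by_vfi.csv"))
  readr::write_csv(bundle$auc_by_axial_length,
                   file.path(dir, "auc_by_axial_length.csv"))
  readr::write_csv(bundle$auc_by_disc_area,
                   file.path(dir, "auc_by_disc_area.csv"))
  readr::write_csv(bundle$roc_points, file.path(dir, "roc_points.csv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
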