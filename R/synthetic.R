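# Synthetic case-control cohort generator. The marker model is constructed
# so the true covariate-specific ROC is exactly the probit ROC-GLM:
# controls' oriented marker ~ N(mu0, sigma0^2); a case with covariates x has
# oriented marker ~ N(mu0 + (sigma0/alpha2) * (alpha1 + beta'x),
# (sigma0/alpha2)^2). By the binormal identity ROC(q) = Phi(a + b Phi^-1(q))
# with a = (mu_D - mu0)/sigma_D and b = sigma0/sigma_D, this yields
# ROC(q | x) = Phi(alpha1 + alpha2 Phi^-1(q) + beta'x).

#' Default per-group covariate distributions
#'
#' Normal marginals per covariate and group emulating an early-glaucoma
#' case-control cohort (173 glaucomatous and 63 unaffected eyes):
#' age 55.16 (11.28) vs 53.71 (11.73) years, VFI 88.99 (9.85) vs 99.27
#' (1.08) percent (truncated at 100), spherical equivalent -2.28 (3.14) vs
#' -1.78 (3.69) D, axial length 24.69 (1.48) vs 24.12 (1.58) mm, corrected
#' disc area 1.98 (0.41) vs 2.00 (0.47) mm^2 (truncated at 0). Truncation
#' is enforced by rejection sampling so requested group sizes are never
#' silently altered.
#'
#' @return A tibble with columns `covariate`, `group`, `mean`, `sd`,
#'   `lower`, `upper`.
#' @export
covariate_distributions <- function() {
  tibble::tribble(
    ~covariate, ~group, ~mean, ~sd, ~lower, ~upper,
    "age", "glaucoma", 55.16, 11.28, 18, Inf,
    "age", "control", 53.71, 11.73, 18, Inf,
    "vfi", "glaucoma", 88.99, 9.85, 0, 100,
    "vfi", "control", 99.27, 1.08, 0, 100,
    "spherical_equivalent", "glaucoma", -2.28, 3.14, -Inf, Inf,
    "spherical_equivalent", "control", -1.78, 3.69, -Inf, Inf,
    "axial_length", "glaucoma", 24.69, 1.48, 1.82, Inf,
    "axial_length", "control", 24.12, 1.58, 1.82, Inf,
    "disc_area_corrected", "glaucoma", 1.98, 0.41, 0, Inf,
    "disc_area_corrected", "control", 2.00, 0.47, 0, Inf
  )
}

# Ancillary clinical fields (not part of the ROC model) drawn from the same
# cohort's group marginals so the characteristics table is exercised
# end-to-end; quality fields are set to passing values.
ancillary_distributions <- function() {
  tibble::tribble(
    ~field, ~group, ~mean, ~sd, ~lower, ~upper,
    "bcva_logmar", "glaucoma", 0.07, 0.12, -0.3, 0.30,
    "bcva_logmar", "control", 0.06, 0.11, -0.3, 0.30,
    "iop", "glaucoma", 13.08, 2.45, 5, 21,
    "iop", "control", 13.23, 2.19, 5, 21,
    "md", "glaucoma", -4.19, 3.45, -Inf, Inf,
    "md", "control", -0.47, 1.53, -Inf, Inf,
    "psd", "glaucoma", 6.74, 4.12, 0, Inf,
    "psd", "control", 1.85, 0.52, 0, Inf,
    "cylinder", "glaucoma", -0.6, 0.6, -3, 3,
    "cylinder", "control", -0.6, 0.6, -3, 3
  )
}

# Control-group marker means/SDs (thickness scale) per marker name.
control_marker_defaults <- function(marker) {
  defaults <- list(
    rnfl_avg = c(mean = 93.05, sd = 8.80),
    gcipl_avg = c(mean = 79.21, sd = 11.68),
    gcipl_min = c(mean = 76.81, sd = 6.83)
  )
  if (marker %in% names(defaults)) defaults[[marker]] else
    c(mean = 0, sd = 1)
}

#' Generative truth for a synthetic cohort
#'
#' Holds the true ROC regression coefficients and the control marker
#' distribution from which a cohort is generated; the induced
#' covariate-specific ROC is exactly
#' Phi(alpha1 + alpha2 Phi^-1(q) + beta' x).
#'
#' @param alpha1 True ROC intercept.
#' @param alpha2 True slope on the probit of the FPR; must be positive.
#' @param betas Named numeric vector of true covariate coefficients (names
#'   must match covariate columns; may be empty for a covariate-free
#'   marker).
#' @param marker Marker column name to populate.
#' @param direction Marker direction, see [marker_spec()].
#' @param mu0,sigma0 Control marker mean and SD on the observed (thickness)
#'   scale; default to the packaged control-group values for the named
#'   marker.
#' @param n_cases,n_controls Group sizes (defaults 173/63).
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(alpha1, alpha2, betas = c(),
                            marker = "gcipl_avg",
                            direction = c("lower_is_diseased",
                                          "higher_is_diseased"),
                            mu0 = NULL, sigma0 = NULL,
                            n_cases = 173, n_controls = 63) {
  direction <- match.arg(direction)
  check_number(alpha1, "alpha1")
  check_number(alpha2, "alpha2", lower = 1e-12)
  if (length(betas) && is.null(names(betas))) abort("betas must be named")
  ctrl <- control_marker_defaults(marker)
  if (is.null(mu0)) mu0 <- unname(ctrl["mean"])
  if (is.null(sigma0)) sigma0 <- unname(ctrl["sd"])
  check_number(sigma0, "sigma0", lower = 1e-12)
  stopifnot(n_cases >= 1, n_controls >= 1)
  structure(
    list(alpha1 = alpha1, alpha2 = alpha2, betas = betas, marker = marker,
         direction = direction, mu0 = mu0, sigma0 = sigma0,
         n_cases = as.integer(n_cases), n_controls = as.integer(n_controls)),
    class = "synthetic_truth"
  )
}

#' Truth taken from a reference coefficient row set
#'
#' Convenience constructor building a [synthetic_truth()] from one marker's
#' rows of [reference_coefficients()].
#'
#' @param marker One of `"rnfl_avg"`, `"gcipl_avg"`, `"gcipl_min"`.
#' @param ... Passed to [synthetic_truth()] (e.g. group sizes).
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth_reference <- function(marker = "gcipl_avg", ...) {
  co <- reference_coefficient_vector(marker)
  betas <- co[setdiff(names(co), c("(Intercept)", "probit_fpr"))]
  synthetic_truth(alpha1 = unname(co["(Intercept)"]),
                  alpha2 = unname(co["probit_fpr"]),
                  betas = betas, marker = marker, ...)
}

rtruncnorm_reject <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

draw_fields <- function(dists, grp, n, field_col = "covariate") {
  rows <- dists[dists$group == grp, , drop = FALSE]
  cols <- lapply(seq_len(nrow(rows)), function(i) {
    rtruncnorm_reject(n, rows$mean[i], rows$sd[i], rows$lower[i], rows$upper[i])
  })
  names(cols) <- rows[[field_col]]
  tibble::as_tibble(cols)
}

#' Generate a synthetic case-control cohort
#'
#' Draws per-group covariates from `dists` (independently per eye), then
#' the marker from the binormal construction that makes the true
#' covariate-specific ROC equal the probit ROC-GLM with the truth's
#' coefficients. Only the cases' covariates shift the marker; the controls'
#' marker is covariate-independent, mirroring the pooled-reference fitting
#' convention. All eye-record fields are populated, with quality fields set
#' to passing values; the measured disc area is back-computed from the
#' generated corrected area via the Bennett factor so the magnification
#' stage round-trips. Byte-identical output for a fixed seed.
#'
#' @param truth A [synthetic_truth()].
#' @param dists Covariate distributions, see [covariate_distributions()].
#' @param seed Integer seed.
#' @return A cohort tibble with the canonical eye-record columns.
#' @export
generate_cohort <- function(truth, dists = covariate_distributions(), seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  check_number(seed, "seed")
  missing_cov <- setdiff(names(truth$betas), unique(dists$covariate))
  if (length(missing_cov)) {
    abort(paste0("no distribution for covariate(s): ",
                 paste(missing_cov, collapse = ", ")))
  }
  n1 <- truth$n_cases
  n0 <- truth$n_controls
  with_seed(seed, {
    cov_case <- draw_fields(dists, "glaucoma", n1)
    cov_ctrl <- draw_fields(dists, "control", n0)
    anc_case <- draw_fields(ancillary_distributions(), "glaucoma", n1,
                            field_col = "field")
    anc_ctrl <- draw_fields(ancillary_distributions(), "control", n0,
                            field_col = "field")
    sex <- c(
      ifelse(runif(n1) < 0.497, "female", "male"),
      ifelse(runif(n0) < 0.524, "female", "male")
    )
    eye <- sample(c("OD", "OS"), n1 + n0, replace = TRUE)

    sgn <- if (truth$direction == "lower_is_diseased") -1 else 1
    mu0_oriented <- sgn * truth$mu0
    sigma_d <- truth$sigma0 / truth$alpha2
    lp <- truth$alpha1 + if (length(truth$betas)) {
      as.matrix(cov_case[, names(truth$betas), drop = FALSE]) %*%
        truth$betas
    } else {
      rep(0, n1)
    }
    marker_case <- rnorm(n1, mu0_oriented + sigma_d * as.numeric(lp), sigma_d)
    marker_ctrl <- rnorm(n0, mu0_oriented, truth$sigma0)

    other <- setdiff(c("rnfl_avg", "gcipl_avg", "gcipl_min"), truth$marker)
    other_case <- lapply(other, function(mk) {
      d <- control_marker_defaults(mk)
      # non-model markers: shifted group marginal, clinically plausible only
      rtruncnorm_reject(n1, unname(d["mean"]) * 0.82, unname(d["sd"]), 1, Inf)
    })
    other_ctrl <- lapply(other, function(mk) {
      d <- control_marker_defaults(mk)
      rtruncnorm_reject(n0, unname(d["mean"]), unname(d["sd"]), 1, Inf)
    })
    names(other_case) <- names(other_ctrl) <- other

    covs <- dplyr::bind_rows(cov_case, cov_ctrl)
    anc <- dplyr::bind_rows(anc_case, anc_ctrl)
    cohort <- tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n1 + n0)),
      eye = eye,
      group = rep(c("glaucoma", "control"), c(n1, n0)),
      sex = sex
    )
    cohort <- dplyr::bind_cols(cohort, covs, anc)
    cohort[[truth$marker]] <- pmax(sgn * c(marker_case, marker_ctrl), 1)
    for (mk in other) cohort[[mk]] <- c(other_case[[mk]], other_ctrl[[mk]])
    cohort$disc_area_measured <- cohort$disc_area_corrected /
      bennett_correction_factor(cohort$axial_length)
    cohort$signal_strength_macula <- 9
    cohort$signal_strength_disc <- 9
    cohort$vf_fixation_loss <- 5
    cohort$vf_false_positive <- 5
    cohort[, intersect(EYE_COLUMNS, names(cohort))]
  })
}

#' Parameter-recovery study for the ROC regression
#'
#' Repeatedly generates cohorts from a known truth, refits the model, and
#' summarises per-coefficient bias, RMSE and (optionally) bootstrap
#' confidence-interval coverage. Fit failures are counted and reported, and
#' only abort the study above a 10% failure rate.
#'
#' @param truth A [synthetic_truth()].
#' @param dists Covariate distributions.
#' @param n_replicates Number of generate-fit replicates (>= 50 advised).
#' @param seed Master seed; replicate seeds fan out from it.
#' @param B Bootstrap replicates per fit for coverage (0 skips coverage).
#' @param grid FPR grid used for fitting.
#' @return A tibble with one row per coefficient: truth, mean estimate,
#'   bias, Monte-Carlo SE of the mean, RMSE, coverage (if `B > 0`), and the
#'   replicate failure count as an attribute `n_failed`.
#' @export
recovery_study <- function(truth, dists = covariate_distributions(),
                           n_replicates = 100, seed = 1, B = 0,
                           grid = fpr_grid()) {
  stopifnot(inherits(truth, "synthetic_truth"), n_replicates >= 2)
  true_vec <- c("(Intercept)" = truth$alpha1, probit_fpr = truth$alpha2,
                truth$betas)
  covars <- names(truth$betas)
  est <- matrix(NA_real_, n_replicates, length(true_vec),
                dimnames = list(NULL, names(true_vec)))
  covered <- matrix(NA, n_replicates, length(true_vec),
                    dimnames = list(NULL, names(true_vec)))
  base <- substream_seed(seed, "recovery")
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    rep_seed <- (base + r * 6151) %% 2147483647
    cohort <- generate_cohort(truth, dists, seed = rep_seed)
    fit <- tryCatch(
      suppressWarnings(roc_glm(cohort, truth$marker, covariates = covars,
                               direction = truth$direction, grid = grid)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    est[r, ] <- fit$coefficients[names(true_vec)]
    if (B > 0) {
      fit <- tryCatch(
        roc_glm_boot(fit, B = B, seed = (rep_seed + 911) %% 2147483647),
        error = function(e) NULL
      )
      if (!is.null(fit)) {
        ci <- fit$bootstrap
        covered[r, ] <- true_vec >= ci$conf.low[match(names(true_vec), ci$term)] &
          true_vec <= ci$conf.high[match(names(true_vec), ci$term)]
      }
    }
  }
  if (n_failed / n_replicates > 0.10) {
    abort(paste0("fit failure rate ", n_failed, "/", n_replicates,
                 " exceeds 10%"))
  }
  ok <- !is.na(est[, 1])
  out <- tibble::tibble(
    term = names(true_vec),
    truth = unname(true_vec),
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - unname(true_vec),
    mc_se = apply(est[ok, , drop = FALSE], 2, sd) / sqrt(sum(ok)),
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            rep(true_vec, each = sum(ok)))^2)),
    coverage = if (B > 0) colMeans(covered[ok, , drop = FALSE], na.rm = TRUE)
               else NA_real_
  )
  attr(out, "n_failed") <- n_failed
  attr(out, "n_replicates") <- n_replicates
  out
}
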