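# S3 methods for roc_glm objects: print, tidy, glance, autoplot.

#' @export
print.roc_glm <- function(x, ...) {
  cat("Covariate-adjusted probit ROC regression\n")
  cat("  marker:", x$marker$name, paste0("(", x$marker$direction, ")"), "\n")
  cat("  cases:", x$n_cases, " controls:", x$n_controls,
      " FPR grid:", length(x$grid), "points\n")
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$bootstrap)) {
    cat("Bootstrap (B =", x$bootstrap_B, ") percentile 95% CIs available;",
        "see tidy()\n")
  }
  invisible(x)
}

#' Tidy a ROC regression fit
#'
#' One row per model term. When [roc_glm_boot()] has been run, the
#' bootstrap percentile confidence intervals and normal-approximation
#' p-values are reported; otherwise only the point estimates and the naive
#' (within-case-correlation-ignoring, hence invalid for inference) standard
#' errors, flagged by the `method` column.
#'
#' @param x A `roc_glm` fit.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`, `method`.
#' @method tidy roc_glm
#' @export
tidy.roc_glm <- function(x, ...) {
  if (!is.null(x$bootstrap)) {
    return(x$bootstrap)
  }
  se <- if (!is.null(x$naive_vcov)) sqrt(diag(x$naive_vcov)) else
    rep(NA_real_, length(x$coefficients))
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    conf.low = NA_real_,
    conf.high = NA_real_,
    p.value = NA_real_,
    method = "naive_probit_invalid"
  )
}

#' Glance at a ROC regression fit
#'
#' @param x A `roc_glm` fit.
#' @param ... Unused.
#' @return A one-row tibble with sample sizes, the ROC intercept and slope,
#'   grid size and convergence flag.
#' @method glance roc_glm
#' @export
glance.roc_glm <- function(x, ...) {
  tibble::tibble(
    marker = x$marker$name,
    n_cases = x$n_cases,
    n_controls = x$n_controls,
    alpha1 = x$alpha1,
    alpha2 = x$alpha2,
    grid_size = length(x$grid),
    converged = x$converged,
    bootstrap_B = if (is.null(x$bootstrap_B)) NA_integer_ else x$bootstrap_B
  )
}

#' ROC curve points for plotting or export
#'
#' @param object A `roc_glm` fit or named coefficient vector.
#' @param profiles A data frame of covariate profiles (one curve per row);
#'   an optional `label` column names the curves.
#' @param n Number of FPR points per curve.
#' @return A tibble with `label`, profile columns, `fpr`, `tpr`.
#' @export
roc_curve_points <- function(object, profiles = tibble::tibble(.rows = 1),
                             n = 101) {
  profiles <- tibble::as_tibble(profiles)
  q <- seq(1 / (n + 1), n / (n + 1), length.out = n)
  has_label <- "label" %in% names(profiles)
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    prof <- profiles[i, setdiff(names(profiles), "label"), drop = FALSE]
    lab <- if (has_label) profiles$label[i] else paste0("profile ", i)
    tibble::tibble(label = lab, prof, fpr = q,
                   tpr = roc_at(object, q, prof))
  })
}

#' Plot covariate-specific ROC curves
#'
#' @param object A `roc_glm` fit.
#' @param profiles A data frame of covariate profiles (one curve per row),
#'   optionally with a `label` column.
#' @param n Number of FPR points per curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_glm
#' @export
autoplot.roc_glm <- function(object, profiles = NULL, n = 101, ...) {
  if (is.null(profiles)) {
    profiles <- tibble::as_tibble(as.list(colMeans(object$data$x_case)))
    if (ncol(profiles)) profiles$label <- "mean case profile"
  }
  pts <- roc_curve_points(object, profiles, n = n)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive rate (1 - specificity)",
                  y = "Sensitivity",
                  colour = "Profile",
                  title = paste("Covariate-specific ROC:", object$marker$name)) +
    ggplot2::theme_minimal()
}
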