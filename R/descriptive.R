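# Group-comparison layer: two-sample Student t, Fisher exact, Pearson
# correlation, and the demographic/ocular characteristics table.

#' Pooled-variance two-sample Student t-test
#'
#' Classical Student form with pooled variance and n_a + n_b - 2 degrees of
#' freedom (not Welch).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @export
student_t <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("each group needs at least 2 observations")
  }
  if (stats::var(group_a) + stats::var(group_b) == 0) {
    abort("zero pooled variance")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = ht$p.value,
                 method = "student_t")
}

#' Student t-test from summary statistics
#'
#' Pooled two-sample t computed from per-group n, mean and SD, so printed
#' summary rows are testable without raw data. Identical to [student_t()]
#' on the same data to numerical precision.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A.
#' @param mean_b,sd_b,n_b Summary statistics of group B.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @export
student_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  if (sd_a + sd_b == 0) abort("zero pooled variance")
  df <- n_a + n_b - 2
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df)
  t <- (mean_a - mean_b) / (sp * sqrt(1 / n_a + 1 / n_b))
  tibble::tibble(statistic = t, df = df,
                 p.value = 2 * stats::pt(-abs(t), df),
                 method = "student_t_summary")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided p-value under the minimum-likelihood
#' convention (sum of table probabilities no larger than the observed
#' one). A zero margin yields p = 1 by convention, with a message.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return A one-row tibble: `p.value`, `method`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) abort("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers")
  }
  p <- if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    inform("zero margin in 2x2 table; p = 1 by convention")
    1
  } else {
    stats::fisher.test(table)$p.value
  }
  tibble::tibble(p.value = p, method = "fisher_exact")
}

#' Sample Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return The sample Pearson correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("at least 3 complete pairs required")
  if (stats::var(x) == 0 || stats::var(y) == 0) abort("constant input")
  stats::cor(x, y)
}

# Default variable layout of the characteristics table.
default_table_one_vars <- function() {
  tibble::tibble(
    variable = c("age", "sex", "bcva_logmar", "iop", "spherical_equivalent",
                 "axial_length", "md", "psd", "vfi", "disc_area_measured",
                 "disc_area_corrected", "rnfl_avg", "gcipl_avg", "gcipl_min"),
    type = c("continuous", "categorical", rep("continuous", 12))
  )
}

#' Group characteristics comparison table
#'
#' Per-variable group means and SDs (or counts and percentages for
#' categoricals) with a pooled Student t-test for continuous variables and
#' a Fisher exact test for 2-level categoricals, comparing the case and
#' control groups.
#'
#' @param cohort A cohort tibble with a `group` column.
#' @param variables A data frame with columns `variable`, `type`
#'   (`"continuous"` or `"categorical"`); defaults to the standard
#'   demographic/ocular layout, restricted to columns present.
#' @param group,case_level Group column and case level.
#' @return A tibble with one row per variable: per-group n/mean/sd (or
#'   count/percent), test name, p-value.
#' @export
table_one <- function(cohort, variables = NULL, group = "group",
                      case_level = "glaucoma") {
  stopifnot(is.data.frame(cohort), group %in% names(cohort))
  if (is.null(variables)) {
    variables <- dplyr::filter(default_table_one_vars(),
                               .data$variable %in% names(cohort))
  }
  unknown <- setdiff(variables$variable, names(cohort))
  if (length(unknown)) {
    abort(paste0("unknown variable(s): ", paste(unknown, collapse = ", ")))
  }
  is_case <- cohort[[group]] == case_level
  if (!any(is_case) || !any(!is_case)) abort("both groups are required")
  purrr::pmap_dfr(variables, function(variable, type, ...) {
    v <- cohort[[variable]]
    if (type == "continuous") {
      a <- v[is_case & !is.na(v)]
      b <- v[!is_case & !is.na(v)]
      ht <- student_t(a, b)
      tibble::tibble(
        variable = variable, type = type,
        n_case = length(a), n_control = length(b),
        mean_case = mean(a), sd_case = sd(a),
        mean_control = mean(b), sd_control = sd(b),
        test = "student_t", p.value = ht$p.value
      )
    } else {
      lv <- sort(unique(as.character(v[!is.na(v)])))
      if (length(lv) != 2L) {
        abort(paste0("categorical variable '", variable,
                     "' must have exactly 2 levels"))
      }
      tab <- table(factor(as.character(v), levels = lv), is_case)[, c("TRUE", "FALSE")]
      ht <- fisher_exact_2x2(tab)
      tibble::tibble(
        variable = variable, type = type,
        n_case = sum(is_case & !is.na(v)), n_control = sum(!is_case & !is.na(v)),
        mean_case = tab[1, 1], sd_case = 100 * tab[1, 1] / sum(tab[, 1]),
        mean_control = tab[1, 2], sd_control = 100 * tab[1, 2] / sum(tab[, 2]),
        test = "fisher_exact", p.value = ht$p.value
      )
    }
  })
}
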