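# Covariate-adjusted probit ROC regression via the Alonzo-Pepe
# placement-value / binary-indicator construction.
#
# Model: ROC(q | x) = Phi(alpha1 + alpha2 * Phi^-1(q) + beta' x), fitted by
# probit regression of the indicators 1{pv_i <= q_j} on [1, Phi^-1(q_j), x_i]
# where pv_i is case i's placement value in the pooled control distribution.

#' Marker specification
#'
#' Declares a diagnostic marker and the direction in which it signals
#' disease. OCT thickness markers thin with glaucoma, so they default to
#' `lower_is_diseased`; the fitting machinery works on oriented values where
#' larger always means more diseased.
#'
#' @param name Marker (column) name, e.g. `"rnfl_avg"`, `"gcipl_avg"`,
#'   `"gcipl_min"`.
#' @param direction `"lower_is_diseased"` or `"higher_is_diseased"`.
#' @return A list of class `marker_spec`.
#' @export
marker_spec <- function(name,
                        direction = c("lower_is_diseased",
                                      "higher_is_diseased")) {
  stopifnot(is.character(name), length(name) == 1L)
  direction <- match.arg(direction)
  structure(list(name = name, direction = direction), class = "marker_spec")
}

#' Orient marker values so larger means more diseased
#'
#' @param values Numeric marker measurements.
#' @param spec A [marker_spec()].
#' @return `values`, negated when the marker decreases with disease.
#' @export
orient_marker <- function(values, spec) {
  stopifnot(inherits(spec, "marker_spec"))
  if (spec$direction == "lower_is_diseased") -values else values
}

#' False-positive-rate evaluation grid
#'
#' Strictly increasing interior FPR values at which the placement-value
#' indicators are expanded. The default is the m-point uniform interior grid
#' q_j = (2j - 1) / (2m), which avoids the probit singularities at 0 and 1.
#'
#' @param m Number of grid points (>= 2), default 100.
#' @param values Optional explicit grid, overriding `m`.
#' @return A numeric vector of class `fpr_grid`.
#' @export
fpr_grid <- function(m = 100, values = NULL) {
  q <- if (is.null(values)) (2 * seq_len(m) - 1) / (2 * m) else as.numeric(values)
  if (length(q) < 2L || any(q <= 0) || any(q >= 1) || any(diff(q) <= 0)) {
    abort("FPR grid must be >= 2 strictly increasing values in (0, 1)")
  }
  structure(q, class = c("fpr_grid", "numeric"))
}

#' Placement values of cases in the control distribution
#'
#' The placement value of a case is the proportion of controls whose
#' oriented marker value is at least as disease-like: pv_i = (1/n0) *
#' #\{controls >= case_i\} under the inclusive tie rule (ties count), or
#' #\{controls > case_i\} under the strict rule. The ROC curve is the CDF of
#' the case placement values.
#'
#' @param case_values Oriented marker values of cases.
#' @param control_values Oriented marker values of controls (>= 1 required).
#' @param ties `"inclusive"` (default) or `"strict"`.
#' @return Numeric vector of placement values in \[0, 1\], one per case.
#' @export
placement_values <- function(case_values, control_values,
                             ties = c("inclusive", "strict")) {
  ties <- match.arg(ties)
  if (length(control_values) == 0L || all(is.na(control_values))) {
    abort("control sample must be non-empty")
  }
  sc <- sort(control_values)
  n0 <- length(sc)
  if (ties == "inclusive") {
    # controls >= v  =  n0 - #{controls < v}
    (n0 - findInterval(case_values, sc, left.open = TRUE)) / n0
  } else {
    (n0 - findInterval(case_values, sc)) / n0
  }
}

#' Expand placement values into the binary-indicator table
#'
#' Builds the long-format table on which the probit regression is fitted:
#' one row per (case, grid point) with the indicator u_ij = 1\{pv_i <= q_j\},
#' the probit of the grid point, and the case's covariates.
#'
#' @param pv Placement values, one per case.
#' @param grid An [fpr_grid()].
#' @param covariates Optional data frame of case covariates (one row per
#'   case).
#' @return A tibble with `case`, `q`, `probit_fpr`, `u` and the covariate
#'   columns; `n_cases * length(grid)` rows.
#' @export
expand_indicators <- function(pv, grid = fpr_grid(), covariates = NULL) {
  if (!inherits(grid, "fpr_grid")) grid <- fpr_grid(values = grid)
  n <- length(pv)
  m <- length(grid)
  out <- tibble::tibble(
    case = rep(seq_len(n), each = m),
    q = rep(as.numeric(grid), times = n),
    probit_fpr = rep(qnorm(as.numeric(grid)), times = n),
    u = as.integer(rep(pv, each = m) <= rep(as.numeric(grid), times = n))
  )
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (nrow(covariates) != n) abort("one covariate row per case required")
    out <- dplyr::bind_cols(out, covariates[out$case, , drop = FALSE])
  }
  out
}

#' Fit the covariate-adjusted probit ROC regression
#'
#' Fits ROC(q | x) = Phi(alpha1 + alpha2 Phi^-1(q) + beta' x) by maximum
#' likelihood probit regression of the Alonzo-Pepe binary indicators.
#' Covariates enter through the cases only, on their raw scales; the pooled
#' empirical control distribution is the reference. Naive probit standard
#' errors are retained for diagnostics but flagged invalid (indicators
#' within a case are correlated); use [roc_glm_boot()] for inference.
#'
#' @param data A cohort data frame with the marker, covariate and group
#'   columns.
#' @param marker Marker column name, or a [marker_spec()].
#' @param covariates Character vector of covariate column names (may be
#'   empty for an unadjusted fit).
#' @param direction Marker direction when `marker` is a bare name.
#' @param grid An [fpr_grid()].
#' @param ties Placement-value tie rule, see [placement_values()].
#' @param group Name of the group column (values `"glaucoma"`/`"control"`
#'   by default).
#' @param case_level Level of `group` identifying cases.
#' @return An object of class `roc_glm` with coefficients `(Intercept)`
#'   (alpha1), `probit_fpr` (alpha2) and one beta per covariate.
#' @export
roc_glm <- function(data, marker,
                    covariates = character(0),
                    direction = c("lower_is_diseased", "higher_is_diseased"),
                    grid = fpr_grid(),
                    ties = c("inclusive", "strict"),
                    group = "group", case_level = "glaucoma") {
  stopifnot(is.data.frame(data))
  if (!inherits(marker, "marker_spec")) {
    marker <- marker_spec(marker, match.arg(direction))
  }
  ties <- match.arg(ties)
  if (!inherits(grid, "fpr_grid")) grid <- fpr_grid(values = grid)
  need <- setdiff(c(marker$name, covariates, group), names(data))
  if (length(need)) {
    abort(paste0("data lacks column(s): ", paste(need, collapse = ", ")))
  }
  is_case <- data[[group]] == case_level
  keep <- !is.na(data[[marker$name]]) & !is.na(is_case)
  if (length(covariates)) {
    keep <- keep & stats::complete.cases(data[, covariates, drop = FALSE])
  }
  data <- data[keep, , drop = FALSE]
  is_case <- is_case[keep]
  if (!any(is_case) || !any(!is_case)) {
    abort("both cases and controls are required")
  }
  y_case <- orient_marker(data[[marker$name]][is_case], marker)
  y_ctrl <- orient_marker(data[[marker$name]][!is_case], marker)
  x_case <- as.matrix(data[is_case, covariates, drop = FALSE])
  storage.mode(x_case) <- "double"

  pv <- placement_values(y_case, y_ctrl, ties = ties)
  fit <- fit_indicator_probit(pv, grid, x_case)
  structure(
    list(
      coefficients = fit$coefficients,
      alpha1 = unname(fit$coefficients["(Intercept)"]),
      alpha2 = unname(fit$coefficients["probit_fpr"]),
      betas = fit$coefficients[setdiff(names(fit$coefficients),
                                       c("(Intercept)", "probit_fpr"))],
      covariate_names = covariates,
      marker = marker,
      grid = grid,
      ties = ties,
      n_cases = length(y_case),
      n_controls = length(y_ctrl),
      converged = fit$converged,
      separation = fit$separation,
      naive_vcov = fit$naive_vcov,   # invalid for inference; bootstrap instead
      data = list(y_case = y_case, y_ctrl = y_ctrl, x_case = x_case),
      bootstrap = NULL,
      bootstrap_draws = NULL
    ),
    class = "roc_glm"
  )
}

# Probit regression of u_ij on [1, probit(q_j), x_i]; `weights` are
# per-case multiplicities (the bootstrap uses them instead of duplicating
# rows), `start` warm-starts the IRLS iterations. The "glm" engine is
# stats::glm.fit; "irls" is a lean probit scorer with identical maximum
# likelihood solutions (asserted in the test suite) used where thousands of
# refits are needed (bootstrap, recovery studies).
fit_indicator_probit <- function(pv, grid, x_case, weights = NULL,
                                 start = NULL, engine = c("glm", "irls")) {
  engine <- match.arg(engine)
  n <- length(pv)
  m <- length(grid)
  zq <- qnorm(as.numeric(grid))
  X <- cbind(
    "(Intercept)" = 1,
    probit_fpr = rep(zq, times = n),
    x_case[rep(seq_len(n), each = m), , drop = FALSE]
  )
  u <- as.numeric(rep(pv, each = m) <= rep(as.numeric(grid), times = n))
  w <- if (is.null(weights)) rep(1, n * m) else rep(weights, each = m)
  if (all(u == u[1])) {
    # e.g. a marker constant in both groups: the indicator response is
    # one-sided and the likelihood has no interior maximum
    warn("quasi-separation: degenerate indicator response (constant marker?)")
  }
  if (engine == "glm") {
    fit <- withCallingHandlers(
      stats::glm.fit(X, u, weights = w, start = start,
                     family = stats::binomial(link = "probit"),
                     control = stats::glm.control(maxit = 100)),
      warning = function(cnd) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(cnd))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    co <- fit$coefficients
    converged <- fit$converged
    irls_w <- fit$weights
  } else {
    fit <- probit_irls(X, u, w0 = w, start = start)
    co <- fit$beta
    converged <- fit$converged
    irls_w <- fit$irls_w
  }
  names(co) <- colnames(X)
  # quasi-separation shows up as runaway coefficients on the probit scale
  # (extreme fitted probabilities alone are normal at peripheral grid points)
  separation <- any(!is.finite(co)) || max(abs(co)) > 15
  if (!converged) {
    warn("probit ROC regression did not converge; treat estimates as diagnostic")
  } else if (separation) {
    warn("quasi-separation in the indicator probit fit (degenerate marker?)")
  }
  # naive vcov from the final IRLS weights (ignores within-case correlation)
  naive_vcov <- tryCatch(
    solve(crossprod(X * sqrt(irls_w))),
    error = function(e) NULL
  )
  list(coefficients = co, converged = converged,
       separation = separation, naive_vcov = naive_vcov)
}

# Structured Fisher-scoring probit fit for the indicator regression.
# Exploits the block structure of the design (covariates constant within a
# case, the probit-FPR column constant across cases) to assemble the
# weighted normal equations in O(n*m) without materialising the n*m x p
# design matrix. Same ML solution as glm.fit (asserted in tests); used
# where thousands of refits are needed.
probit_irls_fast <- function(q, x_case, pv, w_case = NULL, start,
                             maxit = 50, tol = 1e-9) {
  m <- length(q)
  n <- length(pv)
  k <- if (is.null(x_case)) 0L else ncol(x_case)
  p <- 2L + k
  if (is.null(w_case)) w_case <- rep(1, n)
  zq <- qnorm(as.numeric(q))
  u <- as.numeric(rep(pv, each = m) <= rep(as.numeric(q), times = n))
  beta <- start
  converged <- FALSE
  for (it in seq_len(maxit)) {
    a <- beta[1] + if (k) drop(x_case %*% beta[3:p]) else numeric(n)
    eta <- rep(beta[2] * zq, times = n) + rep(a, each = m)
    # clamp the linear predictor: beyond +/-8 probit units the indicator
    # carries no information and the working weights underflow
    eta <- pmin(pmax(eta, -8), 8)
    mu <- pnorm(eta)
    d <- dnorm(eta)
    v <- mu * (1 - mu)
    wr <- d * d / v
    wz <- wr * eta + d * (u - mu) / v
    cw0 <- .colSums(wr, m, n)
    wrz <- wr * zq
    cw1 <- .colSums(wrz, m, n)
    cw2 <- .colSums(wrz * zq, m, n)
    cz0 <- .colSums(wz, m, n)
    cz1 <- .colSums(wz * zq, m, n)
    S <- w_case * cw0
    Tz <- w_case * cw1
    A <- matrix(0, p, p)
    A[1, 1] <- sum(S)
    A[1, 2] <- A[2, 1] <- sum(Tz)
    A[2, 2] <- sum(w_case * cw2)
    rhs <- numeric(p)
    rhs[1] <- sum(w_case * cz0)
    rhs[2] <- sum(w_case * cz1)
    if (k) {
      A[1, 3:p] <- A[3:p, 1] <- drop(crossprod(x_case, S))
      A[2, 3:p] <- A[3:p, 2] <- drop(crossprod(x_case, Tz))
      A[3:p, 3:p] <- crossprod(x_case * sqrt(S))
      rhs[3:p] <- drop(crossprod(x_case, w_case * cz0))
    }
    beta_new <- drop(solve(A, rhs))
    rel <- max(abs(beta_new - beta)) / max(1, max(abs(beta_new)))
    beta <- beta_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, converged = converged)
}

# Minimal Fisher-scoring probit fit. Same ML solution as glm.fit with a
# probit link, a fraction of the bookkeeping.
probit_irls <- function(X, y, w0 = NULL, start = NULL, maxit = 100,
                        tol = 1e-10) {
  if (is.null(w0)) w0 <- rep(1, nrow(X))
  if (is.null(start)) {
    eta <- qnorm((w0 * y + 0.5) / (w0 + 1))
  } else {
    eta <- drop(X %*% start)
  }
  dev_old <- Inf
  beta <- start
  converged <- FALSE
  W <- w0
  for (it in seq_len(maxit)) {
    mu <- pmin(pmax(pnorm(eta), 1e-10), 1 - 1e-10)
    d <- pmax(dnorm(eta), 1e-300)
    W <- w0 * d * d / (mu * (1 - mu))
    z <- eta + (y - mu) / d
    XW <- X * W
    beta <- solve(crossprod(XW, X), crossprod(XW, z))
    eta <- drop(X %*% beta)
    mu2 <- pmin(pmax(pnorm(eta), 1e-10), 1 - 1e-10)
    dev <- -2 * sum(w0 * (y * log(mu2) + (1 - y) * log(1 - mu2)))
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  list(beta = drop(beta), converged = converged, irls_w = W)
}

coef_from <- function(object) {
  if (inherits(object, "roc_glm")) {
    object$coefficients
  } else if (is.numeric(object) && !is.null(names(object))) {
    object
  } else {
    abort("expected a roc_glm fit or a named coefficient vector")
  }
}

linear_predictor <- function(co, profile) {
  betas <- co[setdiff(names(co), c("(Intercept)", "probit_fpr"))]
  if (length(betas)) {
    profile <- as.list(profile)
    missing <- setdiff(names(betas), names(profile))
    if (length(missing)) {
      abort(paste0("profile lacks covariate(s): ",
                   paste(missing, collapse = ", ")))
    }
    xs <- vapply(names(betas), function(nm) as.numeric(profile[[nm]]), numeric(1))
    unname(co["(Intercept)"] + sum(betas * xs))
  } else {
    unname(co["(Intercept)"])
  }
}

#' Covariate-specific ROC curve value
#'
#' Evaluates ROC(q | x) = Phi(alpha1 + alpha2 Phi^-1(q) + beta' x) at
#' false-positive rate(s) `q` for a covariate profile. Strictly increasing
#' in q whenever alpha2 > 0.
#'
#' @param object A `roc_glm` fit or a named coefficient vector containing
#'   `(Intercept)`, `probit_fpr` and the covariate betas.
#' @param q False-positive rate(s) in the open interval (0, 1).
#' @param profile Named list/one-row data frame of covariate values; may be
#'   empty for an unadjusted model.
#' @return Sensitivity value(s) in (0, 1).
#' @export
roc_at <- function(object, q, profile = list()) {
  co <- coef_from(object)
  if (any(q <= 0 | q >= 1)) abort("q must lie in the open interval (0, 1)")
  lp <- linear_predictor(co, profile)
  pnorm(lp + unname(co["probit_fpr"]) * qnorm(q))
}

#' Covariate-specific AUROC (closed form)
#'
#' The binormal model gives the area under the covariate-specific ROC curve
#' in closed form: AUC(x) = Phi((alpha1 + beta' x) / sqrt(1 + alpha2^2)).
#' Requires alpha2 > 0 (a proper binormal ROC).
#'
#' @inheritParams roc_at
#' @return AUROC in (0, 1).
#' @export
roc_auc <- function(object, profile = list()) {
  co <- coef_from(object)
  a2 <- unname(co["probit_fpr"])
  if (is.na(a2) || a2 <= 0) {
    abort("invalid fit: the probit-FPR slope (alpha2) must be positive")
  }
  pnorm(linear_predictor(co, profile) / sqrt(1 + a2^2))
}

#' Covariate-specific AUROC by numerical integration
#'
#' Quadrature oracle for [roc_auc()]: integrates the ROC curve over (0, 1)
#' after the substitution q = Phi(z), using Gauss-Legendre nodes on the
#' z-scale. Used to cross-check the closed form.
#'
#' @inheritParams roc_at
#' @param n_nodes Number of quadrature nodes (>= 64 recommended).
#' @return AUROC in (0, 1).
#' @export
roc_auc_numeric <- function(object, profile = list(), n_nodes = 256) {
  co <- coef_from(object)
  stopifnot(n_nodes >= 4)
  # AUC = \int_0^1 ROC(q) dq = \int Phi(lp + a2 z) phi(z) dz over the real line
  gl <- gauss_legendre(n_nodes, -9, 9)
  lp <- linear_predictor(co, profile)
  a2 <- unname(co["probit_fpr"])
  sum(gl$w * pnorm(lp + a2 * gl$x) * dnorm(gl$x))
}

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenvalue
# construction of the Jacobi matrix.
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (b - a) / 2 * x[ord] + (a + b) / 2, w = (b - a) / 2 * w[ord])
}

#' Stratified bootstrap inference for a ROC regression
#'
#' Resamples cases and controls separately with replacement, refits the
#' probit ROC regression per replicate (recomputing placement values against
#' each control resample), and reports percentile 95% confidence intervals
#' with two-sided p-values from the normal approximation using the
#' bootstrap standard error. Deterministic for a fixed seed.
#'
#' @param fit A `roc_glm` fit.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level, default 0.95.
#' @return `fit` with components `bootstrap` (a tibble with one row per
#'   coefficient: estimate, conf.low, conf.high, p.value, method) and
#'   `bootstrap_draws` (B x p matrix of replicate coefficients).
#' @export
roc_glm_boot <- function(fit, B = 1000, seed, conf = 0.95) {
  stopifnot(inherits(fit, "roc_glm"))
  if (B < 100) abort("B must be at least 100")
  check_number(seed, "seed")
  n1 <- fit$n_cases
  n0 <- fit$n_controls
  m <- length(fit$grid)
  x_case <- if (length(fit$covariate_names)) fit$data$x_case else NULL
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, B, length(fit$coefficients),
                  dimnames = list(NULL, names(fit$coefficients)))
    for (b in seq_len(B)) {
      w1 <- tabulate(sample.int(n1, n1, replace = TRUE), nbins = n1)
      ctrl_b <- fit$data$y_ctrl[sample.int(n0, n0, replace = TRUE)]
      pv_b <- placement_values(fit$data$y_case, ctrl_b, ties = fit$ties)
      est <- tryCatch(
        probit_irls_fast(fit$grid, x_case, pv_b, w_case = w1,
                         start = unname(fit$coefficients),
                         maxit = 25, tol = 1e-7),
        error = function(e) NULL
      )
      if (!is.null(est) && est$converged && all(is.finite(est$beta)) &&
            max(abs(est$beta)) < 50) {
        out[b, ] <- est$beta
      }
    }
    out
  })
  failed <- rowSums(is.na(draws)) > 0
  if (mean(failed) > 0.10) {
    abort(paste0("bootstrap failure rate ", round(100 * mean(failed), 1),
                 "% exceeds 10%"))
  }
  draws_ok <- draws[!failed, , drop = FALSE]
  alpha <- 1 - conf
  est <- fit$coefficients
  se <- apply(draws_ok, 2, sd)
  fit$bootstrap <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    conf.low = apply(draws_ok, 2, stats::quantile, probs = alpha / 2,
                     names = FALSE),
    conf.high = apply(draws_ok, 2, stats::quantile, probs = 1 - alpha / 2,
                      names = FALSE),
    p.value = 2 * pnorm(-abs(unname(est) / unname(se))),
    method = "bootstrap_percentile"
  )
  fit$bootstrap_draws <- draws_ok
  fit$bootstrap_B <- B
  fit$bootstrap_failed <- sum(failed)
  fit
}

#' AUROC over a grid of covariate profiles
#'
#' Evaluates the closed-form covariate-specific AUROC at each row of a
#' profile table.
#'
#' @param object A `roc_glm` fit or named coefficient vector.
#' @param profiles A data frame with one column per model covariate and one
#'   row per profile.
#' @return `profiles` with an added `auc` column (empty in, empty out).
#' @export
auc_profile_table <- function(object, profiles) {
  stopifnot(is.data.frame(profiles))
  profiles <- tibble::as_tibble(profiles)
  profiles$auc <- if (nrow(profiles)) {
    vapply(seq_len(nrow(profiles)),
           function(i) roc_auc(object, profiles[i, , drop = FALSE]),
           numeric(1))
  } else {
    numeric(0)
  }
  profiles
}
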