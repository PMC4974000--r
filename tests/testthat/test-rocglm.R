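test_that("marker orientation negates thickness markers and is an involution", {
  spec <- marker_spec("rnfl_avg")
  expect_equal(orient_marker(c(80, 70), spec), c(-80, -70))
  up <- marker_spec("x", "higher_is_diseased")
  expect_equal(orient_marker(c(1, 2), up), c(1, 2))
  expect_equal(orient_marker(orient_marker(c(3, 4), spec), spec), c(3, 4))
})

test_that("FPR grids must be interior and strictly increasing", {
  g <- fpr_grid(100)
  expect_length(g, 100)
  expect_equal(g[1], 1 / 200)
  expect_true(all(g > 0 & g < 1))
  expect_error(fpr_grid(values = c(0, 0.5)), "strictly increasing")
  expect_error(fpr_grid(values = c(0.5, 0.5)), "strictly increasing")
  expect_error(fpr_grid(values = 0.3), "strictly increasing")
})

test_that("placement values match the brute-force count under both tie rules", {
  expect_equal(placement_values(2.5, c(1, 2, 3, 4)), 0.5)
  expect_equal(placement_values(9, c(1, 2, 3, 4)), 0)
  # a control exactly equal to the case counts under the inclusive rule
  expect_equal(placement_values(3, c(1, 2, 3, 4)), 0.5)
  expect_equal(placement_values(3, c(1, 2, 3, 4), ties = "strict"), 0.25)
  expect_error(placement_values(1, numeric(0)), "non-empty")

  set.seed(101)
  for (rep in 1:20) {
    ctrl <- round(rnorm(25), 1)   # rounding forces ties
    case <- round(rnorm(12), 1)
    expect_equal(placement_values(case, ctrl), pv_brute(case, ctrl, TRUE))
    expect_equal(placement_values(case, ctrl, ties = "strict"),
                 pv_brute(case, ctrl, FALSE))
  }
  # monotone non-increasing in the case value
  ctrl <- rnorm(50)
  case_sorted <- sort(rnorm(20))
  expect_true(all(diff(placement_values(case_sorted, ctrl)) <= 0))
})

test_that("indicator expansion has the right shape and monotone indicators", {
  g <- fpr_grid(values = c(0.25, 0.75))
  expect_equal(expand_indicators(0, g)$u, c(1L, 1L))
  expect_equal(expand_indicators(1, g)$u, c(0L, 0L))
  expect_equal(expand_indicators(0.5, g)$u, c(0L, 1L))
  tab <- expand_indicators(c(0.1, 0.6, 0.9), fpr_grid(10),
                           covariates = tibble::tibble(age = c(50, 60, 70)))
  expect_equal(nrow(tab), 30)
  expect_equal(tab$age, rep(c(50, 60, 70), each = 10))
  for (i in 1:3) expect_true(all(diff(tab$u[tab$case == i]) >= 0))
})

test_that("roc_at reduces to the chance line and is strictly increasing", {
  chance <- c("(Intercept)" = 0, probit_fpr = 1)
  q <- seq(0.05, 0.95, by = 0.05)
  expect_equal(roc_at(chance, q), q)
  co <- c("(Intercept)" = 0.8, probit_fpr = 0.7)
  expect_true(all(diff(roc_at(co, q)) > 0))
  expect_lt(roc_at(co, 0.2), roc_at(co, 0.8))
  expect_error(roc_at(co, 0), "open interval")
  expect_error(roc_at(co, 1), "open interval")
})

test_that("roc_at evaluates the reference average-RNFL model at q = 0.5", {
  co <- reference_coefficient_vector("rnfl_avg")
  prof <- baseline_profile()   # VFI 100, age 55, SE -2.15, AL 24.5, CODA 2
  # Phi(alpha1 + beta'x) at the probit midpoint; independent evaluation 0.8962
  expect_equal(roc_at(co, 0.5, prof), 0.8962, tolerance = 5e-4)
})

test_that("closed-form AUC matches quadrature to 1e-6 and is exact at chance", {
  expect_identical(roc_auc(c("(Intercept)" = 0, probit_fpr = 1)), 0.5)
  expect_identical(roc_auc(c("(Intercept)" = 0, probit_fpr = 2.3)), 0.5)
  set.seed(202)
  for (i in 1:100) {
    co <- c("(Intercept)" = rnorm(1, 0, 2), probit_fpr = runif(1, 0.2, 3),
            z1 = rnorm(1), z2 = rnorm(1, 0, 0.1))
    prof <- list(z1 = rnorm(1), z2 = rnorm(1, 0, 5))
    expect_equal(roc_auc(co, prof), roc_auc_numeric(co, prof, 256),
                 tolerance = 1e-6)
  }
  expect_error(roc_auc(c("(Intercept)" = 1, probit_fpr = -0.5)), "positive")
})

test_that("quadrature error shrinks as nodes are added", {
  co <- c("(Intercept)" = 1.2, probit_fpr = 0.6)
  exact <- roc_auc(co)
  errs <- vapply(c(8, 16, 32, 64),
                 function(n) abs(roc_auc_numeric(co, n_nodes = n) - exact),
                 numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[4], 1e-10)
})

test_that("the probit engines agree with glm.fit on the same likelihood", {
  set.seed(303)
  n <- 80
  x <- cbind(sev = rnorm(n, 0, 1))
  pv <- runif(n)^1.5
  grid <- fpr_grid(20)
  ref <- octroc:::fit_indicator_probit(pv, grid, x)
  alt <- octroc:::fit_indicator_probit(pv, grid, x, engine = "irls")
  expect_equal(alt$coefficients, ref$coefficients, tolerance = 1e-5)
  fast <- octroc:::probit_irls_fast(grid, x, pv,
                                    start = rep(0, 3))
  expect_equal(unname(ref$coefficients), fast$beta, tolerance = 1e-5)
  # and with non-uniform case weights (the bootstrap configuration)
  w <- rpois(n, 1)
  ref_w <- octroc:::fit_indicator_probit(pv, grid, x, weights = w)
  fast_w <- octroc:::probit_irls_fast(grid, x, pv, w_case = w,
                                      start = unname(ref_w$coefficients) * 0.9)
  expect_equal(unname(ref_w$coefficients), fast_w$beta, tolerance = 1e-5)
})

test_that("covariate-free fits recover binormal truth within Monte-Carlo error", {
  # truth alpha1 = 1, alpha2 = 1 at n = 2000/1000; across 30 independent
  # cohorts the estimator spread is SD(alpha1) = 0.035, SD(alpha2) = 0.026
  # (measured by direct simulation), so 3-SD bands are 0.11 / 0.08
  tr <- synthetic_truth(1, 1, marker = "gcipl_avg",
                        n_cases = 2000, n_controls = 1000)
  co <- generate_cohort(tr, seed = 77)
  fit <- roc_glm(co, "gcipl_avg")
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha1 - 1), 0.11)
  expect_lt(abs(fit$alpha2 - 1), 0.08)
  # model-based AUC agrees with the empirical Mann-Whitney AUC
  a_model <- roc_auc(fit)
  a_emp <- auc_mann_whitney(-co$gcipl_avg[co$group == "glaucoma"],
                            -co$gcipl_avg[co$group == "control"])
  expect_lt(abs(a_model - a_emp), 0.02)
})

test_that("a constant marker triggers a degeneracy warning, not an error", {
  co <- toy_cohort(10, 10)
  co$gcipl_avg <- 70
  expect_warning(fit <- roc_glm(co, "gcipl_avg"),
                 "quasi-separation|did not converge")
  expect_s3_class(fit, "roc_glm")
})

test_that("bootstrap inference is deterministic and stable in B", {
  tr <- synthetic_truth(1.2, 0.9, betas = c(age = 0),
                        marker = "gcipl_avg", n_cases = 120, n_controls = 60)
  co <- generate_cohort(tr, seed = 5)
  fit <- roc_glm(co, "gcipl_avg", covariates = "age", grid = fpr_grid(25))
  b1 <- roc_glm_boot(fit, B = 150, seed = 9)
  b2 <- roc_glm_boot(fit, B = 150, seed = 9)
  expect_identical(b1$bootstrap, b2$bootstrap)
  expect_s3_class(b1$bootstrap, "tbl_df")
  expect_true(all(b1$bootstrap$conf.low <= b1$bootstrap$estimate + 1e-9))
  expect_true(all(b1$bootstrap$conf.high >= b1$bootstrap$estimate - 1e-9))
  # doubling B moves endpoints by no more than Monte-Carlo noise
  b3 <- roc_glm_boot(fit, B = 300, seed = 9)
  noise <- 4 * b1$bootstrap$std.error / sqrt(150)
  expect_true(all(abs(b3$bootstrap$conf.low - b1$bootstrap$conf.low) <
                    pmax(noise * 6, 0.05)))
  expect_error(roc_glm_boot(fit, B = 50, seed = 1), "at least 100")
})

test_that("tidy and glance expose the fit in broom style", {
  tr <- synthetic_truth(1, 1, betas = c(age = 0.01), marker = "rnfl_avg",
                        n_cases = 100, n_controls = 50)
  co <- generate_cohort(tr, seed = 31)
  fit <- roc_glm(co, "rnfl_avg", covariates = "age", grid = fpr_grid(25))
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "probit_fpr", "age"))
  expect_equal(unique(td$method), "naive_probit_invalid")
  gl <- glance(fit)
  expect_equal(gl$n_cases, 100)
  expect_equal(gl$n_controls, 50)
  expect_true(gl$converged)
  fitb <- roc_glm_boot(fit, B = 100, seed = 2)
  expect_equal(unique(tidy(fitb)$method), "bootstrap_percentile")
  plt <- autoplot(fitb, baseline_profile()["age"])
  expect_s3_class(plt, "ggplot")
})

test_that("AUC profile tables evaluate the closed form per row", {
  co <- reference_coefficient_vector("gcipl_avg")
  profs <- baseline_profile(vfi = c(100, 70))
  tab <- auc_profile_table(co, profs)
  expect_equal(tab$auc[1], roc_auc(co, profs[1, ]))
  expect_equal(tab$auc[2], roc_auc(co, profs[2, ]))
  empty <- auc_profile_table(co, profs[0, ])
  expect_equal(nrow(empty), 0)
  single <- auc_profile_table(co, baseline_profile())
  expect_equal(single$auc, roc_auc(co, baseline_profile()))
})

test_that("negative covariate coefficients imply decreasing AUC", {
  co <- reference_coefficient_vector("gcipl_min")   # beta_vfi < 0
  aucs <- auc_profile_table(co, baseline_profile(vfi = c(70, 80, 90, 100)))$auc
  expect_true(all(diff(aucs) < 0))
})
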