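test_that("pooled Student t behaves at the identities and boundaries", {
  x <- c(1, 2, 3, 4)
  same <- student_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(same$df, 6)
  expect_error(student_t(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(student_t(1, c(1, 2)), "at least 2")
})

test_that("summary-statistic t equals the raw-data t to numerical precision", {
  set.seed(11)
  for (rep in 1:10) {
    a <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2))
    b <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 2))
    raw <- student_t(a, b)
    summ <- student_t_summary(mean(a), sd(a), length(a),
                              mean(b), sd(b), length(b))
    expect_equal(summ$statistic, raw$statistic, tolerance = 1e-12)
    expect_equal(summ$p.value, raw$p.value, tolerance = 1e-12)
  }
})

test_that("the axial-length group comparison reproduces from summaries", {
  res <- student_t_summary(24.69, 1.48, 173, 24.12, 1.58, 63)
  expect_lt(abs(res$p.value - 0.011), 5e-4)
})

test_that("Fisher exact p follows the minimum-likelihood convention", {
  # female/male counts by group
  expect_equal(fisher_exact_2x2(matrix(c(86, 33, 87, 30), 2))$p.value,
               0.769, tolerance = 5e-4)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  # fully crossed table: oracle by direct hypergeometric enumeration
  tab <- matrix(c(10, 0, 0, 10), 2)
  probs <- dhyper(0:10, 10, 10, 10)
  oracle <- sum(probs[probs <= dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  got <- fisher_exact_2x2(tab)$p.value
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_lt(got, 0.001)
  # transposition and simultaneous row/column swap invariance
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(rpois(4, 8), 2)
    p0 <- fisher_exact_2x2(m)$p.value
    expect_equal(fisher_exact_2x2(t(m))$p.value, p0)
    expect_equal(fisher_exact_2x2(m[2:1, 2:1])$p.value, p0)
  }
  expect_message(p_zero <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))$p.value,
                 "zero margin")
  expect_equal(p_zero, 1)
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("Pearson correlation matches known identities and sampling", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x), 1)
  expect_equal(pearson_r(x, -x + 3), -1)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  set.seed(33)
  z <- matrix(rnorm(2e4), ncol = 2)
  y <- -0.3 * z[, 1] + sqrt(1 - 0.09) * z[, 2]
  expect_lt(abs(pearson_r(z[, 1], y) - (-0.3)), 0.03)
})

test_that("the characteristics table runs both test families per variable", {
  tr <- synthetic_truth_reference("gcipl_avg", n_cases = 150, n_controls = 80)
  co <- add_corrected_disc_area(generate_cohort(tr, seed = 8))
  tab <- table_one(co)
  expect_true(all(c("sex") %in% tab$variable[tab$test == "fisher_exact"]))
  expect_true("axial_length" %in% tab$variable[tab$test == "student_t"])
  expect_true(all(tab$p.value >= 0 & tab$p.value <= 1))
  expect_equal(unique(tab$n_case[tab$type == "continuous"]), 150)
  # a deliberately shifted variable dominates the evidence
  co2 <- co
  co2$axial_length <- co2$axial_length +
    ifelse(co2$group == "glaucoma", 3, 0)
  demo_vars <- tibble::tibble(
    variable = c("age", "iop", "spherical_equivalent", "axial_length"),
    type = "continuous")
  tab2 <- table_one(co2, demo_vars)
  expect_equal(tab2$variable[which.min(tab2$p.value)], "axial_length")
  # single-variable spec gives a single row; unknown names are config errors
  one <- table_one(co, tibble::tibble(variable = "age", type = "continuous"))
  expect_equal(nrow(one), 1)
  expect_error(table_one(co, tibble::tibble(variable = "nope",
                                            type = "continuous")),
               "unknown variable")
})

test_that("group-identical simulated data yields well-spread p-values", {
  # same distribution in both groups: across 40 null replicates the
  # age-row p-value should not concentrate near 0
  dists <- covariate_distributions()
  dists$mean[dists$covariate == "age"] <- 55
  dists$sd[dists$covariate == "age"] <- 11.3
  tr <- synthetic_truth(1, 1, marker = "gcipl_avg",
                        n_cases = 60, n_controls = 60)
  ps <- vapply(1:40, function(r) {
    co <- generate_cohort(tr, dists, seed = 9000 + r)
    student_t(co$age[co$group == "glaucoma"],
              co$age[co$group == "control"])$p.value
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.2)       # null rejection rate stays near 5%
  expect_gt(mean(ps), 0.3)              # p-values roughly uniform
})
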