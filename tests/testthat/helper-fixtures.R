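# Shared fixtures: tiny cohorts, pattern-deviation maps, brute-force oracles.

toy_cohort <- function(n_case = 3, n_ctrl = 3) {
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n_case + n_ctrl)),
    eye = rep(c("OD", "OS"), length.out = n_case + n_ctrl),
    group = rep(c("glaucoma", "control"), c(n_case, n_ctrl)),
    age = 50 + seq_len(n_case + n_ctrl),
    sex = rep(c("female", "male"), length.out = n_case + n_ctrl),
    bcva_logmar = 0.05,
    iop = 14,
    spherical_equivalent = -2,
    cylinder = -0.5,
    axial_length = 24.5,
    md = c(rep(-5, n_case), rep(-0.5, n_ctrl)),
    psd = c(rep(6, n_case), rep(1.8, n_ctrl)),
    vfi = c(rep(88, n_case), rep(99, n_ctrl)),
    disc_area_measured = 2.0,
    rnfl_avg = c(rep(75, n_case), rep(93, n_ctrl)) + seq_len(n_case + n_ctrl),
    gcipl_avg = c(rep(70, n_case), rep(80, n_ctrl)) + seq_len(n_case + n_ctrl),
    gcipl_min = c(rep(60, n_case), rep(77, n_ctrl)) + seq_len(n_case + n_ctrl),
    signal_strength_macula = 8,
    signal_strength_disc = 8,
    vf_fixation_loss = 5,
    vf_false_positive = 5
  )
}

write_toy_csv <- function(cohort, path = withr::local_tempfile(fileext = ".csv",
                                                              .local_envir = parent.frame())) {
  readr::write_csv(cohort, path)
  path
}

# pattern deviation map from (x, y, category) triples
pd_map <- function(...) {
  pts <- list(...)
  tibble::tibble(
    x_deg = vapply(pts, function(p) as.numeric(p[[1]]), numeric(1)),
    y_deg = vapply(pts, function(p) as.numeric(p[[2]]), numeric(1)),
    p_category = vapply(pts, function(p) as.character(p[[3]]), character(1))
  )
}

# brute-force placement values (independent of the findInterval path)
pv_brute <- function(case, ctrl, inclusive = TRUE) {
  vapply(case, function(v) {
    if (inclusive) mean(ctrl >= v) else mean(ctrl > v)
  }, numeric(1))
}

# empirical AUC: Mann-Whitney with ties counted half (oriented values)
auc_mann_whitney <- function(case, ctrl) {
  cmp <- outer(case, ctrl, ">") + 0.5 * outer(case, ctrl, "==")
  mean(cmp)
}

table3_profile <- function(vfi) {
  baseline_profile(vfi = vfi)
}
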