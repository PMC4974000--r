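test_that("the packaged 30-2 grid has the standard layout", {
  grid <- vf_grid_30_2()
  expect_equal(nrow(grid), 76)
  expect_equal(sum(grid$is_blind_spot), 2)
  expect_setequal(grid$y_deg[grid$is_blind_spot], c(-3, 3))
  expect_true(all(grid$x_deg[grid$is_blind_spot] == 15))
  # 6-degree lattice offset 3 degrees from the meridians
  expect_true(all((abs(grid$x_deg) - 3) %% 6 == 0))
  expect_true(all((abs(grid$y_deg) - 3) %% 6 == 0))
  # interior points exist on both sides of the midline
  expect_true(any(!grid$is_edge & grid$y_deg > 0))
  expect_true(any(!grid$is_edge & grid$y_deg < 0))
})

test_that("reliability requires fixation loss < 20% and false positives < 33%", {
  expect_true(vf_reliable(19.9, 32.9))
  expect_false(vf_reliable(20, 10))
  expect_false(vf_reliable(10, 33))
  expect_true(vf_reliable(0, 0))
  expect_equal(vf_reliable(c(5, 25), c(5, 5)), c(TRUE, FALSE))
  expect_error(vf_reliable(120, 5), "percentages")
})

test_that("defect clusters require >=3 contiguous non-edge points with a <1% member", {
  # three mutually adjacent interior points, one at <1%
  m1 <- pd_map(c(3, 9, "<2%"), c(9, 9, "<2%"), c(3, 15, "<1%"))
  cl <- vf_defect_clusters(m1)
  expect_equal(nrow(cl), 3)
  expect_equal(unique(cl$cluster), 1L)

  # same cluster but no point reaching <1%: not a defect
  m2 <- pd_map(c(3, 9, "<2%"), c(9, 9, "<2%"), c(3, 15, "<2%"))
  expect_equal(nrow(vf_defect_clusters(m2)), 0)

  # one of the three on the edge ring: too small once edges are removed
  m3_edge <- pd_map(c(3, 21, "<1%"), c(3, 27, "<2%"), c(9, 21, "<2%"))
  grid <- vf_grid_30_2()
  expect_true(grid$is_edge[grid$x_deg == 3 & grid$y_deg == 27])
  expect_equal(nrow(vf_defect_clusters(m3_edge)), 0)

  # only two contiguous points: too small
  m4 <- pd_map(c(3, 9, "<1%"), c(9, 9, "<2%"))
  expect_equal(nrow(vf_defect_clusters(m4)), 0)

  # >=5% points never participate
  m5 <- pd_map(c(3, 9, ">=5%"), c(9, 9, "<2%"), c(3, 15, "<1%"))
  expect_equal(nrow(vf_defect_clusters(m5)), 0)

  # unknown coordinates are an input error
  expect_error(vf_defect_clusters(pd_map(c(0, 0, "<1%"))), "not on the 30-2")
})

test_that("clusters may not span the horizontal midline unless allowed", {
  m <- pd_map(c(3, 3, "<1%"), c(3, -3, "<2%"), c(9, 3, "<2%"), c(9, -3, "<2%"))
  split_cl <- vf_defect_clusters(m)
  # hemifield rule: two pairs, neither of size 3
  expect_equal(nrow(split_cl), 0)
  joined <- vf_defect_clusters(m, span_midline = TRUE)
  expect_equal(nrow(joined), 4)
  expect_equal(unique(joined$cluster), 1L)
})

test_that("clusters are maximal, disjoint, and invariant to point order", {
  set.seed(404)
  m <- pd_map(
    c(3, 9, "<2%"), c(9, 9, "<1%"), c(15, 9, "<2%"),
    c(-15, -9, "<2%"), c(-9, -9, "<2%"), c(-9, -15, "<0.5%")
  )
  cl <- vf_defect_clusters(m)
  expect_equal(dplyr::n_distinct(cl$cluster), 2)
  expect_equal(nrow(cl), 6)
  # no adjacent pair across different clusters
  pairs <- expand.grid(i = seq_len(nrow(cl)), j = seq_len(nrow(cl)))
  cross <- with(pairs, cl$cluster[i] != cl$cluster[j] &
                  abs(cl$x_deg[i] - cl$x_deg[j]) <= 6 &
                  abs(cl$y_deg[i] - cl$y_deg[j]) <= 6 &
                  sign(cl$y_deg[i]) == sign(cl$y_deg[j]))
  expect_false(any(cross))
  # permutation invariance
  perm <- m[sample(nrow(m)), ]
  cl_perm <- vf_defect_clusters(perm)
  key <- function(d) sort(paste(d$x_deg, d$y_deg))
  expect_identical(key(cl_perm), key(cl))
})

test_that("glaucomatous classification is the cluster/GHT disjunction", {
  empty <- pd_map()[0, ]
  no_depress <- pd_map(c(3, 9, ">=5%"))
  cluster <- pd_map(c(3, 9, "<2%"), c(9, 9, "<2%"), c(3, 15, "<1%"))
  expect_true(vf_classify_glaucomatous(no_depress, "outside normal limits"))
  expect_false(vf_classify_glaucomatous(no_depress, "within normal limits"))
  expect_true(vf_classify_glaucomatous(cluster, "within normal limits"))
  expect_true(vf_classify_glaucomatous(cluster, "outside normal limits"))
  expect_false(vf_classify_glaucomatous(empty, "borderline"))
  expect_error(vf_classify_glaucomatous(empty, "bogus state"))
})

test_that("defect confirmation needs two reliable positive examinations", {
  two_good <- tibble::tibble(defect = c(TRUE, TRUE),
                             fixation_loss = c(5, 10),
                             false_positive = c(5, 10))
  expect_true(vf_confirmed_defect(two_good))
  one_unreliable <- tibble::tibble(defect = c(TRUE, TRUE),
                                   fixation_loss = c(5, 25),
                                   false_positive = c(5, 5))
  expect_false(vf_confirmed_defect(one_unreliable))
  single <- tibble::tibble(defect = TRUE, reliable = TRUE)
  expect_false(vf_confirmed_defect(single))
  mixed <- tibble::tibble(defect = c(TRUE, FALSE, TRUE),
                          reliable = c(TRUE, TRUE, TRUE))
  expect_true(vf_confirmed_defect(mixed))
  expect_error(vf_confirmed_defect(two_good[0, ]), "at least one")
})
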