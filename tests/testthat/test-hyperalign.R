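toy_src <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2, byrow = TRUE)
toy_tgt <- matrix(c(-24, 16, -45, 35, -66, 54), ncol = 2, byrow = TRUE)
rot90 <- matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE)  # (x, y) -> (-y, x)

test_that("the scale-translate-rotate toy alignment lands at distance 2", {
  tf <- procrustes_transform(rot90, scale = 10, translation = c(5, 5))
  moved <- apply_transform(toy_src, tf)
  expect_equal(moved, matrix(c(-25, 15, -45, 35, -65, 55), ncol = 2,
                             byrow = TRUE))
  expect_equal(procrustes_distance(moved, toy_tgt), 2)

  ident <- procrustes_transform(diag(2))
  expect_equal(apply_transform(toy_src, ident), toy_src)
  expect_equal(apply_transform(matrix(c(1, 0), 1),
                               procrustes_transform(diag(2), scale = 2)),
               matrix(c(2, 0), 1))
  expect_error(apply_transform(toy_src, procrustes_transform(diag(3))),
               "mismatch")
})

test_that("the Procrustes distance is the root-sum-square metric", {
  expect_equal(procrustes_distance(toy_src, toy_src), 0)
  b <- toy_src; b[2, 1] <- b[2, 1] + 3
  expect_equal(procrustes_distance(toy_src, b), 3)
  expect_error(procrustes_distance(toy_src, matrix(0, 2, 2)), "mismatch")

  set.seed(81)
  for (i in 1:5) {
    x <- matrix(rnorm(12), 4); y <- matrix(rnorm(12), 4)
    z <- matrix(rnorm(12), 4)
    expect_equal(procrustes_distance(x, y), procrustes_distance(y, x))
    expect_lte(procrustes_distance(x, z),
               procrustes_distance(x, y) + procrustes_distance(y, z) + 1e-12)
  }
})

test_that("Procrustes fitting recovers planted transforms", {
  # self-alignment: scale 1 and zero residual (the collinear toy leaves the
  # rotation underdetermined, so only the fit quality is pinned)
  fit0 <- procrustes_fit(toy_src, toy_src)
  expect_equal(fit0$scale, 1, tolerance = 1e-10)
  expect_lt(procrustes_distance(apply_transform(toy_src, fit0), toy_src), 1e-8)
  set.seed(80)
  full <- matrix(rnorm(10 * 3), 10, 3)
  fitf <- procrustes_fit(full, full)
  expect_lt(max(abs(fitf$rotation - diag(3))), 1e-8)
  expect_lt(max(abs(fitf$translation)), 1e-8)

  set.seed(82)
  for (i in 1:5) {
    src <- matrix(rnorm(8 * 3), 8, 3)
    QR <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(QR) %*% diag(sign(diag(qr.R(QR))), 3)
    tf <- procrustes_transform(R, runif(1, 0.5, 3), rnorm(3))
    tgt <- apply_transform(src, tf)
    fit <- procrustes_fit(src, tgt)
    expect_lt(procrustes_distance(apply_transform(src, fit), tgt), 1e-8)
  }

  # the optimal fit does at least as well as the illustrative hand transform
  fit <- procrustes_fit(toy_src, toy_tgt)
  expect_lte(procrustes_distance(apply_transform(toy_src, fit), toy_tgt), 2)

  expect_error(procrustes_fit(matrix(1, 4, 2), matrix(rnorm(8), 4, 2)),
               "degenerate")

  # fit-then-apply never increases the distance on the fitting pair
  set.seed(83)
  a <- matrix(rnorm(20), 5, 4); b <- matrix(rnorm(20), 5, 4)
  f <- procrustes_fit(a, b)
  expect_lte(procrustes_distance(apply_transform(a, f), b),
             procrustes_distance(a, b))
})

test_that("zero padding widens matrices reversibly", {
  rm0 <- response_matrix(matrix(rnorm(50), 10, 5), subject = "S1")
  expect_identical(pad_to_dimension(rm0, 5), rm0)
  pad <- pad_to_dimension(rm0, 8)
  expect_equal(pad$q, 8)
  expect_true(all(pad$data[, 6:8] == 0))
  expect_equal(pad$data[, 1:5], rm0$data)
  expect_equal(pad$original_q, 5)
  expect_error(pad_to_dimension(rm0, 3), "wider")
})

test_that("hyperalignment aligns exact transformed copies to a common space", {
  set.seed(84)
  common <- response_matrix(matrix(rnorm(30 * 8), 30, 8), subject = "COMMON")
  gs <- gen_subjects(common, 3, noise_sd = 0, seed = 85)
  cs <- hyperalign(gs$subjects, iterations = 3)
  aligned <- lapply(gs$subjects, function(s)
    apply_transform(pad_to_dimension(s, cs$d)$data, cs$transforms[[s$subject]]))
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(procrustes_distance(aligned[[i]], aligned[[j]]), 1e-6)
  # residual log is non-increasing on noise-free inputs
  expect_true(all(diff(cs$residual_log) <= 1e-8))

  # single subject: common space is its own data
  cs1 <- hyperalign(gs$subjects[1])
  expect_lt(procrustes_distance(
    apply_transform(gs$subjects[[1]]$data, cs1$transforms[[1]]), cs1$common),
    1e-6)

  # unequal voxel counts: dimensionality is the per-ROI maximum
  qs <- c(81, 90, 128)
  common2 <- response_matrix(matrix(rnorm(20 * 128), 20, 128))
  gs2 <- gen_subjects(common2, 3, noise_sd = 0, truncate_q = qs, seed = 86)
  cs2 <- hyperalign(gs2$subjects, iterations = 2)
  expect_equal(cs2$d, 128)

  bad <- gs$subjects
  bad[[2]] <- response_matrix(matrix(rnorm(29 * 8), 29, 8), subject = "S2")
  expect_error(hyperalign(bad), "mismatch")
})

test_that("projection averages transformed subjects for both splits", {
  set.seed(87)
  common_tr <- response_matrix(matrix(rnorm(24 * 6), 24, 6), split = "train")
  gs <- gen_subjects(common_tr, 2, noise_sd = 0, seed = 88)
  cs <- hyperalign(gs$subjects)
  pr1 <- project(gs$subjects[1], test = NULL, cs = cs)
  expect_equal(pr1$train$data,
               apply_transform(gs$subjects[[1]]$data, cs$transforms[["S1"]]),
               tolerance = 1e-12)

  # identical subjects: the mean equals any one transformed subject
  twin <- gs$subjects[[1]]
  twin2 <- response_matrix(twin$data, subject = "S2")
  cs2 <- hyperalign(list(twin, twin2))
  pr2 <- project(list(twin, twin2), test = NULL, cs = cs2)
  expect_equal(pr2$train$data,
               apply_transform(pad_to_dimension(twin, cs2$d)$data,
                               cs2$transforms[["S1"]]),
               tolerance = 1e-8)

  # noisy rotated subjects: the mean hyperaligned data tracks the source
  # better than either unaligned subject does
  set.seed(89)
  src <- matrix(rnorm(120 * 6), 120, 6)
  subs3 <- lapply(1:2, function(i) {
    QR <- qr(matrix(rnorm(36), 6, 6))
    R <- qr.Q(QR) %*% diag(sign(diag(qr.R(QR))), 6)
    response_matrix(src %*% R + matrix(rnorm(120 * 6, 0, 0.6), 120, 6),
                    subject = paste0("S", i))
  })
  cs3 <- hyperalign(subs3, iterations = 2)
  pr3 <- project(subs3, test = NULL, cs = cs3)
  fit_back <- procrustes_fit(pr3$train$data, src)
  r_mean <- cor(as.vector(apply_transform(pr3$train$data, fit_back)),
                as.vector(src))
  r_subj <- vapply(subs3, function(s) {
    fb <- procrustes_fit(s$data, src)
    cor(as.vector(apply_transform(s$data, fb)), as.vector(src))
  }, numeric(1))
  expect_gt(r_mean, max(r_subj))

  missing <- response_matrix(matrix(rnorm(24 * 6), 24, 6), subject = "S9")
  expect_error(project(list(missing), test = NULL, cs = cs), "S9")
})
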