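test_that("image generation is reproducible and clutter drives complexity", {
  g1 <- gen_images(3, clutter_range = c(0, 30), size = 64, seed = 5)
  g2 <- gen_images(3, clutter_range = c(0, 30), size = 64, seed = 5)
  expect_identical(g1$images, g2$images)
  expect_length(g1$images, 3)
  expect_length(g1$clutter, 3)

  lo <- gen_images(1, clutter_range = c(0, 0), size = 128, seed = 6)
  hi <- gen_images(1, clutter_range = c(50, 50), size = 128, seed = 6)
  gl <- gradient_complexity(rgb_to_lab(lo$images[[1]]))
  gh <- gradient_complexity(rgb_to_lab(hi$images[[1]]))
  expect_lt(gl, gh)

  # rank correlation between clutter and gradient/PNG measures is positive
  gs <- gen_images(12, clutter_range = c(0, 50), size = 128, seed = 7)
  tab <- visual_complexity_table(gs$images, size = 128)
  expect_gt(cor(gs$clutter, tab$gradient, method = "spearman"), 0)
  expect_gt(cor(gs$clutter, tab$png_bytes, method = "spearman"), 0)
})

test_that("audio generation is reproducible and rate-ordered", {
  a1 <- gen_audio(2, duration = 5, seed = 8)
  a2 <- gen_audio(2, duration = 5, seed = 8)
  expect_identical(a1$clips[[1]]$samples, a2$clips[[1]]$samples)

  lo <- gen_audio(1, rate_range = c(1, 1), duration = 20, seed = 9)
  hi <- gen_audio(1, rate_range = c(6, 6), duration = 20, seed = 9)
  expect_lt(event_density(lo$clips[[1]]), event_density(hi$clips[[1]]))

  silent <- gen_audio(1, rate_range = c(0, 0), duration = 2, noise_sd = 0,
                      seed = 10)
  expect_true(all(silent$clips[[1]]$samples == 0))
})

test_that("planted responses have the configured slope and sign structure", {
  set.seed(11)
  x <- rnorm(40); x <- (x - mean(x)) / pop_sd_test(x)

  sl <- plant_slopes(list(A = list(q = 1000, slope = 0.5, neg_frac = 0.5)),
                     seed = 12)$A
  expect_equal(mean(sl < 0), 0.5, tolerance = 0.05)
  expect_true(all(abs(sl) >= 0.5 * 0.75 - 1e-12 & abs(sl) <= 0.5 * 1.25))

  rm0 <- gen_responses(x, sl[1:5], noise_sd = 0, seed = 13)
  for (v in 1:5) expect_equal(rm0$data[, v], sl[v] * x, tolerance = 1e-12)

  # planted ROI slope-magnitude ordering is recovered by mean |beta|
  sl2 <- plant_slopes(list(hi = list(q = 40, slope = 0.8, neg_frac = 0.2),
                           lo = list(q = 40, slope = 0.2, neg_frac = 0.2)),
                      seed = 14)
  mb <- vapply(sl2, function(s) {
    Y <- gen_responses(x, s, noise_sd = 1, seed = 15)$data
    mean(abs(encode_roi(x, scale(Y, scale = apply(Y, 2, pop_sd_test)))))
  }, numeric(1))
  expect_gt(mb["hi"], mb["lo"])
})

test_that("subject synthesis inverts cleanly under hyperalignment", {
  common <- response_matrix(matrix(rnorm(25 * 6), 25, 6))
  gs <- gen_subjects(common, 3, noise_sd = 0, seed = 16)
  cs <- hyperalign(gs$subjects, iterations = 2)
  aligned <- lapply(gs$subjects, function(s)
    apply_transform(s$data, cs$transforms[[s$subject]]))
  expect_lt(procrustes_distance(aligned[[1]], aligned[[2]]), 1e-6)
  expect_lt(procrustes_distance(aligned[[2]], aligned[[3]]), 1e-6)

  one <- gen_subjects(common, 1, seed = 17)
  expect_length(one$subjects, 1)

  trunc <- gen_subjects(common, 2, truncate_q = c(6, 4), seed = 18)
  expect_equal(trunc$subjects[[2]]$q, 4)
  pad <- pad_to_dimension(trunc$subjects[[2]], 6)
  expect_equal(pad$q, 6)
  expect_equal(pad$data[, 1:4], trunc$subjects[[2]]$data)
})

test_that("tag clustering recovers planted blocks and ranks members", {
  gt <- gen_tag_matrix(k = 16, per_cluster = 9, n_tags = 136, seed = 19)
  sel <- cluster_select_stimuli(gt$tags, k = 16, per_cluster_train = 8)
  # recovered clusters equal planted blocks
  tab <- table(gt$blocks, sel$cluster)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(sum(sel$assignment == "test"), 16)
  expect_equal(sum(sel$assignment == "train"), 128)

  # duplicated rows co-cluster
  expect_true(all(tapply(sel$cluster, gt$blocks,
                         function(z) length(unique(z))) == 1))

  # k = number of stimuli: every stimulus its own cluster, all test
  small <- gen_tag_matrix(k = 4, per_cluster = 1, n_tags = 30, seed = 20)
  sel2 <- cluster_select_stimuli(small$tags, k = 4, per_cluster_train = 1)
  expect_true(all(sel2$assignment == "test"))

  expect_error(cluster_select_stimuli(matrix(0, 3, 4), k = 2), "all-zero")
})

test_that("responses driven by measured image complexity are decodable", {
  # end-to-end: images -> gradient measure -> planted responses -> decoding
  gs <- gen_images(36, clutter_range = c(0, 50), size = 64, seed = 21)
  grad <- vapply(gs$images, function(im)
    gradient_complexity(rgb_to_lab(im)), numeric(1))
  is_tr <- rep(c(TRUE, FALSE), c(27, 9))
  mx <- mean(grad[is_tr]); sx <- pop_sd_test(grad[is_tr])
  x <- (grad - mx) / sx

  sl <- plant_slopes(list(on = list(q = 16, slope = 0.6, neg_frac = 0.2),
                          off = list(q = 16, slope = 0, neg_frac = 0)),
                     seed = 22)
  for (roi in c("on", "off")) {
    Ytr <- gen_responses(x[is_tr], sl[[roi]], noise_sd = 1, seed = 23)$data
    Yte <- gen_responses(x[!is_tr], sl[[roi]], noise_sd = 1, seed = 24)$data
    std <- standardize_pair(list(x = x[is_tr], Y = Ytr),
                            list(x = x[!is_tr], Y = Yte))
    sv <- svd(std$train$Y)
    pt <- permutation_test(
      function(tr, te) {
        m <- fit_decoding(tr$Y, tr$x, sv = sv)
        evaluate(m, te$x, te$Y)$r
      },
      train = list(x = std$train$x, Y = std$train$Y),
      test = list(x = std$test$x, Y = std$test$Y),
      reps = 120, seed = 25)
    if (roi == "on") expect_lte(pt$p, 0.05) else expect_gt(pt$p, 0.05)
  }
})
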