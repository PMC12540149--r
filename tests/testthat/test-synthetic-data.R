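test_that("patches have the requested geometry and value range", {
  cfg <- tiny_generator(side = 100L)
  for (cl in nbi_classes()) {
    set.seed(2)
    p <- generate_patch(cl, cfg)
    expect_equal(dim(p), c(100L, 100L, 3L))
    expect_true(min(p) >= 0 && max(p) <= 255)
  }
})

test_that("texture families are statistically distinct", {
  cfg <- tiny_generator(side = 64L, noise = 0)
  set.seed(9); he <- generate_patch("He", cfg)
  set.seed(9); hbv <- generate_patch("Hbv", cfg)
  # healthy tissue is the low-variance family by construction
  expect_lt(var(as.vector(he)), var(as.vector(hbv)))
  means <- sapply(nbi_classes(), function(cl) {
    set.seed(4)
    colMeans(apply(generate_patch(cl, cfg), 3, as.vector))
  })
  # mean-RGB centroids pairwise well separated
  d <- as.matrix(dist(t(means)))
  expect_gt(min(d[upper.tri(d)]), 10)
})

test_that("salt-and-pepper corruption touches exactly the noised pixels", {
  side <- 48L
  clean_cfg <- tiny_generator(side = side, noise = 0)
  noisy_cfg <- tiny_generator(side = side, noise = 0.2)
  set.seed(31); clean <- generate_patch("IPCL", clean_cfg)
  set.seed(31); noisy <- generate_patch("IPCL", noisy_cfg)
  differs <- apply(clean != noisy, c(1, 2), any)
  extreme <- noisy[, , 1] %in% c(0, 255) &
    noisy[, , 2] %in% c(0, 255) & noisy[, , 3] %in% c(0, 255)
  dim(extreme) <- c(side, side)
  # every differing pixel is an injected extreme, and vice versa (clean
  # values are clamped to [1, 254], so injection always changes the pixel)
  expect_true(all(differs == extreme))
  frac <- mean(differs)
  expect_gt(frac, 0.12); expect_lt(frac, 0.28)
})

test_that("unknown labels and degenerate sizes are rejected", {
  expect_error(generate_patch("Tumor", tiny_generator()),
               class = "nbi_bad_label")
  expect_error(generator_config(patch_side = 8), class = "nbi_bad_config")
  expect_error(generator_config(noise_fraction = 1.5),
               class = "nbi_bad_config")
})

test_that("generated datasets are balanced, split and reproducible", {
  cfg <- tiny_generator(per_class = 5L, side = 32L, noise = 0.05, seed = 7L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(cfg, d1)
  m2 <- generate_dataset(cfg, d2)
  expect_equal(nrow(m1), 20L)
  expect_equal(unname(table(m1$class_label)), array(rep(5L, 4)),
               ignore_attr = TRUE)
  expect_true(all(file.exists(m1$file_path)))
  expect_false(anyDuplicated(m1$image_id) > 0)
  # same seed twice: identical manifests (modulo paths) and pixel data
  expect_equal(m1[c("image_id", "class_label", "split")],
               m2[c("image_id", "class_label", "split")])
  expect_identical(read_patch(m1$file_path[1]), read_patch(m2$file_path[1]))
  # manifest round-trips through its CSV
  expect_equal(read_manifest(file.path(d1, "manifest.csv"))$image_id,
               m1$image_id)
})

test_that("split proportions are stratified within rounding", {
  cfg <- tiny_generator(per_class = 20L, side = 32L)
  m <- generate_dataset(cfg, withr::local_tempdir())
  per <- table(m$class_label, m$split)
  expect_true(all(per[, "train"] == 14L))
  expect_true(all(per[, "val"] == 3L))
  expect_true(all(per[, "test"] == 3L))
})

test_that("a nearest-centroid classifier on mean RGB beats chance", {
  cfg <- tiny_generator(per_class = 12L, side = 32L, noise = 0.05)
  m <- generate_dataset(cfg, withr::local_tempdir())
  feats <- t(vapply(m$file_path,
                    function(p) apply(read_patch(p), 3, mean),
                    numeric(3)))
  tr <- m$split != "test"
  cents <- sapply(nbi_classes(), function(cl) {
    colMeans(feats[tr & m$class_label == cl, , drop = FALSE])
  })
  pred <- nbi_classes()[apply(feats[!tr, ], 1, function(f) {
    which.min(colSums((cents - f)^2))
  })]
  acc <- mean(pred == m$class_label[!tr])
  expect_gt(acc, 0.25)
})
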