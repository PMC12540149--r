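test_that("AlexNet-style extractor exposes the reference constants", {
  net <- build_alexnet_extractor(seed = 1)
  tab <- extractor_summary(net)
  expect_equal(attr(tab, "input_side"), 64L)
  convs <- tab[tab$type == "conv", ]
  expect_equal(nrow(convs), 5L)          # five convolutional layers
  expect_equal(convs$units[2], 256L)     # conv2: 256 filters of 3x3
  expect_equal(convs$kernel[2], 3L)
  denses <- tab[tab$type == "dense", ]
  expect_equal(denses$units, c(4096L, 4096L))
  expect_equal(tab$dropout[!is.na(tab$dropout)], c(0.5, 0.5))
  expect_equal(sum(tab$type == "maxpool"), 3L)
  # a zero image yields a finite embedding of FC width
  emb <- extractor_embed(net, array(0, c(100, 100, 3)))
  expect_length(emb, 4096L)
  expect_true(all(is.finite(emb)))
})

test_that("fire modules concatenate their expand branches", {
  ns <- asNamespace("nbiclass")
  set.seed(3)
  fire <- ns$layer_fire(4, 3, 5, 6)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  out <- ns$fire_forward(fire, x)$out
  expect_equal(dim(out), c(6L, 6L, 11L))  # expand1x1 + expand3x3 channels
})

test_that("SqueezeNet-style embeddings have the pooled width and no collapse", {
  spec <- extractor_spec("squeezenet_style", width = 0.2,
                         embedding_dim = 24L)
  net <- build_squeezenet_extractor(spec, seed = 5)
  img <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  emb <- extractor_embed(net, img)
  expect_length(emb, 24L)  # equals the final 1x1 conv channel count
  shifted <- pmin(img + 40, 255)
  expect_false(isTRUE(all.equal(emb, extractor_embed(net, shifted))))
})

test_that("capsule extractor output is capsule-shaped and bounded", {
  caps <- capsule_params(primary_dim = 8, primary_channels = 16,
                         num_output_capsules = 5, output_dim = 6)
  net <- build_capsnet_extractor(extractor_spec("capsnet", width = 0.2),
                                 caps = caps, seed = 9)
  set.seed(10)
  img <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  emb <- extractor_embed(net, img)
  expect_length(emb, 5L * 6L)
  norms <- sqrt(rowSums(matrix(emb, 5, 6, byrow = TRUE)^2))
  expect_true(all(norms < 1))
  # deterministic build + forward at fixed seed
  net2 <- build_capsnet_extractor(extractor_spec("capsnet", width = 0.2),
                                  caps = caps, seed = 9)
  expect_identical(emb, extractor_embed(net2, img))
})

test_that("fused features concatenate in fixed order with span bookkeeping", {
  ex <- build_extractors(width = 0.15, fc_units = 32L, seed = 4)
  img <- generate_patch("Le", tiny_generator(side = 48L))
  f <- extract_fused(img, ex)
  dims <- vapply(ex, function(e) e$embedding_dim, integer(1))
  expect_length(as.numeric(f), sum(dims))
  spans <- attr(f, "spans")
  expect_equal(spans$extractor, c("alexnet", "squeezenet", "capsnet"))
  expect_equal(spans$end - spans$start + 1L, unname(dims))
  # determinism
  expect_identical(as.numeric(f), as.numeric(extract_fused(img, ex)))
  # permuting extractor order permutes blocks but not the value multiset
  g <- extract_fused(img, ex[c(3, 1, 2)])
  expect_equal(sort(as.numeric(g)), sort(as.numeric(f)))
  expect_equal(attr(g, "spans")$extractor,
               c("capsnet", "alexnet", "squeezenet"))
})

test_that("extractor training with a softmax head reduces the loss", {
  cfg <- tiny_generator(per_class = 3L, side = 32L)
  set.seed(6)
  images <- list(); labels <- character(0)
  for (cl in nbi_classes()) {
    for (i in 1:3) {
      images <- c(images, list(generate_patch(cl, cfg)))
      labels <- c(labels, cl)
    }
  }
  net <- build_squeezenet_extractor(
    extractor_spec("squeezenet_style", input_side = 32L, width = 0.15,
                   embedding_dim = 16L), seed = 2)
  trained <- train_extractor(net, images, labels, epochs = 4,
                             batch_size = 4, seed = 11)
  expect_true(trained$trained)
  expect_length(trained$layers, length(net$layers))  # head removed
  expect_lt(tail(trained$loss_history, 1), trained$loss_history[1])
  # training is deterministic under a fixed seed
  trained2 <- train_extractor(net, images, labels, epochs = 4,
                              batch_size = 4, seed = 11)
  expect_identical(trained$loss_history, trained2$loss_history)
})
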