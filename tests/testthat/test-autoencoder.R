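make_ae_1d <- function(we, be, wd, bd, act = "relu") {
  p <- ae_params(1L, 1L, activation = act, decoder_activation = act,
                 seed = 1)
  p$We <- matrix(we, 1, 1); p$be <- be
  p$Wd <- matrix(wd, 1, 1); p$bd <- bd
  p
}

test_that("encode and decode evaluate the affine maps exactly", {
  p <- make_ae_1d(2, 1, 1, 0)
  expect_equal(encode(3, p), 7)          # relu(2 * 3 + 1)
  expect_equal(decode(7, p), 7)          # relu(1 * 7 + 0)
  expect_equal(decode(encode(3, p), p), 7)
  # zero map
  p0 <- make_ae_1d(0, 0, 0, 0)
  expect_equal(encode(5, p0), 0)
  expect_equal(decode(0, p0), 0)
  # sigmoid keeps the latent in (0, 1)
  ps <- ae_params(4L, 2L, activation = "sigmoid", seed = 2)
  z <- encode(matrix(rnorm(20), 5, 4), ps)
  expect_true(all(z > 0 & z < 1))
  expect_error(encode(c(1, 2), p), class = "nbi_shape_error")
  expect_error(decode(c(1, 2), p), class = "nbi_shape_error")
})

test_that("reconstruction loss is the mean squared error", {
  expect_equal(reconstruction_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(reconstruction_loss(c(1, 2), c(0, 0)), 2.5)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(reconstruction_loss(x, x + 2 * (y - x)),
               4 * reconstruction_loss(x, y))
  expect_error(reconstruction_loss(1:3, 1:4), class = "nbi_shape_error")
})

test_that("a linear bottleneck recovers a linear manifold", {
  set.seed(42)
  basis <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3)))
  scores <- matrix(rnorm(200 * 3, sd = 2), 200, 3)
  X <- scores %*% t(basis)
  fit <- train_autoencoder(X, ae_hyperparams(latent_dim = 3,
                                             learning_rate = 5e-3,
                                             batch_size = 32,
                                             epochs = 120),
                           seed = 7, activation = "linear")
  hist <- fit$loss_history
  expect_lt(tail(hist, 1), 0.1 * hist[1])
  # the oracle: a rank-3 linear projection (PCA) reconstructs exactly;
  # the trained bottleneck should approach that regime
  pc <- stats::prcomp(X, center = TRUE, rank. = 3)
  oracle <- mean((X - (pc$x %*% t(pc$rotation) +
                         rep(pc$center, each = nrow(X))))^2)
  expect_lt(tail(hist, 1), oracle + 0.05 * hist[1])
})

test_that("a full-width linear autoencoder drives the loss toward zero", {
  set.seed(3)
  X <- matrix(rnorm(50 * 4), 50, 4)
  fit <- train_autoencoder(X, ae_hyperparams(latent_dim = 4,
                                             learning_rate = 1e-2,
                                             batch_size = 16,
                                             epochs = 200),
                           seed = 5, activation = "linear")
  expect_lt(tail(fit$loss_history, 1), 0.02)
})

test_that("training is deterministic and improves in the median", {
  set.seed(1)
  X <- matrix(rnorm(80 * 10), 80, 10)
  h <- ae_hyperparams(latent_dim = 4, epochs = 15)
  f1 <- train_autoencoder(X, h, seed = 9)
  f2 <- train_autoencoder(X, h, seed = 9)
  expect_identical(f1$loss_history, f2$loss_history)
  finals <- initials <- numeric(5)
  for (s in 1:5) {
    f <- train_autoencoder(X, h, seed = s)
    initials[s] <- f$loss_history[1]
    finals[s] <- tail(f$loss_history, 1)
  }
  expect_lt(median(finals), median(initials))
})

test_that("the latent classifier separates Gaussian blobs", {
  blobs <- make_blobs(30, d = 20, sep = 4, sd = 1, seed = 13)
  tr <- rep(c(TRUE, FALSE), times = c(20, 10))
  tr <- as.vector(sapply(1:4, function(k) tr))
  model <- train_ae_classifier(blobs$X[tr, ], blobs$y[tr],
                               ae_hyperparams(latent_dim = 5, epochs = 40),
                               seed = 21)
  post <- classify(blobs$X[!tr, ], model)
  expect_equal(rowSums(post), rep(1, sum(!tr)), tolerance = 1e-6)
  pred <- predict(model, blobs$X[!tr, ])
  expect_gt(mean(as.character(pred) == blobs$y[!tr]), 0.9)
})

test_that("posteriors are equivariant under feature permutation", {
  blobs <- make_blobs(10, d = 8, sep = 5, seed = 3)
  model <- train_ae_classifier(blobs$X, blobs$y,
                               ae_hyperparams(latent_dim = 4, epochs = 20),
                               seed = 4)
  perm <- sample(8)
  pmodel <- model
  pmodel$params$We <- model$params$We[, perm, drop = FALSE]
  pmodel$scaler$mean <- model$scaler$mean[perm]
  pmodel$scaler$sd <- model$scaler$sd[perm]
  expect_equal(classify(blobs$X[, perm], pmodel), classify(blobs$X, model),
               tolerance = 1e-12)
})

test_that("untrained models and bad labels are rejected", {
  expect_error(classify(matrix(0, 1, 3), structure(list(trained = FALSE),
                                                   class = "nbi_ae_classifier")),
               class = "nbi_untrained")
  expect_error(train_ae_classifier(matrix(rnorm(20), 5, 4),
                                   c("a", "b", "c", "d", "e"),
                                   ae_hyperparams(latent_dim = 2)),
               class = "nbi_bad_label")
})
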