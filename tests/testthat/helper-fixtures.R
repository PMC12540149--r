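# Shared fixtures: small images, reduced-size extractors, scripted RNG
# streams and independent brute-force oracles used across test files.

tiny_generator <- function(per_class = 4L, side = 32L, noise = 0,
                           seed = 1L) {
  generator_config(patch_side = side, per_class_count = per_class,
                   noise_fraction = noise, seed = seed)
}

# A deterministic uniform stream independent of R's RNG, for scripted
# optimizer traces (same stream can be replayed into an oracle).
lcg_stream <- function(seed) {
  s <- as.double(seed)
  function(k) {
    out <- numeric(k)
    for (j in seq_len(k)) {
      s <<- (1103515245 * s + 12345) %% 2^31
      out[j] <- s / 2^31
    }
    out
  }
}

# Plain-loop dynamic routing written directly from the recursion
# (softmax couplings, weighted sum, squash, agreement update); kept
# independent of the package implementation.
routing_oracle <- function(U, iterations) {
  n_i <- dim(U)[1]; n_j <- dim(U)[2]; d <- dim(U)[3]
  b <- matrix(0, n_i, n_j)
  v <- NULL
  for (it in seq_len(iterations)) {
    cc <- matrix(0, n_i, n_j)
    for (i in seq_len(n_i)) {
      e <- exp(b[i, ] - max(b[i, ]))
      cc[i, ] <- e / sum(e)
    }
    s <- matrix(0, n_j, d)
    for (j in seq_len(n_j)) {
      for (i in seq_len(n_i)) s[j, ] <- s[j, ] + cc[i, j] * U[i, j, ]
    }
    v <- matrix(0, n_j, d)
    for (j in seq_len(n_j)) {
      r <- sqrt(sum(s[j, ]^2))
      if (r > 0) v[j, ] <- s[j, ] * r / (1 + r^2)
    }
    if (it < iterations) {
      for (i in seq_len(n_i)) {
        for (j in seq_len(n_j)) b[i, j] <- b[i, j] + sum(U[i, j, ] * v[j, ])
      }
    }
  }
  list(v = v, coupling = cc)
}

# Brute-force reflect-border median filter (per channel, double loop).
median_oracle <- function(img, k = 3L, mode = "reflect") {
  half <- (k - 1L) %/% 2L
  out <- img
  H <- dim(img)[1]; W <- dim(img)[2]
  refl <- function(idx, n) {
    if (mode == "reflect") {
      idx[idx < 1] <- 2 - idx[idx < 1]
      idx[idx > n] <- 2 * n - idx[idx > n]
    } else {
      idx <- pmin(pmax(idx, 1), n)
    }
    idx
  }
  for (ch in 1:3) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        ri <- refl(i + seq(-half, half), H)
        rj <- refl(j + seq(-half, half), W)
        out[i, j, ch] <- stats::median(img[ri, rj, ch])
      }
    }
  }
  out
}

# Micro pipeline configuration: reduced-width extractors, few patches.
micro_config <- function(seed = 3L, per_class = 6L) {
  pipeline_config(
    seed = seed,
    generator = generator_config(patch_side = 64, per_class_count = per_class,
                                 seed = seed),
    width = 0.15, fc_units = 64L,
    extractor_epochs = 1L, ooa_n = 2L, ooa_iterations = 2L,
    tune_epochs_cap = 10L)
}

# Four well-separated Gaussian blobs in d dimensions.
make_blobs <- function(n_per_class, d = 20L, sep = 10, sd = 1, seed = 1L) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(4 * d), 4, d) * sep
  X <- do.call(rbind, lapply(1:4, function(k) {
    matrix(stats::rnorm(n_per_class * d, sd = sd), n_per_class, d) +
      rep(centers[k, ], each = n_per_class)
  }))
  list(X = X, y = rep(nbi_classes(), each = n_per_class))
}
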