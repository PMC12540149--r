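sphere <- function(x) sum(x^2)

test_that("initialization samples inside the bounds, deterministically", {
  sp <- ooa_space(c(-2, 0), c(1, 5))
  st <- ooa_init(sp, 8, sphere, seed = 3)
  expect_true(all(sweep(st$positions, 2, sp$lower, ">=")))
  expect_true(all(sweep(st$positions, 2, sp$upper, "<=")))
  expect_equal(st$best_fitness, min(st$fitness))
  st2 <- ooa_init(sp, 8, sphere, seed = 3)
  expect_identical(st$positions, st2$positions)
  # zero-draw limit lands on the lower bound
  res <- ooa_optimize(sphere, sp, n = 2, iterations = 1,
                      rand_fn = function(k) rep(0, k))
  expect_equal(res$state$positions[1, ], sp$lower)
  expect_error(ooa_space(c(0, 1), c(1, 1)), class = "nbi_bad_config")
  expect_error(ooa_init(sp, 1, sphere), class = "nbi_bad_config")
})

test_that("fish sets collect strictly better members plus the best", {
  expect_equal(ooa_fish_set(c(3, 1, 2), 1), c(2, 3))
  expect_equal(ooa_fish_set(c(3, 1, 2), 2), 2)   # the best itself
  expect_equal(ooa_fish_set(c(3, 1, 2), 3), 2)
  expect_equal(ooa_fish_set(c(5, 5, 5), 2), 1)   # ties excluded
})

test_that("step candidates match hand-evaluated fixtures", {
  ns <- asNamespace("nbiclass")
  # x = 2, fish at 0, r = 1, I = 1: 2 + 1 * (0 - 1 * 2) = 0
  expect_equal(ns$ooa_exploration_candidate(2, 0, 1, 1), 0)
  # offset (LB + r (UB - LB)) / k with LB = 0, UB = 1, r = 0.5, k = 10
  sp <- ooa_space(0, 1)
  expect_equal(ns$ooa_exploitation_candidate(0, sp, 0.5, 10), 0.05)
  expect_equal(ns$clip_to_bounds(c(-3, 7), ooa_space(c(0, 0), c(1, 1))),
               c(0, 1))
})

test_that("every evaluated position is clipped into the bounds", {
  sp <- ooa_space(c(-1, 2, 0), c(1, 3, 10))
  seen <- list()
  obj <- function(x) { seen[[length(seen) + 1L]] <<- x; sum(x^2) }
  res <- ooa_optimize(obj, sp, n = 6, iterations = 15, seed = 17)
  pos <- do.call(rbind, seen)
  expect_true(all(sweep(pos, 2, sp$lower, ">=") &
                    sweep(pos, 2, sp$upper, "<=")))
  expect_true(all(diff(res$history) <= 1e-15))
})

test_that("per-member fitness never worsens across iterations", {
  sp <- ooa_space(rep(-5, 3), rep(5, 3))
  fits <- list()
  # track the population fitness after each iteration via small budgets
  prev <- NULL
  for (T in 1:6) {
    r <- ooa_optimize(sphere, sp, n = 5, iterations = T, seed = 99)
    fits[[T]] <- r$state$fitness
    if (!is.null(prev)) expect_true(all(fits[[T]] <= prev + 1e-15))
    prev <- fits[[T]]
  }
})

test_that("a scripted one-iteration run matches an independent trace", {
  sp <- ooa_space(c(-4, -4), c(4, 4))
  n <- 3L; m <- 2L
  got <- ooa_optimize(sphere, sp, n = n, iterations = 1,
                      rand_fn = lcg_stream(7))
  # independent replay of the documented draw order
  rf <- lcg_stream(7)
  u <- matrix(rf(n * m), n, m, byrow = TRUE)
  pos <- sweep(sweep(u, 2, sp$upper - sp$lower, "*"), 2, sp$lower, "+")
  ff <- apply(pos, 1, sphere)
  best <- which.min(ff)
  best_f <- ff[best]
  for (i in 1:n) {
    fs <- sort(union(which(ff < ff[i]), best))
    cf_idx <- if (length(fs) == 1L) fs else fs[1L + floor(rf(1) * length(fs))]
    r1 <- rf(m)
    I <- 1 + floor(rf(1) * 2)
    cand <- pmin(pmax(pos[i, ] + r1 * (pos[cf_idx, ] - I * pos[i, ]),
                      sp$lower), sp$upper)
    if (sphere(cand) < ff[i]) { pos[i, ] <- cand; ff[i] <- sphere(cand) }
    r2 <- rf(m)
    cand2 <- pmin(pmax(pos[i, ] + (sp$lower + r2 * (sp$upper - sp$lower)) / 1,
                       sp$lower), sp$upper)
    if (sphere(cand2) < ff[i]) { pos[i, ] <- cand2; ff[i] <- sphere(cand2) }
    if (ff[i] < best_f) { best_f <- ff[i]; best <- i }
  }
  expect_equal(got$state$positions, pos, tolerance = 1e-12)
  expect_equal(got$state$fitness, ff, tolerance = 1e-12)
  expect_equal(got$best_fitness, best_f, tolerance = 1e-12)
})

test_that("the optimizer solves the sphere benchmark", {
  sp <- ooa_space(rep(-5, 5), rep(5, 5))
  res <- ooa_optimize(sphere, sp, n = 20, iterations = 100, seed = 1)
  expect_lt(res$best_fitness, 1e-2)
  expect_length(res$history, 101L)
})

test_that("the optimizer beats random search at equal budget", {
  rastrigin <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
  for (fn in list(sphere, rastrigin)) {
    sp <- ooa_space(rep(-5.12, 2), rep(5.12, 2))
    n <- 10L; T <- 20L
    budget <- n + 2L * n * T
    ooa_best <- rs_best <- numeric(10)
    for (s in 1:10) {
      ooa_best[s] <- ooa_optimize(fn, sp, n = n, iterations = T,
                                  seed = s)$best_fitness
      set.seed(s + 1000)
      xs <- matrix(runif(budget * 2, -5.12, 5.12), budget, 2)
      rs_best[s] <- min(apply(xs, 1, fn))
    }
    expect_lt(median(ooa_best), median(rs_best))
  }
})

test_that("non-finite objectives raise a labelled error", {
  sp <- ooa_space(-1, 1)
  expect_error(ooa_optimize(function(x) NaN, sp, n = 2, iterations = 1,
                            seed = 1),
               class = "nbi_bad_objective")
  expect_error(ooa_optimize(sphere, sp, n = 2, iterations = 0, seed = 1),
               class = "nbi_bad_config")
})

test_that("macro precision evaluates TP / (TP + FP) fixtures", {
  y_true <- c("Hbv", "Hbv", "Hbv", "He")
  y_pred <- c("Hbv", "Hbv", "Hbv", "Hbv")   # TP = 3, FP = 1
  expect_equal(macro_precision(y_true, y_pred, classes = "Hbv"), 0.75)
  expect_equal(macro_precision(c("He", "He"), c("He", "He"),
                               classes = "He"), 1)  # FP = 0, TP > 0
})

test_that("hyperparameter tuning returns the best observed candidate", {
  blobs <- make_blobs(9, d = 6, sep = 6, seed = 2)
  tr <- rep(rep(c(TRUE, FALSE), times = c(6, 3)), 4)
  sp <- ooa_space(lower = c(2, 1e-3, 4, 0, 5),
                  upper = c(5, 1e-2, 16, 0.3, 12),
                  integer_dims = c(1L, 3L, 5L),
                  names = c("latent_dim", "learning_rate", "batch_size",
                            "dropout", "epochs"))
  tuned <- tune_ae_hyperparams(blobs$X[tr, ], blobs$y[tr],
                               blobs$X[!tr, ], blobs$y[!tr],
                               space = sp, n = 2, iterations = 2, seed = 5,
                               epochs_cap = 8)
  expect_s3_class(tuned$best_hyper, "ae_hyperparams")
  expect_gte(tuned$best_fitness, max(tuned$evaluations$score) - 1e-12)
  expect_true(all(diff(tuned$history) >= -1e-15))
  expect_true(tuned$best_hyper$latent_dim == round(tuned$best_hyper$latent_dim))
  # deterministic under the same master seed
  tuned2 <- tune_ae_hyperparams(blobs$X[tr, ], blobs$y[tr],
                                blobs$X[!tr, ], blobs$y[!tr],
                                space = sp, n = 2, iterations = 2, seed = 5,
                                epochs_cap = 8)
  expect_equal(tuned$best_fitness, tuned2$best_fitness)
  expect_equal(unclass(tuned$best_hyper), unclass(tuned2$best_hyper))
})
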