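# Osprey Optimisation Algorithm: a population metaheuristic for bounded
# continuous minimization. Each member ("osprey") holds a position in
# [LB, UB]^m. Per iteration every member first performs an exploration
# move toward a randomly chosen strictly-better member (a "fish"), then
# an exploitation move adding a (1/t)-scaled random offset; both
# candidates are clipped to the bounds and accepted only if they
# strictly improve the member's fitness, so per-member fitness is
# non-increasing.
#
# Internally the algorithm minimizes; maximization is handled by
# negating the objective.

#' Bounded search space
#'
#' @param lower,upper Numeric vectors of per-dimension bounds
#'   (`lower < upper` elementwise).
#' @param integer_dims Indices of dimensions rounded to integers when a
#'   position is decoded (the search itself stays continuous).
#' @param names Optional dimension names.
#' @return An object of class `ooa_space`.
#' @export
ooa_space <- function(lower, upper, integer_dims = integer(0),
                      names = NULL) {
  if (length(lower) != length(upper) || any(!is.finite(c(lower, upper)))) {
    nbi_stop("lower and upper must be finite and of equal length",
             class = "nbi_bad_config")
  }
  if (any(lower >= upper)) {
    nbi_stop("need lower < upper in every dimension",
             class = "nbi_bad_config")
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 m = length(lower),
                 integer_dims = as.integer(integer_dims),
                 names = names),
            class = "ooa_space")
}

clip_to_bounds <- function(x, space) {
  pmin(pmax(x, space$lower), space$upper)
}

#' Initialize the osprey population
#'
#' Positions are drawn uniformly inside the bounds,
#' `OS_ij = LB_j + u_ij (UB_j - LB_j)`, and every member's fitness is
#' evaluated.
#'
#' @param space An [ooa_space()].
#' @param n Population size (>= 2).
#' @param fn Objective function mapping a position vector to a finite
#'   scalar (minimized).
#' @param seed RNG seed.
#' @return An `ooa_state` list: `positions` (n x m), `fitness` (length
#'   n), `best_index`, `best_position`, `best_fitness`, `t = 0`.
#' @export
ooa_init <- function(space, n, fn, seed = NULL) {
  stopifnot(inherits(space, "ooa_space"))
  if (n < 2L) nbi_stop("population size must be >= 2",
                       class = "nbi_bad_config")
  with_seed(seed, {
    u <- matrix(stats::runif(n * space$m), n, space$m)
    pos <- sweep(sweep(u, 2L, space$upper - space$lower, "*"),
                 2L, space$lower, "+")
    ff <- apply(pos, 1L, function(x) eval_objective(fn, x))
    bi <- which.min(ff)
    structure(list(positions = pos, fitness = ff, best_index = bi,
                   best_position = pos[bi, ], best_fitness = ff[bi],
                   t = 0L, space = space),
              class = "ooa_state")
  })
}

eval_objective <- function(fn, x) {
  v <- fn(x)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    nbi_stop("objective returned a non-finite value at position (",
             paste(signif(x, 6), collapse = ", "), ")",
             class = "nbi_bad_objective")
  }
  as.numeric(v)
}

#' Fish set of one osprey
#'
#' Indices of the population members with strictly lower fitness than
#' member `i`, together with the best member. For the best member itself
#' this is just the best member; ties are excluded by the strict
#' inequality.
#'
#' @param fitness Numeric fitness vector.
#' @param i Member index.
#' @param best_index Index of the best member (argmin of `fitness`);
#'   computed if missing.
#' @return Sorted integer vector of candidate indices.
#' @export
ooa_fish_set <- function(fitness, i, best_index = which.min(fitness)) {
  sort(union(which(fitness < fitness[i]), best_index))
}

# Exploration candidate for one member: move toward the chosen fish.
# x' = x + r (cf - I x), r ~ U[0,1]^m per dimension, I in {1, 2}.
ooa_exploration_candidate <- function(x, cf, r, I) {
  x + r * (cf - I * x)
}

# Exploitation candidate: x' = x + (LB + r (UB - LB)) / t.
ooa_exploitation_candidate <- function(x, space, r, t) {
  x + (space$lower + r * (space$upper - space$lower)) / t
}

#' Run the Osprey Optimisation Algorithm
#'
#' Per iteration and member: exploration (move toward a random member of
#' the fish set, scaled by a per-dimension uniform draw and an intensity
#' factor `I` drawn from \{1, 2\}), then exploitation (add a
#' `1/t`-decaying uniform offset). Candidates are clipped to the bounds
#' and accepted only on strict improvement, so the best fitness is
#' non-increasing over iterations.
#'
#' @param fn Objective function of one position vector.
#' @param space An [ooa_space()].
#' @param n Population size (default 20).
#' @param iterations Iteration budget T (default 100).
#' @param seed RNG seed.
#' @param maximize If `TRUE` the objective is negated internally and
#'   reported on its original scale.
#' @param intensity `"integer"` draws the exploration factor I from
#'   \{1, 2\} (the canonical rule); `"uniform"` draws it from U\[1, 2\].
#' @param rand_fn Uniform generator `function(k)` returning `k` draws in
#'   \[0, 1); override for scripted traces (default [stats::runif]).
#' @return List of class `ooa_result`: `best_position`, `best_fitness`,
#'   `history` (best-so-far per iteration, including iteration 0),
#'   `mean_history`, and the final `state`.
#' @export
ooa_optimize <- function(fn, space, n = 20L, iterations = 100L,
                         seed = NULL, maximize = FALSE,
                         intensity = c("integer", "uniform"),
                         rand_fn = NULL) {
  stopifnot(inherits(space, "ooa_space"))
  intensity <- match.arg(intensity)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    nbi_stop("iterations must be >= 1", class = "nbi_bad_config")
  }
  obj <- if (maximize) function(x) -eval_objective(fn, x) else
    function(x) eval_objective(fn, x)
  with_seed(seed, {
    if (is.null(rand_fn)) rand_fn <- function(k) stats::runif(k)
    # init draws fill member 1's dimensions first, then member 2, ...
    u <- matrix(rand_fn(n * space$m), n, space$m, byrow = TRUE)
    pos <- sweep(sweep(u, 2L, space$upper - space$lower, "*"),
                 2L, space$lower, "+")
    ff <- apply(pos, 1L, obj)
    bi <- which.min(ff)
    st <- structure(list(positions = pos, fitness = ff, best_index = bi,
                         best_position = pos[bi, ], best_fitness = ff[bi],
                         t = 0L, space = space),
                    class = "ooa_state")
    history <- numeric(iterations + 1L)
    mean_history <- numeric(iterations + 1L)
    history[1L] <- st$best_fitness
    mean_history[1L] <- mean(st$fitness)
    for (t in seq_len(iterations)) {
      st$t <- t
      for (i in seq_len(n)) {
        # exploration: chase a fish (strictly better member or the best)
        fs <- ooa_fish_set(st$fitness, i, st$best_index)
        cf_idx <- if (length(fs) == 1L) fs else
          fs[1L + floor(rand_fn(1L) * length(fs))]
        cf <- st$positions[cf_idx, ]
        r <- rand_fn(space$m)
        I <- if (intensity == "integer") 1 + floor(rand_fn(1L) * 2) else
          1 + rand_fn(1L)
        cand <- clip_to_bounds(
          ooa_exploration_candidate(st$positions[i, ], cf, r, I), space)
        fcand <- obj(cand)
        if (fcand < st$fitness[i]) {
          st$positions[i, ] <- cand
          st$fitness[i] <- fcand
        }
        # exploitation: local 1/t-scaled perturbation
        r2 <- rand_fn(space$m)
        cand2 <- clip_to_bounds(
          ooa_exploitation_candidate(st$positions[i, ], space, r2, t),
          space)
        fcand2 <- obj(cand2)
        if (fcand2 < st$fitness[i]) {
          st$positions[i, ] <- cand2
          st$fitness[i] <- fcand2
        }
        if (st$fitness[i] < st$best_fitness) {
          st$best_fitness <- st$fitness[i]
          st$best_index <- i
          st$best_position <- st$positions[i, ]
        }
      }
      st$best_index <- which.min(st$fitness)
      history[t + 1L] <- st$best_fitness
      mean_history[t + 1L] <- mean(st$fitness)
    }
    sgn <- if (maximize) -1 else 1
    structure(list(best_position = st$best_position,
                   best_fitness = sgn * st$best_fitness,
                   history = sgn * history,
                   mean_history = sgn * mean_history,
                   state = st),
              class = "ooa_result")
  })
}

#' @export
print.ooa_result <- function(x, ...) {
  cat(sprintf("<ooa_result: best fitness %.6g after %d iterations>\n",
              x$best_fitness, length(x$history) - 1L))
  invisible(x)
}

# Decode an OOA position into an ae_hyperparams object.
decode_hyper_position <- function(x, space) {
  names(x) <- space$names
  x[space$integer_dims] <- round(x[space$integer_dims])
  do.call(ae_hyperparams, as.list(x))
}

#' Default search space for autoencoder hyperparameters
#'
#' Latent width 8-64 (integer), learning rate 1e-4 to 1e-2, batch size
#' 8-64 (integer), latent dropout 0-0.5, epochs 10-60 (integer).
#'
#' @param max_latent Upper bound on the latent width (clipped below the
#'   feature dimension by the tuner).
#' @return An [ooa_space()] with named dimensions.
#' @export
ae_search_space <- function(max_latent = 64L) {
  ooa_space(lower = c(8, 1e-4, 8, 0, 10),
            upper = c(max_latent, 1e-2, 64, 0.5, 60),
            integer_dims = c(1L, 3L, 5L),
            names = c("latent_dim", "learning_rate", "batch_size",
                      "dropout", "epochs"))
}

#' Macro-averaged precision
#'
#' `P = TP / (TP + FP)` per class, averaged over the classes present in
#' the truth; the tuning fitness.
#'
#' @param y_true,y_pred Label vectors.
#' @param classes Class levels.
#' @return Scalar in \[0, 1\].
#' @export
macro_precision <- function(y_true, y_pred, classes = nbi_classes()) {
  p <- vapply(classes, function(cl) {
    tp <- sum(y_pred == cl & y_true == cl)
    fp <- sum(y_pred == cl & y_true != cl)
    if (tp + fp == 0L) 0 else tp / (tp + fp)
  }, numeric(1))
  mean(p[classes %in% unique(as.character(y_true))])
}

#' Tune autoencoder hyperparameters with the OOA
#'
#' Each candidate position decodes to an [ae_hyperparams()] bundle
#' (integer dimensions rounded); the objective trains the autoencoder
#' classifier on the training features and scores it on the validation
#' split. The fitness is maximized via internal negation. A candidate
#' whose training fails is assigned the worst possible fitness and the
#' search continues.
#'
#' @param train_x,train_y Training features (matrix) and labels.
#' @param val_x,val_y Validation features and labels.
#' @param space An [ooa_space()] over the hyperparameters (default
#'   [ae_search_space()]).
#' @param n Population size (default 6).
#' @param iterations OOA iterations (default 5).
#' @param seed Master seed; per-candidate training seeds are derived
#'   deterministically from it.
#' @param fitness `"precision"` (macro-averaged `TP / (TP + FP)`, the
#'   default) or `"accuracy"` (plain fraction correct).
#' @param epochs_cap Optional cap on the decoded epoch count, to keep
#'   per-candidate training cheap during the search.
#' @param classes Class levels.
#' @param verbose Report per-evaluation fitness.
#' @return List of class `ooa_tuning`: `best_hyper`, `best_fitness`,
#'   `history` (per-iteration best fitness), `evaluations` (data.frame
#'   of decoded candidates and their scores).
#' @export
tune_ae_hyperparams <- function(train_x, train_y, val_x, val_y,
                                space = ae_search_space(), n = 6L,
                                iterations = 5L, seed = NULL,
                                fitness = c("precision", "accuracy"),
                                epochs_cap = NULL,
                                classes = nbi_classes(), verbose = FALSE) {
  fitness <- match.arg(fitness)
  evals <- new.env(parent = emptyenv())
  evals$log <- list()
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  objective <- function(x) {
    counter$k <- counter$k + 1L
    hyper <- tryCatch(decode_hyper_position(x, space),
                      error = function(e) NULL)
    score <- 0
    if (!is.null(hyper)) {
      if (!is.null(epochs_cap)) {
        hyper$epochs <- min(hyper$epochs, as.integer(epochs_cap))
      }
      hyper$latent_dim <- min(hyper$latent_dim, ncol(train_x))
      score <- tryCatch({
        model <- train_ae_classifier(train_x, train_y, hyper,
                                     seed = derive_seed(seed, counter$k),
                                     classes = classes)
        pred <- predict(model, val_x)
        if (fitness == "precision") {
          macro_precision(val_y, pred, classes)
        } else {
          mean(as.character(pred) == as.character(val_y))
        }
      }, error = function(e) {
        warning("candidate ", counter$k, " failed: ",
                conditionMessage(e), call. = FALSE)
        0
      })
    }
    evals$log[[counter$k]] <- c(as.list(stats::setNames(x, space$names)),
                                list(score = score))
    if (verbose) {
      message(sprintf("  candidate %d: fitness %.4f", counter$k, score))
    }
    score
  }
  res <- ooa_optimize(objective, space, n = n, iterations = iterations,
                      seed = seed, maximize = TRUE)
  best_hyper <- decode_hyper_position(res$best_position, space)
  if (!is.null(epochs_cap)) {
    best_hyper$epochs <- min(best_hyper$epochs, as.integer(epochs_cap))
  }
  best_hyper$latent_dim <- min(best_hyper$latent_dim, ncol(train_x))
  structure(list(best_hyper = best_hyper,
                 best_fitness = res$best_fitness,
                 history = res$history,
                 mean_history = res$mean_history,
                 evaluations = do.call(rbind,
                                       lapply(evals$log, as.data.frame))),
            class = "ooa_tuning")
}
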