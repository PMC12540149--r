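# Autoencoder over fused features plus a latent-space classifier.
# The encoder and decoder are each a single affine map with a pointwise
# nonlinearity: Z = act(X We' + be), Xhat = act(Z Wd' + bd). Training
# minimizes mean squared reconstruction error; classification adds a
# softmax head on the latent code, fine-tuned with cross-entropy after
# reconstruction pretraining.

ae_act <- function(x, kind) {
  switch(kind,
         relu = pmax(x, 0),
         sigmoid = 1 / (1 + exp(-x)),
         linear = x,
         nbi_stop("unknown activation: ", kind, class = "nbi_bad_config"))
}

ae_act_grad <- function(pre, out, kind) {
  switch(kind,
         relu = (pre > 0) * 1,
         sigmoid = out * (1 - out),
         linear = array(1, dim(pre)))
}

#' Autoencoder parameter container
#'
#' @param input_dim Feature dimension of the input.
#' @param latent_dim Bottleneck dimension (must be < `input_dim` for a
#'   proper bottleneck; equality is allowed for diagnostics).
#' @param activation Encoder nonlinearity: `"relu"`, `"sigmoid"` or
#'   `"linear"`.
#' @param decoder_activation Decoder output nonlinearity; default
#'   `"linear"` so reconstructions span the standardized feature range.
#' @param seed RNG seed for initialization.
#' @return An object of class `ae_params` with weights `We`
#'   (`latent_dim` x `input_dim`), `be`, `Wd` (`input_dim` x
#'   `latent_dim`), `bd`.
#' @export
ae_params <- function(input_dim, latent_dim, activation = "relu",
                      decoder_activation = "linear", seed = NULL) {
  if (latent_dim > input_dim) {
    nbi_stop("latent_dim must not exceed input_dim",
             class = "nbi_bad_config")
  }
  with_seed(seed, {
    structure(list(
      We = matrix(stats::rnorm(latent_dim * input_dim,
                               0, sqrt(1 / input_dim)),
                  latent_dim, input_dim),
      be = numeric(latent_dim),
      Wd = matrix(stats::rnorm(input_dim * latent_dim,
                               0, sqrt(1 / latent_dim)),
                  input_dim, latent_dim),
      bd = numeric(input_dim),
      activation = activation,
      decoder_activation = decoder_activation,
      input_dim = as.integer(input_dim),
      latent_dim = as.integer(latent_dim)),
      class = "ae_params")
  })
}

as_row_matrix <- function(X, dim_needed, what) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != dim_needed) {
    nbi_stop(what, ": expected width ", dim_needed, ", got ", ncol(X),
             class = "nbi_shape_error")
  }
  X
}

#' Encode features to the latent space
#'
#' Computes `Z = act(We X + be)` row-wise.
#'
#' @param X Numeric vector of length `input_dim`, or a matrix with one
#'   sample per row.
#' @param p An [ae_params()] object.
#' @return Latent representation; a vector if `X` was a vector.
#' @export
encode <- function(X, p) {
  stopifnot(inherits(p, "ae_params"))
  vec <- is.null(dim(X))
  X <- as_row_matrix(X, p$input_dim, "encode")
  Z <- ae_act(tcrossprod(X, p$We) + rep(p$be, each = nrow(X)),
              p$activation)
  if (vec) as.vector(Z) else Z
}

#' Decode latent vectors back to feature space
#'
#' Computes `Xhat = act(Wd Z + bd)` row-wise.
#'
#' @param Z Numeric vector of length `latent_dim`, or a matrix with one
#'   sample per row.
#' @param p An [ae_params()] object.
#' @return Reconstruction; a vector if `Z` was a vector.
#' @export
decode <- function(Z, p) {
  stopifnot(inherits(p, "ae_params"))
  vec <- is.null(dim(Z))
  Z <- as_row_matrix(Z, p$latent_dim, "decode")
  Xh <- ae_act(tcrossprod(Z, p$Wd) + rep(p$bd, each = nrow(Z)),
               p$decoder_activation)
  if (vec) as.vector(Xh) else Xh
}

#' Mean squared reconstruction error
#'
#' `L = (1/n) sum_i (X_i - Xhat_i)^2` over all entries; zero exactly when
#' the reconstruction equals the input.
#'
#' @param X Original features (vector or matrix).
#' @param Xhat Reconstruction of the same shape.
#' @return A nonnegative scalar.
#' @export
reconstruction_loss <- function(X, Xhat) {
  if (length(X) != length(Xhat)) {
    nbi_stop("X and Xhat must have the same length",
             class = "nbi_shape_error")
  }
  if (length(X) == 0L) {
    nbi_stop("empty input", class = "nbi_shape_error")
  }
  mean((X - Xhat)^2)
}

#' Autoencoder hyperparameter bundle
#'
#' The tunable quantities searched by [tune_ae_hyperparams()].
#'
#' @param latent_dim Bottleneck width (count).
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size Mini-batch size (count).
#' @param dropout Dropout rate on the latent code during supervised
#'   fine-tuning, in \[0, 1).
#' @param epochs Training epochs per phase (count).
#' @return An object of class `ae_hyperparams`.
#' @export
ae_hyperparams <- function(latent_dim = 32L, learning_rate = 1e-3,
                           batch_size = 16L, dropout = 0.1, epochs = 30L) {
  if (learning_rate <= 0 || dropout < 0 || dropout >= 1 ||
      latent_dim < 1L || batch_size < 1L || epochs < 1L) {
    nbi_stop("invalid autoencoder hyperparameters",
             class = "nbi_bad_config")
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 dropout = dropout, epochs = as.integer(epochs)),
            class = "ae_hyperparams")
}

adam_update_mat <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  p <- p - lr * (st$m / (1 - beta1^t)) / (sqrt(st$v / (1 - beta2^t)) + eps)
  list(p = p, st = st)
}

#' Train an autoencoder by reconstruction
#'
#' Minimizes the mean squared reconstruction error with Adam over
#' mini-batches. Features should be standardized beforehand (the
#' pipeline standardizes per dimension on the training split).
#'
#' @param features Numeric matrix, one sample per row.
#' @param hyper An [ae_hyperparams()].
#' @param seed RNG seed (initialization and shuffling).
#' @param activation Encoder nonlinearity (default `"relu"`).
#' @param decoder_activation Decoder output nonlinearity (default
#'   `"linear"`).
#' @return An object of class `nbi_autoencoder`: the fitted
#'   [ae_params()] plus `loss_history` (per-epoch mean training loss,
#'   with the pre-training loss as the first element).
#' @export
train_autoencoder <- function(features, hyper = ae_hyperparams(),
                              seed = NULL, activation = "relu",
                              decoder_activation = "linear") {
  features <- as.matrix(features)
  n <- nrow(features); d <- ncol(features)
  if (hyper$latent_dim > d) {
    nbi_stop("latent_dim exceeds feature dimension",
             class = "nbi_bad_config")
  }
  with_seed(seed, {
    p <- ae_params(d, hyper$latent_dim, activation = activation,
                   decoder_activation = decoder_activation)
    st <- lapply(p[c("We", "be", "Wd", "bd")],
                 function(x) list(m = x * 0, v = x * 0))
    t <- 0L
    init_loss <- reconstruction_loss(features, decode(encode(features, p), p))
    hist <- c(init_loss, numeric(hyper$epochs))
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      for (start in seq.int(1L, n, by = hyper$batch_size)) {
        idx <- ord[start:min(start + hyper$batch_size - 1L, n)]
        Xb <- features[idx, , drop = FALSE]
        pre_e <- tcrossprod(Xb, p$We) + rep(p$be, each = length(idx))
        Z <- ae_act(pre_e, p$activation)
        pre_d <- tcrossprod(Z, p$Wd) + rep(p$bd, each = length(idx))
        Xh <- ae_act(pre_d, p$decoder_activation)
        if (!all(is.finite(Xh))) {
          nbi_stop("autoencoder training diverged (non-finite loss)",
                   class = "nbi_divergence")
        }
        dXh <- 2 * (Xh - Xb) / length(Xb)
        dpd <- dXh * ae_act_grad(pre_d, Xh, p$decoder_activation)
        gWd <- crossprod(dpd, Z); gbd <- colSums(dpd)
        dZ <- dpd %*% p$Wd
        dpe <- dZ * ae_act_grad(pre_e, Z, p$activation)
        gWe <- crossprod(dpe, Xb); gbe <- colSums(dpe)
        t <- t + 1L
        for (nm in c("We", "be", "Wd", "bd")) {
          g <- switch(nm, We = gWe, be = gbe, Wd = gWd, bd = gbd)
          u <- adam_update_mat(p[[nm]], g, st[[nm]], hyper$learning_rate, t)
          p[[nm]] <- u$p; st[[nm]] <- u$st
        }
      }
      hist[ep + 1L] <- reconstruction_loss(
        features, decode(encode(features, p), p))
      if (!is.finite(hist[ep + 1L])) {
        nbi_stop("autoencoder training diverged (non-finite loss)",
                 class = "nbi_divergence")
      }
    }
    structure(list(params = p, loss_history = hist, hyper = hyper),
              class = "nbi_autoencoder")
  })
}

#' Train the autoencoder-based classifier
#'
#' Two-phase training: (1) reconstruction pretraining of the autoencoder
#' on the (standardized) feature matrix; (2) supervised fine-tuning of
#' the encoder together with a softmax head on the latent code, using
#' cross-entropy and Adam, with dropout on the latent code. Feature
#' standardization statistics (per-dimension mean and standard deviation
#' of the training data) are stored in the model and re-applied at
#' prediction time.
#'
#' @param features Numeric matrix of raw (unstandardized) fused features,
#'   one sample per row.
#' @param labels Class labels (character or factor) aligned with rows.
#' @param hyper An [ae_hyperparams()].
#' @param seed RNG seed.
#' @param classes Class levels (default [nbi_classes()]).
#' @param pretrain Run the reconstruction phase (default `TRUE`).
#' @return An object of class `nbi_ae_classifier`.
#' @export
train_ae_classifier <- function(features, labels, hyper = ae_hyperparams(),
                                seed = NULL, classes = nbi_classes(),
                                pretrain = TRUE) {
  features <- as.matrix(features)
  y <- match(as.character(labels), classes)
  if (anyNA(y)) nbi_stop("labels outside class set", class = "nbi_bad_label")
  mu <- colMeans(features)
  sdv <- apply(features, 2L, stats::sd)
  sdv[sdv < 1e-8] <- 1
  Xs <- sweep(sweep(features, 2L, mu), 2L, sdv, "/")
  n <- nrow(Xs); k <- length(classes)
  ae <- if (pretrain) {
    train_autoencoder(Xs, hyper, seed = derive_seed(seed, 11L))
  } else {
    structure(list(params = ae_params(ncol(Xs), hyper$latent_dim,
                                      seed = derive_seed(seed, 11L)),
                   loss_history = numeric(0), hyper = hyper),
              class = "nbi_autoencoder")
  }
  p <- ae$params
  with_seed(derive_seed(seed, 12L), {
    Wh <- matrix(stats::rnorm(hyper$latent_dim * k,
                              0, sqrt(1 / hyper$latent_dim)),
                 hyper$latent_dim, k)
    bh <- numeric(k)
    st <- list(We = list(m = p$We * 0, v = p$We * 0),
               be = list(m = p$be * 0, v = p$be * 0),
               Wh = list(m = Wh * 0, v = Wh * 0),
               bh = list(m = bh * 0, v = bh * 0))
    t <- 0L
    ce_hist <- numeric(hyper$epochs)
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq.int(1L, n, by = hyper$batch_size)) {
        idx <- ord[start:min(start + hyper$batch_size - 1L, n)]
        m <- length(idx)
        Xb <- Xs[idx, , drop = FALSE]
        pre_e <- tcrossprod(Xb, p$We) + rep(p$be, each = m)
        Z <- ae_act(pre_e, p$activation)
        drop_mask <- if (hyper$dropout > 0) {
          matrix((stats::runif(m * hyper$latent_dim) >= hyper$dropout) /
                   (1 - hyper$dropout), m, hyper$latent_dim)
        } else NULL
        Zd <- if (is.null(drop_mask)) Z else Z * drop_mask
        logits <- Zd %*% Wh + rep(bh, each = m)
        lmax <- apply(logits, 1L, max)
        P <- exp(logits - lmax)
        P <- P / rowSums(P)
        ep_loss <- ep_loss -
          sum(log(pmax(P[cbind(seq_len(m), y[idx])], 1e-12)))
        dlog <- P
        dlog[cbind(seq_len(m), y[idx])] <-
          dlog[cbind(seq_len(m), y[idx])] - 1
        dlog <- dlog / m
        gWh <- crossprod(Zd, dlog); gbh <- colSums(dlog)
        dZ <- dlog %*% t(Wh)
        if (!is.null(drop_mask)) dZ <- dZ * drop_mask
        dpe <- dZ * ae_act_grad(pre_e, Z, p$activation)
        gWe <- crossprod(dpe, Xb); gbe <- colSums(dpe)
        t <- t + 1L
        u <- adam_update_mat(p$We, gWe, st$We, hyper$learning_rate, t)
        p$We <- u$p; st$We <- u$st
        u <- adam_update_mat(p$be, gbe, st$be, hyper$learning_rate, t)
        p$be <- u$p; st$be <- u$st
        u <- adam_update_mat(Wh, gWh, st$Wh, hyper$learning_rate, t)
        Wh <- u$p; st$Wh <- u$st
        u <- adam_update_mat(bh, gbh, st$bh, hyper$learning_rate, t)
        bh <- u$p; st$bh <- u$st
      }
      ce_hist[ep] <- ep_loss / n
    }
    structure(list(params = p, head = list(W = Wh, b = bh),
                   scaler = list(mean = mu, sd = sdv),
                   classes = classes, hyper = hyper,
                   recon_history = ae$loss_history, ce_history = ce_hist,
                   trained = TRUE),
              class = "nbi_ae_classifier")
  })
}

#' Class posteriors from the autoencoder classifier
#'
#' Standardizes the features with the training-split statistics, encodes
#' them, and applies the softmax head. Each posterior row sums to 1; the
#' predicted class is the argmax.
#'
#' @param X Feature vector or matrix (raw scale).
#' @param model A trained `nbi_ae_classifier`.
#' @return Posterior matrix (samples x 4) with class-named columns.
#' @export
classify <- function(X, model) {
  if (!inherits(model, "nbi_ae_classifier") || !isTRUE(model$trained)) {
    nbi_stop("model must be a trained nbi_ae_classifier",
             class = "nbi_untrained")
  }
  X <- as_row_matrix(X, model$params$input_dim, "classify")
  Xs <- sweep(sweep(X, 2L, model$scaler$mean), 2L, model$scaler$sd, "/")
  Z <- encode(Xs, model$params)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  logits <- Z %*% model$head$W + rep(model$head$b, each = nrow(Z))
  P <- exp(logits - apply(logits, 1L, max))
  P <- P / rowSums(P)
  colnames(P) <- model$classes
  P
}

#' @export
predict.nbi_ae_classifier <- function(object, newdata,
                                      type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- classify(newdata, object)
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.nbi_ae_classifier <- function(x, ...) {
  cat(sprintf(
    "<nbi_ae_classifier: %d -> %d latent, %d classes, dropout %.2f>\n",
    x$params$input_dim, x$params$latent_dim, length(x$classes),
    x$hyper$dropout))
  invisible(x)
}
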