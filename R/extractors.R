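# The three convolutional feature extractors whose embeddings are fused:
# an AlexNet-style network (five conv layers + two 4096-unit FC layers),
# a SqueezeNet-style network built from fire modules, and a capsule
# network (primary capsules + dynamically routed output capsules).
# Extractors are trained on the task with a temporary softmax head
# (Adam, categorical cross-entropy), then frozen; the classification head
# is dropped and features are read from the penultimate representation.

#' Capsule squashing nonlinearity
#'
#' Maps a vector `s` to `(||s||^2 / (1 + ||s||^2)) * s / ||s||`: the
#' direction is preserved and the output norm is `||s||^2 / (1 + ||s||^2)`,
#' which lies strictly below 1 and increases monotonically with `||s||`.
#' The zero vector maps to the zero vector (the continuous limit).
#'
#' @param s A finite numeric vector.
#' @return A vector of the same length with norm in \[0, 1).
#' @export
squash <- function(s) {
  if (!is.numeric(s) || anyNA(s) || any(!is.finite(s))) {
    nbi_stop("squash requires a finite numeric vector",
             class = "nbi_bad_input")
  }
  r <- sqrt(sum(s * s))
  if (r < 1e-300) return(s * 0)
  s * (r / (1 + r * r))
}

#' Routing softmax over parent capsules
#'
#' Converts routing logits for one child capsule into coupling
#' coefficients over its parent capsules:
#' `c_j = exp(b_j) / sum_k exp(b_k)`, computed with a max shift for
#' numerical stability. If `b` is a matrix the softmax is applied row-wise
#' (one row per child capsule).
#'
#' @param b Numeric vector of logits, or a matrix with one row per child.
#' @return Nonnegative coefficients summing to 1 (per row).
#' @export
routing_softmax <- function(b) {
  if (is.matrix(b)) {
    z <- b - apply(b, 1L, max)
    e <- exp(z)
    return(e / rowSums(e))
  }
  z <- b - max(b)
  e <- exp(z)
  e / sum(e)
}

#' Dynamic routing between capsule layers
#'
#' Runs the routing-by-agreement recursion on prediction vectors
#' `U[i, j, ]` (child capsule `i`'s prediction for parent `j`): coupling
#' coefficients `c = softmax(b)` over parents, aggregate input
#' `s_j = sum_i c_ij U_ij`, output `v_j = squash(s_j)`, and agreement
#' update `b_ij <- b_ij + U_ij . v_j`. Logits start at zero. All output
#' norms are below 1 by the squash bound.
#'
#' @param U Numeric array of shape `(n_child, n_parent, out_dim)`.
#' @param iterations Number of routing iterations (default 3).
#' @return List with `v` (matrix `n_parent` x `out_dim`), `coupling`
#'   (matrix `n_child` x `n_parent` used to compute the final `v`),
#'   `b` (final logits), `s`, and squash internals `r`, `h`.
#' @export
dynamic_routing <- function(U, iterations = 3L) {
  if (length(dim(U)) != 3L) {
    nbi_stop("U must be a (child, parent, dim) array",
             class = "nbi_bad_input")
  }
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    nbi_stop("iterations must be >= 1", class = "nbi_bad_input")
  }
  n_in <- dim(U)[1]; n_out <- dim(U)[2]; d_out <- dim(U)[3]
  Um <- matrix(U, n_in * n_out, d_out)          # (i, j) pairs as rows
  b <- matrix(0, n_in, n_out)
  cpl <- NULL; sq <- NULL; s <- NULL
  for (it in seq_len(iterations)) {
    cpl <- routing_softmax(b)
    s <- matrix(0, n_out, d_out)
    for (j in seq_len(n_out)) {
      rows <- (j - 1L) * n_in + seq_len(n_in)
      s[j, ] <- colSums(cpl[, j] * Um[rows, , drop = FALSE])
    }
    sq <- squash_rows(s)
    if (it < iterations) {
      agree <- Um %*% t(sq$v)                   # (i,j) rows x parents
      for (j in seq_len(n_out)) {
        rows <- (j - 1L) * n_in + seq_len(n_in)
        b[, j] <- b[, j] + agree[rows, j]
      }
    }
  }
  list(v = sq$v, coupling = cpl, b = b, s = s, r = sq$r, h = sq$h)
}

#' Specification of one feature extractor
#'
#' @param name One of `"alexnet_style"`, `"squeezenet_style"`,
#'   `"capsnet"`.
#' @param input_side Input image side in pixels (default 64; patches are
#'   resized to this side before the forward pass).
#' @param fc_units Width of the two fully connected layers of the
#'   AlexNet-style network (default 4096; the embedding is the second FC
#'   layer's activations).
#' @param dropout Dropout rate after each FC layer / before the final
#'   SqueezeNet convolution (default 0.5).
#' @param embedding_dim Embedding width for the SqueezeNet-style network
#'   (channels of its final 1 x 1 convolution; default 128).
#' @param width Channel multiplier in (0, 1\] shrinking every
#'   convolutional stage, for desk-scale experiments (default 1 = the
#'   reference architecture).
#' @return An object of class `extractor_spec`.
#' @export
extractor_spec <- function(name = c("alexnet_style", "squeezenet_style",
                                    "capsnet"),
                           input_side = 64L, fc_units = 4096L,
                           dropout = 0.5, embedding_dim = 128L,
                           width = 1) {
  name <- match.arg(name)
  input_side <- as.integer(input_side)
  if (is.na(input_side) || input_side < 16L || input_side %% 16L != 0L) {
    nbi_stop("input_side must be a multiple of 16 and >= 16",
             class = "nbi_bad_config")
  }
  if (width <= 0 || width > 1) {
    nbi_stop("width must be in (0, 1]", class = "nbi_bad_config")
  }
  structure(list(name = name, input_side = input_side,
                 fc_units = as.integer(fc_units), dropout = dropout,
                 embedding_dim = as.integer(embedding_dim), width = width),
            class = "extractor_spec")
}

scale_ch <- function(n, width) max(8L, as.integer(round(n * width)))

#' Build the AlexNet-style extractor
#'
#' Five 3 x 3 convolutional layers (96, 256, 384, 384, 256 filters at
#' `width = 1`), ReLU throughout, 2 x 2 stride-2 max pooling after conv1,
#' conv2 and conv5, then two fully connected layers of `fc_units` ReLU
#' units each followed by dropout. conv1 uses stride 2 so that the
#' flattened dimension stays manageable at the 64-px input side. The
#' softmax classification layer is attached only during training; the
#' embedding is the second FC layer's activation vector.
#'
#' @param spec An [extractor_spec()] with `name = "alexnet_style"`.
#' @param seed RNG seed for weight initialization.
#' @return An object of class `nbi_extractor`.
#' @export
build_alexnet_extractor <- function(spec = extractor_spec("alexnet_style"),
                                    seed = NULL) {
  stopifnot(inherits(spec, "extractor_spec"))
  if (spec$name != "alexnet_style") {
    nbi_stop("spec.name must be alexnet_style", class = "nbi_bad_config")
  }
  w <- spec$width
  ch <- c(scale_ch(96L, w), if (w == 1) 256L else scale_ch(256L, w),
          scale_ch(384L, w), scale_ch(384L, w), scale_ch(256L, w))
  side <- spec$input_side %/% 16L        # conv1 stride 2 + three pools
  flat <- side * side * ch[5]
  with_seed(seed, {
    layers <- list(
      layer_conv(3L, 3L, ch[1], stride = 2L),
      layer_maxpool(),
      layer_conv(3L, ch[1], ch[2]),
      layer_maxpool(),
      layer_conv(3L, ch[2], ch[3]),
      layer_conv(3L, ch[3], ch[4]),
      layer_conv(3L, ch[4], ch[5]),
      layer_maxpool(),
      layer_flatten(),
      layer_dense(flat, spec$fc_units),
      layer_dropout(spec$dropout),
      layer_dense(spec$fc_units, spec$fc_units),
      layer_dropout(spec$dropout)
    )
    structure(list(name = "alexnet_style", spec = spec, layers = layers,
                   embedding_dim = spec$fc_units, trained = FALSE),
              class = "nbi_extractor")
  })
}

#' Build the SqueezeNet-style extractor
#'
#' A stride-2 stem convolution followed by fire modules (1 x 1 squeeze
#' convolution feeding parallel 1 x 1 and 3 x 3 expand convolutions whose
#' outputs are concatenated), interleaved with max pooling, then dropout,
#' a final 1 x 1 convolution of `embedding_dim` channels and global
#' average pooling. The embedding is the pooled vector, so its length
#' equals the final convolution's channel count.
#'
#' @inheritParams build_alexnet_extractor
#' @param spec An [extractor_spec()] with `name = "squeezenet_style"`.
#' @return An object of class `nbi_extractor`.
#' @export
build_squeezenet_extractor <- function(spec = extractor_spec("squeezenet_style"),
                                       seed = NULL) {
  stopifnot(inherits(spec, "extractor_spec"))
  if (spec$name != "squeezenet_style") {
    nbi_stop("spec.name must be squeezenet_style", class = "nbi_bad_config")
  }
  w <- spec$width
  stem <- scale_ch(64L, w)
  s1 <- scale_ch(16L, w); e1 <- scale_ch(64L, w)
  s2 <- scale_ch(32L, w); e2 <- scale_ch(128L, w)
  with_seed(seed, {
    layers <- list(
      layer_conv(3L, 3L, stem, stride = 2L),
      layer_maxpool(),
      layer_fire(stem, s1, e1, e1),
      layer_fire(2L * e1, s1, e1, e1),
      layer_maxpool(),
      layer_fire(2L * e1, s2, e2, e2),
      layer_dropout(spec$dropout),
      layer_conv(1L, 2L * e2, spec$embedding_dim),
      layer_gap()
    )
    structure(list(name = "squeezenet_style", spec = spec, layers = layers,
                   embedding_dim = spec$embedding_dim, trained = FALSE),
              class = "nbi_extractor")
  })
}

#' Capsule layer configuration
#'
#' @param primary_dim Dimension of each primary capsule (default 8).
#' @param primary_channels Channels of the convolution feeding the
#'   primary capsules (default 32; must be a multiple of `primary_dim`).
#' @param num_output_capsules Number of routed output capsules
#'   (default 8).
#' @param output_dim Dimension of each output capsule (default 16).
#' @param routing_iterations Routing iterations (default 3).
#' @return An object of class `capsule_params`.
#' @export
capsule_params <- function(primary_dim = 8L, primary_channels = 32L,
                           num_output_capsules = 8L, output_dim = 16L,
                           routing_iterations = 3L) {
  if (primary_channels %% primary_dim != 0L) {
    nbi_stop("primary_channels must be a multiple of primary_dim",
             class = "nbi_bad_config")
  }
  if (routing_iterations < 1L) {
    nbi_stop("routing_iterations must be >= 1", class = "nbi_bad_config")
  }
  structure(list(primary_dim = as.integer(primary_dim),
                 primary_channels = as.integer(primary_channels),
                 num_output_capsules = as.integer(num_output_capsules),
                 output_dim = as.integer(output_dim),
                 routing_iterations = as.integer(routing_iterations)),
            class = "capsule_params")
}

#' Build the capsule-network extractor
#'
#' A convolutional stem, a stride-2 convolution whose activation map is
#' reshaped into primary capsules (squashed vectors of
#' `caps$primary_dim` components), and a routed capsule layer with
#' `caps$num_output_capsules` output capsules of `caps$output_dim`
#' dimensions. The embedding is the concatenation of the output capsule
#' vectors, so its length is `num_output_capsules * output_dim` and every
#' capsule's norm is below 1.
#'
#' @inheritParams build_alexnet_extractor
#' @param spec An [extractor_spec()] with `name = "capsnet"`.
#' @param caps A [capsule_params()].
#' @return An object of class `nbi_extractor`.
#' @export
build_capsnet_extractor <- function(spec = extractor_spec("capsnet"),
                                    caps = capsule_params(), seed = NULL) {
  stopifnot(inherits(spec, "extractor_spec"))
  if (spec$name != "capsnet") {
    nbi_stop("spec.name must be capsnet", class = "nbi_bad_config")
  }
  w <- spec$width
  stem <- scale_ch(64L, w)
  side <- spec$input_side %/% 8L       # stem stride 2, pool, caps stride 2
  n_in <- side * side * caps$primary_channels %/% caps$primary_dim
  with_seed(seed, {
    layers <- list(
      layer_conv(3L, 3L, stem, stride = 2L),
      layer_maxpool(),
      layer_conv(3L, stem, caps$primary_channels, stride = 2L,
                 activation = "linear"),
      layer_primary_caps(caps$primary_dim),
      layer_caps_routing(n_in, caps$primary_dim,
                         caps$num_output_capsules, caps$output_dim,
                         caps$routing_iterations)
    )
    structure(list(name = "capsnet", spec = spec, caps = caps,
                   layers = layers,
                   embedding_dim = caps$num_output_capsules * caps$output_dim,
                   trained = FALSE),
              class = "nbi_extractor")
  })
}

#' Build the default extractor trio
#'
#' @param input_side Shared input side (default 64).
#' @param width Channel multiplier for desk-scale runs (default 1).
#' @param fc_units AlexNet-style FC width (default 4096).
#' @param caps A [capsule_params()].
#' @param seed RNG seed; each extractor derives its own stream.
#' @return Named list of `nbi_extractor` objects in fusion order
#'   (alexnet, squeezenet, capsnet).
#' @export
build_extractors <- function(input_side = 64L, width = 1, fc_units = 4096L,
                             caps = capsule_params(), seed = NULL) {
  list(
    alexnet = build_alexnet_extractor(
      extractor_spec("alexnet_style", input_side = input_side,
                     fc_units = fc_units, width = width),
      seed = derive_seed(seed, 1L)),
    squeezenet = build_squeezenet_extractor(
      extractor_spec("squeezenet_style", input_side = input_side,
                     width = width),
      seed = derive_seed(seed, 2L)),
    capsnet = build_capsnet_extractor(
      extractor_spec("capsnet", input_side = input_side, width = width),
      caps = caps, seed = derive_seed(seed, 3L))
  )
}

#' Summarize an extractor's architecture
#'
#' @param net An `nbi_extractor`.
#' @return A `data.frame` with one row per layer: type, kernel size,
#'   stride, filter/unit count and dropout rate where applicable.
#' @export
extractor_summary <- function(net) {
  stopifnot(inherits(net, "nbi_extractor"))
  rows <- lapply(net$layers, function(l) {
    data.frame(
      type = l$type,
      kernel = if (l$type == "conv") l$k else NA_integer_,
      stride = if (l$type == "conv") l$stride else NA_integer_,
      units = switch(l$type, conv = l$out_ch, dense = l$out_dim,
                     caps_routing = l$n_out * l$out_dim, NA_integer_),
      dropout = if (l$type == "dropout") l$rate else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "input_side") <- net$spec$input_side
  attr(out, "embedding_dim") <- net$embedding_dim
  out
}

#' @export
print.nbi_extractor <- function(x, ...) {
  cat(sprintf("<nbi_extractor: %s, input %dx%dx3, embedding %d, %s>\n",
              x$name, x$spec$input_side, x$spec$input_side,
              x$embedding_dim,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Resize to the extractor's input side and scale to roughly [-0.5, 0.5].
prep_input <- function(img, side) {
  resize_patch(img, side) / 255 - 0.5
}

#' Forward an image through one extractor (evaluation mode)
#'
#' @param net An `nbi_extractor`.
#' @param img An H x W x 3 patch in \[0, 255\]; resized internally.
#' @return The embedding as a numeric vector.
#' @export
extractor_embed <- function(net, img) {
  assert_image_patch(img)
  x <- prep_input(img, net$spec$input_side)
  net_forward(net, x, train = FALSE)$out
}

#' Train an extractor with a temporary softmax head
#'
#' Attaches a dense softmax classification head to the embedding, trains
#' the whole network with Adam on categorical cross-entropy, then drops
#' the head. Gradients are averaged over mini-batches; dropout is active
#' during training only.
#'
#' @param net An `nbi_extractor`.
#' @param images List of H x W x 3 patches in \[0, 255\].
#' @param labels Factor or character vector of class labels.
#' @param epochs Training epochs (default 3).
#' @param batch_size Mini-batch size (default 8).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed RNG seed (shuffling, dropout, head init).
#' @param classes Class levels (default [nbi_classes()]).
#' @param verbose Print per-epoch loss.
#' @return The trained extractor (head removed, `trained = TRUE`) with a
#'   `loss_history` field of mean per-epoch cross-entropy.
#' @export
train_extractor <- function(net, images, labels, epochs = 3L,
                            batch_size = 8L, lr = 1e-3, seed = NULL,
                            classes = nbi_classes(), verbose = FALSE) {
  stopifnot(inherits(net, "nbi_extractor"))
  y <- match(as.character(labels), classes)
  if (anyNA(y)) {
    nbi_stop("labels outside the class set", class = "nbi_bad_label")
  }
  n <- length(images)
  k <- length(classes)
  with_seed(seed, {
    head <- layer_dense(net$embedding_dim, k, activation = "linear")
    full <- net
    full$layers <- c(net$layers, list(head))
    state <- adam_init(full)
    t <- 0L
    hist <- numeric(epochs)
    xs <- lapply(images, prep_input, side = net$spec$input_side)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq.int(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        acc <- NULL
        bloss <- 0
        for (i in idx) {
          fw <- net_forward(full, xs[[i]], train = TRUE)
          p <- softmax_vec(fw$out)
          bloss <- bloss - log(max(p[y[i]], 1e-12))
          dlog <- p
          dlog[y[i]] <- dlog[y[i]] - 1
          bw <- net_backward(full, fw$caches, dlog)
          acc <- accumulate_grads(acc, bw$grads)
        }
        acc <- scale_grads(acc, 1 / length(idx))
        t <- t + 1L
        upd <- adam_step(full, acc, state, lr, t)
        full <- upd$net
        state <- upd$state
        ep_loss <- ep_loss + bloss
      }
      hist[ep] <- ep_loss / n
      if (verbose) {
        message(sprintf("  [%s] epoch %d/%d  ce %.4f", net$name, ep,
                        epochs, hist[ep]))
      }
    }
    out <- net
    out$layers <- full$layers[seq_along(net$layers)]
    out$trained <- TRUE
    out$loss_history <- hist
    out
  })
}

#' Fuse the three extractors' embeddings for one image
#'
#' Resizes the patch to each extractor's input side, forwards it in
#' evaluation mode, and concatenates the embeddings in the fixed order
#' alexnet, squeezenet, capsnet. Span offsets of each extractor's block
#' are recorded in the `"spans"` attribute.
#'
#' @param img An H x W x 3 patch in \[0, 255\].
#' @param extractors Named list from [build_extractors()].
#' @return Numeric vector of length equal to the summed embedding
#'   dimensions, with a `"spans"` attribute.
#' @export
extract_fused <- function(img, extractors) {
  assert_image_patch(img)
  parts <- lapply(extractors, extractor_embed, img = img)
  ends <- cumsum(lengths(parts))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  spans <- data.frame(extractor = names(extractors), start = starts,
                      end = ends)
  structure(unlist(parts, use.names = FALSE), spans = spans)
}

#' Fused feature matrix for a set of images
#'
#' @param images List of patches, or a manifest `data.frame` whose
#'   `file_path` column is read from disk.
#' @param extractors Named list from [build_extractors()].
#' @param verbose Report progress every 50 images.
#' @return Numeric matrix, one row per image, with the `"spans"`
#'   attribute of [extract_fused()].
#' @export
extract_features <- function(images, extractors, verbose = FALSE) {
  if (is.data.frame(images)) {
    images <- lapply(images$file_path, read_patch)
  }
  rows <- vector("list", length(images))
  spans <- NULL
  for (i in seq_along(images)) {
    f <- extract_fused(images[[i]], extractors)
    if (is.null(spans)) spans <- attr(f, "spans")
    rows[[i]] <- as.numeric(f)
    if (verbose && i %% 50L == 0L) {
      message(sprintf("  extracted %d/%d", i, length(images)))
    }
  }
  structure(do.call(rbind, rows), spans = spans)
}
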