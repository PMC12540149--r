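# End-to-end orchestration: generate (or ingest) patches, median-filter,
# train the three extractors, fuse features, tune the autoencoder
# classifier with the OOA, train the final model and evaluate on the
# held-out test split. `nbi_fit()` is the central fitting function; it
# returns a classed model with predict/print/summary methods, and
# `run_pipeline()` wraps it with data generation and artifact writing.

#' Pipeline configuration
#'
#' Collects the per-stage configurations and the master seed. Every
#' random stage derives its own stream from `seed`, so a full run is
#' reproducible from this object alone.
#'
#' @param seed Master RNG seed.
#' @param generator A [generator_config()] for synthetic data.
#' @param filter A [filter_config()] for preprocessing.
#' @param input_side Extractor input side (default 64).
#' @param width Extractor channel multiplier (default 1).
#' @param fc_units AlexNet-style FC width (default 4096).
#' @param caps A [capsule_params()].
#' @param extractor_epochs,extractor_batch,extractor_lr Extractor
#'   training schedule.
#' @param ooa_n,ooa_iterations OOA population size and iteration budget.
#' @param ooa_fitness `"precision"` or `"accuracy"`.
#' @param tune_epochs_cap Epoch cap for per-candidate training during
#'   tuning.
#' @param ooa_space Optional [ooa_space()] overriding
#'   [ae_search_space()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            generator = generator_config(seed = seed),
                            filter = filter_config(),
                            input_side = 64L, width = 1, fc_units = 4096L,
                            caps = capsule_params(),
                            extractor_epochs = 3L, extractor_batch = 8L,
                            extractor_lr = 1e-3,
                            ooa_n = 6L, ooa_iterations = 5L,
                            ooa_fitness = c("precision", "accuracy"),
                            tune_epochs_cap = 30L,
                            ooa_space = NULL) {
  structure(list(seed = as.integer(seed), generator = generator,
                 filter = filter, input_side = as.integer(input_side),
                 width = width, fc_units = as.integer(fc_units),
                 caps = caps,
                 extractor_epochs = as.integer(extractor_epochs),
                 extractor_batch = as.integer(extractor_batch),
                 extractor_lr = extractor_lr,
                 ooa_n = as.integer(ooa_n),
                 ooa_iterations = as.integer(ooa_iterations),
                 ooa_fitness = match.arg(ooa_fitness),
                 tune_epochs_cap = as.integer(tune_epochs_cap),
                 ooa_space = ooa_space),
            class = "pipeline_config")
}

run_stage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"),
                               name))
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    nbi_stop("stage '", name, "' failed: ", conditionMessage(e),
             class = "nbi_stage_error")
  })
  if (verbose) {
    message(sprintf("[%s] %s done (%.1f s)",
                    format(Sys.time(), "%H:%M:%S"), name,
                    proc.time()[["elapsed"]] - t0))
  }
  out
}

#' Fit the fused-feature autoencoder classifier
#'
#' The central modelling routine: median-filters the training and
#' validation images in memory, trains the three extractors on the
#' training split with temporary softmax heads, fuses their embeddings,
#' tunes the autoencoder hyperparameters with the OOA against validation
#' fitness, and trains the final autoencoder classifier with the best
#' hyperparameters.
#'
#' @param manifest Manifest `data.frame` with `file_path`, `class_label`
#'   and `split` columns (see [generate_dataset()]).
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return An object of class `nbi_model`.
#' @export
nbi_fit <- function(manifest, config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("file_path", "class_label", "split")
  if (!all(need %in% names(manifest))) {
    nbi_stop("manifest lacks columns: ",
             paste(setdiff(need, names(manifest)), collapse = ", "),
             class = "nbi_bad_manifest")
  }
  tr <- manifest$split == "train"
  va <- manifest$split == "val"
  if (!any(tr) || !any(va)) {
    nbi_stop("manifest needs non-empty train and val splits",
             class = "nbi_bad_manifest")
  }
  seed <- config$seed
  imgs <- run_stage("preprocess (median filter)", verbose, {
    lapply(manifest$file_path[tr | va], function(p) {
      median_filter(read_patch(p), config$filter)
    })
  })
  labs <- manifest$class_label[tr | va]
  tr2 <- manifest$split[tr | va] == "train"
  extractors <- run_stage("train extractors", verbose, {
    ex <- build_extractors(input_side = config$input_side,
                           width = config$width,
                           fc_units = config$fc_units, caps = config$caps,
                           seed = derive_seed(seed, 21L))
    for (nm in names(ex)) {
      ex[[nm]] <- train_extractor(
        ex[[nm]], imgs[tr2], labs[tr2],
        epochs = config$extractor_epochs,
        batch_size = config$extractor_batch,
        lr = config$extractor_lr,
        seed = derive_seed(seed, 22L + match(nm, names(ex))),
        verbose = verbose)
    }
    ex
  })
  feats <- run_stage("extract fused features", verbose, {
    extract_features(imgs, extractors, verbose = verbose)
  })
  ftr <- feats[tr2, , drop = FALSE]
  fva <- feats[!tr2, , drop = FALSE]
  tuning <- run_stage("OOA hyperparameter tuning", verbose, {
    space <- if (is.null(config$ooa_space)) {
      ae_search_space(max_latent = min(64L, ncol(ftr)))
    } else config$ooa_space
    tune_ae_hyperparams(ftr, labs[tr2], fva, labs[!tr2],
                        space = space, n = config$ooa_n,
                        iterations = config$ooa_iterations,
                        seed = derive_seed(seed, 31L),
                        fitness = config$ooa_fitness,
                        epochs_cap = config$tune_epochs_cap,
                        verbose = verbose)
  })
  classifier <- run_stage("final autoencoder training", verbose, {
    train_ae_classifier(ftr, labs[tr2], tuning$best_hyper,
                        seed = derive_seed(seed, 41L))
  })
  structure(list(extractors = extractors, classifier = classifier,
                 tuning = tuning, config = config,
                 classes = nbi_classes(),
                 feature_spans = attr(feats, "spans"),
                 n_train = sum(tr2), n_val = sum(!tr2)),
            class = "nbi_model")
}

# Accept a manifest data.frame, a list of patches, or one patch.
coerce_images <- function(newdata) {
  if (is.data.frame(newdata)) {
    lapply(newdata$file_path, read_patch)
  } else if (is.list(newdata)) {
    newdata
  } else if (is_image_patch(newdata)) {
    list(newdata)
  } else {
    nbi_stop("newdata must be a manifest, a list of patches, or a patch",
             class = "nbi_bad_input")
  }
}

#' Predict classes for new patches
#'
#' Applies the fitted preprocessing (median filter), extracts fused
#' features with the frozen extractors and returns posterior
#' probabilities or class labels.
#'
#' @param object An `nbi_model`.
#' @param newdata Manifest `data.frame`, list of H x W x 3 patches, or a
#'   single patch.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted labels, or a posterior matrix.
#' @export
predict.nbi_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  images <- coerce_images(newdata)
  images <- lapply(images, median_filter, cfg = object$config$filter)
  feats <- extract_features(images, object$extractors)
  if (type == "prob") classify(feats, object$classifier) else
    predict(object$classifier, feats)
}

#' @export
print.nbi_model <- function(x, ...) {
  dims <- vapply(x$extractors, function(e) e$embedding_dim, integer(1))
  cat("Fused-feature autoencoder classifier\n")
  cat(sprintf("  extractors: %s (fused dim %d)\n",
              paste(sprintf("%s[%d]", names(dims), dims), collapse = " + "),
              sum(dims)))
  cat(sprintf("  autoencoder: latent %d, lr %.2g, dropout %.2f, epochs %d\n",
              x$classifier$hyper$latent_dim,
              x$classifier$hyper$learning_rate, x$classifier$hyper$dropout,
              x$classifier$hyper$epochs))
  cat(sprintf("  tuned validation fitness: %.4f\n", x$tuning$best_fitness))
  cat(sprintf("  trained on %d patches (%d validation)\n",
              x$n_train, x$n_val))
  invisible(x)
}

#' @export
summary.nbi_model <- function(object, ...) {
  cat("== Extractors ==\n")
  for (nm in names(object$extractors)) {
    cat("--", nm, "--\n")
    print(extractor_summary(object$extractors[[nm]]))
  }
  cat("\n== Tuned hyperparameters ==\n")
  utils::str(unclass(object$tuning$best_hyper))
  cat("\n== OOA convergence (best fitness per iteration) ==\n")
  print(signif(object$tuning$history, 4))
  invisible(object)
}

#' Run the full pipeline end to end
#'
#' Generates (or ingests) the dataset, fits the model with [nbi_fit()],
#' evaluates it on the held-out test split and writes the artifacts:
#' `metrics.json`, `confusion_matrix.csv`, `ooa_history.csv`,
#' `manifest.csv` and a reproducibility record (`run_record.json`) with
#' all derived seeds and a checksum of the configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for artifacts.
#' @param manifest Optional pre-built manifest (e.g. from
#'   [ingest_external_dataset()]); when `NULL` a synthetic dataset is
#'   generated under `out_dir/data` from `config$generator`.
#' @param verbose Print stage progress.
#' @return List of class `nbi_run`: `model` (the `nbi_model`), `metrics`
#'   (an `nbi_metrics` for the test split), `manifest`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         manifest = NULL, verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(manifest)) {
    manifest <- run_stage("generate synthetic dataset", verbose, {
      generate_dataset(config$generator, file.path(out_dir, "data"))
    })
  }
  model <- nbi_fit(manifest, config, verbose = verbose)
  te <- manifest$split == "test"
  if (!any(te)) {
    nbi_stop("manifest has no test split", class = "nbi_bad_manifest")
  }
  metrics <- run_stage("evaluate on test split", verbose, {
    post <- predict(model, manifest[te, , drop = FALSE], type = "prob")
    pred <- model$classes[max.col(post, ties.method = "first")]
    compute_metrics(manifest$class_label[te], pred, post)
  })
  paths <- run_stage("write artifacts", verbose, {
    p <- list(
      metrics = file.path(out_dir, "metrics.json"),
      confusion = file.path(out_dir, "confusion_matrix.csv"),
      ooa_history = file.path(out_dir, "ooa_history.csv"),
      manifest = file.path(out_dir, "manifest.csv"),
      record = file.path(out_dir, "run_record.json"))
    jsonlite::write_json(metrics_as_list(metrics), p$metrics,
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame.matrix(unclass(metrics$confusion)),
                     p$confusion)
    utils::write.csv(
      data.frame(iteration = seq_along(model$tuning$history) - 1L,
                 best_fitness = model$tuning$history,
                 mean_fitness = model$tuning$mean_history),
      p$ooa_history, row.names = FALSE)
    utils::write.csv(manifest, p$manifest, row.names = FALSE)
    cfg_json <- jsonlite::toJSON(rapply(unclass(config), unclass,
                                        how = "replace"),
                                 auto_unbox = TRUE, force = TRUE)
    jsonlite::write_json(
      list(seed = config$seed,
           derived_seeds = list(generator = config$generator$seed,
                                extractors = derive_seed(config$seed, 21L),
                                tuning = derive_seed(config$seed, 31L),
                                final_model = derive_seed(config$seed, 41L)),
           config_checksum = sum(utf8ToInt(as.character(cfg_json))),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      p$record, auto_unbox = TRUE)
    p
  })
  structure(list(model = model, metrics = metrics, manifest = manifest,
                 paths = paths, config = config),
            class = "nbi_run")
}

#' @export
print.nbi_run <- function(x, ...) {
  cat("Pipeline run on", x$metrics$n, "test patches\n\n")
  print(x$model)
  cat("\nTest-split macro metrics:\n")
  print(round(x$metrics$macro, 4))
  invisible(x)
}

#' Diagnostic plots for a pipeline run
#'
#' Draws the OOA convergence trace and a shaded confusion matrix.
#'
#' @param x An `nbi_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nbi_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  h <- x$model$tuning$history
  graphics::plot(seq_along(h) - 1L, h, type = "b", pch = 19,
                 xlab = "OOA iteration", ylab = "best validation fitness",
                 main = "Tuning convergence", ...)
  cm <- unclass(x$metrics$confusion)
  k <- nrow(cm)
  graphics::image(seq_len(k), seq_len(k), t(cm[k:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = "Confusion matrix")
  graphics::axis(1, at = seq_len(k), labels = colnames(cm))
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(cm)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    graphics::text(j, k + 1L - i, cm[i, j])
  }
  invisible(x)
}

#' Build a manifest from a class-labelled directory tree
#'
#' Expects `root_dir` to contain one subdirectory per tissue class
#' (matched case-insensitively against `Hbv`, `He`, `IPCL`, `Le`) of
#' PNG/JPEG images. Per-class counts are compared against the study
#' composition of 330 patches per class, with a warning on mismatch.
#' Unknown subdirectories are an error.
#'
#' @param root_dir Dataset root directory.
#' @param split_fractions Stratified split fractions (named `train`,
#'   `val`, `test`, summing to 1).
#' @param seed RNG seed for the split assignment.
#' @param expected_per_class Reference per-class count (default 330).
#' @return A manifest `data.frame`.
#' @export
ingest_external_dataset <- function(root_dir,
                                    split_fractions = c(train = 0.7,
                                                        val = 0.15,
                                                        test = 0.15),
                                    seed = 1L, expected_per_class = 330L) {
  if (!dir.exists(root_dir)) {
    nbi_stop("directory not found: ", root_dir, class = "nbi_io_error")
  }
  dirs <- list.dirs(root_dir, recursive = FALSE, full.names = TRUE)
  if (length(dirs) == 0L) {
    nbi_stop("no class subdirectories under ", root_dir,
             class = "nbi_bad_manifest")
  }
  cls_map <- match(tolower(basename(dirs)), tolower(nbi_classes()))
  if (anyNA(cls_map)) {
    nbi_stop("unknown class folder(s): ",
             paste(basename(dirs)[is.na(cls_map)], collapse = ", "),
             "; accepted names (case-insensitive): ",
             paste(nbi_classes(), collapse = ", "),
             class = "nbi_bad_label")
  }
  records <- list()
  with_seed(seed, {
    for (d in seq_along(dirs)) {
      cl <- nbi_classes()[cls_map[d]]
      files <- list.files(dirs[d], pattern = "\\.(png|jpe?g)$",
                          ignore.case = TRUE, full.names = TRUE)
      if (length(files) == 0L) next
      if (length(files) != expected_per_class) {
        warning(sprintf("class %s has %d images (study composition: %d)",
                        cl, length(files), expected_per_class),
                call. = FALSE)
      }
      splits <- stratified_split(length(files), split_fractions)
      records[[cl]] <- data.frame(
        image_id = paste0(cl, "_", sub("\\.[^.]+$", "", basename(files))),
        file_path = files, class_label = cl, split = splits,
        stringsAsFactors = FALSE)
    }
  })
  if (length(records) == 0L) {
    nbi_stop("no images found under ", root_dir,
             class = "nbi_bad_manifest")
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}
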