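# Synthetic four-class texture patches emulating the laryngeal NBI patch
# dataset layout: 100 x 100 px RGB patches in four balanced classes, with
# optional salt-and-pepper corruption so the median-filter stage has an
# observable effect.
#
# The four texture families are procedural stand-ins, not histology:
#   Hbv  - curvilinear high-contrast filaments on a reddish base
#   He   - smooth, low-variance pale background
#   IPCL - scattered dark dots on a pink base
#   Le   - bright irregular blobs on a dull base
# They are constructed to differ in simple pixel statistics (mean colour,
# variance) so that downstream learning is verifiable against chance.

#' The four tissue class labels
#'
#' Returns the class taxonomy used throughout the package: hypertrophic
#' blood vessels (`Hbv`), healthy tissue (`He`), IPCL-like vessels
#' (`IPCL`) and leukoplakia (`Le`), in their stable encoding order
#' (integer codes 0 to 3).
#'
#' @return Character vector of length four.
#' @export
nbi_classes <- function() c("Hbv", "He", "IPCL", "Le")

#' Configuration for the synthetic patch generator
#'
#' @param patch_side Side length of the square patches, in pixels
#'   (default 100, matching the study patches).
#' @param per_class_count Number of patches per class (default 330, for a
#'   1,320-patch dataset across the four classes).
#' @param noise_fraction Proportion of pixels replaced by salt-and-pepper
#'   noise, in \[0, 1\] (default 0.05).
#' @param seed Integer RNG seed for reproducible generation.
#' @param texture_params Named list of per-class amplitude/frequency
#'   scalars; missing entries fall back to defaults.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(patch_side = 100L, per_class_count = 330L,
                             noise_fraction = 0.05, seed = 1L,
                             texture_params = list()) {
  patch_side <- as.integer(patch_side)
  per_class_count <- as.integer(per_class_count)
  if (is.na(patch_side) || patch_side < 16L) {
    nbi_stop("patch_side must be an integer >= 16", class = "nbi_bad_config")
  }
  if (is.na(per_class_count) || per_class_count < 1L) {
    nbi_stop("per_class_count must be >= 1", class = "nbi_bad_config")
  }
  if (!is.numeric(noise_fraction) || noise_fraction < 0 || noise_fraction > 1) {
    nbi_stop("noise_fraction must lie in [0, 1]", class = "nbi_bad_config")
  }
  defaults <- list(
    Hbv  = list(amplitude = 90, frequency = 9),
    He   = list(amplitude = 6,  frequency = 2),
    IPCL = list(amplitude = 80, frequency = 14),
    Le   = list(amplitude = 70, frequency = 5)
  )
  for (cl in names(texture_params)) {
    if (!cl %in% nbi_classes()) {
      nbi_stop("unknown class in texture_params: ", cl,
               class = "nbi_bad_config")
    }
    defaults[[cl]] <- utils::modifyList(defaults[[cl]], texture_params[[cl]])
  }
  structure(list(patch_side = patch_side, per_class_count = per_class_count,
                 noise_fraction = noise_fraction, seed = seed,
                 texture_params = defaults),
            class = "generator_config")
}

# Smooth random field on an n x n grid: sum of a few random-phase sinusoids
# at the given spatial frequency. Values roughly in [-1, 1].
random_field <- function(n, frequency, waves = 4L) {
  gx <- matrix(seq_len(n) / n, n, n)
  gy <- matrix(seq_len(n) / n, n, n, byrow = TRUE)
  f <- matrix(0, n, n)
  for (w in seq_len(waves)) {
    th <- stats::runif(1, 0, 2 * pi)
    ph <- stats::runif(1, 0, 2 * pi)
    fr <- frequency * stats::runif(1, 0.6, 1.4)
    f <- f + sin(2 * pi * fr * (cos(th) * gx + sin(th) * gy) + ph)
  }
  f / waves
}

#' Generate one synthetic tissue patch
#'
#' Draws a single `patch_side` x `patch_side` RGB patch from the texture
#' family of `label`. The four families differ by construction in mean
#' colour and variance: `Hbv` carries curvilinear high-contrast filaments,
#' `He` is a smooth low-variance background, `IPCL` shows scattered dark
#' dots and `Le` bright irregular blobs. Pixel values are kept in
#' \[1, 254\] before corruption so salt (255) and pepper (0) pixels are
#' unambiguous. Uses the current RNG state; seed via [set.seed()] or
#' [generate_dataset()].
#'
#' @param label One of [nbi_classes()].
#' @param cfg A [generator_config()].
#' @return An H x W x 3 numeric array with values in \[0, 255\].
#' @export
generate_patch <- function(label, cfg = generator_config()) {
  if (!inherits(cfg, "generator_config")) {
    nbi_stop("cfg must be a generator_config", class = "nbi_bad_config")
  }
  if (length(label) != 1L || !label %in% nbi_classes()) {
    nbi_stop("unknown class label: ", paste(label, collapse = ","),
             class = "nbi_bad_label")
  }
  n <- cfg$patch_side
  tp <- cfg$texture_params[[label]]
  base <- switch(label,
    Hbv  = c(150, 70, 80),    # reddish, vessel-rich
    He   = c(210, 170, 170),  # pale pink, homogeneous
    IPCL = c(170, 120, 140),  # mid pink with dark puncta
    Le   = c(110, 100, 90))   # dull base under bright plaques
  img <- array(rep(base, each = n * n), c(n, n, 3L))

  if (label == "Hbv") {
    # filaments: thresholded band structure of a smooth field
    f <- random_field(n, tp$frequency)
    ridge <- exp(-(f / 0.18)^2)          # thin curvilinear ridges near f = 0
    img[, , 1] <- img[, , 1] - tp$amplitude * ridge * 0.9
    img[, , 2] <- img[, , 2] - tp$amplitude * ridge * 0.3
    img[, , 3] <- img[, , 3] - tp$amplitude * ridge * 0.4
    img <- img + array(stats::rnorm(n * n * 3, 0, 6), c(n, n, 3L))
  } else if (label == "He") {
    f <- random_field(n, tp$frequency)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + tp$amplitude * f
    img <- img + array(stats::rnorm(n * n * 3, 0, 1.5), c(n, n, 3L))
  } else if (label == "IPCL") {
    # scattered dark dots: sparse impulse field smoothed into puncta
    ndots <- max(8L, round(n * n / 160))
    cx <- stats::runif(ndots, 1, n)
    cy <- stats::runif(ndots, 1, n)
    gx <- matrix(seq_len(n), n, n)
    gy <- matrix(seq_len(n), n, n, byrow = TRUE)
    dots <- matrix(0, n, n)
    r2 <- (n / tp$frequency / 2.2)^2
    for (d in seq_len(ndots)) {
      dots <- dots + exp(-((gx - cx[d])^2 + (gy - cy[d])^2) / r2)
    }
    dots <- pmin(dots, 1)
    for (ch in 1:3) img[, , ch] <- img[, , ch] - tp$amplitude * dots
    img <- img + array(stats::rnorm(n * n * 3, 0, 4), c(n, n, 3L))
  } else { # Le
    f <- random_field(n, tp$frequency)
    blobs <- pmax(f - 0.25, 0) / 0.75     # irregular bright plaques
    for (ch in 1:3) img[, , ch] <- img[, , ch] + tp$amplitude * 1.6 * blobs
    img <- img + array(stats::rnorm(n * n * 3, 0, 5), c(n, n, 3L))
  }

  img <- pmin(pmax(img, 1), 254)
  if (cfg$noise_fraction > 0) {
    img <- add_salt_pepper(img, cfg$noise_fraction)
  }
  img
}

# Replace a fraction of pixels (all three channels jointly) with salt
# (255) or pepper (0). The position draw happens before the value draw so
# that two runs from the same RNG state corrupt the same pixels whenever
# their noise fractions admit it.
add_salt_pepper <- function(img, fraction) {
  n <- dim(img)[1] * dim(img)[2]
  u <- stats::runif(n)
  hit <- u < fraction
  if (!any(hit)) return(img)
  val <- ifelse(stats::runif(sum(hit)) < 0.5, 0, 255)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[hit] <- val
    img[, , ch] <- plane
  }
  img
}

#' Materialize a balanced synthetic dataset on disk
#'
#' Generates `per_class_count` patches for each of the four classes,
#' writes them as PNG files under `<out_dir>/<class>/<image_id>.png`, and
#' writes a `manifest.csv` with columns
#' `image_id,file_path,class_label,split`. The split is stratified by
#' class at the requested fractions. Generation is deterministic in
#' `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @param split_fractions Named numeric vector over `train`, `val`,
#'   `test`; must sum to 1.
#' @return The manifest as a `data.frame` (invisibly also written to
#'   `<out_dir>/manifest.csv`).
#' @export
generate_dataset <- function(cfg = generator_config(), out_dir,
                             split_fractions = c(train = 0.7, val = 0.15,
                                                 test = 0.15)) {
  if (!inherits(cfg, "generator_config")) {
    nbi_stop("cfg must be a generator_config", class = "nbi_bad_config")
  }
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    nbi_stop("split_fractions must sum to 1", class = "nbi_bad_config")
  }
  if (!all(c("train", "val", "test") %in% names(split_fractions))) {
    nbi_stop("split_fractions needs names train, val, test",
             class = "nbi_bad_config")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    nbi_stop("cannot create output directory: ", out_dir,
             class = "nbi_io_error")
  }
  records <- vector("list", 4L * cfg$per_class_count)
  k <- 0L
  with_seed(cfg$seed, {
    for (cl in nbi_classes()) {
      splits <- stratified_split(cfg$per_class_count, split_fractions)
      for (i in seq_len(cfg$per_class_count)) {
        img <- generate_patch(cl, cfg)
        id <- sprintf("%s_%04d", cl, i)
        path <- file.path(out_dir, cl, paste0(id, ".png"))
        write_patch(img, path)
        k <- k + 1L
        records[[k]] <- data.frame(image_id = id, file_path = path,
                                   class_label = cl, split = splits[i],
                                   stringsAsFactors = FALSE)
      }
    }
  })
  manifest <- do.call(rbind, records)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

# Deterministic (given RNG state) stratified split assignment for one
# class of `n` items. Counts are rounded to integers that sum to n, with
# train absorbing the remainder.
stratified_split <- function(n, fractions) {
  n_val <- round(n * fractions[["val"]])
  n_test <- round(n * fractions[["test"]])
  n_train <- n - n_val - n_test
  sample(c(rep("train", n_train), rep("val", n_val), rep("test", n_test)))
}

#' Load the manifest written by [generate_dataset()]
#'
#' @param path Path to a manifest CSV.
#' @return A `data.frame` with columns `image_id`, `file_path`,
#'   `class_label`, `split`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    nbi_stop("manifest not found: ", path, class = "nbi_io_error")
  }
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "file_path", "class_label", "split")
  if (!all(need %in% names(m))) {
    nbi_stop("manifest lacks required columns: ",
             paste(setdiff(need, names(m)), collapse = ", "),
             class = "nbi_bad_manifest")
  }
  m
}
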