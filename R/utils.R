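#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules: image IO, resizing, seeded RNG
# scoping. Images are H x W x 3 numeric arrays with values in [0, 255].

nbi_stop <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "nbi_error")))
}

is_image_patch <- function(x) {
  is.numeric(x) && is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L
}

assert_image_patch <- function(x, what = "img") {
  if (!is_image_patch(x)) {
    nbi_stop(what, " must be an H x W x 3 numeric array",
             class = "nbi_bad_image")
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    nbi_stop(what, " must have finite values in [0, 255]",
             class = "nbi_bad_image")
  }
  invisible(x)
}

#' Read an RGB patch from a PNG file
#'
#' @param path Path to a PNG file.
#' @return An H x W x 3 numeric array with values in \[0, 255\].
#' @export
read_patch <- function(path) {
  if (!file.exists(path)) {
    nbi_stop("image file not found: ", path, class = "nbi_io_error")
  }
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' Write an RGB patch to a PNG file
#'
#' @param img An H x W x 3 numeric array with values in \[0, 255\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patch <- function(img, path) {
  assert_image_patch(img)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    png::writePNG(img / 255, target = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    nbi_stop("failed to write image: ", path, class = "nbi_io_error")
  }
  invisible(path)
}

# Bilinear resize of an RGB patch to side x side (EBImage affine transform).
resize_patch <- function(img, side) {
  if (dim(img)[1] == side && dim(img)[2] == side) return(img)
  out <- EBImage::resize(img / 255, w = side, h = side)
  pmin(pmax(out * 255, 0), 255)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. `seed = NULL` leaves the
# global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic child seed below 2^31 derived from a master seed and an
# index, used to give every pipeline stage / tuning candidate its own
# reproducible stream.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}
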