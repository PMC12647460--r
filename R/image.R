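#' RGB images and instance label maps
#'
#' `organtraits` represents an RGB image as a numeric array of dimension
#' `c(height, width, 3)` with channel order (R, G, B) and intensities in
#' `[0, 255]`, and an instance label map as an integer matrix of the same
#' height/width where 0 is background and `k >= 1` is organ instance `k`.
#' Image coordinates are 0-based, origin at the top-left corner,
#' `x` = column and `y` = row; a pixel's center sits at integer coordinates.
#'
#' @param pixels numeric array `c(H, W, 3)` in `[0, 255]`.
#' @return `rgb_image()` returns its validated input invisibly classed as
#'   `"rgb_image"` (a plain array; the class is informational).
#' @name image-representation
NULL

#' @rdname image-representation
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_organtraits("an RGB image must be an H x W x 3 array")
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop_organtraits("image height and width must be >= 1")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop_organtraits("pixel intensities must lie in [0, 255]")
  }
  structure(pixels, class = c("rgb_image", class(pixels)))
}

# EBImage stores color images as (x = width, y = height, channel); convert.
from_ebimage <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) {
    d <- array(rep(d, 3L), dim = c(dim(d), 3L))
    warning("grayscale input replicated to 3 channels", call. = FALSE)
  }
  if (dim(d)[3] == 4L) d <- d[, , 1:3, drop = FALSE] # drop alpha
  aperm(d, c(2L, 1L, 3L)) * 255
}

to_ebimage <- function(pixels) {
  EBImage::Image(aperm(pixels / 255, c(2L, 1L, 3L)), colormode = "Color")
}

#' Read an RGB image from PNG or JPEG
#'
#' Decodes to an `H x W x 3` array with channels in (R, G, B) order and 8-bit
#' intensity scale regardless of on-disk layout; 16-bit inputs are rescaled to
#' `[0, 255]`, grayscale inputs are replicated to three channels with a warning.
#'
#' @param path path to a PNG or JPEG file.
#' @return numeric array `c(H, W, 3)`, values in `[0, 255]`.
#' @export
#' @examples
#' img <- generate_rosette(scene_spec(n_organs = 4, seed = 1))$image
#' f <- tempfile(fileext = ".png")
#' write_image(img, f)
#' img2 <- read_image(f)
#' stopifnot(identical(dim(img), dim(img2)))
read_image <- function(path) {
  if (!file.exists(path)) stop_organtraits("image file does not exist: ", path)
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) {
      stop_organtraits("cannot decode '", path, "' as PNG/JPEG: ", conditionMessage(e))
    }
  )
  px <- from_ebimage(img)
  # EBImage already maps 8- and 16-bit integer data to [0,1]; scale is uniform.
  rgb_image(clamp(px, 0, 255))
}

#' Write an RGB image to PNG or JPEG
#'
#' @param pixels `H x W x 3` array in `[0, 255]`.
#' @param path output path; format chosen from the extension (.png/.jpg/.jpeg).
#' @param quality JPEG quality (ignored for PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path, quality = 95L) {
  EBImage::writeImage(to_ebimage(pixels), path, quality = quality)
  invisible(path)
}

#' Read an instance label map from a single-channel integer image
#'
#' Labels are relabeled on load to a contiguous set `{0..N}` preserving the
#' order of first appearance in raster-scan order (rows top to bottom, columns
#' left to right); 0 stays background. The number of instances is available as
#' `attr(map, "n_instances")`.
#'
#' @param path path to a single-channel PNG (8- or 16-bit).
#' @return integer matrix `H x W`.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop_organtraits("label-map file does not exist: ", path)
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) {
      stop_organtraits("cannot decode '", path, "': ", conditionMessage(e))
    }
  )
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) {
    chans <- dim(d)[3]
    flat <- matrix(d, ncol = chans)
    if (all(abs(flat - flat[, 1]) < 1e-9)) {
      d <- d[, , 1] # gray stored as identical channels
    } else {
      stop_organtraits(
        "'", path, "' is a multi-channel image, not a label map; ",
        "convert it to a single-channel integer image first"
      )
    }
  }
  labels <- matrix(as.integer(round(t(d) * 65535)), nrow = ncol(d), ncol = nrow(d))
  # readImage scales n-bit integer data to [0,1] by (2^n - 1). 8-bit content
  # then lands on exact multiples of 257; undo that so 8-bit label values
  # come back numerically unchanged before relabeling.
  if (length(labels) > 0L && all(labels %% 257L == 0L)) {
    labels <- labels %/% 257L
  }
  relabel_map(labels)
}

#' Write an instance label map as an 8-bit single-channel PNG
#'
#' @param map integer matrix, labels in `0..255` (an image holds far fewer
#'   organ instances in practice).
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(map, path) {
  if (max(map) > 255L) {
    stop_organtraits("label values exceed the 8-bit PNG range (max 255 instances)")
  }
  EBImage::writeImage(EBImage::Image(t(map / 255)), path)
  invisible(path)
}

#' Relabel an instance map to contiguous labels `{0..N}`
#'
#' A map whose labels already form `{1..N}` is returned unchanged. Otherwise
#' labels are compacted in order of first appearance in raster scan (rows top
#' to bottom, columns left to right); background (0) is untouched. The
#' per-label pixel multiset is unchanged, only names move.
#'
#' @param map integer matrix with non-negative labels.
#' @return integer matrix with labels `0..N` and attribute `n_instances = N`.
#' @export
relabel_map <- function(map) {
  if (any(map < 0)) stop_organtraits("label map contains negative values")
  storage.mode(map) <- "integer"
  labs <- sort(unique(as.vector(map)))
  labs <- labs[labs != 0L]
  if (identical(labs, seq_along(labs))) {
    attr(map, "n_instances") <- length(labs)
    return(map)
  }
  relabel_raster(map)
}

# Always relabel by raster-scan first appearance (row-major).
relabel_raster <- function(map) {
  seen <- unique(as.vector(t(map)))
  seen <- seen[seen != 0L]
  lut <- integer(max(c(map, 0L)) + 1L)
  lut[seen + 1L] <- seq_along(seen)
  out <- matrix(lut[map + 1L], nrow = nrow(map), ncol = ncol(map))
  attr(out, "n_instances") <- length(seen)
  out
}

#' Labels present in an instance map (background excluded)
#' @param map integer matrix.
#' @return increasing integer vector of instance labels.
#' @export
map_labels <- function(map) {
  u <- sort(unique(as.vector(map)))
  u[u != 0L]
}

# Luma grayscale on [0, 255].
luma_gray <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}
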