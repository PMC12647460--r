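#' Paired image/label augmentation
#'
#' Applies a sequence of augmentation operations to an image and its instance
#' label map. Geometric operations (flip, rotation, scaling, cropping) are
#' applied identically to both; the label map is always resampled
#' nearest-neighbor so labels stay integral. Photometric operations (noise,
#' color dithering) touch the image only. All randomness flows from `seed`.
#'
#' Supported operations (elements of `ops`): `"hflip"`, `"rotate90"`
#' (90 degrees clockwise), `list("gaussian_noise", sigma = )`,
#' `list("color_dither", delta = )`, `list("random_scale", range = c(lo, hi))`,
#' `list("random_crop", size = c(h, w))`.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param map integer label matrix of matching size.
#' @param ops non-empty list of operations, applied in order.
#' @param seed integer seed.
#' @return list with `image` and `map`.
#' @export
augment <- function(image, map, ops, seed = 1L) {
  assert_same_dim(image, map)
  if (length(ops) == 0L) stop_organtraits("ops must be non-empty")
  withr::with_seed(seed, {
    for (op in ops) {
      name <- if (is.character(op)) op[1] else as.character(op[[1]])
      pars <- if (is.list(op)) op[-1] else list()
      res <- switch(name,
        hflip = aug_hflip(image, map),
        rotate90 = aug_rotate90(image, map),
        gaussian_noise = aug_noise(image, map, pars$sigma %||% 5),
        color_dither = aug_dither(image, map, pars$delta %||% 10),
        random_scale = aug_scale(image, map, pars$range %||% c(0.8, 1.2)),
        random_crop = aug_crop(image, map, pars$size),
        stop_organtraits("unknown augmentation op: ", name)
      )
      image <- res$image
      map <- res$map
    }
  })
  list(image = image, map = map)
}

aug_hflip <- function(image, map) {
  w <- ncol(map)
  list(image = image[, w:1, , drop = FALSE], map = map[, w:1, drop = FALSE])
}

# 90 degrees clockwise: (r, c) -> (c, H - r + 1).
aug_rotate90 <- function(image, map) {
  h <- nrow(map)
  rot_m <- function(m) t(m)[, h:1, drop = FALSE]
  img2 <- array(0, dim = c(ncol(map), h, 3))
  for (ch in 1:3) img2[, , ch] <- rot_m(image[, , ch])
  list(image = img2, map = rot_m(map))
}

aug_noise <- function(image, map, sigma) {
  if (sigma > 0) {
    image <- clamp(image + array(stats::rnorm(length(image), 0, sigma), dim(image)), 0, 255)
  }
  list(image = image, map = map)
}

aug_dither <- function(image, map, delta) {
  if (delta > 0) {
    image <- clamp(image + array(stats::runif(length(image), -delta, delta), dim(image)), 0, 255)
  }
  list(image = image, map = map)
}

aug_scale <- function(image, map, range) {
  s <- stats::runif(1, range[1], range[2])
  h <- nrow(map); w <- ncol(map)
  h2 <- max(1L, round(h * s)); w2 <- max(1L, round(w * s))
  ri <- clamp(round((seq_len(h2) - 0.5) / s + 0.5), 1L, h)
  ci <- clamp(round((seq_len(w2) - 0.5) / s + 0.5), 1L, w)
  img2 <- array(0, dim = c(h2, w2, 3))
  for (ch in 1:3) img2[, , ch] <- image[ri, ci, ch]
  list(image = img2, map = map[ri, ci, drop = FALSE])
}

aug_crop <- function(image, map, size) {
  if (is.null(size)) stop_organtraits("random_crop needs size = c(h, w)")
  h <- nrow(map); w <- ncol(map)
  if (size[1] > h || size[2] > w) {
    stop_organtraits("crop size (", size[1], "x", size[2], ") exceeds image (", h, "x", w, ")")
  }
  r0 <- sample.int(h - size[1] + 1L, 1L)
  c0 <- sample.int(w - size[2] + 1L, 1L)
  list(
    image = image[r0:(r0 + size[1] - 1L), c0:(c0 + size[2] - 1L), , drop = FALSE],
    map = map[r0:(r0 + size[1] - 1L), c0:(c0 + size[2] - 1L), drop = FALSE]
  )
}
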