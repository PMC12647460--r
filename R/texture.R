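#' Texture traits: Hu moment invariants and gray-gradient co-occurrence
#'
#' The 22 texture traits of the catalog are computed over the union of all
#' organ pixels in an image: the 7 Hu moment invariants of the binary organ
#' support, and 15 features of the gray-gradient co-occurrence matrix (GGCM),
#' the joint histogram of quantized gray level and quantized Sobel gradient
#' magnitude.
#'
#' @name texture
NULL

#' Hu moment invariants of the organ support
#'
#' Computes the standard seven Hu invariants phi1..phi7 from central moments
#' normalized by `mu00^((p+q)/2 + 1)`. By default the region is treated as a
#' binary `{0,1}` density (shape descriptor); set `weighted = TRUE` for a
#' grayscale-weighted variant (luma intensities as density). phi7's sign is
#' preserved, so mirror images are distinguishable. phi1..phi6 are invariant
#' under translation exactly and under rotation/scaling up to digitization
#' error.
#'
#' @param image `H x W x 3` RGB array (only used when `weighted = TRUE`).
#' @param map integer label matrix; the union of labels > 0 is the support.
#' @param weighted use luma intensities instead of the binary support.
#' @return named numeric vector `Hu_moment1` .. `Hu_moment7`; all `NA` for an
#'   empty support.
#' @export
hu_moments <- function(image, map, weighted = FALSE) {
  assert_same_dim(image, map)
  sel <- map > 0L
  nm <- paste0("Hu_moment", 1:7)
  if (!any(sel)) return(stats::setNames(rep(trait_sentinel(), 7L), nm))
  idx <- which(sel, arr.ind = TRUE)
  x <- idx[, 2] - 1 # x = column, 0-based
  y <- idx[, 1] - 1
  w <- if (weighted) luma_gray(image)[sel] else rep(1, length(x))
  stats::setNames(hu_from_points(x, y, w), nm)
}

# Hu invariants from weighted point coordinates.
hu_from_points <- function(x, y, w) {
  m00 <- sum(w)
  xb <- sum(w * x) / m00
  yb <- sum(w * y) / m00
  dx <- x - xb
  dy <- y - yb
  mu <- function(p, q) sum(w * dx^p * dy^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
        (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
        (3 * (n30 + n12)^2 - (n21 + n03)^2)
  )
}

# Shift a matrix by (dr, dc) with edge replication.
shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- clamp(seq_len(nr) - dr, 1L, nr)
  ci <- clamp(seq_len(nc) - dc, 1L, nc)
  m[ri, ci, drop = FALSE]
}

# Sobel gradient magnitude of a grayscale matrix (edge-replicated frame).
sobel_magnitude <- function(g) {
  gx <- (shift_replicate(g, -1, -1) + 2 * shift_replicate(g, 0, -1) + shift_replicate(g, 1, -1)) -
    (shift_replicate(g, -1, 1) + 2 * shift_replicate(g, 0, 1) + shift_replicate(g, 1, 1))
  gy <- (shift_replicate(g, -1, -1) + 2 * shift_replicate(g, -1, 0) + shift_replicate(g, -1, 1)) -
    (shift_replicate(g, 1, -1) + 2 * shift_replicate(g, 1, 0) + shift_replicate(g, 1, 1))
  sqrt(gx^2 + gy^2)
}

# Fill background pixels adjacent to the support with the value of their
# nearest organ neighbor (orthogonal neighbors first, then diagonal; fixed
# N, S, W, E, NW, NE, SW, SE priority for determinism), so the Sobel window
# of boundary organ pixels never mixes in background intensities.
fill_background_ring <- function(gray, sel) {
  shifts <- list(
    c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)
  )
  out <- gray
  filled <- sel
  for (s in shifts) {
    nb_sel <- shift_replicate(sel, s[1], s[2])
    nb_val <- shift_replicate(gray, s[1], s[2])
    take <- !filled & nb_sel
    out[take] <- nb_val[take]
    filled <- filled | take
  }
  out
}

#' Gray-gradient co-occurrence matrix over organ pixels
#'
#' Grayscale by luma (`0.299 R + 0.587 G + 0.114 B`); gradient magnitude by a
#' 3x3 Sobel on the grayscale with background pixels at the support boundary
#' replaced by their nearest organ value (and the image frame replicated).
#' Gray is linearly quantized to 16 bins over `[0, 255]`, gradient to 16 bins
#' over `[0, max gradient within the support]`; the joint histogram is
#' accumulated over organ pixels only and normalized to sum 1. A constant
#' organ (zero gradient range) puts all mass in gradient bin 1.
#'
#' @inheritParams hu_moments
#' @param gray_bins,gradient_bins number of quantization bins (16 each).
#' @return `gray_bins x gradient_bins` matrix summing to 1, with attributes
#'   `counts` (raw histogram) and `max_gradient`.
#' @export
gray_gradient_matrix <- function(image, map, gray_bins = 16L, gradient_bins = 16L) {
  assert_same_dim(image, map)
  sel <- map > 0L
  if (!any(sel)) stop_organtraits("gray_gradient_matrix needs at least one organ pixel")
  g <- luma_gray(image)
  g_filled <- fill_background_ring(g, sel)
  grad <- sobel_magnitude(g_filled)
  gv <- g[sel]
  sv <- grad[sel]
  gbin <- pmin(floor(gv / 256 * gray_bins), gray_bins - 1L) + 1L
  gmax <- max(sv)
  sbin <- if (gmax > 0) pmin(floor(sv / gmax * gradient_bins), gradient_bins - 1L) + 1L
  else rep(1L, length(sv))
  counts <- matrix(0, gray_bins, gradient_bins)
  tab <- table(factor(gbin, levels = 1:gray_bins), factor(sbin, levels = 1:gradient_bins))
  counts[] <- as.numeric(tab)
  M <- counts / sum(counts)
  attr(M, "counts") <- counts
  attr(M, "max_gradient") <- gmax
  M
}

ggcm_feature_names <- function() {
  c(
    "GGCM_Small_Gradient_Dominance", "GGCM_Large_Gradient_Dominance",
    "GGCM_Gray_Asymmetry", "GGCM_Gradient_Asymmetry", "GGCM_Energy",
    "GGCM_Gray_Mean", "GGCM_Gradient_Mean",
    "GGCM_Gray_Variance", "GGCM_Gradient_Variance", "GGCM_Correlation",
    "GGCM_Gray_Entropy", "GGCM_Gradient_Entropy", "GGCM_Mixed_Entropy",
    "GGCM_Inertia", "GGCM_Inverse_Difference_Moment"
  )
}

#' The 15 canonical gray-gradient co-occurrence features
#'
#' With `M(i, j)` the normalized matrix (gray bin `i`, gradient bin `j`,
#' 1-based), marginals `p_g(i) = sum_j M(i,j)`, `p_s(j) = sum_i M(i,j)`,
#' means/SDs `mu_g, mu_s, sigma_g, sigma_s` of the bin-index marginals:
#' small/large gradient dominance `sum M/j^2` and `sum M*j^2`; gray/gradient
#' asymmetry `sum p^2`; energy `sum M^2`; gray/gradient mean and variance of
#' the marginals; correlation
#' `sum (i-mu_g)(j-mu_s) M / (sigma_g sigma_s)` (0 when a marginal is
#' degenerate); entropies `-sum p log p` and mixed entropy `-sum M log M`
#' (natural log, `0 log 0 = 0`); inertia `sum (i-j)^2 M`; inverse difference
#' moment `sum M / (1 + (i-j)^2)`.
#'
#' @param M normalized matrix from [gray_gradient_matrix()].
#' @return named numeric vector of the 15 features, in catalog order.
#' @export
ggcm_features <- function(M) {
  if (abs(sum(M) - 1) > 1e-6) stop_organtraits("GGCM must be normalized to sum 1")
  ni <- nrow(M); nj <- ncol(M)
  i <- matrix(seq_len(ni), ni, nj)
  j <- matrix(seq_len(nj), ni, nj, byrow = TRUE)
  pg <- rowSums(M)
  ps <- colSums(M)
  mu_g <- sum(seq_len(ni) * pg)
  mu_s <- sum(seq_len(nj) * ps)
  var_g <- sum((seq_len(ni) - mu_g)^2 * pg)
  var_s <- sum((seq_len(nj) - mu_s)^2 * ps)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  corr <- if (var_g > 0 && var_s > 0) {
    sum((i - mu_g) * (j - mu_s) * M) / sqrt(var_g * var_s)
  } else 0
  stats::setNames(c(
    sum(M / j^2),
    sum(M * j^2),
    sum(pg^2),
    sum(ps^2),
    sum(M^2),
    mu_g,
    mu_s,
    var_g,
    var_s,
    corr,
    ent(pg),
    ent(ps),
    ent(M),
    sum((i - j)^2 * M),
    sum(M / (1 + (i - j)^2))
  ), ggcm_feature_names())
}

#' All 22 texture traits of one image
#' @inheritParams hu_moments
#' @return named numeric vector: `Hu_moment1..7` then the 15 GGCM features.
#'   All `NA` when the map has no organ pixels.
#' @export
texture_traits <- function(image, map) {
  if (!any(map > 0L)) {
    return(stats::setNames(
      rep(trait_sentinel(), 22L),
      c(paste0("Hu_moment", 1:7), ggcm_feature_names())
    ))
  }
  c(hu_moments(image, map), ggcm_features(gray_gradient_matrix(image, map)))
}
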