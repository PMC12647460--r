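#' Classical segmentation baselines
#'
#' The comparison baselines: excess-green (ExG) index plus Otsu thresholding,
#' K-means color clustering, and connected-component instance extraction. On
#' scenes with touching organs these under-count instances relative to the
#' ground-truth masks — the characteristic failure mode that motivates
#' instance segmentation.
#'
#' @name baselines
NULL

#' Excess-green vegetation index
#'
#' `ExG = 2G - R - B` per pixel on 0-255 channels; range `[-510, 510]`.
#' High values indicate green vegetation.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @return numeric matrix `H x W`.
#' @export
exg_index <- function(image) {
  2 * image[, , 2] - image[, , 1] - image[, , 3]
}

#' Linearly rescale a grayscale grid to integers in `[0, 255]`
#' @param gray numeric matrix.
#' @return integer-valued matrix in `[0, 255]` (constant input maps to 0).
#' @export
rescale_to_uint8 <- function(gray) {
  rng <- range(gray)
  if (rng[1] == rng[2]) {
    return(matrix(0L, nrow(gray), ncol(gray)))
  }
  matrix(
    as.integer(round((gray - rng[1]) / (rng[2] - rng[1]) * 255)),
    nrow(gray), ncol(gray)
  )
}

#' Otsu threshold of an 8-bit grayscale grid
#'
#' Selects the threshold maximizing the between-class variance over the
#' 256-bin histogram; ties are broken toward the lower threshold. The
#' foreground mask is `value > threshold` (greenness-style grids are high for
#' plants). A constant image yields an empty foreground with a warning.
#'
#' @param gray matrix of integers in `[0, 255]`.
#' @return list with `threshold` (intensity) and `mask` (0/1 integer matrix).
#' @export
otsu_threshold <- function(gray) {
  v <- as.vector(gray)
  if (any(v < 0 | v > 255) || any(v != round(v))) {
    stop_organtraits("otsu_threshold expects integers in [0, 255]; see rescale_to_uint8()")
  }
  if (min(v) == max(v)) {
    warning("constant image: empty foreground", call. = FALSE)
    return(list(
      threshold = v[1],
      mask = matrix(0L, nrow(gray), ncol(gray))
    ))
  }
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                 # P(class0) for thresholds t = 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  thr <- which.max(sigma_b) - 1L     # which.max takes the first (lowest) tie
  mask <- matrix(as.integer(gray > thr), nrow(gray), ncol(gray))
  list(threshold = thr, mask = mask)
}

# k-means++ center initialization on an n x d matrix, seeded.
kmeanspp_centers <- function(X, k, seed) {
  withr::with_seed(seed, {
    n <- nrow(X)
    centers <- matrix(NA_real_, k, ncol(X))
    centers[1, ] <- X[sample.int(n, 1L), ]
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    if (k > 1L) {
      for (j in 2:k) {
        pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[j, ] <- X[sample.int(n, 1L, prob = pr), ]
        d2j <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
        d2 <- pmin(d2, d2j)
      }
    }
    centers
  })
}

#' K-means color clustering of an RGB image
#'
#' Lloyd's algorithm on RGB triples with k-means++-style seeding from the
#' given seed; runs to convergence or 300 iterations and is deterministic for
#' a fixed seed. The cluster with the highest mean ExG is designated "plant".
#' If the image has fewer distinct colors than `k`, `k` is reduced with a
#' warning.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param k number of clusters (>= 1).
#' @param seed integer seed controlling initialization.
#' @return list with `clusters` (integer matrix `H x W`, values `1..k`),
#'   `centers` (`k x 3`), `plant_cluster` (cluster id), and `mask`
#'   (0/1 matrix of the plant cluster).
#' @export
kmeans_segment <- function(image, k, seed = 1L) {
  if (k < 1L) stop_organtraits("k must be >= 1")
  X <- cbind(
    as.vector(image[, , 1]),
    as.vector(image[, , 2]),
    as.vector(image[, , 3])
  )
  ndistinct <- nrow(unique(X))
  if (k > ndistinct) {
    warning("k reduced from ", k, " to ", ndistinct, " (distinct colors)", call. = FALSE)
    k <- ndistinct
  }
  if (k == 1L) {
    centers <- matrix(colMeans(X), 1L)
    cl <- rep(1L, nrow(X))
  } else {
    init <- kmeanspp_centers(unique(X), k, seed)
    km <- suppressWarnings(
      stats::kmeans(X, centers = init, iter.max = 300L, algorithm = "Lloyd")
    )
    centers <- km$centers
    cl <- km$cluster
  }
  clusters <- matrix(as.integer(cl), nrow(image), ncol(image))
  # mean ExG per cluster from its center color
  exg_c <- 2 * centers[, 2] - centers[, 1] - centers[, 3]
  plant <- which.max(exg_c)
  list(
    clusters = clusters,
    centers = centers,
    plant_cluster = plant,
    mask = matrix(as.integer(clusters == plant), nrow(image), ncol(image))
  )
}

# Connected-component labeling via the pixel-adjacency graph (igraph).
# Returns an integer matrix with components labeled 1..N in raster-scan order
# of their first pixel; attribute n_components.
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop_organtraits("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask > 0)
  out <- matrix(0L, h, w)
  if (length(fg) == 0L) {
    attr(out, "n_components") <- 0L
    return(out)
  }
  id <- integer(h * w)
  id[fg] <- seq_along(fg)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  rc <- arrayInd(fg, c(h, w))
  for (s in shifts) {
    r2 <- rc[, 1] + s[1]
    c2 <- rc[, 2] + s[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    ok2 <- id[nb] > 0L
    if (any(ok2)) {
      edges[[length(edges) + 1L]] <- cbind(id[fg[ok]][ok2], id[nb][ok2])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)$membership
  out[fg] <- comp
  # relabel in raster-scan (row-major) order of first appearance
  out <- relabel_raster(out)
  attr(out, "n_components") <- attr(out, "n_instances")
  out
}

#' Extract instances from a binary mask by connected components
#'
#' Maximal connected foreground components are labeled `1..N` in raster-scan
#' order of their first pixel; components below `min_area` pixels are dropped
#' (salt-noise suppression) and the survivors relabeled contiguously.
#'
#' @param mask 0/1 integer matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param min_area minimum component area in pixels (default 20).
#' @return integer label matrix with attribute `n_instances`.
#' @export
connected_components <- function(mask, connectivity = 8L, min_area = 20L) {
  lab <- label_components(mask, connectivity)
  n <- attr(lab, "n_components")
  if (n > 0L && min_area > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    drop <- which(sizes < min_area)
    if (length(drop) > 0L) {
      lab[lab %in% drop] <- 0L
      lab <- relabel_raster(lab)
    }
  }
  attr(lab, "n_instances") <- length(map_labels(lab))
  lab
}

#' Run a classical baseline segmenter on an image
#'
#' `"otsu"`: Otsu thresholding of the rescaled ExG index; `"kmeans"`: K-means
#' (k = 2) plant-cluster mask. Either way the binary mask is turned into
#' instances by 8-connected components.
#'
#' @param image `H x W x 3` RGB array.
#' @param method `"otsu"` or `"kmeans"`.
#' @param seed seed for the K-means initialization.
#' @param min_area minimum instance area in pixels.
#' @return integer instance label matrix.
#' @export
segment_baseline <- function(image, method = c("otsu", "kmeans"), seed = 1L,
                             min_area = 20L) {
  method <- match.arg(method)
  mask <- switch(method,
    otsu = otsu_threshold(rescale_to_uint8(exg_index(image)))$mask,
    kmeans = kmeans_segment(image, k = 2L, seed = seed)$mask
  )
  connected_components(mask, connectivity = 8L, min_area = min_area)
}
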