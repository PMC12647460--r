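#' Read a LabelMe-dialect polygon annotation file
#'
#' Parses the JSON layout used by the LabelMe annotation tool: a `shapes`
#' array whose elements carry a `label` string and a `points` list of
#' `(x, y)` vertices, plus `imageHeight` / `imageWidth`.
#'
#' @param path path to a LabelMe JSON file.
#' @return a list with `shapes` (list of `list(label=, points=)` where
#'   `points` is an n x 2 matrix of x,y image coordinates), `imageHeight`,
#'   `imageWidth`.
#' @export
read_labelme <- function(path) {
  if (!file.exists(path)) stop_organtraits("annotation file does not exist: ", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$imageHeight) || is.null(j$imageWidth)) {
    stop_organtraits("'", path, "' lacks imageHeight/imageWidth")
  }
  shapes <- lapply(j$shapes %||% list(), function(s) {
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p)[1:2])))
    list(label = as.character(s$label %||% "organ"), points = pts)
  })
  list(
    shapes = shapes,
    imageHeight = as.integer(j$imageHeight),
    imageWidth = as.integer(j$imageWidth)
  )
}

#' Write a LabelMe-dialect polygon annotation file
#'
#' @param ann annotation list as returned by [read_labelme()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(ann, path) {
  shapes <- lapply(ann$shapes, function(s) {
    list(
      label = s$label,
      points = lapply(seq_len(nrow(s$points)), function(i) as.numeric(s$points[i, ])),
      shape_type = "polygon"
    )
  })
  jsonlite::write_json(
    list(
      shapes = shapes,
      imageHeight = ann$imageHeight,
      imageWidth = ann$imageWidth
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# Even-odd (ray-crossing) point-in-polygon test on pixel centers, with
# boundary pixel-centers counted as inside. Vectorized over query points.
# px, py: query coordinates; vx, vy: polygon vertices (open ring).
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  stopifnot(n >= 3L)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary check: point within the segment's bounding box and collinear
    dx <- x2 - x1; dy <- y2 - y1
    cross <- (px - x1) * dy - (py - y1) * dx
    within <- (px >= pmin(x1, x2) - 1e-9) & (px <= pmax(x1, x2) + 1e-9) &
      (py >= pmin(y1, y2) - 1e-9) & (py <= pmax(y1, y2) + 1e-9)
    on_edge <- on_edge | (abs(cross) <= 1e-9 * max(1, abs(dx), abs(dy)) & within)
    # even-odd crossing of the horizontal ray towards +x
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * dx / dy
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside | on_edge
}

#' Rasterize polygon annotations to an instance label map
#'
#' A pixel belongs to a polygon iff its center lies inside under the even-odd
#' rule; pixel centers that fall exactly on a polygon edge count as inside.
#' Shapes are rasterized in file order and later shapes overwrite earlier ones
#' where they overlap. Polygons with fewer than 3 vertices are skipped with a
#' warning; an empty shape list yields an all-zero map.
#'
#' @param ann annotation list as returned by [read_labelme()].
#' @return integer matrix `imageHeight x imageWidth` with labels `0..N` and
#'   attribute `n_instances`.
#' @export
rasterize_polygons <- function(ann) {
  h <- ann$imageHeight
  w <- ann$imageWidth
  if (is.null(h) || is.null(w) || h < 1L || w < 1L) {
    stop_organtraits("annotation must carry imageHeight/imageWidth >= 1")
  }
  map <- matrix(0L, nrow = h, ncol = w)
  lab <- 0L
  for (s in ann$shapes) {
    pts <- s$points
    if (is.null(pts) || nrow(pts) < 3L) {
      warning("skipping polygon with fewer than 3 vertices", call. = FALSE)
      next
    }
    lab <- lab + 1L
    vx <- clamp(pts[, 1], 0, w - 1)
    vy <- clamp(pts[, 2], 0, h - 1)
    x0 <- max(0L, floor(min(vx)))
    x1 <- min(w - 1L, ceiling(max(vx)))
    y0 <- max(0L, floor(min(vy)))
    y1 <- min(h - 1L, ceiling(max(vy)))
    if (x1 < x0 || y1 < y0) next
    grid <- expand.grid(x = x0:x1, y = y0:y1)
    hit <- points_in_polygon(grid$x, grid$y, vx, vy)
    if (any(hit)) {
      map[cbind(grid$y[hit] + 1L, grid$x[hit] + 1L)] <- lab
    }
  }
  relabel_map(map)
}
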