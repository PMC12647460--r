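#' Per-instance geometry and plant-level morphological traits
#'
#' The morphometry layer turns an instance label map into per-organ geometry
#' (area, perimeter, bounding rectangles, convex hull) and aggregates it into
#' the 35-entry morphological trait set reported per image. All values are in
#' pixel units.
#'
#' Conventions (stated because they fix the numbers):
#' * Area is the count of pixels carrying a label.
#' * Perimeter is the length of the traced outer contour polygon through
#'   boundary pixel *centers*; orthogonal steps contribute 1, diagonal steps
#'   sqrt(2). An `n x n` square therefore measures `4(n-1)`. This polyline
#'   estimator overstates smooth boundaries by up to ~8% (staircase effect);
#'   see the methods vignette. Holes are ignored (outer contour only).
#' * Convex hull, minimum-area rectangle, and the axis-aligned box treat each
#'   pixel as a unit square: hulls/rectangles are computed over boundary-pixel
#'   corner points, so a filled `10 x 10` block has hull area 100 and the
#'   containment chain area <= hull_area <= mbb_area <= ortho box area holds.
#' * Roundness is the isoperimetric ratio `4*pi*area / perimeter^2`.
#'
#' @name morphometry
NULL

#' Pixel count of one instance
#' @param map integer label matrix.
#' @param label instance label (>= 1) present in `map`.
#' @return area in square pixels.
#' @export
instance_area <- function(map, label) {
  n <- sum(map == label)
  if (n == 0L) stop_organtraits("label ", label, " not present in map")
  n
}

# Ordered outer contour of one instance as 0-based (x, y) pixel centers.
# If the instance is not 8-connected, traces the largest component (warns).
instance_contour <- function(map, label) {
  sel <- map == label
  if (!any(sel)) stop_organtraits("label ", label, " not present in map")
  comp <- label_components(sel, connectivity = 8L)
  ncomp <- attr(comp, "n_components")
  if (ncomp > 1L) {
    warning("instance ", label, " is not 8-connected; using its largest component",
      call. = FALSE
    )
    sizes <- tabulate(comp[comp > 0L], nbins = ncomp)
    sel <- comp == which.max(sizes)
  }
  # crop to the bounding box (padded) for tracing speed
  rows <- range(which(rowSums(sel) > 0))
  cols <- range(which(colSums(sel) > 0))
  sub <- sel[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  oc <- EBImage::ocontour(matrix(as.integer(sub), nrow(sub), ncol(sub)))[[1]]
  # ocontour returns 0-based (row, col) pairs; convert to (x, y)
  cbind(
    x = oc[, 2] + (cols[1] - 1L),
    y = oc[, 1] + (rows[1] - 1L)
  )
}

# Polyline length of a closed contour through pixel centers.
contour_length <- function(contour) {
  n <- nrow(contour)
  if (n < 2L) return(0)
  p <- rbind(contour, contour[1L, , drop = FALSE])
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Outer-contour perimeter of one instance
#' @inheritParams instance_area
#' @return perimeter in pixels; 0 for a single-pixel instance (degenerate
#'   contour, excluded from roundness aggregates).
#' @export
instance_perimeter <- function(map, label) {
  contour_length(instance_contour(map, label))
}

#' Isoperimetric roundness
#' @param area area in square pixels.
#' @param perimeter perimeter in pixels.
#' @return `4*pi*area / perimeter^2` (1 for an ideal circle, pi/4 for an ideal
#'   square); `NA` when `perimeter == 0`.
#' @export
roundness <- function(area, perimeter) {
  ifelse(perimeter > 0, 4 * pi * area / perimeter^2, trait_sentinel())
}

#' Axis-aligned ("orthogonal") bounding-rectangle extents
#' @inheritParams instance_area
#' @return named numeric `c(length=, width=)`, `length >= width`; extents are
#'   `max - min + 1` per axis (pixel-as-unit-square).
#' @export
orthogonal_bbox <- function(map, label) {
  idx <- which(map == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_organtraits("label ", label, " not present in map")
  ext_r <- diff(range(idx[, 1])) + 1
  ext_c <- diff(range(idx[, 2])) + 1
  c(length = max(ext_r, ext_c), width = min(ext_r, ext_c))
}

# Corner points (pixel-as-unit-square model) of a set of pixel centers.
pixel_corners <- function(centers) {
  x <- centers[, 1]; y <- centers[, 2]
  cbind(
    x = c(x - 0.5, x + 0.5, x + 0.5, x - 0.5),
    y = c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  )
}

#' Minimum-area enclosing rectangle of a point set
#'
#' Rotating-calipers semantics: the optimal rectangle has a side collinear
#' with an edge of the convex hull, so only hull-edge orientations are
#' examined. Degenerate (collinear) input yields width 0 and area 0.
#'
#' @param points n x 2 matrix of (x, y) vertices, n >= 1.
#' @return named numeric `c(length=, width=, area=)` with `length >= width`.
#' @export
min_area_rect <- function(points) {
  points <- unique(points[, 1:2, drop = FALSE])
  n <- nrow(points)
  if (n == 1L) return(c(length = 0, width = 0, area = 0))
  h <- grDevices::chull(points[, 1], points[, 2])
  hull <- points[h, , drop = FALSE]
  m <- nrow(hull)
  if (m < 2L) return(c(length = 0, width = 0, area = 0))
  edges <- rbind(hull, hull[1L, ])
  best <- c(length = Inf, width = Inf, area = Inf)
  for (i in seq_len(m)) {
    d <- edges[i + 1L, ] - edges[i, ]
    len <- sqrt(sum(d^2))
    if (len == 0) next
    u <- d / len               # edge direction
    v <- c(-u[2], u[1])        # normal
    pu <- hull %*% u
    pv <- hull %*% v
    e1 <- diff(range(pu))
    e2 <- diff(range(pv))
    area <- e1 * e2
    if (area < best["area"] - 1e-12) {
      best <- c(length = max(e1, e2), width = min(e1, e2), area = area)
    }
  }
  if (!is.finite(best["area"])) { # all points coincide along a segment
    e <- sqrt(max(stats::dist(hull)^2))
    best <- c(length = e, width = 0, area = 0)
  }
  best
}

#' Convex-hull (shoelace) area of a point set
#' @param points n x 2 matrix of (x, y) coordinates.
#' @return hull area in square pixels; 0 for fewer than 3 non-collinear points.
#' @export
convex_hull_area <- function(points) {
  points <- unique(points[, 1:2, drop = FALSE])
  if (nrow(points) < 3L) return(0)
  h <- grDevices::chull(points[, 1], points[, 2])
  if (length(h) < 3L) return(0)
  hx <- points[h, 1]; hy <- points[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Per-instance geometry records for every instance in a map
#'
#' @param map integer label matrix (labels need not be contiguous).
#' @return tibble with one row per instance: `label`, `area`, `perimeter`,
#'   `roundness`, `ortho_length`, `ortho_width`, `mbb_length`, `mbb_width`,
#'   `mbb_area`, `hull_area`, plus list-columns `contour` (ordered boundary
#'   pixel centers) and `hull_points` (boundary-pixel corner points feeding
#'   plant-level hulls).
#' @export
instance_records <- function(map) {
  labels <- map_labels(map)
  rows <- lapply(labels, function(lab) {
    area <- instance_area(map, lab)
    contour <- instance_contour(map, lab)
    per <- contour_length(contour)
    corners <- pixel_corners(contour)
    mbb <- min_area_rect(corners)
    ob <- orthogonal_bbox(map, lab)
    tibble::tibble(
      label = lab,
      area = area,
      perimeter = per,
      roundness = roundness(area, per),
      ortho_length = ob[["length"]],
      ortho_width = ob[["width"]],
      mbb_length = mbb[["length"]],
      mbb_width = mbb[["width"]],
      mbb_area = mbb[["area"]],
      hull_area = convex_hull_area(corners),
      contour = list(contour),
      hull_points = list(corners)
    )
  })
  if (length(rows) == 0L) {
    return(tibble::tibble(
      label = integer(), area = numeric(), perimeter = numeric(),
      roundness = numeric(), ortho_length = numeric(), ortho_width = numeric(),
      mbb_length = numeric(), mbb_width = numeric(), mbb_area = numeric(),
      hull_area = numeric(), contour = list(), hull_points = list()
    ))
  }
  dplyr::bind_rows(rows)
}

# The 35 morphological trait names, in the fixed catalog order.
morph_trait_names <- function() {
  c(
    "Average Perimeter", "Maximum Perimeter", "STD_Perimeter", "CV_Perimeter",
    "Average Roundness", "Maximum Roundness", "STD_Roundness", "CV_Roundness",
    "Total Leaf Number", "Total Leaf Area", "Average Leaf Area",
    "Maximum Leaf Area", "STD_Area", "CV_Area",
    "Average length_ori", "Average width_ori", "c_max_ori", "h_max_ori",
    "Average Length", "Maximum Length", "STD_Length", "CV_Length",
    "Average Width", "Maximum Width", "STD_Width", "CV_Width",
    "Average MBB_Area", "MBB_Area", "STD_MBB_Area", "CV_MBB_Area",
    "Average Area/MBB_Area", "STD_Area/MBB_Area",
    "Average Perimeter/Area", "STD_Perimeter/Area",
    "Convex Hull Leaf Area"
  )
}

#' Aggregate per-instance geometry into the 35 morphological traits
#'
#' Average/Maximum/SD/CV summaries use the population SD (divide by `n`) and
#' CV as a plain ratio. `length_ori`/`width_ori` come from the axis-aligned
#' box (`c_max_ori`/`h_max_ori` are their maxima); `Length`/`Width`/`MBB_Area`
#' come from minimum-area rectangles; `MBB_Area` (no prefix) is the maximum
#' over instances. Ratio traits: `Average Area/MBB_Area` is the mean of
#' per-instance ratios; `Average Perimeter/Area` is mean perimeter over mean
#' area; the SD variants are the SD of the numerator trait divided by the mean
#' of the denominator trait. `Convex Hull Leaf Area` is the hull area over the
#' union of all instance pixels. Degenerate single-pixel instances (zero
#' perimeter) are excluded from the roundness aggregates.
#'
#' @param records tibble from [instance_records()]; may have zero rows, in
#'   which case counts and totals are 0 and every other trait is `NA`.
#' @return named numeric vector of length 35 (names from the trait catalog).
#' @export
aggregate_morphology <- function(records) {
  out <- stats::setNames(rep(trait_sentinel(), 35L), morph_trait_names())
  n <- nrow(records)
  out["Total Leaf Number"] <- n
  out["Total Leaf Area"] <- if (n > 0L) sum(records$area) else 0
  if (n == 0L) return(out)

  agg4 <- function(x) c(mean(x), max(x), pop_sd(x), cv_ratio(x))
  rnd <- records$roundness[is.finite(records$roundness)]

  out[c("Average Perimeter", "Maximum Perimeter", "STD_Perimeter", "CV_Perimeter")] <-
    agg4(records$perimeter)
  if (length(rnd) > 0L) {
    out[c("Average Roundness", "Maximum Roundness", "STD_Roundness", "CV_Roundness")] <-
      agg4(rnd)
  }
  out[c("Average Leaf Area", "Maximum Leaf Area", "STD_Area", "CV_Area")] <-
    c(mean(records$area), max(records$area), pop_sd(records$area), cv_ratio(records$area))
  out["Average length_ori"] <- mean(records$ortho_length)
  out["Average width_ori"] <- mean(records$ortho_width)
  out["c_max_ori"] <- max(records$ortho_length)
  out["h_max_ori"] <- max(records$ortho_width)
  out[c("Average Length", "Maximum Length", "STD_Length", "CV_Length")] <-
    agg4(records$mbb_length)
  out[c("Average Width", "Maximum Width", "STD_Width", "CV_Width")] <-
    agg4(records$mbb_width)
  out["Average MBB_Area"] <- mean(records$mbb_area)
  out["MBB_Area"] <- max(records$mbb_area)
  out["STD_MBB_Area"] <- pop_sd(records$mbb_area)
  out["CV_MBB_Area"] <- cv_ratio(records$mbb_area)

  ok <- records$mbb_area > 0
  if (any(ok)) {
    out["Average Area/MBB_Area"] <- mean(records$area[ok] / records$mbb_area[ok])
  }
  if (mean(records$mbb_area) > 0) {
    out["STD_Area/MBB_Area"] <- pop_sd(records$area) / mean(records$mbb_area)
  }
  out["Average Perimeter/Area"] <- mean(records$perimeter) / mean(records$area)
  out["STD_Perimeter/Area"] <- pop_sd(records$perimeter) / mean(records$area)
  out["Convex Hull Leaf Area"] <-
    convex_hull_area(do.call(rbind, records$hull_points))
  out
}
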