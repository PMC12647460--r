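# Per-instance geometry and the 35-trait morphological aggregation.

test_that("area is the exact pixel count, cross-checked on a digital disk", {
  expect_equal(instance_area(digital_square(10L), 1L), 100L)
  m <- matrix(0L, 3, 3)
  m[2, 2] <- 1L
  expect_equal(instance_area(m, 1L), 1L)
  expect_error(instance_area(m, 4L), "not present")

  r <- 20L
  disk <- digital_disk(r)
  # independent oracle: exhaustive center scan
  n <- nrow(disk)
  c0 <- (n - 1) / 2
  cnt <- 0L
  for (row in seq_len(n)) {
    for (col in seq_len(n)) {
      if ((col - 1 - c0)^2 + (row - 1 - c0)^2 <= r^2) cnt <- cnt + 1L
    }
  }
  expect_equal(instance_area(disk, 1L), cnt)
})

test_that("perimeter follows the center-polyline convention: 4(n-1) for squares, 0 for a pixel", {
  for (n in c(3L, 10L, 25L)) {
    expect_equal(instance_perimeter(digital_square(n), 1L), 4 * (n - 1))
  }
  single <- matrix(0L, 3, 3)
  single[2, 2] <- 1L
  expect_equal(instance_perimeter(single, 1L), 0)
})

test_that("digital-disk perimeter shows the known staircase overestimate and roundness stays near 1", {
  # The center-polyline estimator overstates smooth boundaries: exactly 1 at
  # axis-aligned tangents, up to cos(22.5°)+(sqrt(2)-1)sin(22.5°) ≈ 1.083 at
  # worst; a circle averages ~1.05. Assert within those analytic bounds.
  disk <- digital_disk(50L)
  p <- instance_perimeter(disk, 1L)
  expect_gt(p / (2 * pi * 50), 1.0)
  expect_lt(p / (2 * pi * 50), 1.083)
  r <- roundness(instance_area(disk, 1L), p)
  expect_gt(r, 0.9)
  expect_lt(r, 1.1)
})

test_that("roundness identities hold for ideal shapes and degenerate input is NA", {
  r <- 7
  expect_equal(roundness(pi * r^2, 2 * pi * r), 1)
  s <- 9
  expect_equal(roundness(s^2, 4 * s), pi / 4)
  expect_true(is.na(roundness(5, 0)))
})

test_that("orthogonal bounding box reports sorted extents (max - min + 1)", {
  m <- matrix(0L, 30, 30)
  m[4:13, 6:25] <- 1L # 10 rows x 20 cols
  expect_equal(orthogonal_bbox(m, 1L), c(length = 20, width = 10))
  single <- matrix(0L, 3, 3)
  single[2, 2] <- 1L
  expect_equal(orthogonal_bbox(single, 1L), c(length = 1, width = 1))

  # 45°-rotated bar of true size 30 x 6: both extents near 26, verified by scan
  g <- expand.grid(x = 0:59, y = 0:59)
  u <- (g$x - 30) * cos(pi / 4) + (g$y - 30) * sin(pi / 4)
  v <- -(g$x - 30) * sin(pi / 4) + (g$y - 30) * cos(pi / 4)
  bar <- matrix(0L, 60, 60)
  hit <- abs(u) <= 15 & abs(v) <= 3
  bar[cbind(g$y[hit] + 1L, g$x[hit] + 1L)] <- 1L
  ob <- orthogonal_bbox(bar, 1L)
  scan_len <- diff(range(g$x[hit])) + 1
  scan_wid <- diff(range(g$y[hit])) + 1
  expect_equal(unname(ob), sort(c(scan_len, scan_wid), decreasing = TRUE))
  expect_lt(abs(ob[["length"]] - 26), 2.5)
})

test_that("minimum-area rectangle matches constructed optima and a brute-force search", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_equal(min_area_rect(sq), c(length = 10, width = 10, area = 100))

  # 30 x 10 rectangle rotated 37 degrees
  th <- 37 * pi / 180
  base <- rbind(c(0, 0), c(30, 0), c(30, 10), c(0, 10))
  rot <- base %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  mr <- min_area_rect(rot)
  expect_equal(unname(mr), c(30, 10, 300), tolerance = 1e-6)

  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(min_area_rect(tri)[["area"]], bruteforce_min_rect_area(tri, 0.01),
    tolerance = 1e-4
  )

  col <- rbind(c(0, 0), c(1, 1), c(2, 2), c(5, 5))
  mc <- min_area_rect(col)
  expect_equal(mc[["width"]], 0)
  expect_equal(mc[["area"]], 0)
  expect_equal(min_area_rect(rbind(c(2, 2))), c(length = 0, width = 0, area = 0))
})

test_that("convex hull area equals the shoelace of the hull and an independent gift-wrap oracle", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_equal(convex_hull_area(sq), 100)
  expect_equal(convex_hull_area(rbind(c(0, 0), c(3, 3), c(6, 6))), 0)
  set.seed(5)
  for (i in 1:8) {
    pts <- cbind(stats::runif(50, 0, 40), stats::runif(50, 0, 40))
    expect_equal(convex_hull_area(pts), giftwrap_hull_area(pts), tolerance = 1e-9)
  }
})

test_that("aggregation reproduces closed-form summaries (population SD, CV ratio)", {
  m <- matrix(0L, 40, 80)
  m[5:14, 5:14] <- 1L # 100 px
  m[5:14, 30:49] <- 2L # 200 px
  rec <- instance_records(m)
  tr <- aggregate_morphology(rec)
  expect_equal(tr[["Average Leaf Area"]], 150)
  expect_equal(tr[["Maximum Leaf Area"]], 200)
  expect_equal(tr[["STD_Area"]], 50)
  expect_equal(tr[["CV_Area"]], 1 / 3)
  expect_equal(tr[["Total Leaf Number"]], 2)
  expect_equal(tr[["Total Leaf Area"]], 300)
  expect_equal(length(tr), 35L)

  one <- instance_records(digital_square(8L))
  t1 <- aggregate_morphology(one)
  expect_equal(t1[["STD_Perimeter"]], 0)
  expect_equal(t1[["CV_Length"]], 0)
  expect_equal(t1[["Average Leaf Area"]], t1[["Maximum Leaf Area"]])

  empty <- aggregate_morphology(instance_records(matrix(0L, 5, 5)))
  expect_equal(empty[["Total Leaf Number"]], 0)
  expect_equal(empty[["Total Leaf Area"]], 0)
  expect_true(is.na(empty[["Average Perimeter"]]))
})

test_that("per-instance containment chain and CV identity hold on generated rosettes", {
  for (s in c(1L, 8L)) {
    sc <- generate_rosette(scene_spec(n_organs = 7, seed = s))
    rec <- instance_records(sc$truth$map)
    expect_true(all(rec$area <= rec$hull_area + 0.5 * rec$perimeter))
    expect_true(all(rec$hull_area <= rec$mbb_area + 1e-9))
    expect_true(all(rec$mbb_area <= rec$ortho_length * rec$ortho_width + 1e-9))
    expect_true(all(rec$mbb_length >= rec$mbb_width))
    tr <- aggregate_morphology(rec)
    # CV * Average = STD for every summarized trait family
    expect_equal(tr[["CV_Perimeter"]] * tr[["Average Perimeter"]], tr[["STD_Perimeter"]])
    expect_equal(tr[["CV_Area"]] * tr[["Average Leaf Area"]], tr[["STD_Area"]])
    expect_equal(tr[["CV_Length"]] * tr[["Average Length"]], tr[["STD_Length"]])
    expect_equal(tr[["CV_MBB_Area"]] * tr[["Average MBB_Area"]], tr[["STD_MBB_Area"]])
  }
})

test_that("aggregates are permutation-invariant and geometry survives translation and rotation", {
  sc <- generate_rosette(scene_spec(n_organs = 6, seed = 4))
  map <- sc$truth$map
  rec <- instance_records(map)
  tr <- aggregate_morphology(rec)

  # permute instance labels
  labs <- map_labels(map)
  perm <- rev(labs)
  pm <- map
  for (i in seq_along(labs)) pm[map == labs[i]] <- perm[i]
  tr_p <- aggregate_morphology(instance_records(pm))
  expect_equal(tr_p, tr)

  # translate the scene by (7, 11)
  tm <- matrix(0L, nrow(map) + 20L, ncol(map) + 20L)
  tm[7 + seq_len(nrow(map)), 11 + seq_len(ncol(map))] <- map
  expect_equal(aggregate_morphology(instance_records(tm)), tr)

  # rotate 90 degrees: area, perimeter, mbb dims, hull area unchanged exactly
  rot <- t(map)[, nrow(map):1, drop = FALSE]
  rr <- instance_records(rot)
  ord <- order(rr$area)
  ord0 <- order(rec$area)
  expect_equal(rr$area[ord], rec$area[ord0])
  expect_equal(rr$perimeter[ord], rec$perimeter[ord0])
  expect_equal(rr$mbb_length[ord], rec$mbb_length[ord0], tolerance = 1e-9)
  expect_equal(rr$mbb_width[ord], rec$mbb_width[ord0], tolerance = 1e-9)
  expect_equal(rr$hull_area[ord], rec$hull_area[ord0], tolerance = 1e-9)
})
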