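# Synthetic scene generators and augmentation.

test_that("scenes are bit-identical for identical specs", {
  s1 <- generate_rosette(scene_spec(n_organs = 8, seed = 11))
  s2 <- generate_rosette(scene_spec(n_organs = 8, seed = 11))
  expect_identical(s1$image, s2$image)
  expect_identical(unclass(s1$truth$map), unclass(s2$truth$map))
  q1 <- generate_silique_scene(scene_spec("silique", seed = 7))
  q2 <- generate_silique_scene(scene_spec("silique", seed = 7))
  expect_identical(q1$image, q2$image)
})

test_that("non-overlapping rosettes recover counts and areas exactly through the pipeline", {
  sc <- generate_rosette(scene_spec(n_organs = 8, overlap = 0, seed = 11))
  expect_equal(nrow(sc$truth$organs), 8L)
  rec <- instance_records(sc$truth$map)
  tr <- aggregate_morphology(rec)
  expect_equal(tr[["Total Leaf Number"]], 8)
  expect_equal(tr[["Total Leaf Area"]], sum(sc$truth$organs$area))
  expect_equal(as.numeric(rec$area), as.numeric(sc$truth$organs$area))
  # disjoint scenes: latent = visible
  expect_equal(sc$truth$organs$latent_area, sc$truth$organs$area)
})

test_that("the occlusion target is tracked within ±0.1 over 20 seeds", {
  target <- 0.3
  occ <- vapply(1:20, function(s) {
    o <- generate_rosette(scene_spec(n_organs = 10, overlap = target, seed = 200 + s))$truth$organs
    mean((o$latent_area - o$area) / o$latent_area)
  }, numeric(1))
  expect_lt(abs(mean(occ) - target), 0.1)
})

test_that("silique scenes: stems are background, capsule length is recovered by the min-rect", {
  sc <- generate_silique_scene(scene_spec("silique", n_organs = 12, overlap = 0, seed = 3))
  expect_equal(nrow(sc$truth$organs), 12L)
  # truth vs truth evaluation is perfect
  prf <- precision_recall_f1(match_instances(sc$truth$map, sc$truth$map))
  expect_equal(unname(prf), c(1, 1, 1))
  rec <- instance_records(sc$truth$map)
  j <- match(rec$label, sc$truth$organs$label)
  expect_true(all(abs(rec$mbb_length - sc$truth$organs$drawn_length[j]) <= 2))
})

test_that("crossing pairs merge under connected components (baseline failure mode)", {
  sc <- generate_silique_scene(scene_spec("silique", n_organs = 10, overlap = 0.3, seed = 21))
  truth <- sc$truth$map
  comp <- connected_components(matrix(as.integer(truth > 0), nrow(truth)), 8L, min_area = 1L)
  expect_lt(attr(comp, "n_instances"), attr(truth, "n_instances"))
})

test_that("truth-vs-truth end-to-end gives perfect metrics and zero MAPE on every trait", {
  sc <- generate_rosette(scene_spec(n_organs = 6, seed = 31))
  m <- match_instances(sc$truth$map, sc$truth$map)
  expect_equal(unname(precision_recall_f1(m)), c(1, 1, 1))
  expect_equal(dic(m$n_pred, m$n_truth), 0)
  tr <- measure_traits(sc$image, sc$truth$map)
  vals <- unlist(tr[trait_catalog()])
  vals <- vals[is.finite(vals) & vals != 0]
  expect_equal(mape(vals, vals), 0)
})

test_that("hflip is an involution and zero-sigma noise is the identity", {
  sc <- generate_rosette(scene_spec(n_organs = 4, seed = 2))
  twice <- augment(sc$image, sc$truth$map, list("hflip"), seed = 1)
  twice <- augment(twice$image, twice$map, list("hflip"), seed = 1)
  expect_equal(twice$image, sc$image)
  expect_equal(twice$map, unclass(sc$truth$map), ignore_attr = TRUE)

  same <- augment(sc$image, sc$truth$map, list(list("gaussian_noise", sigma = 0)), seed = 4)
  expect_equal(same$image, sc$image)
})

test_that("rotate90 preserves instance areas exactly and swaps or preserves box sides", {
  sc <- generate_rosette(scene_spec(n_organs = 5, seed = 19))
  rot <- augment(sc$image, sc$truth$map, list("rotate90"), seed = 1)
  a0 <- sort(tabulate(sc$truth$map[sc$truth$map > 0]))
  a1 <- sort(tabulate(rot$map[rot$map > 0]))
  expect_equal(a1, a0)
  rec0 <- instance_records(sc$truth$map)
  rec1 <- instance_records(rot$map)
  expect_equal(sort(rec1$mbb_length), sort(rec0$mbb_length), tolerance = 1e-9)
  expect_equal(sort(rec1$mbb_width), sort(rec0$mbb_width), tolerance = 1e-9)
})

test_that("geometric ops stay paired, photometric ops leave the map alone, crops validate", {
  sc <- generate_rosette(scene_spec(n_organs = 4, seed = 23))
  out <- augment(
    sc$image, sc$truth$map,
    list(
      list("random_scale", range = c(0.6, 0.9)),
      list("color_dither", delta = 8),
      list("random_crop", size = c(100, 100))
    ),
    seed = 9
  )
  expect_equal(dim(out$image)[1:2], c(100L, 100L))
  expect_equal(dim(out$map), c(100L, 100L))
  expect_true(all(out$map %in% c(0L, map_labels(sc$truth$map))))
  # deterministic in the seed
  out2 <- augment(
    sc$image, sc$truth$map,
    list(
      list("random_scale", range = c(0.6, 0.9)),
      list("color_dither", delta = 8),
      list("random_crop", size = c(100, 100))
    ),
    seed = 9
  )
  expect_identical(out$image, out2$image)
  expect_error(
    augment(sc$image, sc$truth$map, list(list("random_crop", size = c(999, 10))), seed = 1),
    "exceeds"
  )
  expect_error(augment(sc$image, sc$truth$map, list(), seed = 1), "non-empty")
})
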