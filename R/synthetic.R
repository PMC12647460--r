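#' Synthetic rosette and silique scenes with exact ground truth
#'
#' Seeded generators for two scene families that emulate the imaging setups
#' this kind of pipeline is applied to: top-view rosettes of overlapping
#' elliptical leaves with petioles on a soil-like background, and
#' flatbed-scan-like scenes of elongated siliques attached to a thin stem.
#' Every scene comes with an exact instance label map and per-organ ground
#' truth, so each pipeline stage can be tested without external data.
#' Occlusion is realized by draw order — later organs overwrite earlier ones
#' in both the image and the label map — so ground truth describes *visible*
#' pixel sets (what a segmenter can recover); latent full-shape areas are
#' stored alongside for sensitivity studies.
#'
#' @name synthetic-scenes
NULL

#' Scene specification
#'
#' @param organ `"leaf"` (rosette) or `"silique"` (flatbed scan).
#' @param n_organs number of organs to place (rosettes are realistic with
#'   3-20 leaves).
#' @param size_range organ length range in pixels (leaf = petiole + blade
#'   length; silique = capsule end-to-end length).
#' @param overlap target mean occluded-area fraction in `[0, 1)` for
#'   rosettes; for silique scenes any positive value requests crossing pairs.
#' @param background `"textured"` (default; smooth blotches + pixel noise) or
#'   `"flat"`.
#' @param image_size image side length in pixels (scenes are square).
#' @param seed integer seed; scenes are bit-identical for identical specs.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(organ = c("leaf", "silique"),
                       n_organs = if (organ == "leaf") 8L else 12L,
                       size_range = if (organ == "leaf") c(40, 80) else c(60, 100),
                       overlap = 0,
                       background = c("textured", "flat"),
                       image_size = if (organ == "leaf") 256L else 320L,
                       seed = 1L) {
  organ <- match.arg(organ)
  background <- match.arg(background)
  if (n_organs < 0L) stop_organtraits("n_organs must be >= 0")
  if (overlap < 0 || overlap >= 1) stop_organtraits("overlap must be in [0, 1)")
  if (image_size < 4 * max(size_range) / 3) {
    stop_organtraits("image_size too small for the requested organ sizes")
  }
  structure(
    list(
      organ = organ, n_organs = as.integer(n_organs), size_range = size_range,
      overlap = overlap, background = background,
      image_size = as.integer(image_size), seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

# --- low-level raster helpers (0-based x = col, y = row coordinates) -------

# Pixel mask of an ellipse: center (cx, cy), semi-axes (a, b), rotation phi.
ellipse_mask_idx <- function(h, w, cx, cy, a, b, phi) {
  x0 <- max(0, floor(cx - a - b)); x1 <- min(w - 1, ceiling(cx + a + b))
  y0 <- max(0, floor(cy - a - b)); y1 <- min(h - 1, ceiling(cy + a + b))
  if (x1 < x0 || y1 < y0) return(integer(0))
  gx <- rep(x0:x1, times = y1 - y0 + 1)
  gy <- rep(y0:y1, each = x1 - x0 + 1)
  dx <- gx - cx; dy <- gy - cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  hit <- (u / a)^2 + (v / b)^2 <= 1
  (gx[hit]) * h + gy[hit] + 1L # column-major linear index into an h x w matrix
}

# Pixel mask within distance `radius` of a sampled polyline (n x 2, x/y cols).
polyline_mask_idx <- function(h, w, line, radius) {
  x0 <- max(0, floor(min(line[, 1]) - radius)); x1 <- min(w - 1, ceiling(max(line[, 1]) + radius))
  y0 <- max(0, floor(min(line[, 2]) - radius)); y1 <- min(h - 1, ceiling(max(line[, 2]) + radius))
  if (x1 < x0 || y1 < y0) return(integer(0))
  gx <- rep(x0:x1, times = y1 - y0 + 1)
  gy <- rep(y0:y1, each = x1 - x0 + 1)
  d2min <- rep(Inf, length(gx))
  for (i in seq_len(nrow(line))) {
    d2 <- (gx - line[i, 1])^2 + (gy - line[i, 2])^2
    d2min <- pmin(d2min, d2)
  }
  hit <- d2min <= radius^2
  (gx[hit]) * h + gy[hit] + 1L
}

# Quadratic bezier sample points between p0 and p2 with control p1.
bezier_points <- function(p0, p1, p2, n = 60L) {
  t <- seq(0, 1, length.out = n)
  cbind(
    (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
    (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  )
}

# Background canvas (H x W x 3) for a scene.
scene_background <- function(h, w, style, base) {
  img <- array(rep(base, each = h * w), dim = c(h, w, 3))
  if (style == "textured") {
    coarse <- matrix(stats::runif(64, -18, 18), 8, 8)
    up <- coarse[
      pmin(8L, 1L + (seq_len(h) - 1L) %/% ceiling(h / 8)),
      pmin(8L, 1L + (seq_len(w) - 1L) %/% ceiling(w / 8))
    ]
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] + up + matrix(stats::rnorm(h * w, 0, 4), h, w)
    }
  }
  clamp(img, 0, 255)
}

paint_pixels <- function(img, idx, color, jitter_sd = 6) {
  n <- length(idx)
  hw <- dim(img)[1] * dim(img)[2]
  for (ch in 1:3) {
    img[idx + (ch - 1L) * hw] <-
      clamp(color[ch] + stats::rnorm(n, 0, jitter_sd), 0, 255)
  }
  img
}

# Assemble image + ground truth. `map` carries original placement ids (sparse
# allowed); per-id vectors are indexed by those ids. Labels are compacted to
# {1..N} in raster-scan first-appearance order, keeping the organ table
# aligned with the relabeled map.
finish_scene <- function(img, map, latent_by_id, length_by_id, width_by_id) {
  seen <- unique(as.vector(t(map)))
  seen <- seen[seen != 0L]
  lut <- integer(max(c(map, 0L)) + 1L)
  lut[seen + 1L] <- seq_along(seen)
  newmap <- matrix(lut[map + 1L], nrow(map), ncol(map))
  attr(newmap, "n_instances") <- length(seen)
  vis <- if (length(seen) > 0L) {
    tabulate(newmap[newmap > 0L], nbins = length(seen))
  } else integer(0)
  organs <- tibble::tibble(
    label = seq_along(seen),
    area = as.numeric(vis),
    latent_area = as.numeric(latent_by_id[seen]),
    drawn_length = as.numeric(length_by_id[seen]),
    drawn_width = as.numeric(width_by_id[seen])
  )
  list(
    image = clamp(img, 0, 255),
    truth = list(
      map = newmap,
      organs = organs,
      summary = tibble::tibble(
        `Total Leaf Number` = nrow(organs),
        `Total Leaf Area` = sum(organs$area)
      )
    )
  )
}

# --- rosette generator -----------------------------------------------------

# Draw the rosette for a fixed radial scale factor sigma; `geo` holds the
# pre-drawn random placement parameters so sigma can be varied without
# consuming RNG state.
draw_rosette <- function(geo, sigma, h, w) {
  map <- matrix(0L, h, w)
  latent <- integer(length(geo$L))
  idx_list <- vector("list", length(geo$L))
  cx0 <- (w - 1) / 2
  cy0 <- (h - 1) / 2
  for (i in seq_along(geo$L)) {
    L <- geo$L[i]
    a <- 0.35 * L
    b <- a * geo$b_ratio[i]
    th <- geo$theta[i]
    d <- sigma * (0.3 * L + a)
    blade <- ellipse_mask_idx(h, w, cx0 + d * cos(th), cy0 + d * sin(th), a, b, th)
    # petiole reaches half an axis into the blade so the union stays 8-connected
    rr <- seq(geo$r0[i], d - 0.5 * a, length.out = max(2L, ceiling(d)))
    pet <- polyline_mask_idx(
      h, w,
      cbind(cx0 + rr * cos(th), cy0 + rr * sin(th)),
      radius = geo$pet_r[i]
    )
    idx <- unique(c(blade, pet))
    idx_list[[i]] <- idx
    latent[i] <- length(idx)
    map[idx] <- i
  }
  list(map = map, idx = idx_list, latent = latent)
}

occlusion_fraction <- function(drawn) {
  n <- length(drawn$latent)
  if (n == 0L) return(0)
  vis <- tabulate(drawn$map[drawn$map > 0L], nbins = n)
  keep <- drawn$latent > 0
  if (!any(keep)) return(0)
  mean((drawn$latent[keep] - vis[keep]) / drawn$latent[keep])
}

#' Generate a top-view rosette scene
#'
#' Places `n_organs` elliptical leaf blades with petiole stalks radiating from
#' the rosette center with jittered angles and green-hued per-leaf color
#' jitter, on a soil-like background. With `overlap = 0` leaf supports are
#' kept strictly disjoint (placements are re-jittered and, after bounded
#' retries, dropped with a warning); with `overlap > 0` the radial compactness
#' is calibrated per scene (bisection on the measured occlusion) so the mean
#' occluded-area fraction tracks the target.
#'
#' @param spec a [scene_spec()] with `organ = "leaf"`.
#' @return list with `image` (`H x W x 3` array in `[0,255]`) and `truth`:
#'   a list with `map` (label matrix; labels `1..N` in raster order),
#'   `organs` (tibble `label`, `area` = visible pixels, `latent_area`,
#'   `drawn_length`, `drawn_width`), and `summary` (tibble
#'   `Total Leaf Number`, `Total Leaf Area`).
#' @export
generate_rosette <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$organ != "leaf") stop_organtraits("spec$organ must be 'leaf'")
  h <- w <- spec$image_size
  n <- spec$n_organs
  withr::with_seed(spec$seed, {
    geo <- list(
      L = stats::runif(n, spec$size_range[1], spec$size_range[2]),
      theta = 2 * pi * (seq_len(n) - 1) / max(n, 1L) +
        stats::runif(n, -0.25, 0.25) * 2 * pi / max(n, 1L),
      b_ratio = stats::runif(n, 0.45, 0.75),
      pet_r = stats::runif(n, 1.2, 1.8)
    )
    # petiole start radius: at the rosette center for occluded scenes, pushed
    # out to where the angular spacing separates stalks for disjoint scenes
    geo$r0 <- rep(
      if (spec$overlap == 0) max(3, 2.2 / sin(pi / max(n, 2L))) else 3,
      n
    )
    colors <- cbind(
      stats::runif(n, 35, 75), stats::runif(n, 115, 185), stats::runif(n, 30, 70)
    )
    img <- scene_background(h, w, spec$background, c(115, 85, 58))
    if (n == 0L) {
      map <- matrix(0L, h, w)
      idx_list <- list()
      latent <- integer(0)
    } else if (spec$overlap == 0) {
      # disjoint placement: grow the scene leaf by leaf, re-jittering on contact
      map <- matrix(0L, h, w)
      idx_list <- vector("list", n)
      latent <- integer(n)
      nominal_theta <- 2 * pi * (seq_len(n) - 1) / n
      for (i in seq_len(n)) {
        placed <- FALSE
        for (try in 0:40) {
          g1 <- lapply(geo, function(v) v[i])
          if (try > 0L) {
            # pull toward the evenly spaced angle, shrink, and push outward
            g1$theta <- nominal_theta[i] +
              (geo$theta[i] - nominal_theta[i]) * 0.7^try +
              stats::runif(1, -0.05, 0.05)
            g1$L <- geo$L[i] * max(0.55, 0.94^try)
          }
          one <- draw_rosette(g1, sigma = 1.15 + 0.04 * try, h = h, w = w)
          idx <- one$idx[[1]]
          if (length(idx) > 0L && all(map[idx] == 0L)) {
            map[idx] <- i
            idx_list[[i]] <- idx
            latent[i] <- length(idx)
            geo$L[i] <- g1$L
            geo$theta[i] <- g1$theta
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          warning("could not place leaf ", i, " without overlap; dropped", call. = FALSE)
        }
      }
    } else {
      # calibrate radial compactness so occlusion tracks the target
      lo <- 0.2; hi <- 1.3
      sigma <- 1
      for (it in 1:14) {
        sigma <- (lo + hi) / 2
        f_mid <- occlusion_fraction(draw_rosette(geo, sigma, h, w))
        # occlusion decreases as sigma grows (leaves move apart)
        if (f_mid > spec$overlap) lo <- sigma else hi <- sigma
      }
      drawn <- draw_rosette(geo, sigma, h, w)
      map <- drawn$map
      idx_list <- drawn$idx
      latent <- drawn$latent
    }
    if (n > 0L) {
      for (i in seq_len(n)) {
        if (length(idx_list[[i]]) == 0L) next
        visidx <- idx_list[[i]][map[idx_list[[i]]] == i]
        img <- paint_pixels(img, visidx, colors[i, ])
      }
    }
    finish_scene(img, map, latent, geo$L, 2 * 0.35 * geo$L * geo$b_ratio)
  })
}

# --- silique generator -----------------------------------------------------

#' Generate a flatbed-scan-like silique scene
#'
#' Draws a thin curved main stem with `n_organs` elongated capsules (high
#' aspect ratio, slight curvature) attached at spaced points, on a bright
#' scanner-bed background. Stem pixels are background class in the label map
#' — only siliques are instances. With `overlap = 0` silique supports are
#' kept disjoint; with `overlap > 0` deliberately crossing pairs are placed,
#' which guarantees that connected components on the binary union of organ
#' pixels merge organs (the classical-baseline failure mode).
#'
#' @param spec a [scene_spec()] with `organ = "silique"`.
#' @return as [generate_rosette()]; `drawn_length` is the capsule end-to-end
#'   length (minimum-rectangle length recovers it to within ~2 px),
#'   `drawn_width` the capsule width.
#' @export
generate_silique_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$organ != "silique") stop_organtraits("spec$organ must be 'silique'")
  h <- w <- spec$image_size
  n <- spec$n_organs
  withr::with_seed(spec$seed, {
    img <- scene_background(h, w, spec$background, c(232, 230, 226))
    map <- matrix(0L, h, w)
    # main stem: gentle S-curve from bottom to top
    amp <- stats::runif(1, 6, 14)
    xoff <- stats::runif(1, -10, 10)
    ys <- seq(h - 2, 1, length.out = 200)
    xs <- w / 2 + amp * sin(seq(0, 2.2 * pi, length.out = 200)) + xoff
    stem <- cbind(xs, ys)
    stem_idx <- polyline_mask_idx(h, w, stem, radius = 1.4)
    img <- paint_pixels(img, stem_idx, c(125, 118, 72), jitter_sd = 4)

    if (n == 0L) {
      finish_scene(img, map, numeric(0), numeric(0), numeric(0))
    } else {
    Ls <- stats::runif(n, spec$size_range[1], spec$size_range[2])
    ws <- stats::runif(n, 5, 8)
    side <- rep_len(c(1, -1), n)
    attach_t <- seq(0.08, 0.92, length.out = max(n, 2L))[seq_len(n)] +
      stats::runif(n, -0.02, 0.02)
    angles <- stats::runif(n, 25, 65) * pi / 180

    idx_list <- vector("list", n)
    latent <- integer(n)
    placed_ok <- logical(n)
    for (i in seq_len(n)) {
      for (try in 1:25) {
        ti <- clamp(attach_t[i] + (try - 1) * stats::runif(1, -0.03, 0.03), 0.03, 0.97)
        A <- stem[max(1L, min(200L, round(ti * 200))), ]
        ang <- angles[i] + (try - 1) * stats::runif(1, -0.15, 0.15)
        dir <- c(side[i] * cos(ang), -sin(ang)) # sideways and up
        chord <- Ls[i] - ws[i]
        B <- A + chord * dir
        perp <- c(-dir[2], dir[1])
        sag <- stats::runif(1, 0.3, 1.5)
        line <- bezier_points(A, (A + B) / 2 + 2 * sag * perp, B)
        idx <- polyline_mask_idx(h, w, line, radius = ws[i] / 2)
        in_frame <- B[1] >= 2 && B[1] <= w - 3 && B[2] >= 2 && B[2] <= h - 3
        disjoint <- length(idx) > 0L && all(map[idx] == 0L)
        if (in_frame && disjoint) {
          map[idx] <- i
          idx_list[[i]] <- idx
          latent[i] <- length(idx)
          placed_ok[i] <- TRUE
          break
        }
      }
      if (!placed_ok[i]) {
        warning("could not place silique ", i, "; dropped", call. = FALSE)
      }
    }

    # deliberate crossing pairs: re-route the partner through an earlier capsule
    n_cross <- if (spec$overlap > 0 && sum(placed_ok) >= 2L) {
      max(1L, round(spec$overlap * n / 2))
    } else 0L
    if (n_cross > 0L) {
      ids <- which(placed_ok)
      for (cc in seq_len(min(n_cross, floor(length(ids) / 2)))) {
        a <- ids[2 * cc - 1]
        b <- ids[2 * cc]
        mid <- arrayInd(idx_list[[a]][ceiling(length(idx_list[[a]]) / 2)], c(h, w))
        Tm <- c(mid[2] - 1, mid[1] - 1) # (x, y) of a's midpoint
        A <- stem[max(1L, min(200L, round(attach_t[b] * 200))), ]
        dirv <- Tm - A
        len0 <- sqrt(sum(dirv^2))
        if (len0 < 1) next
        dir <- dirv / len0
        chord <- max(Ls[b] - ws[b], len0 + 12)
        B <- A + chord * dir
        B <- c(clamp(B[1], 2, w - 3), clamp(B[2], 2, h - 3))
        line <- bezier_points(A, (A + B) / 2, B)
        map[idx_list[[b]]] <- 0L
        idx <- polyline_mask_idx(h, w, line, radius = ws[b] / 2)
        map[idx] <- b # later organ wins: visible-pixel ground truth
        idx_list[[b]] <- idx
        latent[b] <- length(idx)
        Ls[b] <- chord + ws[b]
      }
    }

    greens <- cbind(
      stats::runif(n, 120, 160), stats::runif(n, 150, 185), stats::runif(n, 70, 110)
    )
    for (i in which(placed_ok)) {
      visidx <- idx_list[[i]][map[idx_list[[i]]] == i]
      img <- paint_pixels(img, visidx, greens[i, ], jitter_sd = 5)
    }
    finish_scene(img, map, latent, Ls, ws)
    }
  })
}

#' Generate a scene from a spec (dispatch on organ class)
#' @param spec a [scene_spec()].
#' @return list with `image` and `truth`; see [generate_rosette()].
#' @export
generate_scene <- function(spec) {
  switch(spec$organ,
    leaf = generate_rosette(spec),
    silique = generate_silique_scene(spec)
  )
}
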