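# Shared shape builders and independent oracles for the test suite.

# Digital disk: pixels whose centers lie within `r` of the center of an n x n
# frame. Returns an integer label matrix (single instance).
digital_disk <- function(r, label = 1L, pad = 10L) {
  n <- 2L * (r + pad) + 1L
  c0 <- r + pad
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  m <- matrix(0L, n, n)
  hit <- (g$x - c0)^2 + (g$y - c0)^2 <= r^2
  m[cbind(g$y[hit] + 1L, g$x[hit] + 1L)] <- label
  m
}

# Filled axis-aligned square block of side s, embedded with padding.
digital_square <- function(s, label = 1L, pad = 3L) {
  n <- s + 2L * pad
  m <- matrix(0L, n, n)
  m[(pad + 1L):(pad + s), (pad + 1L):(pad + s)] <- label
  m
}

# Flat gray image matching a label matrix.
flat_image <- function(map, value = 128) {
  array(value, dim = c(nrow(map), ncol(map), 3))
}

# Rasterize an analytic blob (ellipse + offset disk) at a pose; used for
# moment-invariance checks without resampling artifacts.
rasterize_blob <- function(scale = 1, angle = 0, n = 560L) {
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  dx <- g$x - (n - 1) / 2
  dy <- g$y - (n - 1) / 2
  u <- (dx * cos(angle) + dy * sin(angle)) / scale
  v <- (-dx * sin(angle) + dy * cos(angle)) / scale
  hit <- (u / 100)^2 + (v / 42)^2 <= 1 | ((u - 65)^2 + (v - 20)^2) <= 30^2
  m <- matrix(0L, n, n)
  m[cbind(g$y[hit] + 1L, g$x[hit] + 1L)] <- 1L
  m
}

# Independent convex-hull area oracle: gift wrapping + shoelace.
giftwrap_hull_area <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3L) return(0)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull_idx <- integer(0)
  cur <- start
  repeat {
    hull_idx <- c(hull_idx, cur)
    cand <- if (cur == 1L) 2L else 1L
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
        (pts[cand, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      d_c <- sum((pts[cand, ] - pts[cur, ])^2)
      d_j <- sum((pts[j, ] - pts[cur, ])^2)
      if (cand == cur || cr < 0 || (abs(cr) < 1e-12 && d_j > d_c)) cand <- j
    }
    cur <- cand
    if (cur == start || length(hull_idx) > n) break
  }
  hx <- pts[hull_idx, 1]
  hy <- pts[hull_idx, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# Brute-force minimum-area rectangle by rotation search (step in degrees).
bruteforce_min_rect_area <- function(pts, step_deg = 0.01) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  ang <- seq(0, 90, by = step_deg) * pi / 180
  pu <- hull %*% rbind(cos(ang), sin(ang))
  pv <- hull %*% rbind(-sin(ang), cos(ang))
  min((apply(pu, 2, max) - apply(pu, 2, min)) *
    (apply(pv, 2, max) - apply(pv, 2, min)))
}

# Exhaustive-search Otsu oracle: maximize w0*w1*(m0-m1)^2 over all thresholds,
# first (lowest) maximizer wins.
bruteforce_otsu <- function(values) {
  best <- -Inf
  bt <- NA_integer_
  for (t in 0:255) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(values)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best + 1e-9) {
      best <- s
      bt <- t
    }
  }
  bt
}

# Optimal-assignment TP count by exhaustive enumeration over injective
# assignments of predicted to truth labels (small scenes only).
optimal_tp <- function(pred, truth, iou_threshold) {
  pl <- map_labels(pred)
  tl <- map_labels(truth)
  if (length(pl) == 0L || length(tl) == 0L) return(0L)
  iou <- matrix(0, length(pl), length(tl))
  for (i in seq_along(pl)) {
    for (j in seq_along(tl)) {
      a <- pred == pl[i]
      b <- truth == tl[j]
      inter <- sum(a & b)
      if (inter > 0) iou[i, j] <- inter / sum(a | b)
    }
  }
  feas <- iou >= iou_threshold
  small <- if (length(pl) <= length(tl)) seq_along(pl) else seq_along(tl)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  big_n <- max(length(pl), length(tl))
  best <- 0L
  for (p in perms(seq_len(big_n))) {
    assign_big <- p[seq_along(small)]
    tp <- 0L
    for (k in seq_along(small)) {
      i <- if (length(pl) <= length(tl)) small[k] else assign_big[k]
      j <- if (length(pl) <= length(tl)) assign_big[k] else small[k]
      if (j <= ncol(feas) && i <= nrow(feas) && feas[i, j]) tp <- tp + 1L
    }
    best <- max(best, tp)
  }
  best
}

# Random small scene: up to `max_n` rectangular instances on a grid.
random_rect_scene <- function(max_n, size = 48L) {
  m <- matrix(0L, size, size)
  n <- sample.int(max_n, 1L)
  for (k in seq_len(n)) {
    w <- sample(4:12, 1L)
    h <- sample(4:12, 1L)
    r <- sample.int(size - h, 1L)
    c <- sample.int(size - w, 1L)
    m[r:(r + h - 1L), c:(c + w - 1L)] <- k
  }
  relabel_map(m)
}
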