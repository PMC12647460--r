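#' Chromatic-coordinate color traits over organ pixels
#'
#' Computes the 7 color traits of the catalog over the union of all organ
#' pixels. Each organ pixel contributes chromatic coordinates
#' `R/(R+G+B)`, `G/(R+G+B)`, `B/(R+G+B)` (a pure-black pixel
#' contributes `(1/3, 1/3, 1/3)` so it stays on the simplex);
#' `X_Ratio_mean` is the mean of the coordinate and `STD_X_mean` its
#' population SD over organ pixels. `G_All_mean` is the green proportion over
#' the whole plant, i.e. equal to `G_Ratio_mean` (both catalog entries are
#' kept so the 64-trait catalog stays intact). The traits are invariant to a
#' global positive scaling of intensities and to any relabeling of instances.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param map integer label matrix of matching size.
#' @param raw_channel_means also return the raw 0-255 per-channel means as
#'   auxiliary (non-catalog) entries `R_raw_mean`/`G_raw_mean`/`B_raw_mean`.
#' @return named numeric vector with entries `R_Ratio_mean`, `STD_R_mean`,
#'   `G_Ratio_mean`, `STD_G_mean`, `B_Ratio_mean`, `STD_B_mean`, `G_All_mean`
#'   (all in `[0, 1]`), plus the auxiliary entries when requested. All `NA`
#'   when the map has no organ pixels.
#' @export
color_traits <- function(image, map, raw_channel_means = FALSE) {
  assert_same_dim(image, map)
  sel <- map > 0L
  nm <- c(
    "R_Ratio_mean", "STD_R_mean", "G_Ratio_mean", "STD_G_mean",
    "B_Ratio_mean", "STD_B_mean", "G_All_mean"
  )
  if (!any(sel)) {
    out <- stats::setNames(rep(trait_sentinel(), 7L), nm)
    if (raw_channel_means) {
      out <- c(out, R_raw_mean = NA_real_, G_raw_mean = NA_real_, B_raw_mean = NA_real_)
    }
    return(out)
  }
  R <- image[, , 1][sel]
  G <- image[, , 2][sel]
  B <- image[, , 3][sel]
  s <- R + G + B
  zero <- s == 0
  s[zero] <- 1
  r <- R / s; g <- G / s; b <- B / s
  r[zero] <- 1 / 3; g[zero] <- 1 / 3; b[zero] <- 1 / 3
  out <- c(
    R_Ratio_mean = mean(r), STD_R_mean = pop_sd(r),
    G_Ratio_mean = mean(g), STD_G_mean = pop_sd(g),
    B_Ratio_mean = mean(b), STD_B_mean = pop_sd(b),
    G_All_mean = mean(g)
  )
  if (raw_channel_means) {
    out <- c(out, R_raw_mean = mean(R), G_raw_mean = mean(G), B_raw_mean = mean(B))
  }
  out
}
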