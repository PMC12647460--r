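# Internal helpers shared across modules.

# Undefined-trait sentinel: NA_real_ in memory, empty cell in CSV output.
trait_sentinel <- function() NA_real_

# Population standard deviation (divide by n). Per-plant trait dispersion is
# descriptive, not inferential, so no Bessel correction.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(trait_sentinel())
  sqrt(sum((x - mean(x))^2) / n)
}

# Coefficient of variation as a ratio (not percent); sentinel when the mean
# is zero or nothing is defined.
cv_ratio <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(trait_sentinel())
  m <- mean(x)
  if (m == 0) return(trait_sentinel())
  pop_sd(x) / m
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_organtraits <- function(...) stop(..., call. = FALSE)

assert_same_dim <- function(image, map) {
  if (!identical(dim(image)[1:2], dim(map)[1:2])) {
    stop_organtraits(
      "image (", dim(image)[1], "x", dim(image)[2], ") and label map (",
      dim(map)[1], "x", dim(map)[2], ") dimensions differ"
    )
  }
  invisible(TRUE)
}
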