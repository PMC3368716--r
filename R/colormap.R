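#' Define a per-layer colour scale for time-course values
#'
#' Node values are rendered on a two-endpoint gradient mapped linearly onto
#' the interval \code{(min_value, max_value)} of the value's own layer; grey
#' marks absolute zero and missing values.  The scale is mapped separately
#' for each layer, because measurements on different layers may not be
#' comparable in magnitude or units — colours must never be compared across
#' layers.
#'
#' The default gradient runs yellow (layer minimum) to blue (layer maximum).
#' Both orientation conventions are in use in the field, so \code{reversed}
#' flips the endpoints rather than either direction being canonical.  A
#' colourblind-safe preset replaces yellow/blue with a diverging
#' blue--orange pair.
#'
#' @param low_color,high_color RGB triples (integer vectors of length 3 in
#'   0..255) for the layer minimum and maximum.
#' @param zero_color RGB triple used for values that are exactly zero and
#'   for missing values; default grey.
#' @param reversed if \code{TRUE}, swap the two endpoints.
#' @param colorblind_safe if \code{TRUE}, ignore \code{low_color}/
#'   \code{high_color} and use the built-in blue--orange preset.
#' @return an object of class \code{color_scale}.
#' @examples
#' sc <- color_scale()               # yellow -> blue
#' rc <- color_scale(reversed = TRUE) # blue -> yellow
#' @export
color_scale <- function(low_color = c(255L, 255L, 0L),
                        high_color = c(0L, 0L, 255L),
                        zero_color = c(128L, 128L, 128L),
                        reversed = FALSE,
                        colorblind_safe = FALSE) {
  if (isTRUE(colorblind_safe)) {
    low_color <- c(0L, 114L, 178L)    # blue
    high_color <- c(230L, 159L, 0L)   # orange
  }
  check_rgb <- function(x, what) {
    if (!is.numeric(x) || length(x) != 3 || any(x < 0) || any(x > 255))
      stop(what, " must be an RGB triple in [0, 255]", call. = FALSE)
    as.integer(round(x))
  }
  low_color <- check_rgb(low_color, "low_color")
  high_color <- check_rgb(high_color, "high_color")
  zero_color <- check_rgb(zero_color, "zero_color")
  if (all(low_color == high_color))
    stop("low_color and high_color must be distinct", call. = FALSE)
  if (isTRUE(reversed)) {
    tmp <- low_color; low_color <- high_color; high_color <- tmp
  }
  structure(list(low_color = low_color, high_color = high_color,
                 zero_color = zero_color, reversed = isTRUE(reversed),
                 colorblind_safe = isTRUE(colorblind_safe)),
            class = "color_scale")
}

#' Map a time-course value to a colour
#'
#' Linear component-wise interpolation between the scale endpoints over the
#' layer's \code{[min_value, max_value]} interval.  A value that is exactly
#' zero (within 1e-12) or missing maps to the zero colour regardless of
#' where zero falls in the interval ("absolute zero").  On a constant layer
#' (\code{min == max}) every value takes the low-endpoint colour.
#'
#' @param value numeric scalar or \code{NA}.
#' @param stats \code{\link{layer_stats}} of the value's own layer.
#' @param scale a \code{\link{color_scale}}.
#' @param tol values outside \code{[min, max]} by more than \code{tol} are
#'   an error (the stats are stale); within \code{tol} they are clamped.
#' @return integer RGB triple.
#' @export
value_to_color <- function(value, stats, scale = color_scale(),
                           tol = 1e-9) {
  stopifnot(inherits(stats, "layer_stats"), inherits(scale, "color_scale"))
  if (length(value) != 1)
    stop("value must be a scalar", call. = FALSE)
  if (is.na(value) || abs(value) < 1e-12) return(scale$zero_color)
  lo <- stats$min_value; hi <- stats$max_value
  span <- hi - lo
  if (value < lo - tol * max(1, abs(span)) ||
      value > hi + tol * max(1, abs(span)))
    stop("value ", value, " outside layer range [", lo, ", ", hi,
         "]: stale layer_stats?", call. = FALSE)
  if (span == 0) return(scale$low_color)
  f <- min(1, max(0, (value - lo) / span))
  as.integer(round(scale$low_color + f * (scale$high_color - scale$low_color)))
}

#' Map a 0-10 similarity bin to a colour
#'
#' Similarity scores are binned to the integers 0..10 and coloured on a
#' white-to-red gradient: bin 0 is white, bin 10 full red, linear in
#' between, so equal bins are coloured identically.
#'
#' @param bin integer in 0..10.
#' @return integer RGB triple.
#' @export
score_to_color <- function(bin) {
  if (length(bin) != 1 || is.na(bin) || bin != round(bin) ||
      bin < 0 || bin > 10)
    stop("bin must be a single integer in 0..10", call. = FALSE)
  f <- bin / 10
  as.integer(round(c(255, 255 - f * 255, 255 - f * 255)))
}

#' Convert an RGB triple to a hex string
#'
#' @param rgb integer vector of length 3 in 0..255.
#' @return string like \code{"#FFFF00"}.
#' @export
rgb_to_hex <- function(rgb) {
  stopifnot(length(rgb) == 3)
  grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
}
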