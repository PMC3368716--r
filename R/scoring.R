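#' Average similarity score of a time-series vector
#'
#' Scheme (a): the arithmetic mean of the non-missing values.
#'
#' @param v numeric vector with at least one non-missing value.
#' @return the mean of the non-missing values.
#' @export
average_score <- function(v) {
  if (all(is.na(v))) stop("all values missing", call. = FALSE)
  mean(v, na.rm = TRUE)
}

#' Wilson score lower bound of a time-series vector
#'
#' Scheme (b): each non-missing time-point value is converted to a
#' Bernoulli "rating" — positive iff strictly greater than
#' \code{positive_threshold} — and the score is the lower bound of the
#' Wilson score confidence interval for the Bernoulli parameter:
#' \deqn{\frac{\hat p + \frac{z^2}{2n} - z\sqrt{\frac{\hat p(1-\hat p)}{n}
#'   + \frac{z^2}{4n^2}}}{1 + \frac{z^2}{n}},}
#' where \eqn{\hat p} is the fraction of positive ratings,
#' \eqn{z = z_{\alpha/2}} is the \eqn{(1-\alpha/2)} Gaussian quantile and
#' \eqn{n} the number of ratings.  The bound balances the observed positive
#' fraction against the uncertainty of a small number of observations: it
#' is always at most \eqn{\hat p}, equals 0 when no rating is positive, and
#' converges to \eqn{\hat p} as \eqn{n} grows.
#'
#' How a continuous value becomes a "positive rating" is a convention of
#' this package, not a property of the interval: the default threshold 0
#' counts strictly positive values, which suits non-negative penetrance
#' scores where any nonzero value means the phenotype was observed.
#'
#' @param v numeric vector with at least one non-missing value.
#' @param alpha significance level for the interval (default 0.05, i.e.
#'   \eqn{z = 1.96}).
#' @param positive_threshold a value counts as a positive rating iff
#'   strictly greater than this (default 0).
#' @return the lower bound, in \eqn{[0, 1]}.
#' @examples
#' wilson_lower_bound(c(rep(1, 5), rep(0, 5)))  # p-hat 0.5, n 10 -> 0.2366
#' @export
wilson_lower_bound <- function(v, alpha = 0.05, positive_threshold = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0) stop("all values missing", call. = FALSE)
  phat <- sum(v > positive_threshold) / n
  if (phat == 0) return(0)  # the bound is exactly 0 with no positives
  z <- stats::qnorm(1 - alpha / 2)
  lb <- (phat + z^2 / (2 * n) -
           z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  min(1, max(0, lb))
}

#' Score every entity of a layer by time-series similarity
#'
#' Computes one raw score per entity on the layer under the chosen scheme,
#' converts the scores to bins 0..10 against that layer's own raw-score
#' range, and assigns the white-to-red bin colour.  Binning is
#' \code{floor(10 * (raw - min) / (max - min))} clamped to \eqn{[0, 10]},
#' so equal raw scores always land in the same bin and ranking is
#' preserved; a degenerate range (all scores equal) maps everything to bin
#' 0.  Scores are computed uniquely per layer: bins on different layers are
#' never comparable, so no cross-layer statement ("most affected
#' phenotype") can be read off the colours.
#'
#' @param net a \code{\link{layered_network}}.
#' @param layer layer name.
#' @param scheme \code{"average"} or \code{"wilson"}.
#' @param alpha,positive_threshold passed to
#'   \code{\link{wilson_lower_bound}} for the Wilson scheme.
#' @return data frame with one row per entity: \code{entity}, \code{layer},
#'   \code{scheme}, \code{raw_score}, \code{bin}, \code{color} (hex).
#'   Entities with no non-missing values get \code{NA} raw score and bin 0.
#' @export
score_layer <- function(net, layer, scheme = c("average", "wilson"),
                        alpha = 0.05, positive_threshold = 0) {
  check_layer(net, layer)
  scheme <- match.arg(scheme)
  m <- layer_values(net, layer)
  raw <- apply(m, 1, function(v) {
    if (all(is.na(v))) return(NA_real_)
    if (scheme == "average") average_score(v)
    else wilson_lower_bound(v, alpha = alpha,
                            positive_threshold = positive_threshold)
  })
  bin <- score_bins(raw)
  data.frame(entity = rownames(m), layer = layer, scheme = scheme,
             raw_score = unname(raw), bin = bin,
             color = vapply(bin, function(b) rgb_to_hex(score_to_color(b)),
                            character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

## 0-10 bins over the finite range of raw scores; floor, clamped;
## degenerate range -> all bin 0; NA raw -> bin 0
score_bins <- function(raw) {
  fin <- raw[is.finite(raw)]
  if (length(fin) == 0) return(rep(0L, length(raw)))
  lo <- min(fin); hi <- max(fin)
  vapply(raw, function(x) {
    if (!is.finite(x) || hi == lo) return(0L)
    as.integer(max(0, min(10, floor(10 * (x - lo) / (hi - lo)))))
  }, integer(1))
}

#' Per-layer trajectory of one entity
#'
#' The timeline evolution of an entity's values on every layer it appears
#' on — the data behind a line chart with one line per layer (for a
#' knockdown screen: the penetrance of each phenotype over time).
#'
#' @param net a \code{\link{layered_network}}.
#' @param entity entity identifier, present on at least one layer.
#' @return data frame in long form: \code{layer}, \code{time_point},
#'   \code{time_index}, \code{value} (missing preserved as \code{NA}); one
#'   row per (layer the entity appears on) x time point, layers in network
#'   order.
#' @seealso \code{\link{plot_entity_track}}
#' @export
track_entity <- function(net, entity) {
  if (length(entity) != 1 || !entity %in% net$entities)
    stop("unknown entity '", paste(entity, collapse = ","), "'",
         call. = FALSE)
  lys <- net$layers[vapply(net$layers,
                           function(ly) entity %in% names(net$values[[ly]]),
                           logical(1))]
  n <- length(net$time_points)
  do.call(rbind, lapply(lys, function(ly) data.frame(
    layer = ly, time_point = net$time_points, time_index = seq_len(n),
    value = net$values[[ly]][[entity]],
    row.names = NULL, stringsAsFactors = FALSE)))
}

#' Line chart of one entity's trajectories
#'
#' Draws one line per layer from \code{\link{track_entity}}.
#'
#' @inheritParams track_entity
#' @param path optional output image file (extension selects the device:
#'   .png, .svg or .pdf); when \code{NULL}, draws on the current device.
#' @return the trajectory table, invisibly.
#' @export
plot_entity_track <- function(net, entity, path = NULL) {
  tr <- track_entity(net, entity)
  if (!is.null(path)) {
    open_device(path, width = 7, height = 5)
    on.exit(grDevices::dev.off())
  }
  lys <- unique(tr$layer)
  cols <- grDevices::hcl.colors(max(3, length(lys)), "Dark 3")[
    seq_along(lys)]
  ylim <- range(tr$value, na.rm = TRUE)
  if (!all(is.finite(ylim))) ylim <- c(0, 1)
  graphics::plot(NA, xlim = c(1, length(net$time_points)), ylim = ylim,
                 xlab = "time point", ylab = "value", main = entity,
                 xaxt = "n")
  graphics::axis(1, at = seq_along(net$time_points),
                 labels = net$time_points)
  for (i in seq_along(lys)) {
    g <- tr[tr$layer == lys[i], ]
    graphics::lines(g$time_index, g$value, col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = lys, col = cols, lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(tr)
}

## choose a graphics device from the file extension
open_device <- function(path, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 96),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop("unsupported image format '.", ext,
              "' (use .png, .svg or .pdf)", call. = FALSE))
}
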