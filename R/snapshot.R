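#' Render a static snapshot of the network at one time point
#'
#' Draws one panel per layer (2D small multiples standing in for a stacked
#' 3D scene): nodes coloured by \code{\link{value_to_color}} against their
#' own layer's range, positioned either by the per-time-point
#' distance-geometry embedding (\code{embed = TRUE}; first two embedding
#' axes) or on a fixed grid shared by all layers, so that an entity keeps
#' the same grid position on every layer.  Intra-layer edges are drawn in
#' light grey; significant correlation edges are overlaid in yellow
#' (positive) or red (negative); tracked entities are drawn at double size;
#' the top changer(s) into this time point are flagged with a marker on
#' every panel for cross-layer recognition.
#'
#' Rendering is a pure function of its inputs: no jitter is used, so the
#' draw manifest (positions, colours, sizes) is identical across runs.
#' Tests and downstream code should consume the manifest, not pixels.
#'
#' @param net a \code{\link{layered_network}}.
#' @param t time-point label.
#' @param path output image file (.png, .svg or .pdf), or \code{NULL} to
#'   draw on the current device.
#' @param embed position nodes by distance-geometry embedding (default);
#'   layers with fewer than 2 usable entities at \code{t} fall back to the
#'   grid.
#' @param correlations optional data frame from
#'   \code{\link{significant_correlations}} (any mix of layers) whose edges
#'   are overlaid.
#' @param tracked character vector of entities to enlarge.
#' @param top_changes flag the top changer(s) between the previous time
#'   point and \code{t} on each layer (skipped when \code{t} is the first
#'   time point).
#' @param k number of top changers per layer when \code{top_changes}.
#' @param scale a \code{\link{color_scale}}.
#' @return invisibly, the draw manifest: data frame with \code{layer},
#'   \code{entity}, \code{x}, \code{y}, \code{size}, \code{color} (hex),
#'   \code{tracked}, \code{top_change}.  Entities with no value at \code{t}
#'   under \code{embed} get \code{NA} coordinates and are not drawn.
#' @export
render_snapshot <- function(net, t, path = NULL, embed = TRUE,
                            correlations = NULL, tracked = character(0),
                            top_changes = FALSE, k = 1,
                            scale = color_scale()) {
  ti <- check_time_point(net, t)
  unknown <- setdiff(tracked, net$entities)
  if (length(unknown))
    stop("unknown tracked entity '", unknown[1], "'", call. = FALSE)

  manifest <- snapshot_manifest(net, ti, embed, tracked, top_changes, k,
                                scale)
  if (!is.null(path)) {
    open_device(path, width = 4 * length(net$layers), height = 4.5)
    on.exit(grDevices::dev.off())
    draw_snapshot(net, manifest, correlations, t)
  } else if (grDevices::dev.cur() != 1) {
    draw_snapshot(net, manifest, correlations, t)
  }
  invisible(manifest)
}

snapshot_manifest <- function(net, ti, embed, tracked, top_changes, k,
                              scale) {
  t <- net$time_points[ti]
  grid_pos <- grid_positions(net$entities)
  rows <- list()
  for (ly in net$layers) {
    st <- layer_stats(net, ly)
    m <- layer_values(net, ly)
    v <- m[, ti]
    pos <- grid_pos[rownames(m), , drop = FALSE]
    if (embed) {
      usable <- sum(!is.na(v))
      if (usable >= 2) {
        emb <- cluster_layer_at_time(net, ly, t)
        pos[] <- NA_real_
        pos[rownames(emb$coordinates), ] <- emb$coordinates[, 1:2]
      }
    }
    top_ents <- character(0)
    if (top_changes && ti > 1) {
      cr <- top_changers(net, ly, net$time_points[ti - 1], k = k)
      top_ents <- cr$top$entity
    }
    cols <- vapply(v, function(x)
      rgb_to_hex(value_to_color(x, st, scale)), character(1))
    rows[[ly]] <- data.frame(
      layer = ly, entity = rownames(m),
      x = pos[, 1], y = pos[, 2],
      size = ifelse(rownames(m) %in% tracked, 2, 1),
      color = unname(cols),
      tracked = rownames(m) %in% tracked,
      top_change = rownames(m) %in% top_ents,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## fixed square grid over the union entity order, shared by all layers
grid_positions <- function(entities) {
  n <- length(entities)
  ncol <- ceiling(sqrt(n))
  i <- seq_len(n) - 1
  matrix(c(i %% ncol, -(i %/% ncol)), ncol = 2,
         dimnames = list(entities, c("x", "y")))
}

draw_snapshot <- function(net, manifest, correlations, t) {
  op <- graphics::par(mfrow = c(1, length(net$layers)),
                      mar = c(1, 1, 3, 1))
  on.exit(graphics::par(op))
  for (ly in net$layers) {
    g <- manifest[manifest$layer == ly & !is.na(manifest$x), , drop = FALSE]
    xlim <- grDevices::extendrange(g$x, f = 0.1)
    ylim <- grDevices::extendrange(g$y, f = 0.1)
    if (!all(is.finite(xlim))) xlim <- c(-1, 1)
    if (!all(is.finite(ylim))) ylim <- c(-1, 1)
    graphics::plot(NA, xlim = xlim, ylim = ylim, axes = FALSE,
                   xlab = "", ylab = "",
                   main = paste0(ly, " @ ", t))
    ie <- net$intra_edges[net$intra_edges$layer == ly, , drop = FALSE]
    for (i in seq_len(nrow(ie))) {
      a <- g[g$entity == ie$entity_a[i], ]
      b <- g[g$entity == ie$entity_b[i], ]
      if (nrow(a) && nrow(b))
        graphics::segments(a$x, a$y, b$x, b$y, col = "grey80")
    }
    if (!is.null(correlations)) {
      cc <- correlations[correlations$layer == ly, , drop = FALSE]
      for (i in seq_len(nrow(cc))) {
        a <- g[g$entity == cc$entity_a[i], ]
        b <- g[g$entity == cc$entity_b[i], ]
        if (nrow(a) && nrow(b))
          graphics::segments(a$x, a$y, b$x, b$y, lwd = 2,
                             col = if (cc$sign[i] == "positive")
                               "gold" else "red")
      }
    }
    graphics::points(g$x, g$y, pch = 21, bg = g$color,
                     cex = 1.6 * g$size)
    tc <- g[g$top_change, , drop = FALSE]
    if (nrow(tc))
      graphics::points(tc$x, tc$y, pch = 8, cex = 2.2, col = "black")
    graphics::text(g$x, g$y, g$entity, pos = 3, cex = 0.6, offset = 0.4)
  }
}

#' Render one snapshot per time point
#'
#' Emits a numbered image series, one file per time point, suitable for
#' assembly into an animation by external tools.
#'
#' @inheritParams render_snapshot
#' @param prefix output path prefix; files are written as
#'   \code{<prefix>_<index>_<label>.<ext>}.
#' @param ext image format (\code{"png"}, \code{"svg"} or \code{"pdf"}).
#' @param ... further arguments passed to \code{\link{render_snapshot}}.
#' @return character vector of the files written, invisibly.
#' @export
render_time_sweep <- function(net, prefix, ext = "png", ...) {
  files <- character(0)
  for (i in seq_along(net$time_points)) {
    f <- sprintf("%s_%03d_%s.%s", prefix, i,
                 gsub("[^A-Za-z0-9._-]", "_", net$time_points[i]), ext)
    render_snapshot(net, net$time_points[i], path = f, ...)
    files <- c(files, f)
  }
  invisible(files)
}
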