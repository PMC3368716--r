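#' Embed points in 3D from a distance matrix (distance geometry)
#'
#' Given a pairwise distance matrix, reconstructs coordinates for each point
#' in 3D space so that points at short distance are placed close together.
#' Realised as classical multidimensional scaling: the squared distances are
#' double-centred (\eqn{B = -\frac{1}{2} J D^2 J} with \eqn{J = I - 11'/n}),
#' the top three eigenpairs of \eqn{B} are taken, and coordinates are the
#' eigenvectors scaled by the square roots of their eigenvalues.  For a
#' distance matrix exactly realisable in at most three dimensions the output
#' reproduces the input distances up to a rigid transform; otherwise it is
#' the best rank-3 approximation, with negative eigenvalues (non-Euclidean
#' input) truncated to zero rather than raised as an error.
#'
#' Coordinates are made deterministic: eigenpairs are sorted by eigenvalue
#' descending and each axis's sign is fixed so its largest-magnitude
#' component is positive.  Only recovered distances are geometrically
#' meaningful; raw coordinates are unique only up to a rigid transform.
#'
#' @param D square symmetric non-negative matrix with zero diagonal
#'   (\code{n >= 1}).
#' @return numeric \code{n x 3} coordinate matrix (rows named after
#'   \code{D}'s rows); fewer than 3 informative axes are padded with zeros.
#' @examples
#' pts <- matrix(rnorm(15), 5, 3)
#' D <- as.matrix(dist(pts))
#' X <- distance_geometry_embed(D)
#' max(abs(as.matrix(dist(X)) - D))   # ~ 0
#' @export
distance_geometry_embed <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n == 0 || ncol(D) != n)
    stop("D must be a non-empty square matrix", call. = FALSE)
  if (any(is.na(D)) || any(D < 0))
    stop("D must be non-negative with no missing entries", call. = FALSE)
  tol <- 1e-8 * max(1, max(D))
  if (max(abs(D - t(D))) > tol)
    stop("D must be symmetric", call. = FALSE)
  if (max(abs(diag(D))) > tol)
    stop("D must have a zero diagonal", call. = FALSE)
  X <- matrix(0, n, 3, dimnames = list(rownames(D), NULL))
  if (n == 1) return(X)
  D2 <- D * D
  ## double-centring without forming J explicitly
  rm <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (sweep(sweep(D2, 1, rm), 2, rm) + gm)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)   # eigenvalues already descending
  k <- min(3, n)
  lam <- pmax(e$values[seq_len(k)], 0)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (lam[j] == 0) { V[, j] <- 0; next }
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  X[, seq_len(k)] <- sweep(V, 2, sqrt(lam), `*`)
  X
}

#' Per-layer, per-time-point clustering of entities
#'
#' Places the entities of one layer in 3D space according to their values at
#' a single time point, so that entities with similar values cluster
#' together.  The pairwise distance between two entities is the absolute
#' difference of their scalar values at that time point; the placement is
#' the distance-geometry embedding of that matrix (exact, since 1-D metrics
#' embed exactly).  The clustering is purely a placement: no number of
#' clusters is specified and no downstream result depends on it.
#'
#' @param net a \code{\link{layered_network}}.
#' @param layer layer name.
#' @param t time-point label.
#' @return object of class \code{embedding}: list with \code{layer},
#'   \code{time_point}, \code{coordinates} (matrix, one named row per entity
#'   with a value at \code{t}), and \code{excluded} (entities of the layer
#'   missing a value at \code{t}).
#' @export
cluster_layer_at_time <- function(net, layer, t) {
  check_layer(net, layer)
  ti <- check_time_point(net, t)
  m <- layer_values(net, layer)
  v <- m[, ti]
  usable <- !is.na(v)
  if (sum(usable) < 2)
    stop("layer '", layer, "' has fewer than 2 entities with values at '",
         t, "'", call. = FALSE)
  vv <- v[usable]
  D <- abs(outer(vv, vv, `-`))
  structure(list(layer = layer, time_point = as.character(t),
                 coordinates = distance_geometry_embed(D),
                 excluded = names(v)[!usable]),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: layer '%s' at time '%s', %d entities (%d excluded)\n",
              x$layer, x$time_point, nrow(x$coordinates),
              length(x$excluded)))
  invisible(x)
}

#' Entities with the highest change between consecutive time points
#'
#' For one layer and a pair of consecutive time points, computes the
#' absolute value change of every entity and reports the \code{k} largest.
#' Ties at the k-th delta are all included, so the report may exceed
#' \code{k}.  Entities missing a value at either time point are skipped.
#'
#' @param net a \code{\link{layered_network}}.
#' @param layer layer name.
#' @param from_t time-point label; the change is measured to the
#'   immediately following time point.  Must not be the last label.
#' @param k number of top changers to report (default 1).
#' @return object of class \code{change_report}: list with \code{layer},
#'   \code{from_time}, \code{to_time}, \code{deltas} (named non-negative
#'   vector, all scored entities), and \code{top} (data frame
#'   \code{entity}, \code{delta} sorted by delta descending).
#' @export
top_changers <- function(net, layer, from_t, k = 1) {
  check_layer(net, layer)
  fi <- check_time_point(net, from_t)
  if (fi >= length(net$time_points))
    stop("'", from_t, "' is the last time point; no following point to ",
         "compare with", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("k must be a positive integer", call. = FALSE)
  m <- layer_values(net, layer)
  d <- abs(m[, fi + 1] - m[, fi])
  d <- d[!is.na(d)]
  ord <- order(-d, match(names(d), rownames(m)))
  d <- d[ord]
  if (length(d) == 0) {
    top <- data.frame(entity = character(0), delta = numeric(0))
  } else {
    thr <- d[min(k, length(d))]
    top <- data.frame(entity = names(d)[d >= thr], delta = d[d >= thr],
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(layer = layer,
                 from_time = net$time_points[fi],
                 to_time = net$time_points[fi + 1],
                 deltas = d, top = top),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf("change report: layer '%s', %s -> %s\n",
              x$layer, x$from_time, x$to_time))
  print(x$top)
  invisible(x)
}
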