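#' Construct a layered time-course network
#'
#' A layered network replicates a set of entities (genes, proteins,
#' phenotypes) across one or more layers, each layer representing one type
#' of biological measurement.  Every entity present on a layer carries a
#' time-series vector of values over a shared grid of time points; missing
#' measurements are kept as \code{NA}, never silently converted to zero.
#'
#' @param layers character vector of unique layer names, in display order.
#' @param time_points character vector of N time-point labels, shared by all
#'   layers.  Labels carry an implied uniform order; no timestamps are
#'   required.
#' @param values named list, one element per layer (names must match
#'   \code{layers}), each itself a named list mapping entity identifier to a
#'   numeric vector of length N (\code{NA} allowed).  An entity may appear on
#'   any subset of layers.
#' @param intra_edges data frame with columns \code{layer}, \code{entity_a},
#'   \code{entity_b}: undirected edges within one layer.  May be \code{NULL}.
#' @param inter_edges data frame with columns \code{layer_a}, \code{entity_a},
#'   \code{layer_b}, \code{entity_b}: undirected edges between two different
#'   layers.  May be \code{NULL}.
#'
#' @return an object of class \code{layered_network} with components
#'   \code{layers}, \code{entities} (union of entity identifiers in order of
#'   first appearance), \code{time_points}, \code{values},
#'   \code{intra_edges}, \code{inter_edges}.
#'
#' @details Invariants enforced at construction: unique layer names, value
#'   vectors all of length N, edge endpoints referencing entities actually
#'   present on the named layer(s), and no self-edges.  Edges are stored in a
#'   canonical order (endpoints sorted) so that two networks with the same
#'   edge set compare equal regardless of input order.
#'
#' @examples
#' net <- layered_network(
#'   layers = "mRNA", time_points = c("d1", "d3", "d5"),
#'   values = list(mRNA = list(nanog = c(1, 2, 3), sox2 = c(0, NA, 5))),
#'   intra_edges = data.frame(layer = "mRNA",
#'                            entity_a = "nanog", entity_b = "sox2"))
#' layer_stats(net, "mRNA")
#' @export
layered_network <- function(layers, time_points, values,
                            intra_edges = NULL, inter_edges = NULL) {
  layers <- as.character(layers)
  time_points <- as.character(time_points)
  if (is.null(intra_edges)) intra_edges <- empty_intra_edges()
  if (is.null(inter_edges)) inter_edges <- empty_inter_edges()
  net <- structure(
    list(layers = layers,
         entities = character(0),
         time_points = time_points,
         values = values,
         intra_edges = canonical_intra(intra_edges),
         inter_edges = canonical_inter(inter_edges)),
    class = "layered_network")
  net$entities <- collect_entities(net)
  validate_layered_network(net)
  net
}

empty_intra_edges <- function() {
  data.frame(layer = character(0), entity_a = character(0),
             entity_b = character(0), stringsAsFactors = FALSE)
}

empty_inter_edges <- function() {
  data.frame(layer_a = character(0), entity_a = character(0),
             layer_b = character(0), entity_b = character(0),
             stringsAsFactors = FALSE)
}

## entities in order of first appearance across layers (layer order, then
## row order within a layer)
collect_entities <- function(net) {
  seen <- character(0)
  for (ly in net$layers) {
    ents <- names(net$values[[ly]])
    seen <- c(seen, setdiff(ents, seen))
  }
  seen
}

## canonical undirected representation: endpoints sorted, duplicates dropped
canonical_intra <- function(e) {
  e <- as.data.frame(lapply(e, as.character), stringsAsFactors = FALSE)
  if (nrow(e) == 0) return(empty_intra_edges())
  swap <- e$entity_a > e$entity_b
  tmp <- e$entity_a[swap]; e$entity_a[swap] <- e$entity_b[swap]
  e$entity_b[swap] <- tmp
  e <- unique(e)
  e <- e[order(e$layer, e$entity_a, e$entity_b), , drop = FALSE]
  rownames(e) <- NULL
  e
}

canonical_inter <- function(e) {
  e <- as.data.frame(lapply(e, as.character), stringsAsFactors = FALSE)
  if (nrow(e) == 0) return(empty_inter_edges())
  key_a <- paste(e$layer_a, e$entity_a, sep = "\r")
  key_b <- paste(e$layer_b, e$entity_b, sep = "\r")
  swap <- key_a > key_b
  for (cols in list(c("layer_a", "layer_b"), c("entity_a", "entity_b"))) {
    tmp <- e[[cols[1]]][swap]
    e[[cols[1]]][swap] <- e[[cols[2]]][swap]
    e[[cols[2]]][swap] <- tmp
  }
  e <- unique(e)
  e <- e[order(e$layer_a, e$entity_a, e$layer_b, e$entity_b), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Validate a layered network
#'
#' Checks every structural invariant of the data model and stops with an
#' informative error on the first violation.
#'
#' @param net a \code{layered_network}.
#' @return \code{net}, invisibly, if valid.
#' @export
validate_layered_network <- function(net) {
  stopifnot(inherits(net, "layered_network"))
  if (anyDuplicated(net$layers))
    stop("duplicate layer name: ",
         net$layers[duplicated(net$layers)][1], call. = FALSE)
  if (length(net$layers) == 0) stop("network has no layers", call. = FALSE)
  if (length(net$time_points) == 0)
    stop("network has no time points", call. = FALSE)
  if (anyDuplicated(net$time_points))
    stop("duplicate time-point label", call. = FALSE)
  if (!setequal(names(net$values), net$layers))
    stop("values must have exactly one element per declared layer",
         call. = FALSE)
  n <- length(net$time_points)
  for (ly in net$layers) {
    vals <- net$values[[ly]]
    if (anyDuplicated(names(vals)))
      stop("duplicate entity '", names(vals)[duplicated(names(vals))][1],
           "' on layer '", ly, "'", call. = FALSE)
    for (ent in names(vals)) {
      v <- vals[[ent]]
      if (!is.numeric(v) || length(v) != n)
        stop("value vector for entity '", ent, "' on layer '", ly,
             "' has length ", length(v), ", expected ", n, call. = FALSE)
    }
  }
  ie <- net$intra_edges
  for (i in seq_len(nrow(ie))) {
    ly <- ie$layer[i]
    if (!ly %in% net$layers)
      stop("edge references unknown layer '", ly, "'", call. = FALSE)
    for (ent in c(ie$entity_a[i], ie$entity_b[i]))
      if (!ent %in% names(net$values[[ly]]))
        stop("edge endpoint '", ent, "' is not present on layer '", ly, "'",
             call. = FALSE)
    if (ie$entity_a[i] == ie$entity_b[i])
      stop("self-edge on layer '", ly, "' at entity '", ie$entity_a[i], "'",
           call. = FALSE)
  }
  xe <- net$inter_edges
  for (i in seq_len(nrow(xe))) {
    for (side in list(c(xe$layer_a[i], xe$entity_a[i]),
                      c(xe$layer_b[i], xe$entity_b[i]))) {
      if (!side[1] %in% net$layers)
        stop("edge references unknown layer '", side[1], "'", call. = FALSE)
      if (!side[2] %in% names(net$values[[side[1]]]))
        stop("edge endpoint '", side[2], "' is not present on layer '",
             side[1], "'", call. = FALSE)
    }
    if (xe$layer_a[i] == xe$layer_b[i] && xe$entity_a[i] == xe$entity_b[i])
      stop("self-edge at ('", xe$layer_a[i], "', '", xe$entity_a[i], "')",
           call. = FALSE)
  }
  invisible(net)
}

#' Entities present on one layer
#'
#' @param net a \code{layered_network}.
#' @param layer layer name.
#' @return character vector of entity identifiers carrying a value vector on
#'   that layer, in declaration order.
#' @export
layer_entities <- function(net, layer) {
  check_layer(net, layer)
  names(net$values[[layer]])
}

check_layer <- function(net, layer) {
  if (!is.character(layer) || length(layer) != 1 || !layer %in% net$layers)
    stop("unknown layer '", paste(layer, collapse = ","), "'", call. = FALSE)
  invisible(layer)
}

check_time_point <- function(net, t) {
  if (length(t) != 1 || !as.character(t) %in% net$time_points)
    stop("unknown time point '", paste(t, collapse = ","), "'",
         call. = FALSE)
  match(as.character(t), net$time_points)
}

#' Value matrix of one layer
#'
#' @param net a \code{layered_network}.
#' @param layer layer name.
#' @return numeric matrix, entities in rows, time points in columns,
#'   \code{NA} for missing measurements.
#' @export
layer_values <- function(net, layer) {
  check_layer(net, layer)
  vals <- net$values[[layer]]
  m <- do.call(rbind, vals)
  if (is.null(m)) m <- matrix(numeric(0), 0, length(net$time_points))
  dimnames(m) <- list(names(vals), net$time_points)
  m
}

#' Per-layer value extremes
#'
#' The minimum and maximum over all non-missing values of a layer across the
#' whole time course.  These are the anchors of the per-layer colour scale:
#' colour is mapped separately for each layer because the measurements on
#' different layers need not be comparable in magnitude or units.
#'
#' @param net a \code{layered_network}.
#' @param layer layer name.
#' @return object of class \code{layer_stats}: list with \code{layer},
#'   \code{min_value}, \code{max_value}.
#' @export
layer_stats <- function(net, layer) {
  m <- layer_values(net, layer)
  v <- m[!is.na(m)]
  if (length(v) == 0)
    stop("layer '", layer, "' has no non-missing values", call. = FALSE)
  structure(list(layer = layer, min_value = min(v), max_value = max(v)),
            class = "layer_stats")
}

#' @export
print.layered_network <- function(x, ...) {
  cat("layered_network:", length(x$layers), "layer(s),",
      length(x$entities), "entities,",
      length(x$time_points), "time points\n")
  cat("  layers:", paste(x$layers, collapse = ", "), "\n")
  cat("  edges:", nrow(x$intra_edges), "intra-layer,",
      nrow(x$inter_edges), "inter-layer\n")
  invisible(x)
}

#' @export
print.layer_stats <- function(x, ...) {
  cat(sprintf("layer '%s': min %g, max %g\n",
              x$layer, x$min_value, x$max_value))
  invisible(x)
}
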