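#' Read a layered time-course network from file
#'
#' Two equivalent on-disk dialects are supported.
#'
#' \strong{TSV dialect} — four sections introduced by header lines:
#' \preformatted{
#' #LAYERS
#' <layer name>                   (one per line)
#' #TIMEPOINTS                    (optional; defaults to t1..tN)
#' <time point label>             (one per line)
#' #VALUES
#' <layer> <entity> <v_1> ... <v_N>   (tab-separated, NA = missing)
#' #EDGES
#' <layerA> <entityA> <layerB> <entityB>  (intra-layer when layerA == layerB)
#' }
#'
#' \strong{JSON dialect} — an object with fields \code{layers},
#' \code{time_points}, \code{values} (layer -> entity -> numeric array with
#' \code{null} for missing), \code{intra_edges} and \code{inter_edges}
#' (arrays of records).
#'
#' @param path file to read.
#' @param format \code{"tsv"}, \code{"json"}, or \code{"auto"} (decide from
#'   the file extension; \code{.json} means JSON, anything else TSV).
#' @return a validated \code{\link{layered_network}}; missing values are
#'   preserved as \code{NA}, not zero.
#' @seealso \code{\link{write_layered_network}}
#' @export
read_layered_network <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") read_network_json(path) else read_network_tsv(path)
}

read_network_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !grepl("^//", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty network file: ", path, call. = FALSE)
  headers <- grep("^#", lines)
  if (length(headers) == 0 || headers[1] != 1)
    stop("format error at line ", if (length(lineno)) lineno[1] else 1,
         ": file must start with a #SECTION header", call. = FALSE)
  known <- c("#LAYERS", "#TIMEPOINTS", "#VALUES", "#EDGES")
  sections <- list()
  for (i in seq_along(headers)) {
    h <- trimws(lines[headers[i]])
    if (!h %in% known)
      stop("format error at line ", lineno[headers[i]],
           ": unknown section header '", h, "'", call. = FALSE)
    if (h %in% names(sections))
      stop("format error at line ", lineno[headers[i]],
           ": duplicate section '", h, "'", call. = FALSE)
    from <- headers[i] + 1
    to <- if (i < length(headers)) headers[i + 1] - 1 else length(lines)
    idx <- if (from > to) integer(0) else from:to
    sections[[h]] <- list(body = lines[idx], lineno = lineno[idx])
  }
  for (req in c("#LAYERS", "#VALUES"))
    if (!req %in% names(sections))
      stop("format error: missing required section ", req, call. = FALSE)

  layers <- trimws(sections[["#LAYERS"]]$body)
  if (length(layers) == 0) stop("format error: #LAYERS section is empty",
                                call. = FALSE)

  vrows <- strsplit(sections[["#VALUES"]]$body, "\t", fixed = TRUE)
  vline <- sections[["#VALUES"]]$lineno
  if (length(vrows) == 0)
    stop("format error: #VALUES section is empty", call. = FALSE)

  if ("#TIMEPOINTS" %in% names(sections)) {
    time_points <- trimws(sections[["#TIMEPOINTS"]]$body)
    n <- length(time_points)
    if (n == 0) stop("format error: #TIMEPOINTS section is empty",
                     call. = FALSE)
  } else {
    n <- length(vrows[[1]]) - 2
    if (n < 1)
      stop("format error at line ", vline[1],
           ": value row needs layer, entity and at least one value",
           call. = FALSE)
    time_points <- paste0("t", seq_len(n))
  }

  values <- stats::setNames(
    lapply(layers, function(x) list()), layers)
  for (i in seq_along(vrows)) {
    f <- vrows[[i]]
    if (length(f) != n + 2)
      stop("validation error at line ", vline[i], ": entity '",
           if (length(f) >= 2) f[2] else "?", "' on layer '",
           if (length(f) >= 1) f[1] else "?", "' has ",
           max(length(f) - 2, 0), " values, expected ", n, call. = FALSE)
    ly <- f[1]; ent <- f[2]
    if (!ly %in% layers)
      stop("validation error at line ", vline[i],
           ": value row names undeclared layer '", ly, "'", call. = FALSE)
    raw <- f[-(1:2)]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & raw != "NA")
    if (length(bad))
      stop("format error at line ", vline[i], ": non-numeric value '",
           raw[bad[1]], "' for entity '", ent, "' on layer '", ly, "'",
           call. = FALSE)
    if (ent %in% names(values[[ly]]))
      stop("validation error at line ", vline[i], ": duplicate entity '",
           ent, "' on layer '", ly, "'", call. = FALSE)
    values[[ly]][[ent]] <- v
  }

  intra <- empty_intra_edges()
  inter <- empty_inter_edges()
  if ("#EDGES" %in% names(sections)) {
    erows <- strsplit(sections[["#EDGES"]]$body, "\t", fixed = TRUE)
    eline <- sections[["#EDGES"]]$lineno
    for (i in seq_along(erows)) {
      f <- erows[[i]]
      if (length(f) != 4)
        stop("format error at line ", eline[i],
             ": edge row needs 4 fields (layerA entityA layerB entityB)",
             call. = FALSE)
      if (f[1] == f[3]) {
        intra <- rbind(intra, data.frame(
          layer = f[1], entity_a = f[2], entity_b = f[4],
          stringsAsFactors = FALSE))
      } else {
        inter <- rbind(inter, data.frame(
          layer_a = f[1], entity_a = f[2], layer_b = f[3], entity_b = f[4],
          stringsAsFactors = FALSE))
      }
    }
  }
  layered_network(layers, time_points, values, intra, inter)
}

read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (req in c("layers", "time_points", "values"))
    if (is.null(x[[req]]))
      stop("format error: JSON network lacks field '", req, "'",
           call. = FALSE)
  layers <- vapply(x$layers, as.character, character(1))
  time_points <- vapply(x$time_points, as.character, character(1))
  values <- lapply(x$values, function(layer_vals) {
    lapply(layer_vals, function(v)
      vapply(v, function(e) if (is.null(e)) NA_real_ else as.numeric(e),
             numeric(1)))
  })
  edge_df <- function(recs, cols, empty) {
    if (is.null(recs) || length(recs) == 0) return(empty)
    do.call(rbind, lapply(recs, function(r) {
      if (!all(cols %in% names(r)))
        stop("format error: edge record lacks field(s) ",
             paste(setdiff(cols, names(r)), collapse = ", "), call. = FALSE)
      as.data.frame(lapply(r[cols], as.character),
                    stringsAsFactors = FALSE)
    }))
  }
  intra <- edge_df(x$intra_edges, c("layer", "entity_a", "entity_b"),
                   empty_intra_edges())
  inter <- edge_df(x$inter_edges,
                   c("layer_a", "entity_a", "layer_b", "entity_b"),
                   empty_inter_edges())
  layered_network(layers, time_points, values, intra, inter)
}

#' Write a layered network to file
#'
#' Inverse of \code{\link{read_layered_network}}: reading a written file
#' reproduces the network exactly (labels and edges exactly, values at full
#' stored double precision, missingness preserved).
#'
#' @param net a validated \code{\link{layered_network}}.
#' @param path output file.
#' @param format \code{"tsv"}, \code{"json"}, or \code{"auto"} (from the
#'   extension).
#' @return \code{path}, invisibly.
#' @export
write_layered_network <- function(net, path,
                                  format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  validate_layered_network(net)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") write_network_json(net, path)
  else write_network_tsv(net, path)
  invisible(path)
}

## %.17g round-trips IEEE doubles through text exactly
fmt_value <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))

write_network_tsv <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  out <- c("#LAYERS", net$layers, "#TIMEPOINTS", net$time_points, "#VALUES")
  for (ly in net$layers)
    for (ent in names(net$values[[ly]]))
      out <- c(out, paste(c(ly, ent, fmt_value(net$values[[ly]][[ent]])),
                          collapse = "\t"))
  out <- c(out, "#EDGES")
  ie <- net$intra_edges
  if (nrow(ie))
    out <- c(out, paste(ie$layer, ie$entity_a, ie$layer, ie$entity_b,
                        sep = "\t"))
  xe <- net$inter_edges
  if (nrow(xe))
    out <- c(out, paste(xe$layer_a, xe$entity_a, xe$layer_b, xe$entity_b,
                        sep = "\t"))
  writeLines(out, con)
}

write_network_json <- function(net, path) {
  df_records <- function(df) {
    if (nrow(df) == 0) return(list())
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  obj <- list(
    layers = net$layers,
    time_points = net$time_points,
    values = net$values,
    intra_edges = df_records(net$intra_edges),
    inter_edges = df_records(net$inter_edges))
  ## I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
}

#' Export one layer as a Pajek .net file
#'
#' Writes the standard Pajek format: \code{*Vertices n}, a 1-based labelled
#' vertex list, then \code{*Edges} with 1-based endpoint indices.
#'
#' @param net a \code{layered_network}.
#' @param layer layer to export.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
export_pajek <- function(net, layer, path) {
  check_layer(net, layer)
  ents <- layer_entities(net, layer)
  ie <- net$intra_edges[net$intra_edges$layer == layer, , drop = FALSE]
  out <- c(paste0("*Vertices ", length(ents)),
           sprintf("%d \"%s\"", seq_along(ents), ents),
           "*Edges")
  if (nrow(ie))
    out <- c(out, sprintf("%d %d",
                          match(ie$entity_a, ents), match(ie$entity_b, ents)))
  writeLines(out, path)
  invisible(path)
}

#' Export one layer as a plain interaction-pair edge list
#'
#' One whitespace-separated pair of entity labels per line (the plain
#' Medusa-style interaction list).
#'
#' @inheritParams export_pajek
#' @return \code{path}, invisibly.
#' @export
export_edgelist <- function(net, layer, path) {
  check_layer(net, layer)
  ie <- net$intra_edges[net$intra_edges$layer == layer, , drop = FALSE]
  writeLines(if (nrow(ie)) paste(ie$entity_a, ie$entity_b) else character(0),
             path)
  invisible(path)
}
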