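#' Specification for a synthetic layered time-course network
#'
#' Describes a network to be generated by \code{\link{generate_network}}:
#' its dimensions, the noise level, and the structures planted into it
#' (correlated pairs, step changes, late-onset latent signals, rare-layer
#' sparsity).  Every planted structure is recorded in the generated
#' network's manifest, so analysis results can be checked against ground
#' truth.
#'
#' The value model is: each (layer, entity) starts from a flat baseline
#' drawn uniformly from \code{base_range}; planted structures overwrite or
#' shift the baseline with piecewise-linear trajectories spanning
#' \code{signal_range}; i.i.d. Gaussian noise of sd \code{noise_sd} is
#' added last; on penetrance-style layers (\code{penetrance = TRUE}) values
#' are clipped at 0, since a penetrance score cannot be negative.
#' Correlated pairs are planted by sharing a linear latent ramp across
#' \code{signal_range} (mirrored for negative sign) plus independent
#' noise, so that at low noise the realised sample correlation exceeds the
#' critical value at the spec's number of time points.  A step change of
#' magnitude \eqn{m} at time index \eqn{i} shifts the trajectory by
#' \eqn{m} from index \eqn{i + 1} on; to be recoverable as the top changer
#' it must exceed the largest per-interval change of any ramp,
#' \code{diff(signal_range) / (n_time_points - 1)}.  A latent signal sits
#' at \code{signal_range[1]} until its onset index, then ramps linearly to
#' \code{signal_range[2]} by the last time point.  On each layer listed in
#' \code{rare_layers}, a fraction \code{rare_sparsity} of the entities not
#' involved in any planted structure on that layer is set to all-zero
#' (noise-free) trajectories — the signature of a rare phenotype.
#'
#' @param layer_names character vector of layer names.
#' @param entity_names character vector of entity identifiers.
#' @param time_labels character vector of time-point labels.
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (\code{>= 0}).
#' @param base_range range the flat per-entity baselines are drawn from.
#' @param signal_range low/high values spanned by planted trajectories.
#' @param penetrance clip values at 0 after adding noise.
#' @param planted_correlated_pairs list of plants, each
#'   \code{list(pair = c(a, b), layers = ..., sign = +1 or -1)}.
#' @param planted_step_changes list of plants, each \code{list(entity,
#'   layer, time_index, magnitude)}; the step occurs between
#'   \code{time_index} and \code{time_index + 1}.
#' @param planted_latent_signals list of plants, each \code{list(entity,
#'   layer, onset)} with \code{onset} a time index.
#' @param rare_layers layers given rare-phenotype sparsity.
#' @param rare_sparsity fraction of (non-planted) entities zeroed on rare
#'   layers, in \eqn{[0, 1]}.
#' @param edge_prob probability of an intra-layer edge per entity pair; the
#'   same edge set is replicated on every layer.
#' @param seed integer RNG seed; the same seed reproduces the network
#'   byte-for-byte.
#' @return an object of class \code{synth_spec}.
#' @seealso \code{\link{synth_preset}}, \code{\link{generate_network}}
#' @export
synth_spec <- function(layer_names, entity_names, time_labels,
                       noise_sd = 0.1,
                       base_range = c(1, 9),
                       signal_range = c(2, 8),
                       penetrance = FALSE,
                       planted_correlated_pairs = list(),
                       planted_step_changes = list(),
                       planted_latent_signals = list(),
                       rare_layers = character(0),
                       rare_sparsity = 0.8,
                       edge_prob = 0,
                       seed = 1) {
  layer_names <- as.character(layer_names)
  entity_names <- as.character(entity_names)
  time_labels <- as.character(time_labels)
  n <- length(time_labels)
  stopifnot(length(layer_names) >= 1, length(entity_names) >= 1, n >= 1,
            !anyDuplicated(layer_names), !anyDuplicated(entity_names))
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (rare_sparsity < 0 || rare_sparsity > 1)
    stop("rare_sparsity must be in [0, 1]", call. = FALSE)
  if (!all(rare_layers %in% layer_names))
    stop("rare layer not in layer_names", call. = FALSE)
  for (p in planted_correlated_pairs) {
    if (length(p$pair) != 2 || p$pair[1] == p$pair[2] ||
        !all(p$pair %in% entity_names))
      stop("planted pair must name two distinct known entities",
           call. = FALSE)
    if (!all(p$layers %in% layer_names))
      stop("planted pair references unknown layer", call. = FALSE)
    if (!p$sign %in% c(-1, 1))
      stop("planted pair sign must be +1 or -1", call. = FALSE)
  }
  for (p in planted_step_changes) {
    if (!p$entity %in% entity_names || !p$layer %in% layer_names)
      stop("planted step change references unknown entity or layer",
           call. = FALSE)
    if (n < 2 || p$time_index < 1 || p$time_index > n - 1)
      stop("planted step change at time index ", p$time_index,
           " is outside the time range (need 1..", max(n - 1, 0), ")",
           call. = FALSE)
  }
  for (p in planted_latent_signals) {
    if (!p$entity %in% entity_names || !p$layer %in% layer_names)
      stop("planted latent signal references unknown entity or layer",
           call. = FALSE)
    if (p$onset < 1 || p$onset > n)
      stop("planted latent signal onset outside the time range",
           call. = FALSE)
  }
  structure(list(layer_names = layer_names, entity_names = entity_names,
                 time_labels = time_labels, noise_sd = noise_sd,
                 base_range = base_range, signal_range = signal_range,
                 penetrance = isTRUE(penetrance),
                 planted_correlated_pairs = planted_correlated_pairs,
                 planted_step_changes = planted_step_changes,
                 planted_latent_signals = planted_latent_signals,
                 rare_layers = rare_layers, rare_sparsity = rare_sparsity,
                 edge_prob = edge_prob, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic layered network from a specification
#'
#' Deterministic given the spec's seed: the same seed yields an identical
#' network; different seeds change only the noise and baselines, never the
#' planted truths.  The manifest of planted structures is attached as the
#' \code{"manifest"} attribute (see \code{\link{synth_manifest}}).
#'
#' @param spec a \code{\link{synth_spec}}.
#' @return a validated \code{\link{layered_network}} with a manifest
#'   attribute.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  lys <- spec$layer_names
  ents <- spec$entity_names
  tls <- spec$time_labels
  n <- length(tls)
  lo <- spec$signal_range[1]; hi <- spec$signal_range[2]
  ramp <- if (n == 1) (lo + hi) / 2 else seq(lo, hi, length.out = n)

  ## entities involved in any plant, per layer (exempt from rare zeroing)
  involved <- stats::setNames(vector("list", length(lys)), lys)
  for (p in spec$planted_correlated_pairs)
    for (ly in p$layers)
      involved[[ly]] <- union(involved[[ly]], p$pair)
  for (p in spec$planted_step_changes)
    involved[[p$layer]] <- union(involved[[p$layer]], p$entity)
  for (p in spec$planted_latent_signals)
    involved[[p$layer]] <- union(involved[[p$layer]], p$entity)

  values <- stats::setNames(vector("list", length(lys)), lys)
  rare_zero <- list()
  for (ly in lys) {
    base <- stats::runif(length(ents), spec$base_range[1],
                         spec$base_range[2])
    V <- matrix(rep(base, n), nrow = length(ents), ncol = n,
                dimnames = list(ents, tls))
    noise_free <- rep(FALSE, length(ents))
    if (ly %in% spec$rare_layers) {
      eligible <- setdiff(ents, involved[[ly]])
      k <- floor(spec$rare_sparsity * length(ents))
      zero_ents <- utils::head(eligible, k)
      V[zero_ents, ] <- 0
      noise_free[match(zero_ents, ents)] <- TRUE
      rare_zero[[ly]] <- zero_ents
    }
    ## shared latent ramps for planted correlated pairs on this layer
    latent <- list()
    for (p in spec$planted_correlated_pairs) {
      if (!ly %in% p$layers) next
      a <- p$pair[1]; b <- p$pair[2]
      mirror <- function(x) (lo + hi) - x
      if (is.null(latent[[a]]) && is.null(latent[[b]])) {
        latent[[a]] <- ramp
        latent[[b]] <- if (p$sign == 1) ramp else mirror(ramp)
      } else if (is.null(latent[[b]])) {
        latent[[b]] <- if (p$sign == 1) latent[[a]] else mirror(latent[[a]])
      } else if (is.null(latent[[a]])) {
        latent[[a]] <- if (p$sign == 1) latent[[b]] else mirror(latent[[b]])
      }
    }
    for (ent in names(latent)) V[ent, ] <- latent[[ent]]
    for (p in spec$planted_latent_signals) {
      if (p$layer != ly) next
      tr <- rep(lo, n)
      if (p$onset < n)
        tr[p$onset:n] <- seq(lo, hi, length.out = n - p$onset + 1)
      else tr[n] <- hi
      V[p$entity, ] <- tr
    }
    for (p in spec$planted_step_changes) {
      if (p$layer != ly) next
      idx <- (p$time_index + 1):n
      V[p$entity, idx] <- V[p$entity, idx] + p$magnitude
    }
    if (spec$noise_sd > 0) {
      noise <- matrix(stats::rnorm(length(V), 0, spec$noise_sd),
                      nrow = nrow(V))
      noise[noise_free, ] <- 0
      V <- V + noise
    }
    if (spec$penetrance) V <- pmax(V, 0)
    values[[ly]] <- stats::setNames(
      lapply(seq_along(ents), function(i) unname(V[i, ])), ents)
  }

  intra <- empty_intra_edges()
  if (spec$edge_prob > 0 && length(ents) >= 2) {
    pairs <- utils::combn(ents, 2)
    keep <- stats::runif(ncol(pairs)) < spec$edge_prob
    if (any(keep)) {
      picked <- pairs[, keep, drop = FALSE]
      intra <- do.call(rbind, lapply(lys, function(ly) data.frame(
        layer = ly, entity_a = picked[1, ], entity_b = picked[2, ],
        stringsAsFactors = FALSE)))
    }
  }

  net <- layered_network(lys, tls, values, intra_edges = intra)
  attr(net, "manifest") <- list(
    seed = spec$seed,
    noise_sd = spec$noise_sd,
    correlated_pairs = spec$planted_correlated_pairs,
    step_changes = spec$planted_step_changes,
    latent_signals = spec$planted_latent_signals,
    rare_zero_entities = rare_zero)
  net
}

#' Manifest of planted structures of a generated network
#'
#' @param net a network from \code{\link{generate_network}}.
#' @return the manifest list (planted correlated pairs, step changes,
#'   latent signals, rare-layer zero entities, seed, noise level).
#' @export
synth_manifest <- function(net) {
  m <- attr(net, "manifest")
  if (is.null(m)) stop("network carries no synthesis manifest",
                       call. = FALSE)
  m
}

#' Preset synthetic-study specifications
#'
#' Two presets mirror the shapes of the two kinds of study this package is
#' aimed at (the values are synthetic throughout):
#'
#' \describe{
#'   \item{\code{esc_core}}{A stem-cell perturbation study: one core gene
#'     set replicated on 4 layers of measurement (histone acetylation
#'     \code{HIS}, RNA polymerase II binding \code{POL}, mRNA abundance
#'     \code{RNA}, protein level \code{PRO}) over 3 time points (days 1, 3,
#'     5).  Plants: two gene pairs negatively correlated on both the mRNA
#'     and protein layers, one pair positively correlated on the
#'     acetylation layer but negatively on the mRNA layer (mixed-sign
#'     recurrence), and one large step change per layer tier between days 1
#'     and 3.}
#'   \item{\code{mitotic_screen}}{A genome-wide knockdown screen: 1067
#'     genes on 7 phenotype layers (mitotic delay, binuclear, polylobed,
#'     grape, large, dynamic, apoptosis) over 90 time points spanning 45
#'     hours, with non-negative penetrance values.  Plants: one positively
#'     correlated gene pair recurring on two phenotype layers, a late-onset
#'     latent signal on the rare \code{grape} phenotype (plus an earlier
#'     mild one on mitotic delay) for one gene, and 80\% all-zero
#'     trajectories on the rare layer.}
#' }
#'
#' @param name \code{"esc_core"} or \code{"mitotic_screen"}.
#' @param n_entities optional override of the entity count (e.g. a smaller
#'   gene subset).
#' @param n_time_points optional override of the number of time points
#'   (e.g. 50 points for a one-cell-cycle window); planted onsets scale
#'   proportionally.
#' @param seed RNG seed (default 1).
#' @param noise_sd optional override of the preset noise level.
#' @return a \code{\link{synth_spec}}.
#' @export
synth_preset <- function(name = c("esc_core", "mitotic_screen"),
                         n_entities = NULL, n_time_points = NULL,
                         seed = 1, noise_sd = NULL) {
  name <- match.arg(name)
  if (name == "esc_core") {
    genes <- c("nanog", "pou5f1", "sox2", "sall4", "esrrb", "klf4",
               "yy1", "ewsr1", "wdr18", "zfp219", "prmt1", "smarcad1",
               "rnf2", "rif1", "zfp281")
    if (!is.null(n_entities)) {
      if (n_entities <= length(genes)) genes <- genes[seq_len(n_entities)]
      else genes <- c(genes, sprintf("gene%03d",
                                     seq_len(n_entities - length(genes))))
    }
    nt <- if (is.null(n_time_points)) 3 else n_time_points
    tls <- if (nt == 3) c("day1", "day3", "day5") else
      paste0("t", seq_len(nt))
    pairs <- list(
      list(pair = c("yy1", "ewsr1"), layers = c("RNA", "PRO"), sign = -1),
      list(pair = c("sall4", "ewsr1"), layers = c("RNA", "PRO"), sign = -1),
      list(pair = c("wdr18", "zfp219"), layers = "HIS", sign = 1),
      list(pair = c("wdr18", "zfp219"), layers = "RNA", sign = -1))
    steps <- if (nt >= 2) list(
      list(entity = "prmt1", layer = "HIS", time_index = 1, magnitude = 5),
      list(entity = "smarcad1", layer = "POL", time_index = 1,
           magnitude = 5),
      list(entity = "rnf2", layer = "RNA", time_index = 1, magnitude = 5))
      else list()
    pairs <- Filter(function(p) all(p$pair %in% genes), pairs)
    steps <- Filter(function(p) p$entity %in% genes, steps)
    synth_spec(layer_names = c("HIS", "POL", "RNA", "PRO"),
               entity_names = genes, time_labels = tls,
               noise_sd = if (is.null(noise_sd)) 0.07 else noise_sd,
               base_range = c(1, 9), signal_range = c(2, 8),
               penetrance = FALSE,
               planted_correlated_pairs = pairs,
               planted_step_changes = steps,
               edge_prob = 0.25, seed = seed)
  } else {
    ne <- if (is.null(n_entities)) 1067 else n_entities
    named <- c("lsm14a", "incenp", "ranbp3")
    genes <- if (ne <= length(named)) named[seq_len(ne)] else
      c(named, sprintf("gene%04d", seq_len(ne - length(named))))
    nt <- if (is.null(n_time_points)) 90 else n_time_points
    tls <- sprintf("h%g", seq_len(nt) * 45 / 90)  # half-hour grid
    plys <- c("mitotic_delay", "binuclear", "polylobed", "grape",
              "large", "dynamic", "apoptosis")
    pairs <- list(list(pair = c("incenp", "ranbp3"),
                       layers = c("polylobed", "mitotic_delay"), sign = 1))
    latents <- list(
      list(entity = "lsm14a", layer = "grape",
           onset = max(1, round(2 / 3 * nt))),
      list(entity = "lsm14a", layer = "mitotic_delay",
           onset = max(1, round(0.2 * nt))))
    pairs <- Filter(function(p) all(p$pair %in% genes), pairs)
    latents <- Filter(function(p) p$entity %in% genes, latents)
    synth_spec(layer_names = plys, entity_names = genes, time_labels = tls,
               noise_sd = if (is.null(noise_sd)) 0.05 else noise_sd,
               base_range = c(0.02, 0.25), signal_range = c(0, 0.9),
               penetrance = TRUE,
               planted_correlated_pairs = pairs,
               planted_latent_signals = latents,
               rare_layers = "grape", rare_sparsity = 0.8,
               edge_prob = 0, seed = seed)
  }
}
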