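## Small fixture networks built in code.

make_tiny_network <- function() {
  layered_network(
    layers = "mRNA",
    time_points = c("t1", "t2", "t3"),
    values = list(mRNA = list(a = c(0, 1, 5), b = c(2, 2, 2))),
    intra_edges = data.frame(layer = "mRNA", entity_a = "a",
                             entity_b = "b"))
}

make_two_layer_network <- function() {
  layered_network(
    layers = c("L1", "L2"),
    time_points = c("t1", "t2", "t3", "t4"),
    values = list(
      L1 = list(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(0, NA, 2, 7)),
      L2 = list(a = c(-1, 0, 1, 2), b = c(10, 20, 30, 40))),
    intra_edges = data.frame(layer = "L1", entity_a = c("a", "b"),
                             entity_b = c("b", "c")),
    inter_edges = data.frame(layer_a = "L1", entity_a = "a",
                             layer_b = "L2", entity_b = "b"))
}

## random valid network for property-style tests
random_network <- function(seed, n_layers = 3, n_entities = 6,
                           n_time = 5, missing_frac = 0.1) {
  set.seed(seed)
  lys <- paste0("L", seq_len(n_layers))
  ents <- paste0("e", seq_len(n_entities))
  tls <- paste0("t", seq_len(n_time))
  values <- lapply(lys, function(ly) {
    vs <- lapply(ents, function(e) {
      v <- round(stats::rnorm(n_time, 5, 3), 3)
      v[stats::runif(n_time) < missing_frac] <- NA
      v
    })
    stats::setNames(vs, ents)
  })
  names(values) <- lys
  pairs <- utils::combn(ents, 2)
  keep <- stats::runif(ncol(pairs)) < 0.3
  intra <- if (any(keep)) data.frame(
    layer = sample(lys, sum(keep), replace = TRUE),
    entity_a = pairs[1, keep], entity_b = pairs[2, keep]) else NULL
  layered_network(lys, tls, values, intra_edges = intra)
}

expect_networks_equal <- function(a, b) {
  expect_identical(a$layers, b$layers)
  expect_identical(a$entities, b$entities)
  expect_identical(a$time_points, b$time_points)
  expect_identical(names(a$values), names(b$values))
  for (ly in a$layers) {
    expect_identical(names(a$values[[ly]]), names(b$values[[ly]]))
    for (ent in names(a$values[[ly]]))
      expect_equal(a$values[[ly]][[ent]], b$values[[ly]][[ent]],
                   tolerance = 0)
  }
  expect_equal(a$intra_edges, b$intra_edges)
  expect_equal(a$inter_edges, b$inter_edges)
}
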