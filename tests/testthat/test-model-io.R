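test_that("a minimal TSV file parses into the expected network", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#LAYERS", "mRNA",
               "#TIMEPOINTS", "t1", "t2", "t3",
               "#VALUES",
               "mRNA\ta\t0\t1\t5",
               "mRNA\tb\t2\t2\t2",
               "#EDGES",
               "mRNA\ta\tmRNA\tb"), f)
  net <- read_layered_network(f)
  expect_s3_class(net, "layered_network")
  expect_identical(net$layers, "mRNA")
  expect_length(net$time_points, 3)
  expect_identical(net$entities, c("a", "b"))
  expect_equal(net$values$mRNA$a, c(0, 1, 5))
  expect_equal(nrow(net$intra_edges), 1)
})

test_that("read/write round trips preserve every field, in both dialects", {
  for (seed in 1:5) {
    net <- random_network(seed)
    for (fmt in c("tsv", "json")) {
      f <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_layered_network(net, f, fmt)
      expect_networks_equal(read_layered_network(f), net)
    }
  }
  ## empty edge set and missing values survive the round trip
  net <- layered_network(
    "L", c("t1", "t2"), list(L = list(a = c(NA, 1.25), b = c(3, NA))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_layered_network(net, f)
  back <- read_layered_network(f)
  expect_networks_equal(back, net)
  expect_true(is.na(back$values$L$a[1]))
})

test_that("time-point labels default to t1..tN when the section is absent", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#LAYERS", "L", "#VALUES", "L\ta\t1\t2\t3\t4"), f)
  net <- read_layered_network(f)
  expect_identical(net$time_points, c("t1", "t2", "t3", "t4"))
})

test_that("malformed files are rejected with errors naming the problem", {
  write_net <- function(lines) {
    f <- tempfile(fileext = ".tsv")
    writeLines(lines, f)
    f
  }
  good <- c("#LAYERS", "L1", "L2",
            "#TIMEPOINTS", "t1", "t2", "t3",
            "#VALUES",
            "L1\ta\t1\t2\t3",
            "L1\tb\t4\t5\t6",
            "L2\ta\t7\t8\t9",
            "#EDGES",
            "L1\ta\tL1\tb")
  expect_s3_class(read_layered_network(write_net(good)), "layered_network")
  ## wrong vector length names the entity and the layer
  bad_len <- good; bad_len[9] <- "L1\ta\t1\t2"
  expect_error(read_layered_network(write_net(bad_len)), "'a'.*'L1'|a.*L1")
  ## dangling edge endpoint (b is not on L2)
  bad_edge <- good; bad_edge[13] <- "L2\ta\tL2\tb"
  expect_error(read_layered_network(write_net(bad_edge)), "not present")
  ## undeclared layer in a value row
  bad_layer <- good; bad_layer[11] <- "L3\ta\t7\t8\t9"
  expect_error(read_layered_network(write_net(bad_layer)), "undeclared")
  ## self-edge
  bad_self <- good; bad_self[13] <- "L1\ta\tL1\ta"
  expect_error(read_layered_network(write_net(bad_self)), "self-edge")
  ## file not starting with a section header
  expect_error(read_layered_network(write_net(c("L1", good))),
               "header")
  ## non-numeric value
  bad_num <- good; bad_num[9] <- "L1\ta\t1\tx\t3"
  expect_error(read_layered_network(write_net(bad_num)), "non-numeric")
  ## fuzz: deleting any single #VALUES or #EDGES field breaks the file
  for (i in c(9, 10, 11, 13)) {
    fields <- strsplit(good[i], "\t")[[1]]
    for (j in seq_along(fields)) {
      mutated <- good
      mutated[i] <- paste(fields[-j], collapse = "\t")
      expect_error(read_layered_network(write_net(mutated)))
    }
  }
})

test_that("layer_stats matches a brute-force scan and layers are independent", {
  net <- make_tiny_network()
  st <- layer_stats(net, "mRNA")
  expect_equal(st$min_value, 0)
  expect_equal(st$max_value, 5)
  ## constant layer
  cnet <- layered_network("L", c("t1", "t2"),
                          list(L = list(a = c(2, 2))))
  expect_equal(unlist(layer_stats(cnet, "L")[c("min_value", "max_value")],
                      use.names = FALSE), c(2, 2))
  for (seed in 1:10) {
    net <- random_network(seed)
    for (ly in net$layers) {
      vals <- unlist(net$values[[ly]])
      st <- layer_stats(net, ly)
      expect_equal(st$min_value, min(vals, na.rm = TRUE))
      expect_equal(st$max_value, max(vals, na.rm = TRUE))
    }
  }
  expect_error(layer_stats(net, "nope"), "unknown layer")
  allna <- layered_network("L", "t1", list(L = list(a = NA_real_)))
  expect_error(layer_stats(allna, "L"), "no non-missing")
})

test_that("Pajek export writes the standard format and re-imports isomorphic",
{
  net <- make_two_layer_network()
  f <- withr::local_tempfile(fileext = ".net")
  export_pajek(net, "L1", f)
  lines <- readLines(f)
  expect_identical(lines[1], "*Vertices 3")
  expect_identical(lines[5], "*Edges")
  expect_length(lines, 7)  # header + 3 vertices + *Edges + 2 edges
  skip_if_not_installed("igraph")
  g <- igraph::read_graph(f, format = "pajek")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  ref <- igraph::graph_from_edgelist(
    as.matrix(net$intra_edges[net$intra_edges$layer == "L1",
                              c("entity_a", "entity_b")]),
    directed = FALSE)
  expect_true(igraph::isomorphic(g, ref))
})

test_that("edge-list export writes one labelled pair per line", {
  net <- make_two_layer_network()
  f <- withr::local_tempfile(fileext = ".txt")
  export_edgelist(net, "L1", f)
  expect_identical(readLines(f), c("a b", "b c"))
  ## empty edge set: header-only Pajek, empty edge list
  export_edgelist(net, "L2", f)
  expect_identical(readLines(f), character(0))
  f2 <- withr::local_tempfile(fileext = ".net")
  export_pajek(net, "L2", f2)
  expect_identical(readLines(f2), c("*Vertices 2", "1 \"a\"", "2 \"b\"",
                                    "*Edges"))
  expect_error(export_pajek(net, "nope", f2), "unknown layer")
})

test_that("constructor enforces the structural invariants", {
  expect_error(layered_network(c("L", "L"), "t1",
                               list(L = list(a = 1))),
               "one element per declared layer|duplicate")
  expect_error(layered_network("L", c("t1", "t2"),
                               list(L = list(a = c(1, 2, 3)))),
               "length")
  expect_error(layered_network("L", "t1", list(L = list(a = 1)),
                               intra_edges = data.frame(
                                 layer = "L", entity_a = "a",
                                 entity_b = "a")),
               "self-edge")
  expect_error(layered_network("L", "t1", list(L = list(a = 1)),
                               intra_edges = data.frame(
                                 layer = "L", entity_a = "a",
                                 entity_b = "zz")),
               "not present")
})
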