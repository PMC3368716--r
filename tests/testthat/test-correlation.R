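test_that("pearson_r matches hand-computed and reference values", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -2 * x + 7), -1)
  ## hand computation: cov(x,y)/(sd x * sd y) = 0.8 for this pair
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  ## pairwise-complete deletion drops the NA pair
  expect_equal(pearson_r(c(1, 2, 3, NA, 5), c(2, 4, 6, 1, 10)), 1)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(c(1, 2), c(1, 2)), "fewer than 3")
  expect_error(pearson_r(1:3, 1:4), "equal length")
})

test_that("critical Pearson coefficient comes from exact t-inversion", {
  ## three time points: one degree of freedom, critical r = 0.997
  expect_equal(round(pearson_critical_r(3, 0.05), 3), 0.997)
  ## df = 10, t_crit = 2.228: r = t/sqrt(t^2 + df) = 0.576
  expect_equal(round(pearson_critical_r(12, 0.05), 3), 0.576)
  t_crit <- stats::qt(0.975, 10)
  expect_equal(pearson_critical_r(12, 0.05),
               t_crit / sqrt(t_crit^2 + 10), tolerance = 1e-12)
  ## strictly decreasing in n, increasing as alpha decreases
  ns <- c(3, 5, 10, 30, 100, 1000)
  for (a in c(0.10, 0.05, 0.02, 0.01)) {
    rs <- vapply(ns, pearson_critical_r, numeric(1), alpha = a)
    expect_true(all(diff(rs) < 0))
  }
  for (n in c(3, 10, 50)) {
    rs <- vapply(c(0.10, 0.05, 0.02, 0.01), function(a)
      pearson_critical_r(n, a), numeric(1))
    expect_true(all(diff(rs) > 0))
  }
  ## n large: critical r approaches 0
  expect_lt(pearson_critical_r(100000, 0.05), 0.01)
  expect_error(pearson_critical_r(2, 0.05), ">= 3")
  expect_error(pearson_critical_r(10, 0.03), "alpha")
  expect_silent(pearson_critical_r(10, 0.03, allow_any_alpha = TRUE))
})

test_that("Spearman significance follows the t formula with df = n - 2", {
  s <- spearman_significance(0, 10)
  expect_equal(s$t_statistic, 0)
  expect_equal(s$p_value, 1)
  ## r = 0.5, n = 11: t = 0.5 * 3 / sqrt(0.75)
  s <- spearman_significance(0.5, 11)
  expect_equal(s$t_statistic, 0.5 * 3 / sqrt(0.75), tolerance = 1e-12)
  expect_equal(s$t_statistic, 1.7320508, tolerance = 1e-6)
  expect_equal(s$p_value, 2 * stats::pt(-1.7320508, 9), tolerance = 1e-6)
  ## |r| = 1: p = 0 by convention
  expect_equal(spearman_significance(1, 5)$p_value, 0)
  expect_equal(spearman_significance(-1, 5)$p_value, 0)
  ## independent arithmetic + t-CDF over a grid
  for (r in seq(-0.9, 0.9, by = 0.3)) {
    for (n in c(3, 5, 12, 40)) {
      s <- spearman_significance(r, n)
      t_ref <- r * sqrt(n - 2) / sqrt(1 - r^2)
      expect_equal(s$t_statistic, t_ref, tolerance = 1e-12)
      expect_equal(s$p_value,
                   2 * stats::pt(abs(t_ref), n - 2, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  }
  expect_error(spearman_significance(0.5, 2), ">= 3")
  expect_error(spearman_significance(1.5, 5), "\\[-1, 1\\]")
})

test_that("the two significance routes agree around the critical value", {
  for (n in c(3, 5, 10, 50)) {
    for (a in c(0.10, 0.05, 0.02, 0.01)) {
      rc <- pearson_critical_r(n, a)
      expect_gt(spearman_significance(rc * (1 - 1e-6), n)$p_value, a)
      expect_lt(spearman_significance(min(rc * (1 + 1e-6), 1 - 1e-12),
                                      n)$p_value, a)
    }
  }
})

test_that("spearman_r uses average ranks and survives monotone transforms", {
  x <- c(3, 1, 4, 1, 5, 9, 2)
  y <- c(2, 7, 1, 8, 2, 8, 1)
  expect_equal(spearman_r(x, y),
               unname(stats::cor(x, y, method = "spearman")))
  ## invariance under strictly monotone transforms of either series
  expect_equal(spearman_r(exp(x), y), spearman_r(x, y))
  expect_equal(spearman_r(x, y^3 + 2 * y), spearman_r(x, y))
})

test_that("significant correlations within a layer follow the PMCC rule", {
  ## planted perfect pair is reported positive at alpha = 0.05
  net <- layered_network(
    "L", c("t1", "t2", "t3"),
    list(L = list(a = c(1, 2, 3), b = c(2, 4, 6), c = c(5, 0, 4))))
  recs <- significant_correlations(net, "L", alpha = 0.05)
  ab <- recs[recs$entity_a == "a" & recs$entity_b == "b", ]
  expect_equal(nrow(ab), 1)
  expect_identical(ab$sign, "positive")
  expect_equal(ab$n, 3L)
  ## r = 0.99 at n = 3 is NOT significant: 0.99 < 0.997
  v1 <- c(0, 1, 2)
  ## construct a pair with r just below 0.997
  v2 <- c(0, 1.2, 2)
  stopifnot(abs(stats::cor(v1, v2)) < pearson_critical_r(3, 0.05),
            abs(stats::cor(v1, v2)) > 0.98)
  net2 <- layered_network("L", c("t1", "t2", "t3"),
                          list(L = list(a = v1, b = v2)))
  expect_equal(nrow(significant_correlations(net2, "L", alpha = 0.05)), 0)
  ## ... but it is at alpha = 0.10 (critical 0.988)
  expect_equal(nrow(significant_correlations(net2, "L", alpha = 0.10)), 1)
  ## constant pairs are skipped and counted, not reported as zero
  net3 <- layered_network(
    "L", c("t1", "t2", "t3"),
    list(L = list(a = c(1, 2, 3), b = c(4, 4, 4))))
  recs3 <- significant_correlations(net3, "L")
  expect_equal(nrow(recs3), 0)
  expect_equal(attr(recs3, "n_skipped_constant"), 1L)
  ## short-overlap pairs skipped
  net4 <- layered_network(
    "L", c("t1", "t2", "t3"),
    list(L = list(a = c(1, NA, 3), b = c(2, 4, NA))))
  expect_equal(attr(significant_correlations(net4, "L"),
                    "n_skipped_short"), 1L)
  ## sign filter applied last
  net5 <- layered_network(
    "L", c("t1", "t2", "t3"),
    list(L = list(a = c(1, 2, 3), b = c(2, 4, 6), d = c(3, 2, 1))))
  pos <- significant_correlations(net5, "L", sign_filter = "positive")
  expect_true(all(pos$sign == "positive"))
  neg <- significant_correlations(net5, "L", sign_filter = "negative")
  expect_true(all(neg$sign == "negative"))
  expect_error(significant_correlations(net5, "nope"), "unknown layer")
  expect_error(significant_correlations(net5, "L", alpha = 0.03), "alpha")
})

test_that("records are symmetric in the pair and never include self-pairs", {
  for (seed in 1:5) {
    net <- random_network(seed, n_entities = 8)
    recs <- significant_correlations(net, "L1", alpha = 0.10)
    if (nrow(recs)) {
      expect_true(all(recs$entity_a != recs$entity_b))
      key <- paste(pmin(recs$entity_a, recs$entity_b),
                   pmax(recs$entity_a, recs$entity_b))
      expect_false(any(duplicated(key)))
    }
  }
})

test_that("Spearman route thresholds on the Eq.-1 p-value", {
  set.seed(11)
  n <- 20
  x <- stats::rnorm(n)
  y <- x + stats::rnorm(n, sd = 0.3)
  net <- layered_network("L", paste0("t", 1:n),
                         list(L = list(a = x, b = y,
                                       c = stats::rnorm(n))))
  recs <- significant_correlations(net, "L", method = "spearman",
                                   alpha = 0.01)
  ab <- recs[recs$entity_a == "a" & recs$entity_b == "b", ]
  expect_equal(nrow(ab), 1)
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ab$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(ab$p_value, ct$p.value, tolerance = 1e-10)
})

test_that("recurrent correlations require min_layers and keep per-layer signs",
{
  ## pair significant on layers 1 and 3 of 4 -> recurrent with those layers
  mk <- function(r_layers) {
    vals <- lapply(paste0("L", 1:4), function(ly) {
      if (ly %in% r_layers)
        list(a = c(1, 2, 3), b = c(2, 4, 6), c = c(5, 1, 3))
      else
        list(a = c(1, 5, 2), b = c(4, 1, 6), c = c(2, 2.5, 0))
    })
    names(vals) <- paste0("L", 1:4)
    layered_network(paste0("L", 1:4), c("t1", "t2", "t3"), vals)
  }
  net <- mk(c("L1", "L3"))
  rc <- recurrent_correlations(net, alpha = 0.05)
  ab <- rc[rc$entity_a == "a" & rc$entity_b == "b", ]
  expect_equal(nrow(ab), 1)
  expect_identical(ab$layers, "L1,L3")
  expect_true(ab$consistent_sign)
  ## significant on one layer only -> absent
  rc1 <- recurrent_correlations(mk("L2"), alpha = 0.05)
  expect_false(any(rc1$entity_a == "a" & rc1$entity_b == "b"))
  expect_error(recurrent_correlations(net, min_layers = 1), "at least 2")
})

test_that("mixed-sign recurrence is reported and sign filters drop it", {
  net <- layered_network(
    c("A", "B"), c("t1", "t2", "t3"),
    list(A = list(x = c(1, 2, 3), y = c(2, 4, 6)),
         B = list(x = c(1, 2, 3), y = c(6, 4, 2))))
  rc <- recurrent_correlations(net)
  expect_equal(nrow(rc), 1)
  expect_identical(rc$signs, "positive,negative")
  expect_false(rc$consistent_sign)
  ## a pair with any negative record is dropped by the positive filter
  expect_equal(nrow(recurrent_correlations(net, sign_filter = "positive")),
               0)
  expect_equal(nrow(recurrent_correlations(net, sign_filter = "negative")),
               0)
})
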