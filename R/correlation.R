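## Significance levels offered for correlation display.  Arbitrary levels
## are deliberately not the default path; see `allow_any_alpha`.
ALLOWED_ALPHAS <- c(0.10, 0.05, 0.02, 0.01)

check_alpha <- function(alpha, allow_any = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must be a number in (0, 1)", call. = FALSE)
  if (!allow_any && !any(abs(alpha - ALLOWED_ALPHAS) < 1e-12))
    stop("alpha must be one of ",
         paste(format(ALLOWED_ALPHAS), collapse = ", "),
         " (use allow_any_alpha = TRUE for other levels)", call. = FALSE)
  alpha
}

## pairwise-complete deletion; returns NULL when fewer than 3 pairs remain
complete_pairs <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  if (sum(ok) < 3) return(NULL)
  list(x = x[ok], y = y[ok])
}

#' Pearson product-moment correlation of two time series
#'
#' Pairs with a missing value in either series are dropped first
#' (pairwise-complete deletion).  A constant series has no defined
#' correlation and is an error, never a silent zero.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs
#'   must remain after deletion.
#' @return the correlation coefficient, in \eqn{[-1, 1]}.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  p <- complete_pairs(x, y)
  if (is.null(p))
    stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  r <- stats::cor(p$x, p$y)
  max(-1, min(1, r))
}

#' Spearman rank correlation of two time series
#'
#' Pearson correlation of the average ranks (ties get average ranks, with
#' no further tie correction).  Invariant under strictly monotone
#' transforms of either series.
#'
#' @inheritParams pearson_r
#' @return the rank correlation coefficient, in \eqn{[-1, 1]}.
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  p <- complete_pairs(x, y)
  if (is.null(p))
    stop("fewer than 3 complete pairs", call. = FALSE)
  pearson_r(rank(p$x), rank(p$y))
}

#' Minimal significant Pearson coefficient (PMCC critical value)
#'
#' The smallest \eqn{|r|} that is significant two-sided at level
#' \code{alpha} for a series of \code{n} points, i.e. the critical value of
#' the Pearson product-moment correlation coefficient at \eqn{df = n - 2}.
#' Computed by exact inversion of the t test for a correlation,
#' \deqn{r_{crit} = t_{crit} / \sqrt{t_{crit}^2 + df},}
#' where \eqn{t_{crit}} is the two-sided Student-t critical value — no
#' lookup table.  At \code{n = 3} (one degree of freedom) and
#' \code{alpha = 0.05} this gives 0.997: with only three time points a
#' correlation must exceed 0.997 in magnitude to reach p < 0.05.
#'
#' @param n number of points in the series (\code{n >= 3}).
#' @param alpha two-sided significance level; one of 0.10, 0.05, 0.02, 0.01
#'   unless \code{allow_any_alpha}.
#' @param allow_any_alpha accept any level in (0, 1).
#' @return the critical \eqn{|r|}, strictly decreasing in \code{n} and
#'   increasing as \code{alpha} decreases.
#' @examples
#' pearson_critical_r(3, 0.05)   # 0.997
#' pearson_critical_r(12, 0.05)  # 0.576
#' @export
pearson_critical_r <- function(n, alpha = 0.05, allow_any_alpha = FALSE) {
  if (!is.numeric(n) || length(n) != 1 || n < 3 || n != round(n))
    stop("n must be an integer >= 3", call. = FALSE)
  check_alpha(alpha, allow_any_alpha)
  df <- n - 2
  t_crit <- stats::qt(1 - alpha / 2, df)
  t_crit / sqrt(t_crit^2 + df)
}

#' Significance of a Spearman rank correlation
#'
#' The statistic
#' \deqn{t = r \sqrt{n - 2} / \sqrt{1 - r^2}}
#' has an approximate Student's t distribution with \eqn{n - 2} degrees of
#' freedom under the null hypothesis of no association, where \eqn{n} is
#' the number of time points.  The p-value is two-sided; \eqn{|r| = 1}
#' gives \eqn{p = 0} by convention.
#'
#' @param r rank correlation coefficient in \eqn{[-1, 1]}.
#' @param n number of points (\code{n >= 3}).
#' @return list with \code{t_statistic} and \code{p_value}.
#' @examples
#' spearman_significance(0.5, 11)  # t = 1.732..., p ~ 0.117
#' @export
spearman_significance <- function(r, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 3 || n != round(n))
    stop("n must be an integer >= 3", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || abs(r) > 1)
    stop("r must be a number in [-1, 1]", call. = FALSE)
  if (abs(r) == 1)
    return(list(t_statistic = sign(r) * Inf, p_value = 0))
  df <- n - 2
  t <- r * sqrt(df) / sqrt(1 - r^2)
  list(t_statistic = t, p_value = 2 * stats::pt(-abs(t), df))
}

#' All significant correlations within one layer
#'
#' Tests every unordered pair of entities on the layer.  For the Pearson
#' method a pair is significant when \eqn{|r|} reaches the PMCC critical
#' value for its (post-deletion) sample size; for the Spearman method when
#' the two-sided p-value from \code{\link{spearman_significance}} is at
#' most \code{alpha}.  Pairs whose post-deletion overlap is under 3 time
#' points, and pairs where either series is constant, are skipped and
#' counted.  Note the samples of a time series are not independent: these
#' tests are a first rough indication of similarity, not a calibrated
#' inference, and no multiple-testing correction is applied by default
#' (\code{bh_adjust} offers Benjamini-Hochberg for the Spearman p-values).
#'
#' @param net a \code{\link{layered_network}}.
#' @param layer layer name.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param alpha significance level, one of 0.10, 0.05, 0.02, 0.01 (default
#'   0.05) unless \code{allow_any_alpha}.
#' @param sign_filter keep \code{"all"} significant pairs (default), or
#'   only \code{"positive"} / \code{"negative"} ones; applied last.
#' @param allow_any_alpha accept any level in (0, 1).
#' @param bh_adjust apply Benjamini-Hochberg adjustment to the Spearman
#'   p-values before thresholding (off by default).
#' @return data frame of significant records with columns \code{layer},
#'   \code{entity_a}, \code{entity_b}, \code{method}, \code{r}, \code{n},
#'   \code{alpha}, \code{significant}, \code{sign}; attributes
#'   \code{n_tested}, \code{n_skipped_constant}, \code{n_skipped_short}
#'   count the pairs examined and skipped.
#' @export
significant_correlations <- function(net, layer,
                                     method = c("pearson", "spearman"),
                                     alpha = 0.05,
                                     sign_filter = c("all", "positive",
                                                     "negative"),
                                     allow_any_alpha = FALSE,
                                     bh_adjust = FALSE) {
  check_layer(net, layer)
  method <- match.arg(method)
  sign_filter <- match.arg(sign_filter)
  check_alpha(alpha, allow_any_alpha)
  m <- layer_values(net, layer)
  ents <- rownames(m)
  rec <- list()
  skipped_const <- 0L; skipped_short <- 0L; tested <- 0L
  if (length(ents) >= 2) {
    for (i in seq_len(length(ents) - 1)) {
      for (j in (i + 1):length(ents)) {
        p <- complete_pairs(m[i, ], m[j, ])
        if (is.null(p)) { skipped_short <- skipped_short + 1L; next }
        if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0) {
          skipped_const <- skipped_const + 1L; next
        }
        tested <- tested + 1L
        n <- length(p$x)
        if (method == "pearson") {
          r <- pearson_r(p$x, p$y)
          sig <- abs(r) >= pearson_critical_r(n, alpha,
                                              allow_any_alpha = TRUE)
          pval <- NA_real_
        } else {
          r <- spearman_r(p$x, p$y)
          pval <- spearman_significance(r, n)$p_value
          sig <- NA  # resolved after optional BH adjustment
        }
        rec[[length(rec) + 1]] <- data.frame(
          layer = layer, entity_a = ents[i], entity_b = ents[j],
          method = method, r = r, n = n, alpha = alpha,
          p_value = pval, significant = sig,
          sign = if (r >= 0) "positive" else "negative",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(layer = character(0), entity_a = character(0),
               entity_b = character(0), method = character(0),
               r = numeric(0), n = integer(0), alpha = numeric(0),
               p_value = numeric(0), significant = logical(0),
               sign = character(0), stringsAsFactors = FALSE)
  if (method == "spearman" && nrow(out)) {
    p <- if (bh_adjust) stats::p.adjust(out$p_value, "BH") else out$p_value
    out$significant <- p <= alpha
  }
  out <- out[which(out$significant), , drop = FALSE]
  if (sign_filter != "all")
    out <- out[out$sign == sign_filter, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_tested = tested, n_skipped_constant = skipped_const,
            n_skipped_short = skipped_short)
}

#' Recurrent cross-layer correlations
#'
#' An entity pair is recurrent when its correlation is significant on at
#' least \code{min_layers} layers.  The per-layer signs are retained and
#' may differ across layers — mixed-sign recurrence (positive on one
#' measurement level, negative on another) is biologically meaningful and
#' is reported, not suppressed; \code{consistent_sign} flags whether all
#' counted layers agree.
#'
#' @inheritParams significant_correlations
#' @param min_layers minimal number of layers a pair must be significant
#'   on (\code{>= 2}).
#' @param sign_filter \code{"all"} (default); \code{"positive"} /
#'   \code{"negative"} drop any pair whose significant records include the
#'   other sign on any counted layer.
#' @return data frame with one row per recurrent pair: \code{entity_a},
#'   \code{entity_b}, \code{n_layers}, \code{layers} and \code{signs}
#'   (comma-separated, in layer order), \code{consistent_sign}.
#' @export
recurrent_correlations <- function(net, method = c("pearson", "spearman"),
                                   alpha = 0.05, min_layers = 2,
                                   sign_filter = c("all", "positive",
                                                   "negative"),
                                   allow_any_alpha = FALSE) {
  method <- match.arg(method)
  sign_filter <- match.arg(sign_filter)
  if (!is.numeric(min_layers) || length(min_layers) != 1 || min_layers < 2)
    stop("min_layers must be at least 2", call. = FALSE)
  recs <- do.call(rbind, lapply(net$layers, function(ly)
    significant_correlations(net, ly, method = method, alpha = alpha,
                             allow_any_alpha = allow_any_alpha)))
  empty <- data.frame(entity_a = character(0), entity_b = character(0),
                      n_layers = integer(0), layers = character(0),
                      signs = character(0), consistent_sign = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(recs) || nrow(recs) == 0) return(empty)
  key <- paste(recs$entity_a, recs$entity_b, sep = "\r")
  out <- do.call(rbind, lapply(split(recs, key), function(g) {
    g <- g[order(match(g$layer, net$layers)), , drop = FALSE]
    data.frame(entity_a = g$entity_a[1], entity_b = g$entity_b[1],
               n_layers = nrow(g),
               layers = paste(g$layer, collapse = ","),
               signs = paste(g$sign, collapse = ","),
               consistent_sign = length(unique(g$sign)) == 1,
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_layers >= min_layers, , drop = FALSE]
  if (sign_filter != "all") {
    keep <- vapply(strsplit(out$signs, ","),
                   function(s) all(s == sign_filter), logical(1))
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$entity_a, out$entity_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
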