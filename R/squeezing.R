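#' Fit the upper edge of a log2 fold-change scatter
#'
#' The scatter of permeation at two elution windows has an upper edge close
#' to the identity line, formed by species whose passage is unchanged between
#' the windows (free passage, or complete retention). The edge is found in
#' three stages: (1) an ordinary least-squares line through all points;
#' (2) points are projected onto that line, the projection range is split
#' into `bin_count` equal-width bins, and within each bin the `top_fraction`
#' of points by signed perpendicular offset above the stage-1 line is kept
#' (at least one per non-empty bin; ties at the cutoff are all kept);
#' (3) an OLS refit through the kept points gives the edge.
#'
#' Convention: pass `x` = the later/reference condition and `y` = the earlier
#' one, so that squeezing species (which elute more at the later window) fall
#' below the edge and [squeezing_scores()] is positive for them.
#'
#' @param x,y named log2 fold-change vectors (e.g. from [log2_scatter()]).
#' @param top_fraction fraction kept per bin, in (0, 0.5]; default 0.04.
#' @param bin_count number of bins along the stage-1 line (>= 2).
#' @return An object of class `edge_line`: `slope`, `intercept`,
#'   `bin_count`, `top_fraction`, `support_ids` (proteins in the refit).
#' @export
fit_edge <- function(x, y, top_fraction = 0.04, bin_count = 20) {
  if (top_fraction <= 0 || top_fraction > 0.5)
    stop_invalid("`top_fraction` must be in (0, 0.5]")
  if (bin_count < 2) stop_invalid("`bin_count` must be >= 2")
  ok <- is.finite(x) & is.finite(y)
  xs <- x[ok]; ys <- y[ok]
  if (length(xs) < 10 * bin_count)
    stop_invalid("insufficient data: need at least ", 10 * bin_count,
                 " finite points, have ", length(xs))
  if (var(xs) < .Machine$double.eps)
    stop_invalid("degenerate fit: x values are collinear vertical")
  ols <- function(px, py) {
    b <- cov(px, py) / var(px)
    c(intercept = mean(py) - b * mean(px), slope = b)
  }
  l1 <- ols(xs, ys)
  # projection parameter along the stage-1 line and signed offset above it
  denom <- 1 + l1["slope"]^2
  t_par <- (xs + l1["slope"] * (ys - l1["intercept"])) / denom
  offset <- (ys - (l1["intercept"] + l1["slope"] * xs)) / sqrt(denom)
  breaks <- seq(min(t_par), max(t_par), length.out = bin_count + 1)
  bin <- findInterval(t_par, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  keep <- logical(length(xs))
  for (bi in unique(bin)) {
    idx <- which(bin == bi)
    k <- max(1L, ceiling(top_fraction * length(idx)))
    thr <- sort(offset[idx], decreasing = TRUE)[k]
    keep[idx[offset[idx] >= thr]] <- TRUE
  }
  l3 <- ols(xs[keep], ys[keep])
  structure(list(slope = unname(l3["slope"]), intercept = unname(l3["intercept"]),
                 bin_count = bin_count, top_fraction = top_fraction,
                 support_ids = names(xs)[keep]),
            class = "edge_line")
}

#' @export
print.edge_line <- function(x, ...) {
  cat(sprintf("edge_line: y = %.4f x + %.4f (support n = %d, top %.1f%% in %d bins)\n",
              x$slope, x$intercept, length(x$support_ids),
              100 * x$top_fraction, x$bin_count))
  invisible(x)
}

#' Squeezing scores: orthogonal distance below the edge
#'
#' Each protein's squeezing score is its perpendicular distance from the
#' fitted upper edge, signed positive below the line -- i.e. positive for
#' proteins retained at the earlier window relative to what the edge
#' predicts, the signature of slow, deformation-limited pore passage.
#' For edge `y = a + b x` the score is `(a + b*x - y) / sqrt(1 + b^2)`.
#'
#' @param x,y the scatter coordinates used for the fit (see [fit_edge()]).
#' @param edge an `edge_line`.
#' @return A [score_vector()] oriented "higher = more squeezing"; proteins
#'   with a missing coordinate get a missing score.
#' @export
squeezing_scores <- function(x, y, edge) {
  stopifnot(inherits(edge, "edge_line"))
  if (!is.finite(edge$slope) || !is.finite(edge$intercept))
    stop_invalid("edge line is not finite")
  s <- (edge$intercept + edge$slope * x - y) / sqrt(1 + edge$slope^2)
  s[!is.finite(x) | !is.finite(y)] <- NA_real_
  ids <- names(x) %||% as.character(seq_along(x))
  score_vector(ids, unname(s), orientation = "higher = more squeezing / more LLPS-like")
}

#' Squeezing scores from a fold-change table
#'
#' Convenience wrapper: builds the log2 scatter of the later elution window
#' (x) against the earlier one (y), fits the upper edge, and scores every
#' protein.
#'
#' @param qt a normalized [quant_table()].
#' @param cond_t1,cond_t2 condition names of the earlier and later windows.
#' @inheritParams fit_edge
#' @return list with elements `edge` ([fit_edge()]) and `scores`
#'   ([squeezing_scores()]).
#' @export
squeezing_score_table <- function(qt, cond_t1, cond_t2,
                                  top_fraction = 0.04, bin_count = 20) {
  sc <- log2_scatter(qt, cond_x = cond_t2, cond_y = cond_t1)
  edge <- fit_edge(sc$x, sc$y, top_fraction = top_fraction, bin_count = bin_count)
  list(edge = edge, scores = squeezing_scores(sc$x, sc$y, edge))
}
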