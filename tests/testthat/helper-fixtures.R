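# Shared fixtures and independent oracles, built in code at test time.

# Hand-specified truth rows covering all four classes.
toy_truth <- function() {
  df <- data.frame(
    species_id = c("free1", "cplx1", "cond1", "cond_core", "mem1"),
    class = c("free", "complex", "condensate", "condensate", "membrane_organelle"),
    d0 = c(5, 40, 60, 60, 800),
    d_mono = c(5, 5, 5, 5, 5),
    c_ratio = c(NA, NA, 1.5, 1.5, NA),
    phi_core = c(NA, NA, 0, 1, NA),
    lam = c(0, 0, 0.8, 0.8, 0),
    abundance = 1,
    stringsAsFactors = FALSE)
  class(df) <- c("species_truth", "data.frame")
  df
}

# Exhaustive Mann-Whitney pair-counting AUC: P(pos > neg) + 0.5 P(equal).
auc_paircount <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Independent re-implementation of the edge-fit binning rule (naive loops,
# lm() fits) used as the oracle for fit_edge.
fit_edge_naive <- function(x, y, top_fraction = 0.04, bin_count = 20) {
  ok <- is.finite(x) & is.finite(y)
  xs <- x[ok]; ys <- y[ok]
  f1 <- lm(ys ~ xs)
  a1 <- coef(f1)[1]; b1 <- coef(f1)[2]
  t_par <- (xs + b1 * (ys - a1)) / (1 + b1^2)
  off <- (ys - (a1 + b1 * xs)) / sqrt(1 + b1^2)
  lo <- min(t_par); width <- (max(t_par) - lo) / bin_count
  bin <- pmin(bin_count, pmax(1L, floor((t_par - lo) / width) + 1L))
  keep <- logical(length(xs))
  for (bi in seq_len(bin_count)) {
    idx <- which(bin == bi)
    if (!length(idx)) next
    k <- max(1L, ceiling(top_fraction * length(idx)))
    thr <- sort(off[idx], decreasing = TRUE)[k]
    keep[idx[off[idx] >= thr]] <- TRUE
  }
  f3 <- lm(ys[keep] ~ xs[keep])
  list(intercept = unname(coef(f3)[1]), slope = unname(coef(f3)[2]),
       support_ids = names(xs)[keep])
}

# Points on a planted edge y = slope*x + intercept, with 90% of them
# displaced strictly downward.
planted_edge_points <- function(n = 2000, slope = 0.8, intercept = -0.1,
                                seed = 1) {
  set.seed(seed)
  x <- runif(n, -6, 0)
  down <- runif(n) < 0.9
  y <- slope * x + intercept - down * (abs(rnorm(n, 0, 0.6)) + 0.02)
  names(x) <- names(y) <- sprintf("p%04d", seq_len(n))
  list(x = x, y = y, on_edge = !down)
}

# Synthetic sedimentation experiment: mitochondria-like species shift to the
# bottom fraction, the rest of the proteome does not.
sedimentation_table <- function(n = 600, seed = 4) {
  set.seed(seed)
  is_mito <- seq_len(n) <= n * 0.2
  ids <- sprintf("s%04d", seq_len(n))
  top <- ifelse(is_mito, 0.35, 1) * 2^rnorm(n, 0, 0.2)
  bottom <- ifelse(is_mito, 1.65, 1) * 2^rnorm(n, 0, 0.2)
  values <- cbind("sed|top" = top, "sed|bottom" = bottom)
  rownames(values) <- ids
  qt <- quant_table(values, data.frame(condition = colnames(values),
                                       experiment = "sed",
                                       stringsAsFactors = FALSE))
  list(qt = qt, mito_ids = ids[is_mito])
}

# Default-conditions synthetic run without the classifier stage (the
# workhorse of the planted-truth checks). Cached per session.
default_run <- local({
  cache <- NULL
  function(seed = 7) {
    if (is.null(cache)) {
      cfg <- pipeline_config(seed = seed, classify = FALSE)
      cache <<- suppressMessages(run_pipeline(cfg, quiet = TRUE))
    }
    cache
  }
})
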