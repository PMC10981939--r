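test_that("fit_edge recovers exact and planted edges", {
  # points exactly on y = x
  x <- seq(-5, 0, length.out = 300); names(x) <- sprintf("p%03d", 1:300)
  e <- fit_edge(x, x, bin_count = 10)
  expect_equal(e$slope, 1, tolerance = 1e-9)
  expect_equal(e$intercept, 0, tolerance = 1e-9)

  # planted edge with strictly-downward displacement: the on-edge points
  # form the upper envelope and are recovered
  pts <- planted_edge_points(seed = 5)
  e2 <- fit_edge(pts$x, pts$y)
  expect_lt(abs(e2$slope - 0.8), 0.05)
  expect_lt(abs(e2$intercept - (-0.1)), 0.05)
  # support points sit on (or at) the edge
  expect_true(all(e2$support_ids %in% names(pts$x)))

  expect_error(fit_edge(x[1:50], x[1:50], bin_count = 20), "insufficient")
  xc <- rep(1, 300); names(xc) <- names(x)
  expect_error(fit_edge(xc, x), "degenerate")
})

test_that("fit_edge agrees with an independent re-implementation of the rule", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 500
    x <- rnorm(n); y <- 0.9 * x - abs(rnorm(n))
    names(x) <- names(y) <- sprintf("p%04d", seq_len(n))
    for (tf in c(0.04, 0.2, 0.5)) {
      got <- fit_edge(x, y, top_fraction = tf, bin_count = 12)
      ref <- fit_edge_naive(x, y, top_fraction = tf, bin_count = 12)
      expect_setequal(got$support_ids, ref$support_ids)
      expect_equal(got$slope, ref$slope, tolerance = 1e-9)
      expect_equal(got$intercept, ref$intercept, tolerance = 1e-9)
    }
  }
})

test_that("squeezing scores equal the closed-form point-line distance", {
  edge <- structure(list(slope = 1, intercept = 0), class = "edge_line")
  # point on the line scores 0
  expect_equal(unname(squeezing_scores(c(a = 1), c(a = 1), edge)$values), 0)
  # |x - y| / sqrt(2) with the below-line sign
  s <- squeezing_scores(c(a = 1), c(a = 1 - 2 * sqrt(2)), edge)
  expect_equal(unname(s$values), 2)
  # random instances against the formula |b*x - y + a| / sqrt(b^2 + 1)
  set.seed(30)
  for (i in 1:20) {
    b <- rnorm(1); a <- rnorm(1)
    x <- rnorm(15); y <- rnorm(15)
    names(x) <- names(y) <- sprintf("p%02d", 1:15)
    e <- structure(list(slope = b, intercept = a), class = "edge_line")
    got <- squeezing_scores(x, y, e)$values
    expect_equal(unname(got), (b * x - y + a) / sqrt(b^2 + 1),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # missing coordinates give missing scores
  sm <- squeezing_scores(c(a = 1, b = NA), c(a = 1, b = 2), edge)
  expect_true(is.na(sm$values["b"]))
  expect_match(sm$orientation, "more squeezing")
})

test_that("edge and scores are translation-equivariant", {
  pts <- planted_edge_points(seed = 6)
  e0 <- fit_edge(pts$x, pts$y)
  e1 <- fit_edge(pts$x, pts$y + 2.5)
  expect_equal(e1$slope, e0$slope, tolerance = 1e-9)
  expect_equal(e1$intercept, e0$intercept + 2.5, tolerance = 1e-9)
  s0 <- squeezing_scores(pts$x, pts$y, e0)$values
  s1 <- squeezing_scores(pts$x, pts$y + 2.5, e1)$values
  expect_equal(s1, s0, tolerance = 1e-9)
})

test_that("support points of the refit lie on the edge up to fit residuals", {
  pts <- planted_edge_points(seed = 7)
  e <- fit_edge(pts$x, pts$y)
  s <- squeezing_scores(pts$x, pts$y, e)$values
  sup <- s[e$support_ids]
  # the refit is OLS through the support: their residuals average to zero
  expect_lt(abs(mean(sup)), 1e-9)
  # and the support hugs the edge: the bulk scores within the residual SD
  # (single kept points in sparse projection bins may deviate further)
  expect_gte(mean(abs(sup) <= 2 * sd(sup)), 0.9)
  expect_lte(median(sup), sd(sup))
})

test_that("noise-free simulator scores rank deformable species by retention", {
  tr <- generate_proteome(600, seed = 15)
  qt <- normalize_q95(cbind_quant(
    simulate_elution(tr, elution_config(d_pore = 30)),
    simulate_elution(tr, elution_config(d_pore = 30, replicate = 2L))))
  sq <- squeezing_score_table(qt, "filt30|T1", "filt30|T2")
  s <- sq$scores$values
  free <- tr$species_id[tr$class == "free"]
  cond <- tr$species_id[tr$class == "condensate"]
  # free species sit near the edge; the per-bin support rule keeps one point
  # per sparse middle bin, so the refit can tilt by a small offset
  expect_lt(max(abs(s[free])), 0.35)
  # squeezing condensates score positive, well above the free cluster
  squeezers <- cond[s[cond] > 0.5]
  expect_gt(length(squeezers), 0)
  expect_gt(min(s[squeezers]), max(s[free]))
  expect_gt(median(s[squeezers]), 2)
})
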