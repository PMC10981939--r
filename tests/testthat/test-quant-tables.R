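test_that("quant tables round-trip through the TSV dialect bit-exactly", {
  tr <- generate_proteome(60, seed = 2)
  qt <- add_measurement_noise(simulate_elution(tr, elution_config(d_pore = 30)),
                              noise_config(0.2, 0.1, seed = 3))
  qt$values[3, 1] <- NA   # a missing measurement
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(qt, p1, p2)
  back <- read_quant_table(p1, p2)
  expect_identical(back$values, qt$values)
  expect_true(is.na(back$values[3, 1]))
  expect_equal(back$conditions, qt$conditions)

  # unknown metadata columns survive
  qt2 <- qt; qt2$conditions$note <- "extra"
  write_quant_table(qt2, p1, p2)
  expect_equal(read_quant_table(p1, p2)$conditions$note, rep("extra", 2))
})

test_that("malformed tables are rejected with informative errors", {
  v <- matrix(1, 2, 1, dimnames = list(c("a", "a"), "e|x"))
  meta <- data.frame(condition = "e|x", experiment = "e")
  expect_error(quant_table(v, meta), "duplicate protein")
  v2 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("e|x", "e|y")))
  expect_error(quant_table(v2, meta), "e\\|y")   # names the missing condition
  v3 <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a", "b"), "e|x"))
  expect_error(quant_table(v3, meta), "nonnegative")
})

test_that("q95 normalization matches a sort-based quantile oracle", {
  # constant table: everything becomes 1
  v <- matrix(2, 10, 2, dimnames = list(sprintf("p%d", 1:10), c("e|a", "e|b")))
  qt <- quant_table(v, data.frame(condition = c("e|a", "e|b"), experiment = "e"))
  expect_equal(unname(normalize_q95(qt)$values), matrix(1, 10, 2))

  # values 1..100: brute-force interpolated quantile on the sorted list
  v <- matrix(as.numeric(1:100), 100, 1,
              dimnames = list(sprintf("p%03d", 1:100), "e|a"))
  qt <- quant_table(v, data.frame(condition = "e|a", experiment = "e"))
  s <- sort(as.vector(v))
  h <- (length(s) - 1) * 0.95 + 1
  oracle_q <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  norm <- normalize_q95(qt)
  expect_equal(unname(norm$values), unname(v) / oracle_q, tolerance = 1e-12)
  # pooled 0.95 quantile is 1 afterwards
  expect_equal(quantile(norm$values, 0.95, names = FALSE), 1, tolerance = 1e-12)

  # idempotence contract: second call errors; renormalizing a flag-reset copy
  # changes nothing
  expect_error(normalize_q95(norm), "already normalized")
  copy <- norm; copy$normalized <- FALSE
  expect_equal(normalize_q95(copy)$values, norm$values, tolerance = 1e-12)

  # degenerate experiment
  v0 <- matrix(0, 5, 1, dimnames = list(sprintf("p%d", 1:5), "e|a"))
  qt0 <- quant_table(v0, data.frame(condition = "e|a", experiment = "e"))
  expect_error(normalize_q95(qt0), "degenerate")
})

test_that("normalization is scale-equivariant per experiment", {
  tr <- generate_proteome(150, seed = 9)
  qt <- add_measurement_noise(
    cbind_quant(simulate_elution(tr, elution_config(d_pore = 30)),
                simulate_elution(tr, elution_config(d_pore = 100))),
    noise_config(0.2, 0.1, seed = 10))
  scaled <- qt
  cols30 <- scaled$conditions$experiment == "filt30"
  scaled$values[, cols30] <- scaled$values[, cols30] * 7.3
  expect_equal(normalize_q95(scaled)$values, normalize_q95(qt)$values,
               tolerance = 1e-9)
})

test_that("condition ratios are antisymmetric log2 ratios", {
  v <- matrix(c(4, 2, 0, 1, 2, 1), 3, 2,
              dimnames = list(c("a", "b", "c"), c("e|x", "e|y")))
  qt <- quant_table(v, data.frame(condition = c("e|x", "e|y"), experiment = "e"))
  r <- condition_ratio(qt, "e|x", "e|y")
  expect_equal(unname(r$values[c("a", "b")]), c(2, 0))
  expect_match(r$orientation, "e\\|x")
  # antisymmetry where both defined
  r2 <- suppressWarnings(condition_ratio(qt, "e|y", "e|x"))
  expect_equal(r$values["a"], -r2$values["a"])
  # zero denominator: NA with a counting warning
  qt$values["c", "e|y"] <- 0
  expect_warning(r3 <- condition_ratio(qt, "e|x", "e|y"), "1 zero denominator")
  expect_true(is.na(r3$values["c"]))
})

test_that("sedimentation ratios recall mitochondria-like species", {
  sed <- sedimentation_table()
  r <- condition_ratio(sed$qt, "sed|bottom", "sed|top")
  auc <- roc_auc(r, sed$mito_ids)$auc
  expect_gt(auc, 0.9)
})

test_that("replicate matching pairs correlated columns only", {
  tr <- generate_proteome(1000, seed = 12)
  t1 <- simulate_elution(tr, elution_config(d_pore = 30, replicate = 1L))
  t2 <- simulate_elution(tr, elution_config(d_pore = 30, replicate = 2L))
  qt <- add_measurement_noise(cbind_quant(t1, t2), noise_config(0.2, 0.1, seed = 13))
  pairs <- match_replicates(qt)
  # T1-with-T1 and T2-with-T2, never a column with itself
  expect_length(pairs, 2)
  keys <- vapply(pairs, function(p) p$key, "")
  expect_false(any(vapply(pairs, function(p) identical(p$a, p$b), TRUE)))
  expect_true(all(vapply(pairs, function(p) p$r, 0) > 0.8))

  # two identical columns: r = 1, matched
  v <- matrix(rep(2^rnorm(50), 2), 50, 2,
              dimnames = list(sprintf("p%d", 1:50), c("e|a", "e|a2")))
  m <- data.frame(condition = c("e|a", "e|a2"), experiment = "e",
                  pore_nm = 30, dilution = 1, window_start = 0, window_end = 1)
  ident <- match_replicates(quant_table(v, m))
  expect_length(ident, 1)
  expect_equal(ident[[1]]$r, 1)

  # independent noise columns of length 1000 are (essentially) never matched
  set.seed(14)
  v2 <- matrix(2^rnorm(2000), 1000, 2,
               dimnames = list(sprintf("p%04d", 1:1000), c("e|a", "e|b")))
  m2 <- data.frame(condition = c("e|a", "e|b"), experiment = "e",
                   pore_nm = 30, dilution = 1, window_start = 0, window_end = 1)
  expect_length(match_replicates(quant_table(v2, m2)), 0)
})
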