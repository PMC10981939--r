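test_that("generate_proteome honors counts, fractions and determinism", {
  expect_equal(nrow(generate_proteome(0)), 0L)
  expect_error(generate_proteome(10, c(free = 0.6, condensate = 0.5)),
               "sum to 1")
  expect_error(generate_proteome(-1), "nonnegative")

  n <- 4000
  tr <- generate_proteome(n, c(free = 0.5, condensate = 0.5), seed = 11)
  n_cond <- sum(tr$class == "condensate")
  expect_lt(abs(n_cond - n * 0.5), 3 * sqrt(n * 0.25))

  tr2 <- generate_proteome(n, c(free = 0.5, condensate = 0.5), seed = 11)
  expect_identical(tr, tr2)

  # class invariants
  expect_true(all(tr$d0 >= tr$d_mono))
  expect_true(all(tr$d0[tr$class == "free"] == tr$d_mono[tr$class == "free"]))
  expect_true(all(tr$lam[tr$class != "condensate"] == 0))
  expect_true(all(tr$lam[tr$class == "condensate"] > 0))
})

test_that("effective_diameter follows dissolution physics", {
  tt <- toy_truth()
  # free species: unchanged at any dilution
  expect_equal(effective_diameter(tt[1, ], 4), tt$d0[1])
  # rigid classes: unchanged
  expect_equal(effective_diameter(tt[c(2, 5), ], 8), tt$d0[c(2, 5)])
  # solid core phi_core = 1: no dissolution even at 8x
  expect_equal(effective_diameter(tt[4, ], 8), tt$d0[4])
  # analytic cube-root scaling, c_ratio = 2, phi_core = 0
  cond <- tt[3, ]; cond$c_ratio <- 2; cond$phi_core <- 0
  for (f in c(1, 1.2, 1.5, 1.9)) {
    phi_f <- max(0, 1 - f / 2); phi_1 <- 0.5
    expected <- max(cond$d_mono, cond$d0 * (phi_f / phi_1)^(1 / 3))
    expect_equal(effective_diameter(cond, f), expected, tolerance = 1e-12)
  }
  # fully dissolved: monomer diameter
  expect_equal(effective_diameter(cond, 2), cond$d_mono)
  expect_error(effective_diameter(tt, 0.9), ">= 1")
})

test_that("simulate_elution handles the trivial passage regimes", {
  tt <- toy_truth()
  cfg <- elution_config(d_pore = 30, windows = list(T1 = c(0, 0.25),
                                                    T2 = c(0.25, 1)))
  qt <- simulate_elution(tt, cfg)
  # free species passes like solvent
  expect_equal(unname(qt$values["free1", ]), c(1, 1))
  # membrane organelle with d_eff = 10 * d_pore stays at the leak floor
  mem <- tt[5, ]; mem$d0 <- 300
  qm <- simulate_elution(mem, elution_config(d_pore = 30, leak = 0.02))
  expect_equal(unname(qm$values[1, ]), c(0.02, 0.02))
  # all outputs within [0, 1]
  expect_true(all(qt$values >= 0 & qt$values <= 1))
  # condensate with lam = 0 is invalid truth
  bad <- tt; bad$lam[3] <- 0
  expect_error(simulate_elution(bad, cfg), "lam > 0")
})

test_that("window means equal dense numerical quadrature of FC(t)", {
  # deformable species across parameter grid, leak = 0 so the unfloored
  # closed form is what the quadrature sees
  grid <- expand.grid(d0 = c(40, 55, 70), lam = c(0.5, 0.8, 1),
                      beta = c(0.3, 0.5), tau0 = c(0.1, 0.15))
  windows <- list(T1 = c(0, 0.25), T2 = c(0.25, 0.6), T3 = c(0.6, 1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tr <- toy_truth()[3, ]
    tr$d0 <- g$d0; tr$lam <- g$lam
    cfg <- elution_config(d_pore = 30, windows = windows, beta = g$beta,
                          tau0 = g$tau0, leak = 0)
    qt <- simulate_elution(tr, cfg)
    r <- g$d0 / 30
    for (w in seq_along(windows)) {
      quad <- integrate(elution_curve, windows[[w]][1], windows[[w]][2],
                        d_ratio = r, lam = g$lam, beta = g$beta,
                        tau0 = g$tau0, rel.tol = 1e-10, subdivisions = 2000L)
      expected <- quad$value / diff(windows[[w]])
      expect_equal(unname(qt$values[1, w]), expected, tolerance = 1e-6)
    }
  }
  # the closed-form example: t_on = 0.3, tau = 0.2, window [0.3, 0.5]
  tr <- toy_truth()[3, ]; tr$d0 <- 60; tr$lam <- 1        # d_ratio = 2
  cfg <- elution_config(d_pore = 30, windows = list(T1 = c(0.3, 0.5)),
                        beta = 0.3, tau0 = 0.1, leak = 0)
  qt <- simulate_elution(tr, cfg)
  analytic <- (0.2 - 0.2 * (1 - exp(-1))) / 0.2
  expect_equal(unname(qt$values[1, 1]), analytic, tolerance = 1e-12)
})

test_that("noise-free elution obeys the window/pore/dilution monotonicities", {
  tr <- generate_proteome(400, seed = 3)
  tabs <- lapply(c(30, 100, 200), function(p)
    simulate_elution(tr, elution_config(d_pore = p)))
  for (qt in tabs) {
    expect_true(all(qt$values >= 0 & qt$values <= 1))
    expect_true(all(qt$values[, 2] >= qt$values[, 1]))   # T2 >= T1
  }
  # nondecreasing in pore size
  expect_true(all(tabs[[2]]$values >= tabs[[1]]$values))
  expect_true(all(tabs[[3]]$values >= tabs[[2]]$values))
  # dilution response: nondecreasing for condensates, constant for
  # phi_core = 1, constant for rigid classes
  tr$phi_core[tr$class == "condensate"][1:20] <- 1
  dils <- lapply(c(1, 1.2, 1.44, 2), function(f)
    simulate_elution(tr, elution_config(d_pore = 30, dilution = f,
                                        windows = list(W = c(0, 1)))))
  for (k in 2:4)
    expect_true(all(dils[[k]]$values >= dils[[k - 1]]$values - 1e-12))
  solid <- tr$species_id[tr$class == "condensate" & tr$phi_core == 1]
  rigid <- tr$species_id[tr$class %in% c("complex", "membrane_organelle")]
  for (k in 2:4) {
    expect_equal(dils[[k]]$values[solid, ], dils[[1]]$values[solid, ])
    expect_equal(dils[[k]]$values[rigid, ], dils[[1]]$values[rigid, ])
  }
})

test_that("measurement noise has the configured moment structure", {
  tr <- generate_proteome(100, seed = 5)
  qt <- simulate_elution(tr, elution_config(d_pore = 30))
  # zero noise is the identity
  qt0 <- add_measurement_noise(qt, noise_config(0, 0, seed = 1))
  expect_identical(qt0$values, qt$values)
  # loading-only noise scales each column by one common factor
  ql <- add_measurement_noise(qt, noise_config(0, 1, seed = 2))
  ratio <- ql$values / qt$values
  expect_equal(apply(ratio, 2, max), apply(ratio, 2, min), tolerance = 1e-12)
  # channel noise SD recovered from 10000 values of 1.0
  ones <- quant_table(matrix(1, 5000, 2, dimnames = list(sprintf("p%d", 1:5000),
                                                         c("e|a", "e|b"))),
                      data.frame(condition = c("e|a", "e|b"), experiment = "e"))
  qn <- add_measurement_noise(ones, noise_config(0.1, 0, seed = 3))
  expect_lt(abs(sd(log2(qn$values)) - 0.1), 0.005)
  # reproducibility
  qn2 <- add_measurement_noise(ones, noise_config(0.1, 0, seed = 3))
  expect_identical(qn$values, qn2$values)
})

test_that("sequence features are class-correlated and reproducible", {
  all_free <- generate_proteome(800, c(free = 1), seed = 6)
  all_cond <- generate_proteome(800, c(condensate = 1), seed = 6)
  f_free <- generate_sequence_features(all_free, seed = 7)
  f_cond <- generate_sequence_features(all_cond, seed = 7)
  expect_lt(mean(f_free$idr_frac), mean(f_cond$idr_frac))
  expect_identical(f_free, generate_sequence_features(all_free, seed = 7))
  frac_cols <- grep("^frac_|^idr_frac$", names(f_free), value = TRUE)
  expect_true(all(f_free[frac_cols] >= 0 & f_free[frac_cols] <= 1))
  # RNA-binding rate within 3 binomial SDs of the configured probability
  big <- generate_proteome(5000, c(condensate = 1), seed = 8)
  fb <- generate_sequence_features(big, seed = 9, p_rna_condensate = 0.6)
  expect_lt(abs(mean(fb$rna_binding) - 0.6), 3 * sqrt(0.6 * 0.4 / 5000))
})

test_that("bead profiles follow the log-normal fill model", {
  tt <- toy_truth()
  expect_error(simulate_bead_profiles(tt, cutoffs = c(15, 7.7)), "ascending")
  # all monomeric: fill 1 everywhere
  bp1 <- simulate_bead_profiles(tt, mono_weight = 1, seed = 1)
  expect_equal(bp1$fill, rep(1, nrow(bp1)))
  # the assay's cutoff series: condensate profiles strictly increasing and
  # matching the log-normal CDF evaluated directly
  bp <- simulate_bead_profiles(tt, cutoffs = c(7.7, 15, 29, 53),
                               mono_weight = 0.3, seed = 2)
  for (sid in tt$species_id) {
    prof <- bp[bp$species_id == sid, ]
    expect_true(all(diff(prof$fill) >= 0))
  }
  cond <- bp[bp$species_id == "cond1", ]
  # recompute: mono_weight + (1-mono_weight) * plnorm(s, log(d0), sdlog)
  sdlog <- uniroot(function(s) 0.3 + 0.7 * plnorm(7.7, log(60), s) - cond$fill[1],
                   c(0.05, 3), tol = 1e-12)$root
  expect_equal(cond$fill, 0.3 + 0.7 * plnorm(c(7.7, 15, 29, 53), log(60), sdlog),
               tolerance = 1e-6)
  # CDF limit: fill -> 1 as s -> Inf
  bp_inf <- simulate_bead_profiles(tt, cutoffs = c(10, 1e9), seed = 3)
  expect_equal(bp_inf$fill[seq(2, nrow(bp_inf), by = 2)],
               rep(1, nrow(tt)), tolerance = 1e-6)
})
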