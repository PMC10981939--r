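#' Default per-class parameter ranges of the synthetic cytoplasm
#'
#' The generator emulates four species classes: free/small proteins, rigid
#' macromolecular complexes, deformable liquid-like condensates (with a
#' saturation concentration and an optional non-dissolving solid core), and
#' membrane-bound organelles. Ranges are the package's synthetic study
#' conditions: condensate assembly diameters are log-uniform over 33-75 nm
#' (the sub-100 nm mesoscale), their saturation ratio c0/c_sat spans
#' 1.15-1.6 so that moderate dilution (1.2-1.6x) dissolves most of them,
#' and deformability `lam` is high (0.5-1) because liquidity is what lets
#' condensates squeeze through pores at all. Complexes (25-70 nm) and
#' membrane organelles (250-1500 nm) are rigid (`lam = 0`).
#'
#' Each entry may contain: `d_mono` (monomer diameter range, nm), `d0`
#' (assembly diameter range, nm; log-uniform for condensates), `c_ratio`,
#' `phi_core_prob` (probability of a nonzero solid core) with
#' `phi_core` range, and `lam`.
#'
#' @return Named list of per-class parameter ranges.
#' @export
class_param_defaults <- function() {
  list(
    free = list(d_mono = c(3, 8)),
    complex = list(d_mono = c(3, 8), d0 = c(25, 70)),
    condensate = list(d_mono = c(3, 8), d0 = c(33, 75), d0_log = TRUE,
                      c_ratio = c(1.15, 1.6),
                      phi_core_prob = 0.2, phi_core = c(0.1, 0.4),
                      lam = c(0.5, 1)),
    membrane_organelle = list(d_mono = c(3, 8), d0 = c(250, 1500))
  )
}

species_classes <- c("free", "complex", "condensate", "membrane_organelle")

#' Generate a synthetic proteome with known ground truth
#'
#' Draws `n_species` species with class labels multinomially distributed
#' according to `class_fractions` and per-class physical parameters from
#' `param_ranges`. The returned table is the simulator's truth: class,
#' assembly diameter `d0` (nm), monomer diameter `d_mono`, saturation ratio
#' `c_ratio` = c0/c_sat and core fraction `phi_core` (condensates only),
#' deformability `lam` (0 for rigid classes), and relative abundance.
#'
#' @param n_species number of species (>= 0).
#' @param class_fractions named fractions over the four classes, summing to 1.
#' @param param_ranges per-class ranges as from [class_param_defaults()].
#' @param seed integer seed; identical seeds reproduce the table exactly.
#' @return data.frame of class `species_truth`.
#' @export
generate_proteome <- function(n_species,
                              class_fractions = c(free = 0.12, complex = 0.23,
                                                  condensate = 0.25,
                                                  membrane_organelle = 0.40),
                              param_ranges = class_param_defaults(),
                              seed = NULL) {
  if (!is.numeric(n_species) || length(n_species) != 1L || n_species < 0)
    stop_invalid("`n_species` must be a single nonnegative count")
  n_species <- as.integer(n_species)
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% species_classes))
    stop_invalid("`class_fractions` must be named by species class")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop_invalid("`class_fractions` must sum to 1")
  out <- with_seed(seed, {
    if (n_species == 0L) {
      data.frame(species_id = character(), class = character(),
                 d0 = numeric(), d_mono = numeric(), c_ratio = numeric(),
                 phi_core = numeric(), lam = numeric(), abundance = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      counts <- as.vector(rmultinom(1, n_species, class_fractions))
      cls <- rep(names(class_fractions), counts)
      n <- length(cls)
      d_mono <- numeric(n); d0 <- numeric(n)
      c_ratio <- rep(NA_real_, n); phi_core <- rep(NA_real_, n)
      lam <- numeric(n)
      for (cl in unique(cls)) {
        idx <- which(cls == cl)
        pr <- param_ranges[[cl]]
        if (is.null(pr)) stop_invalid("no parameter ranges for class ", cl)
        d_mono[idx] <- runif(length(idx), pr$d_mono[1], pr$d_mono[2])
        if (cl == "free") {
          d0[idx] <- d_mono[idx]
        } else if (isTRUE(pr$d0_log)) {
          d0[idx] <- exp(runif(length(idx), log(pr$d0[1]), log(pr$d0[2])))
        } else {
          d0[idx] <- runif(length(idx), pr$d0[1], pr$d0[2])
        }
        if (cl == "condensate") {
          c_ratio[idx] <- runif(length(idx), pr$c_ratio[1], pr$c_ratio[2])
          has_core <- runif(length(idx)) < pr$phi_core_prob
          phi_core[idx] <- ifelse(has_core,
                                  runif(length(idx), pr$phi_core[1], pr$phi_core[2]),
                                  0)
          lam[idx] <- runif(length(idx), pr$lam[1], pr$lam[2])
          d0[idx] <- pmax(d0[idx], d_mono[idx])
        }
      }
      data.frame(species_id = sprintf("P%05d", seq_len(n)),
                 class = cls, d0 = d0, d_mono = d_mono, c_ratio = c_ratio,
                 phi_core = phi_core, lam = lam,
                 abundance = rlnorm(n, 0, 1),
                 stringsAsFactors = FALSE)
    }
  })
  class(out) <- c("species_truth", "data.frame")
  out
}

#' Effective assembly diameter under dilution
#'
#' Condensates partially dissolve when the cytoplasm is diluted below their
#' saturation concentration: the condensed mass fraction is
#' `phi(f) = max(phi_core, 1 - f / c_ratio)` for dilution factor `f`, and the
#' representative assembly diameter scales with the cube root of the
#' condensed mass, `d_eff = max(d_mono, d0 * (phi(f)/phi(1))^(1/3))`.
#' Species with `phi_core = 1` never dissolve; rigid classes and free
#' proteins are dilution-invariant and return `d0`.
#'
#' @param species a `species_truth` table (or single row).
#' @param dilution dilution factor f >= 1.
#' @return numeric vector of effective diameters in nm.
#' @export
effective_diameter <- function(species, dilution) {
  if (!is.numeric(dilution) || length(dilution) != 1L || dilution < 1)
    stop_invalid("`dilution` must be a single factor >= 1")
  d <- species$d0
  is_cond <- species$class == "condensate"
  if (any(is_cond)) {
    cr <- species$c_ratio[is_cond]
    pc <- species$phi_core[is_cond]
    phi_f <- pmax(pc, 1 - dilution / cr)
    phi_1 <- pmax(pc, 1 - 1 / cr)
    ratio <- ifelse(phi_1 > 0, pmax(phi_f, 0) / phi_1, 0)
    d[is_cond] <- pmax(species$d_mono[is_cond],
                       species$d0[is_cond] * ratio^(1 / 3))
  }
  d
}

#' Elution experiment configuration
#'
#' @param d_pore pore cutoff diameter in nm (particles larger than this are
#'   confidently retained).
#' @param dilution lysate dilution factor f >= 1.
#' @param windows ordered, non-overlapping sampling windows as fractions of
#'   total spin time in `[0,1]`: a list of `c(start, end)` pairs or a 2-column
#'   matrix. Names (default `T1`, `T2`, ...) become condition labels.
#' @param beta onset-delay scale of squeezing (dimensionless).
#' @param tau0 squeezing time scale as a fraction of spin time.
#' @param leak residual fold change of fully retained species in `[0,1)`;
#'   the assay's detection floor.
#' @param experiment experiment label used in condition names.
#' @param replicate replicate identifier.
#' @return An object of class `elution_config`.
#' @export
elution_config <- function(d_pore, dilution = 1, windows = list(T1 = c(0, 0.25),
                                                                T2 = c(0.25, 1)),
                           beta = 0.5, tau0 = 0.15, leak = 0.02,
                           experiment = paste0("filt", d_pore),
                           replicate = 1L) {
  if (!is.numeric(d_pore) || d_pore <= 0) stop_invalid("`d_pore` must be > 0")
  if (!is.numeric(dilution) || dilution < 1) stop_invalid("`dilution` must be >= 1")
  if (is.matrix(windows))
    windows <- lapply(seq_len(nrow(windows)), function(i) windows[i, ])
  if (!length(windows)) stop_invalid("at least one window is required")
  if (is.null(names(windows)) || any(!nzchar(names(windows))))
    names(windows) <- paste0("T", seq_along(windows))
  w <- do.call(rbind, windows)
  if (any(w < 0) || any(w > 1) || any(w[, 2] <= w[, 1]))
    stop_invalid("windows must satisfy 0 <= start < end <= 1")
  if (nrow(w) > 1L && any(w[-1L, 1] < w[-nrow(w), 2] - 1e-12))
    stop_invalid("windows must be ordered and non-overlapping")
  if (leak < 0 || leak >= 1) stop_invalid("`leak` must be in [0,1)")
  structure(list(d_pore = d_pore, dilution = dilution, windows = windows,
                 beta = beta, tau0 = tau0, leak = leak,
                 experiment = experiment, replicate = replicate),
            class = "elution_config")
}

#' Instantaneous filtrate concentration of a deformable species
#'
#' The simulator's forward model for squeezing passage: a species whose
#' effective diameter exceeds the pore cutoff by the ratio `r = d_eff/d_pore`
#' starts eluting only after an onset delay `t_on = min(1, beta*(r-1)/lam)`
#' and then approaches free passage as
#' `FC(t) = 1 - exp(-(t - t_on)/tau)` with `tau = tau0*r/lam`. Stiffer
#' (small `lam`) or larger assemblies start later and elute more slowly.
#'
#' @param t spin-time fraction(s) in `[0,1]`.
#' @param d_ratio `d_eff / d_pore` (> 1 for hindered species).
#' @param lam deformability in (0,1].
#' @param beta,tau0 model scales, see [elution_config()].
#' @return FC(t) values in `[0,1]`.
#' @export
elution_curve <- function(t, d_ratio, lam, beta = 0.5, tau0 = 0.15) {
  if (d_ratio <= 1) return(rep(1, length(t)))
  t_on <- min(1, beta * (d_ratio - 1) / lam)
  tau <- tau0 * d_ratio / lam
  ifelse(t < t_on, 0, 1 - exp(-(t - t_on) / tau))
}

# Closed-form window mean of elution_curve over [a, b].
window_mean_fc <- function(a, b, d_ratio, lam, beta, tau0) {
  if (d_ratio <= 1) return(1)
  t_on <- min(1, beta * (d_ratio - 1) / lam)
  tau <- tau0 * d_ratio / lam
  if (b <= t_on) return(0)
  l <- max(a, t_on)
  area <- (b - l) - tau * (exp(-(l - t_on) / tau) - exp(-(b - t_on) / tau))
  area / (b - a)
}

#' Simulate a noise-free filtration elution experiment
#'
#' Applies the passage model to every species in the truth table: free
#' species and anything with effective diameter at or below the pore cutoff
#' pass unhindered (FC = 1); rigid species larger than the pores are retained
#' at the `leak` floor; deformable condensates larger than the pores elute
#' with delayed-onset squeezing kinetics, and each condition value is the
#' mean of FC(t) over its sampling window (floored at `leak`, the detection
#' limit). All outputs lie in `[0, 1]`.
#'
#' @param truth a `species_truth` table from [generate_proteome()].
#' @param cfg an [elution_config()].
#' @return A noise-free [quant_table()].
#' @export
simulate_elution <- function(truth, cfg) {
  stopifnot(inherits(cfg, "elution_config"))
  if (any(truth$class == "condensate" & truth$lam <= 0))
    stop_invalid("invalid truth: condensate species must have lam > 0")
  d_eff <- effective_diameter(truth, cfg$dilution)
  n <- nrow(truth)
  k <- length(cfg$windows)
  values <- matrix(1, n, k)
  for (i in seq_len(n)) {
    if (d_eff[i] <= cfg$d_pore || truth$class[i] == "free") next
    if (truth$lam[i] <= 0) {
      values[i, ] <- cfg$leak
    } else {
      r <- d_eff[i] / cfg$d_pore
      fc <- vapply(cfg$windows, function(w)
        window_mean_fc(w[1], w[2], r, truth$lam[i], cfg$beta, cfg$tau0), 0)
      values[i, ] <- pmax(fc, cfg$leak)
    }
  }
  cond_names <- paste0(cfg$experiment, "|", names(cfg$windows))
  if (cfg$replicate != 1L) cond_names <- paste0(cond_names, ".r", cfg$replicate)
  dimnames(values) <- list(truth$species_id, cond_names)
  w <- do.call(rbind, cfg$windows)
  conditions <- data.frame(
    condition = cond_names, experiment = cfg$experiment,
    pore_nm = cfg$d_pore, dilution = cfg$dilution,
    window = names(cfg$windows), window_start = w[, 1], window_end = w[, 2],
    replicate = cfg$replicate, stringsAsFactors = FALSE)
  quant_table(values, conditions)
}

#' Multiplexed measurement-noise configuration
#'
#' Emulates the noise structure of isobaric-tag quantification: independent
#' log2-multiplicative channel noise per measurement plus a shared log2
#' loading factor per condition column (loading imbalance between channels).
#'
#' @param sigma_channel SD of per-measurement log2 noise (>= 0).
#' @param sigma_loading SD of the per-condition log2 loading factor (>= 0).
#' @param seed integer seed.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(sigma_channel = 0.2, sigma_loading = 0.1, seed = NULL) {
  if (sigma_channel < 0 || sigma_loading < 0)
    stop_invalid("noise SDs must be nonnegative")
  structure(list(sigma_channel = sigma_channel, sigma_loading = sigma_loading,
                 seed = seed), class = "noise_config")
}

#' Add multiplexed measurement noise to a fold-change table
#'
#' Each value is multiplied by `2^eps`, `eps ~ N(0, sigma_channel)`, and each
#' condition column additionally by a shared `2^L`, `L ~ N(0, sigma_loading)`.
#' Positivity is preserved; `NA`s propagate.
#'
#' @param qt a [quant_table()] with nonnegative values.
#' @param noise a [noise_config()].
#' @return The noised `quant_table`.
#' @export
add_measurement_noise <- function(qt, noise) {
  stopifnot(inherits(qt, "quant_table"), inherits(noise, "noise_config"))
  with_seed(noise$seed, {
    v <- qt$values
    eps <- matrix(rnorm(length(v), 0, noise$sigma_channel), nrow(v), ncol(v))
    load <- rnorm(ncol(v), 0, noise$sigma_loading)
    v <- v * 2^(eps + matrix(load, nrow(v), ncol(v), byrow = TRUE))
    quant_table(v, qt$conditions, normalized = qt$normalized)
  })
}

# Bounded [0,1] draw with class-shifted mean (normal, clamped).
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate class-correlated sequence features
#'
#' Per species: fraction of residues in intrinsically disordered regions
#' (IDRs; Beta-distributed, shifted high for condensates), counts of IDRs of
#' any length / >= 30 aa / >= 50 aa, Bernoulli flags for DNA binding, RNA
#' binding and the presence of an RNA-binding domain (condensate-enriched),
#' and amino-acid composition fractions (Gly, Cys, Leu, Ile, aliphatic,
#' aromatic) with class-dependent means mirroring the depletion of aliphatics
#' and enrichment of glycine/aromatics in phase-separating sequences.
#'
#' @param truth a non-empty `species_truth` table.
#' @param seed integer seed.
#' @param p_rna_condensate RNA-binding probability for condensates.
#' @param p_rna_other RNA-binding probability for the other classes.
#' @return data.frame of per-species features, all fractions in `[0,1]`.
#' @export
generate_sequence_features <- function(truth, seed = NULL,
                                       p_rna_condensate = 0.6,
                                       p_rna_other = 0.2) {
  if (!nrow(truth)) stop_invalid("`truth` must be non-empty")
  with_seed(seed, {
    n <- nrow(truth)
    is_cond <- truth$class == "condensate"
    idr_frac <- ifelse(is_cond, rbeta(n, 5, 3), rbeta(n, 2, 6))
    idr_n_any <- rpois(n, ifelse(is_cond, 4, 1.5))
    idr_n30 <- rbinom(n, idr_n_any, ifelse(is_cond, 0.6, 0.4))
    idr_n50 <- rbinom(n, idr_n30, ifelse(is_cond, 0.6, 0.4))
    data.frame(
      protein_id = truth$species_id,
      idr_frac = idr_frac,
      idr_n_any = idr_n_any, idr_n30 = idr_n30, idr_n50 = idr_n50,
      dna_binding = as.integer(runif(n) < ifelse(is_cond, 0.3, 0.1)),
      rna_binding = as.integer(runif(n) < ifelse(is_cond, p_rna_condensate,
                                                 p_rna_other)),
      rna_binding_domain = as.integer(runif(n) < ifelse(is_cond, 0.5, 0.15)),
      frac_G = clamp01(rnorm(n, ifelse(is_cond, 0.080, 0.065), 0.012)),
      frac_C = clamp01(rnorm(n, ifelse(is_cond, 0.010, 0.020), 0.005)),
      frac_L = clamp01(rnorm(n, ifelse(is_cond, 0.070, 0.095), 0.012)),
      frac_I = clamp01(rnorm(n, ifelse(is_cond, 0.040, 0.055), 0.010)),
      frac_aliphatic = clamp01(rnorm(n, ifelse(is_cond, 0.25, 0.33), 0.03)),
      frac_aromatic = clamp01(rnorm(n, ifelse(is_cond, 0.10, 0.08), 0.015)),
      stringsAsFactors = FALSE)
  })
}

#' Simulate curated LLPS database membership lists
#'
#' Emulates several published LLPS databases: each database lists a
#' condensate species with a probability that increases with its disorder
#' content (well-curated phase separators are the strongly disordered ones,
#' mirroring the observation that proteins with higher consensus level show
#' stronger shifts), and non-condensate species only at a small
#' false-annotation rate.
#'
#' @param truth a `species_truth` table.
#' @param seq_features features from [generate_sequence_features()] (for the
#'   disorder coupling).
#' @param n_db number of databases.
#' @param seed integer seed.
#' @param a,b logistic intercept/slope of the per-database inclusion
#'   probability versus IDR fraction for condensates.
#' @param p_false per-database inclusion probability for other classes.
#' @return Named list of protein-id character vectors, one per database.
#' @export
simulate_llps_databases <- function(truth, seq_features, n_db = 5, seed = NULL,
                                    a = -6.5, b = 8, p_false = 0.002) {
  stopifnot(nrow(truth) == nrow(seq_features))
  with_seed(seed, {
    is_cond <- truth$class == "condensate"
    p <- ifelse(is_cond, plogis(a + b * seq_features$idr_frac), p_false)
    out <- lapply(seq_len(n_db), function(d)
      truth$species_id[runif(nrow(truth)) < p])
    names(out) <- paste0("db", seq_len(n_db))
    out
  })
}

#' Generate a reference annotation table for a synthetic proteome
#'
#' Builds the flags used for recall, anchoring and membrane correction:
#' LLPS consensus level (via [merge_llps_references()] over simulated
#' database lists), `complex`, `mitochondrion` (a subset of membrane-bound
#' organelles), `membrane_bound_organelle`, `transmembrane` (enriched in
#' membrane organelles, rare elsewhere), `rna_binding` (copied from the
#' sequence features when supplied) and `bmc_associated`.
#'
#' @param truth a `species_truth` table.
#' @param seq_features optional features from [generate_sequence_features()].
#' @param seed integer seed.
#' @return data.frame annotation table, one row per species.
#' @export
generate_annotations <- function(truth, seq_features = NULL, seed = NULL) {
  if (is.null(seq_features))
    seq_features <- generate_sequence_features(truth, seed = derive_seed(seed %||% 0, 91))
  dbs <- simulate_llps_databases(truth, seq_features,
                                 seed = derive_seed(seed %||% 0, 92))
  consensus <- merge_llps_references(dbs)
  lev <- setNames(consensus$llps_consensus, consensus$protein_id)
  cons <- unname(lev[truth$species_id])
  cons[is.na(cons)] <- 0L
  with_seed(seed, {
    n <- nrow(truth)
    is_mem <- truth$class == "membrane_organelle"
    is_cplx <- truth$class == "complex"
    data.frame(
      protein_id = truth$species_id,
      llps_consensus = as.integer(cons),
      complex = is_cplx,
      membrane_bound_organelle = is_mem,
      mitochondrion = is_mem & runif(n) < 0.5,
      transmembrane = runif(n) < ifelse(is_mem, 0.7, 0.05),
      rna_binding = seq_features$rna_binding == 1L,
      bmc_associated = runif(n) < ifelse(truth$class == "condensate", 0.3, 0.05),
      stringsAsFactors = FALSE)
  })
}

#' Simulate size-exclusion bead profiles
#'
#' For each species, the fill fraction at bead cutoff `s` is
#' `mono_weight + (1 - mono_weight) * CDF_logNormal(s; mu, sigma)`, where the
#' log-normal describes the species' assembly-size distribution: a monomer
#' pool plus assemblies. Free proteins and rigid complexes are given narrow
#' distributions at their own diameter (profiles jump to ~1 by the smallest
#' cutoffs), whereas condensates receive broad distributions spanning the
#' mesoscale. Matching inside/outside intensities and the bead's accessible
#' volume `rho0` are emitted so [fill_fraction()] can invert the forward map.
#'
#' @param truth a `species_truth` table (or subset).
#' @param cutoffs ascending bead cutoff sizes in nm; defaults to the assay's
#'   ~7.7/15/29/53 nm series.
#' @param mono_weight monomeric mass fraction in `[0,1]`.
#' @param rho0 accessible-volume fraction per cutoff (recycled).
#' @param sigma_condensate range of log-SD for condensate size distributions.
#' @param sigma_small log-SD for free/rigid species.
#' @param seed integer seed.
#' @return data.frame in long format: `species_id`, `class`, `cutoff_nm`,
#'   `fill`, `rho0`, `I_out`, `I_in`.
#' @export
simulate_bead_profiles <- function(truth, cutoffs = c(7.7, 15, 29, 53),
                                   mono_weight = 0.3, rho0 = 0.8,
                                   sigma_condensate = c(0.7, 1.2),
                                   sigma_small = 0.2, seed = NULL) {
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop_invalid("`cutoffs` must be strictly ascending")
  if (mono_weight < 0 || mono_weight > 1)
    stop_invalid("`mono_weight` must be in [0,1]")
  rho0 <- rep_len(rho0, length(cutoffs))
  with_seed(seed, {
    n <- nrow(truth)
    sdlog <- ifelse(truth$class == "condensate",
                    runif(n, sigma_condensate[1], sigma_condensate[2]),
                    sigma_small)
    meanlog <- log(truth$d0)
    out <- do.call(rbind, lapply(seq_len(n), function(i) {
      fill <- mono_weight + (1 - mono_weight) *
        plnorm(cutoffs, meanlog[i], sdlog[i])
      I_out <- truth$abundance[i]
      data.frame(species_id = truth$species_id[i], class = truth$class[i],
                 cutoff_nm = cutoffs, fill = fill, rho0 = rho0,
                 I_out = I_out, I_in = fill * I_out * rho0,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
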