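#' Configuration of a full synthetic-cytoplasm pipeline run
#'
#' Collects the simulator parameters, experiment selections, reference
#' definitions and FDR level of one end-to-end run. Alternatively, paths to
#' existing tables (`quant_path`/`conditions_path`/`annotations_path`/
#' `seq_features_path`) may be supplied instead of simulator parameters.
#'
#' @param seed master integer seed; every stage derives its own sub-seed.
#' @param n_species proteome size of the synthetic run.
#' @param class_fractions class composition (see [generate_proteome()]).
#' @param param_ranges per-class parameter ranges.
#' @param pores filtration pore cutoffs in nm (each becomes one two-window
#'   experiment).
#' @param dilutions dilution factors of the dilution series (first must be 1).
#' @param dilution_pore pore cutoff of the dilution series in nm.
#' @param windows elution windows of the filtration experiments.
#' @param replicates number of noise replicates of each filtration
#'   experiment (used for the noise model).
#' @param sigma_channel,sigma_loading measurement-noise SDs (log2).
#' @param behavior_experiments experiments averaged into liquid-like
#'   behavior (filtration pores and dilution factors, see
#'   [liquid_behavior()]).
#' @param consensus_min minimum LLPS consensus level of the reference set.
#' @param fdr nominal FDR of the BMC call in (0, 1].
#' @param classify run the ensemble predictor?
#' @param n_ensembles,n_learners predictor partition and ensemble sizes.
#' @param quant_path,conditions_path,annotations_path,seq_features_path
#'   optional input paths replacing the simulator.
#' @param out_dir output directory (created); `NULL` for no file output.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            n_species = 4000,
                            class_fractions = c(free = 0.12, complex = 0.23,
                                                condensate = 0.25,
                                                membrane_organelle = 0.40),
                            param_ranges = class_param_defaults(),
                            pores = c(30, 100, 200),
                            dilutions = c(1, 1.2, 1.44, 2),
                            dilution_pore = 30,
                            windows = list(T1 = c(0, 0.25), T2 = c(0.25, 1)),
                            replicates = 2,
                            sigma_channel = 0.2, sigma_loading = 0.1,
                            behavior_experiments = list(pores = c(30, 100),
                                                        dilutions = c(1.2, 1.44)),
                            consensus_min = 4,
                            fdr = 0.02,
                            classify = TRUE,
                            n_ensembles = 600, n_learners = 10,
                            quant_path = NULL, conditions_path = NULL,
                            annotations_path = NULL, seq_features_path = NULL,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  simulated <- !is.null(n_species)
  from_files <- !is.null(quant_path)
  if (!simulated && !from_files)
    stop_invalid("config must provide either `n_species` (simulator) or `quant_path` (input files)")
  if (fdr <= 0 || fdr > 1) stop_invalid("config field `fdr` must be in (0, 1]")
  if (simulated && abs(sum(class_fractions) - 1) > 1e-9)
    stop_invalid("config field `class_fractions` must sum to 1")
  if (length(dilutions) && dilutions[1] != 1)
    stop_invalid("config field `dilutions` must start with the undiluted factor 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Top-level keys override the defaults of [pipeline_config()].
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_invalid("reading YAML configs requires the `yaml` package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_invalid("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$class_fractions)) raw$class_fractions <- unlist(raw$class_fractions)
  do.call(pipeline_config, raw)
}

sim_experiment_set <- function(cfg) {
  configs <- list()
  for (p in cfg$pores)
    configs[[paste0("filt", p)]] <-
      elution_config(d_pore = p, windows = cfg$windows,
                     experiment = paste0("filt", p))
  for (f in cfg$dilutions) {
    nm <- paste0("dil", f)
    configs[[nm]] <- elution_config(d_pore = cfg$dilution_pore, dilution = f,
                                    windows = list(W = c(0, 1)),
                                    experiment = "dilution")
    configs[[nm]]$cond_name <- paste0("dilution|x", f)
  }
  configs
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the complete pipeline
#'
#' Orchestrates simulate -> add noise -> normalize -> squeezing scores ->
#' reference recall -> noise model -> liquid-like behavior -> FDR
#' classification -> composition fractions -> (optionally) ensemble
#' predictor, with stage-scoped logging of protein counts. With an
#' `out_dir`, all stage outputs are written as TSV/JSON together with a run
#' manifest (resolved configuration, seed, package version, output
#' checksums); identical configuration and seed reproduce every output
#' bit-exactly.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage logging?
#' @return Invisibly, a list with all stage results (`truth`, `quant_raw`,
#'   `quant`, `squeeze`, `recall`, `noise_model`, `behavior`, `composition`,
#'   `classifier`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "),
                                               ...)
  stage <- "setup"
  result <- tryCatch({
    ## --- simulate or load -------------------------------------------------
    stage <- "input"
    if (!is.null(config$quant_path)) {
      quant_raw <- read_quant_table(config$quant_path, config$conditions_path)
      truth <- NULL
      ann <- read.delim(config$annotations_path, stringsAsFactors = FALSE)
      seqf <- read.delim(config$seq_features_path, stringsAsFactors = FALSE)
      log_msg("loaded ", nrow(quant_raw$values), " proteins from ", config$quant_path)
    } else {
      truth <- generate_proteome(config$n_species, config$class_fractions,
                                 config$param_ranges,
                                 seed = derive_seed(config$seed, 1))
      log_msg("simulated proteome: ", nrow(truth), " species (",
              paste(names(table(truth$class)), table(truth$class),
                    sep = "=", collapse = ", "), ")")
      configs <- sim_experiment_set(config)
      tabs <- list()
      for (nm in names(configs)) {
        ec <- configs[[nm]]
        noisefree <- simulate_elution(truth, ec)
        if (!is.null(ec$cond_name)) {
          colnames(noisefree$values) <- ec$cond_name
          noisefree$conditions$condition <- ec$cond_name
        }
        tabs[[nm]] <- noisefree
      }
      # replicate filtration tables feed the noise model
      rep_tabs <- list()
      for (r in seq_len(config$replicates - 1L)) {
        for (p in config$pores[config$pores %in% config$behavior_experiments$pores]) {
          ec <- elution_config(d_pore = p, windows = config$windows,
                               experiment = paste0("filt", p),
                               replicate = r + 1L)
          rep_tabs[[paste0("filt", p, "r", r + 1L)]] <- simulate_elution(truth, ec)
        }
      }
      quant_raw <- cbind_quant(c(tabs, rep_tabs))
      quant_raw <- add_measurement_noise(
        quant_raw, noise_config(config$sigma_channel, config$sigma_loading,
                                seed = derive_seed(config$seed, 2)))
      seqf <- generate_sequence_features(truth, seed = derive_seed(config$seed, 3))
      ann <- generate_annotations(truth, seqf, seed = derive_seed(config$seed, 4))
      log_msg("simulated ", ncol(quant_raw$values), " conditions; ",
              sum(ann$llps_consensus >= config$consensus_min),
              " proteins at LLPS consensus >= ", config$consensus_min)
    }

    ## --- normalization ----------------------------------------------------
    stage <- "normalize"
    quant <- normalize_q95(quant_raw)
    log_msg("normalized ", length(unique(quant$conditions$experiment)),
            " experiments to their pooled 0.95 quantile")

    ## --- squeezing score --------------------------------------------------
    stage <- "squeezing"
    sq_exp <- paste0("filt", min(config$pores))
    squeeze <- squeezing_score_table(quant, paste0(sq_exp, "|T1"),
                                     paste0(sq_exp, "|T2"))
    log_msg("squeezing scores from ", sq_exp, ": edge slope ",
            round(squeeze$edge$slope, 3), ", ",
            length(squeeze$edge$support_ids), " support proteins")

    ## --- reference recall -------------------------------------------------
    stage <- "recall"
    llps_ids <- ann$protein_id[ann$llps_consensus >= config$consensus_min]
    complex_ids <- ann$protein_id[ann$complex]
    recall <- list(
      llps = roc_auc(squeeze$scores, llps_ids),
      complexes = roc_auc(squeeze$scores, complex_ids))
    if (!is.null(truth)) {
      recall$condensate_truth <- roc_auc(squeeze$scores,
                                         truth$species_id[truth$class == "condensate"])
      recall$complex_truth <- roc_auc(squeeze$scores,
                                      truth$species_id[truth$class == "complex"])
    }
    log_msg("squeezing AUC: LLPS reference ", round(recall$llps$auc, 3),
            ", complexes ", round(recall$complexes$auc, 3))

    ## --- noise model ------------------------------------------------------
    stage <- "noise_model"
    pairs <- match_replicates(quant)
    noise <- build_noise_model(pairs)
    log_msg("noise model: ", length(noise$residuals), " residuals from ",
            noise$n_pairs, " replicate pairs; sd = ",
            round(sd(noise$residuals), 3))

    ## --- liquid-like behavior + FDR --------------------------------------
    stage <- "liquidity"
    anchors <- ann$protein_id[ann$complex | ann$transmembrane]
    scatters <- list()
    for (p in config$behavior_experiments$pores)
      scatters[[paste0("filt", p)]] <-
        log2_scatter(quant, paste0("filt", p, "|T1"), paste0("filt", p, "|T2"))
    for (f in config$behavior_experiments$dilutions)
      scatters[[paste0("dil", f)]] <-
        log2_scatter(quant, "dilution|x1", paste0("dilution|x", f))
    behavior <- liquid_behavior(scatters, anchors)
    filt_cols <- as.vector(outer(paste0("filt", config$behavior_experiments$pores),
                                 names(config$windows), paste, sep = "|"))
    filt_log2 <- log2(quant$values[, filt_cols, drop = FALSE])
    membrane_ids <- ann$protein_id[ann$membrane_bound_organelle | ann$transmembrane]
    behavior <- fdr_classify(behavior, noise, fdr = config$fdr,
                             membrane_ids = membrane_ids,
                             filtration_log2fc = filt_log2)
    composition <- proteome_fractions(behavior, ann)
    log_msg("composition: ", paste(names(composition$fractions),
                                   round(composition$fractions, 3),
                                   sep = "=", collapse = ", "))

    ## --- predictor --------------------------------------------------------
    classifier <- NULL
    if (isTRUE(config$classify)) {
      stage <- "classifier"
      exp_cols <- c(as.vector(outer(paste0("filt", config$behavior_experiments$pores),
                                    names(config$windows), paste, sep = "|")),
                    paste0("dilution|x", config$dilutions))
      fs <- assemble_features(quant, seqf, llps_ids, conditions = exp_cols)
      log_msg("classifier: ", nrow(fs$features), " complete proteins, ",
              ncol(fs$features), " features, ", sum(fs$labels), " class-1")
      cv <- crossval_scores(fs, n_ensembles = config$n_ensembles,
                            n_learners = config$n_learners,
                            seed = derive_seed(config$seed, 5))
      cls_auc <- roc_auc(cv$score[is.finite(cv$score)], llps_ids)
      classifier <- list(scores = cv, auc = cls_auc$auc, features = fs)
      log_msg("classifier cross-validated AUC (LLPS reference): ",
              round(cls_auc$auc, 3))
    }

    ## --- outputs ----------------------------------------------------------
    stage <- "report"
    manifest <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("cytosieve")),
      n_proteins = nrow(quant$values),
      edge = list(slope = squeeze$edge$slope, intercept = squeeze$edge$intercept),
      auc = list(llps = recall$llps$auc, complexes = recall$complexes$auc),
      composition = as.list(composition$fractions),
      fdr_threshold = attr(behavior, "threshold"),
      classifier_auc = if (!is.null(classifier)) classifier$auc else NULL)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      out <- function(f) file.path(config$out_dir, f)
      if (!is.null(truth)) write_tsv(truth, out("truth.tsv"))
      write_quant_table(quant, out("quant_normalized.tsv"), out("conditions.tsv"))
      sq_df <- as.data.frame(squeeze$scores)
      sq_df$used_in_edge <- sq_df$protein_id %in% squeeze$edge$support_ids
      write_tsv(sq_df, out("squeezing_scores.tsv"))
      write_tsv(ann, out("annotations.tsv"))
      write_tsv(recall$llps$roc, out("roc_llps.tsv"))
      beh_df <- as.data.frame(behavior)
      beh_df$behavior <- fmt_num(beh_df$behavior)
      write_tsv(beh_df, out("liquid_behavior.tsv"))
      jsonlite::write_json(as.list(composition$fractions),
                           out("composition.json"), auto_unbox = TRUE, digits = NA)
      if (!is.null(classifier))
        write_tsv(data.frame(protein_id = names(classifier$scores$score),
                             score = fmt_num(classifier$scores$score),
                             n_eval = classifier$scores$n_eval),
                  out("classifier_scores.tsv"))
      files <- list.files(config$out_dir, full.names = TRUE)
      manifest$checksums <- as.list(tools::md5sum(files))
      names(manifest$checksums) <- basename(files)
      jsonlite::write_json(manifest, out("manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      log_msg("wrote report bundle to ", config$out_dir)
    }
    list(truth = truth, quant_raw = quant_raw, quant = quant,
         annotations = ann, seq_features = seqf, squeeze = squeeze,
         recall = recall, noise_model = noise, behavior = behavior,
         composition = composition, classifier = classifier,
         manifest = manifest)
  }, error = function(e) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
    }
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
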