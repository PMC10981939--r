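#' Build the empirical replicate-noise null model
#'
#' For each matched replicate pair, an ordinary least-squares line of log2(y)
#' on log2(x) is fitted and the vertical residuals are pooled across all
#' pairs. The pooled residual distribution is the empirical null for
#' measurement noise: any per-protein shift is compared against it.
#'
#' @param pairs a `replicate_pairs` object from [match_replicates()].
#' @return An object of class `noise_model`: `residuals` (pooled, finite),
#'   `ecdf`, `n_pairs`.
#' @export
build_noise_model <- function(pairs) {
  stopifnot(inherits(pairs, "replicate_pairs"))
  if (!length(pairs)) stop_invalid("cannot build noise model: no matched pairs")
  res <- unlist(lapply(pairs, function(p) {
    b <- cov(p$x, p$y) / var(p$x)
    a <- mean(p$y) - b * mean(p$x)
    p$y - (a + b * p$x)
  }))
  res <- res[is.finite(res)]
  structure(list(residuals = unname(res), ecdf = ecdf(res),
                 n_pairs = length(pairs)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("noise_model: %d pooled residuals from %d pair(s); sd(log2) = %.3f\n",
              length(x$residuals), x$n_pairs, sd(x$residuals)))
  invisible(x)
}

#' Per-protein liquid-like behavior across experiments
#'
#' In each selected experiment's log2 scatter (later window vs earlier, or
#' diluted vs undiluted), a reference line is fitted by OLS through the
#' anchor proteins only -- large complexes and transmembrane-annotated
#' proteins, whose passage is insensitive to squeezing time and dilution.
#' A protein's shift in that experiment is its signed vertical residual from
#' the anchor line (positive = eluting more than the anchors predict), and
#' its liquid-like behavior is the mean shift over the experiments in which
#' it is measured.
#'
#' @param scatters named list of experiments, each a list with named log2
#'   vectors `x` (earlier window / undiluted) and `y` (later / diluted),
#'   e.g. from [log2_scatter()].
#' @param anchor_ids protein ids of the anchor set (complex or transmembrane
#'   flags); must yield >= 2 finite anchors in every experiment.
#' @return An object of class `liquid_behavior`: data.frame with
#'   `protein_id`, `behavior` (log2 units), `n_used`; the per-experiment
#'   residual matrix is attached as attribute `"residuals"`.
#' @export
liquid_behavior <- function(scatters, anchor_ids) {
  stopifnot(is.list(scatters), length(scatters) >= 1)
  if (is.null(names(scatters)))
    names(scatters) <- paste0("exp", seq_along(scatters))
  ids <- sort(unique(unlist(lapply(scatters, function(s) names(s$x)))))
  resid <- matrix(NA_real_, length(ids), length(scatters),
                  dimnames = list(ids, names(scatters)))
  for (e in names(scatters)) {
    s <- scatters[[e]]
    x <- s$x; y <- s$y[names(x)]
    ok <- is.finite(x) & is.finite(y)
    anch <- ok & names(x) %in% anchor_ids
    if (sum(anch) < 2)
      stop_invalid("anchor set has fewer than 2 finite proteins in experiment ", e)
    b <- cov(x[anch], y[anch]) / var(x[anch])
    a <- mean(y[anch]) - b * mean(x[anch])
    resid[names(x)[ok], e] <- y[ok] - (a + b * x[ok])
  }
  n_used <- rowSums(!is.na(resid))
  behavior <- ifelse(n_used > 0, rowMeans(resid, na.rm = TRUE), NA_real_)
  out <- data.frame(protein_id = ids, behavior = unname(behavior),
                    n_used = unname(n_used), stringsAsFactors = FALSE)
  attr(out, "residuals") <- resid
  class(out) <- c("liquid_behavior", "data.frame")
  out
}

#' Classify proteins beyond an FDR threshold of the noise null
#'
#' Finds the smallest observed behavior value `t` whose plug-in false
#' discovery rate estimate `FDR(t) = N_total * S_null(t) / #(behavior >= t)`
#' does not exceed `fdr`, where `S_null` is the null survival function of the
#' noise model after median-aligning it with the anchor-line residuals (a +1
#' pseudo-count in the tail avoids zero estimates at the extreme). Proteins
#' at or beyond the threshold that carry no membrane annotation are flagged
#' `bmc_positive`. Proteins whose log2 fold changes in the filtration
#' experiments all sit within the two-sided null bounds around the origin are
#' flagged `small` (they pass the filters unhindered).
#'
#' An alternative tail-area rule (`method = "tail"`: threshold at the
#' `1 - fdr` null quantile, ignoring the discovery count) is exposed as a
#' configuration switch.
#'
#' @param behavior a [liquid_behavior()] result.
#' @param noise a [build_noise_model()] result.
#' @param fdr nominal false discovery rate in (0, 1]; default 0.02.
#' @param membrane_ids ids with membrane annotation (membrane-bound organelle
#'   or transmembrane), excluded from the BMC call.
#' @param filtration_log2fc optional matrix of log2 fold changes (proteins x
#'   filtration conditions) used for the `small` flag.
#' @param method `"plugin"` (default) or `"tail"`.
#' @return The behavior data.frame with logical columns `bmc_positive`,
#'   `small`, `membrane_excluded` added; the threshold and the small-bound
#'   are attached as attributes `"threshold"` and `"small_bound"`.
#' @export
fdr_classify <- function(behavior, noise, fdr = 0.02, membrane_ids = character(),
                         filtration_log2fc = NULL,
                         method = c("plugin", "tail")) {
  stopifnot(inherits(behavior, "liquid_behavior"), inherits(noise, "noise_model"))
  method <- match.arg(method)
  if (fdr <= 0 || fdr > 1) stop_invalid("`fdr` must be in (0, 1]")
  null_c <- noise$residuals - median(noise$residuals)
  n_null <- length(null_c)
  s_null <- function(t) (sum(null_c >= t) + 1) / (n_null + 1)
  b <- behavior$behavior
  finite <- is.finite(b)
  n_total <- sum(finite)
  if (method == "plugin") {
    cand <- sort(unique(b[finite]))
    thr <- Inf
    for (t in cand) {
      n_disc <- sum(b[finite] >= t)
      if (n_total * s_null(t) / n_disc <= fdr) { thr <- t; break }
    }
    if (!is.finite(thr))
      message("no threshold achieves FDR <= ", fdr, "; zero positives")
  } else {
    thr <- quantile(null_c, 1 - fdr, names = FALSE, type = 7)
  }
  membrane <- behavior$protein_id %in% membrane_ids
  bmc <- finite & b >= thr & !membrane
  small_bound <- quantile(abs(null_c), 1 - fdr, names = FALSE, type = 7)
  if (!is.null(filtration_log2fc)) {
    m <- filtration_log2fc[match(behavior$protein_id, rownames(filtration_log2fc)), ,
                           drop = FALSE]
    measured <- rowSums(is.finite(m)) > 0
    within <- rowSums(abs(m) > small_bound, na.rm = TRUE) == 0
    small <- measured & within & !bmc & !membrane
  } else {
    small <- rep(FALSE, nrow(behavior))
  }
  behavior$bmc_positive <- bmc
  behavior$small <- small
  behavior$membrane_excluded <- membrane
  attr(behavior, "threshold") <- thr
  attr(behavior, "small_bound") <- small_bound
  attr(behavior, "fdr") <- fdr
  behavior
}

#' Proteome composition fractions
#'
#' Partitions the detected proteome into membrane-bound organelle
#' (annotation), BMC (`bmc_positive`), small (`small`), and unassigned
#' (remainder), in that priority order; fractions sum to 1 exactly.
#'
#' @param classified a [fdr_classify()] result.
#' @param annotations annotation data.frame with `protein_id` and
#'   `membrane_bound_organelle`.
#' @return list with `fractions` (named numeric summing to 1), `counts`,
#'   `ids` (per-category id lists) and `n_total`.
#' @export
proteome_fractions <- function(classified, annotations) {
  stopifnot(inherits(classified, "liquid_behavior"),
            all(c("bmc_positive", "small") %in% names(classified)))
  mbo_ids <- annotations$protein_id[annotations$membrane_bound_organelle]
  id <- classified$protein_id
  cat_mbo <- id %in% mbo_ids
  cat_bmc <- classified$bmc_positive & !cat_mbo
  cat_small <- classified$small & !cat_mbo & !cat_bmc
  cat_rest <- !cat_mbo & !cat_bmc & !cat_small
  ids <- list(membrane_bound_organelle = id[cat_mbo], bmc = id[cat_bmc],
              small = id[cat_small], unassigned = id[cat_rest])
  counts <- vapply(ids, length, 0L)
  list(fractions = counts / length(id), counts = counts, ids = ids,
       n_total = length(id))
}
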