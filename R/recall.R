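#' Merge LLPS reference databases into a consensus level
#'
#' The consensus level of a protein is the number of source databases in
#' which it is found; a high level (>= 4 of 5 by convention) defines the
#' high-confidence LLPS reference set.
#'
#' @param membership_lists named list (>= 1 entry) of protein-id vectors,
#'   one per source database.
#' @return data.frame with `protein_id` and `llps_consensus` over the union
#'   of all lists. An empty union returns an empty result with a warning.
#' @export
merge_llps_references <- function(membership_lists) {
  stopifnot(is.list(membership_lists), length(membership_lists) >= 1)
  lists <- lapply(membership_lists, function(l) unique(as.character(l)))
  ids <- sort(unique(unlist(lists)))
  if (!length(ids)) {
    warning("empty union of membership lists")
    return(data.frame(protein_id = character(), llps_consensus = integer(),
                      stringsAsFactors = FALSE))
  }
  counts <- integer(length(ids))
  names(counts) <- ids
  for (l in lists) counts[l] <- counts[l] + 1L
  data.frame(protein_id = ids, llps_consensus = unname(counts),
             stringsAsFactors = FALSE)
}

as_named_scores <- function(scores) {
  if (inherits(scores, "score_vector")) return(scores$values)
  if (is.numeric(scores) && !is.null(names(scores))) return(scores)
  stop_invalid("`scores` must be a score_vector or a named numeric vector")
}

#' ROC curve and AUC of a score against a reference set
#'
#' Ranks the universe by descending score (ties grouped) and plots the true
#' positive rate (recall of the reference set) against the false positive
#' rate (fraction of the rest of the proteome accepted). The area under the
#' curve is computed by the trapezoid rule and equals the Mann-Whitney pair
#' statistic `P(score_pos > score_neg) + 0.5 * P(equal)`.
#'
#' Negatives are the universe minus the positives; proteins belonging to
#' other reference groups are not excluded.
#'
#' @param scores a [score_vector()] or named numeric vector.
#' @param positives protein ids of the reference set.
#' @param universe protein ids to rank; defaults to all finitely scored ids.
#' @return list with `roc` (data.frame `threshold`, `tpr`, `fpr`) and `auc`.
#' @export
roc_auc <- function(scores, positives, universe = NULL) {
  v <- as_named_scores(scores)
  if (is.null(universe)) universe <- names(v)[is.finite(v)]
  v <- v[intersect(universe, names(v))]
  v <- v[is.finite(v)]
  is_pos <- names(v) %in% positives
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos < 1) stop_invalid("undefined AUC: no positives with finite scores in universe")
  if (n_neg < 1) stop_invalid("undefined AUC: no negatives with finite scores in universe")
  o <- order(v, decreasing = TRUE)
  sv <- v[o]; pv <- is_pos[o]
  # group ties: cumulative counts at each distinct threshold
  last_of_group <- c(sv[-1] != sv[-length(sv)], TRUE)
  cum_tp <- cumsum(pv)[last_of_group]
  cum_fp <- cumsum(!pv)[last_of_group]
  tpr <- c(0, cum_tp / n_pos)
  fpr <- c(0, cum_fp / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(threshold = c(Inf, sv[last_of_group]),
                        tpr = tpr, fpr = fpr),
       auc = auc)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Maximum gap between the two empirical CDFs, with the asymptotic two-sided
#' p-value from the Kolmogorov distribution under the standard effective-n
#' scaling (group sizes in this context are tens or more, where the
#' asymptotic p is well calibrated).
#'
#' @param a,b numeric samples with at least 2 finite values each.
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop_invalid("both samples need at least 2 finite values")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Per-group cumulative histograms (ECDFs) on a shared grid
#'
#' @param scores a [score_vector()] or named numeric vector.
#' @param groups named list of protein-id sets.
#' @param grid evaluation points; defaults to the sorted unique finite scores.
#' @return data.frame with column `score` (the grid) and one nondecreasing
#'   ECDF column in `[0,1]` per non-empty group; empty groups are omitted
#'   with a message.
#' @export
cumulative_histogram <- function(scores, groups, grid = NULL) {
  v <- as_named_scores(scores)
  v <- v[is.finite(v)]
  if (is.null(grid)) grid <- sort(unique(v))
  out <- data.frame(score = grid)
  for (g in names(groups)) {
    vals <- v[names(v) %in% groups[[g]]]
    if (!length(vals)) {
      message("group `", g, "` has no finite scores; omitted")
      next
    }
    out[[g]] <- ecdf(vals)(grid)
  }
  out
}
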