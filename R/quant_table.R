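#' Protein-by-condition fold-change table
#'
#' The central container of the pipeline: a nonnegative matrix of fold
#' changes FC = c/c0 (one row per protein, one column per labelled condition)
#' together with per-condition metadata. Condition names follow the
#' `"<experiment>|<condition>"` convention, e.g. `"filt30|T1"`. Missing
#' measurements are `NA` and are propagated, never imputed.
#'
#' @param values numeric matrix, proteins x conditions; rownames are unique
#'   protein identifiers, colnames match `conditions$condition`.
#' @param conditions data.frame of condition metadata with at least columns
#'   `condition`, `experiment`; typical columns also include `pore_nm`,
#'   `dilution`, `window_start`, `window_end`, `replicate`. Unknown columns
#'   are preserved.
#' @param normalized logical flag; `TRUE` once [normalize_q95()] has run.
#' @return An object of class `quant_table`.
#' @seealso [read_quant_table()], [write_quant_table()], [normalize_q95()]
#' @export
quant_table <- function(values, conditions, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_invalid("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop_invalid("`values` must have protein identifiers as rownames")
  if (anyDuplicated(rownames(values)))
    stop_invalid("duplicate protein identifiers in `values`")
  if (!is.data.frame(conditions) || !all(c("condition", "experiment") %in% names(conditions)))
    stop_invalid("`conditions` must be a data.frame with columns `condition` and `experiment`")
  if (is.null(colnames(values)))
    stop_invalid("`values` must have condition names as colnames")
  missing_meta <- setdiff(colnames(values), conditions$condition)
  if (length(missing_meta))
    stop_invalid("condition(s) missing from metadata: ",
                 paste(missing_meta, collapse = ", "))
  if (nrow(conditions) != ncol(values) ||
      !identical(sort(as.character(conditions$condition)), sort(colnames(values))))
    stop_invalid("`conditions` rows must match the matrix columns one-to-one")
  if (any(values < 0, na.rm = TRUE))
    stop_invalid("fold changes must be nonnegative")
  conditions <- conditions[match(colnames(values), conditions$condition), , drop = FALSE]
  rownames(conditions) <- NULL
  structure(list(values = values, conditions = conditions,
                 normalized = isTRUE(normalized)),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d proteins x %d conditions (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  cat("experiments:", paste(unique(x$conditions$experiment), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$values)

#' Combine fold-change tables column-wise
#'
#' Joins tables over the union of proteins (absent measurements become `NA`).
#' Condition names must not collide.
#'
#' @param ... `quant_table` objects.
#' @return A single `quant_table`.
#' @export
cbind_quant <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !inherits(tabs[[1]], "quant_table"))
    tabs <- tabs[[1]]
  stopifnot(length(tabs) >= 1L, all(vapply(tabs, inherits, TRUE, "quant_table")))
  cols <- unname(unlist(lapply(tabs, function(t) colnames(t$values))))
  if (anyDuplicated(cols)) stop_invalid("duplicate condition names across tables")
  ids <- unique(unlist(lapply(tabs, function(t) rownames(t$values))))
  values <- matrix(NA_real_, length(ids), length(cols),
                   dimnames = list(ids, cols))
  for (t in tabs) values[rownames(t$values), colnames(t$values)] <- t$values
  meta_cols <- unique(unlist(lapply(tabs, function(t) names(t$conditions))))
  conds <- do.call(rbind, lapply(tabs, function(t) {
    m <- t$conditions
    for (nm in setdiff(meta_cols, names(m))) m[[nm]] <- NA
    m[meta_cols]
  }))
  quant_table(values, conds, normalized = all(vapply(tabs, `[[`, TRUE, "normalized")))
}

# Serialization uses %.17g so finite doubles round-trip bit-exactly.
fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Write a fold-change table and its condition metadata as TSV
#'
#' @param qt a [quant_table()].
#' @param path file for the protein x condition matrix (first column
#'   `protein_id`).
#' @param conditions_path file for the condition metadata.
#' @return Invisibly, `qt`.
#' @export
write_quant_table <- function(qt, path, conditions_path) {
  stopifnot(inherits(qt, "quant_table"))
  mat <- apply(qt$values, 2, fmt_num)
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = nrow(qt$values),
                                     dimnames = dimnames(qt$values))
  df <- data.frame(protein_id = rownames(qt$values), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- qt$conditions
  meta$normalized <- qt$normalized
  write.table(meta, conditions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(qt)
}

#' Read a fold-change table written by [write_quant_table()]
#'
#' Expects the package's own TSV dialect (header row, tab separators, UTF-8,
#' `.` decimal). Round-trips bit-exactly for finite values; unknown metadata
#' columns survive.
#'
#' @param path matrix TSV (first column `protein_id`).
#' @param conditions_path condition metadata TSV.
#' @return A [quant_table()].
#' @export
read_quant_table <- function(path, conditions_path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = NA)
  if (!"protein_id" %in% names(df))
    stop_invalid("matrix file must have a `protein_id` first column")
  if (anyDuplicated(df$protein_id))
    stop_invalid("duplicate protein identifiers in ", path)
  values <- as.matrix(df[setdiff(names(df), "protein_id")])
  storage.mode(values) <- "double"
  rownames(values) <- df$protein_id
  meta <- read.delim(conditions_path, check.names = FALSE, stringsAsFactors = FALSE)
  normalized <- isTRUE(all(as.logical(meta$normalized %||% FALSE)))
  meta$normalized <- NULL
  quant_table(values, meta, normalized = normalized)
}

#' Normalize each experiment to its pooled 0.95 quantile
#'
#' Fold changes are normalized separately for each experiment (the group of
#' condition columns sharing one `experiment` label) by dividing every value
#' by the experiment's pooled 0.95 empirical quantile (linear interpolation
#' between order statistics). The highest fold changes represent unhindered
#' flowthrough, so after normalization free passage sits at FC ~ 1 and the
#' shared per-experiment loading scale cancels. Pooling the experiment's
#' columns (rather than normalizing each channel) preserves the contrast
#' between elution windows that the squeezing score relies on.
#'
#' @param qt a raw [quant_table()].
#' @param q quantile used for anchoring; default 0.95.
#' @return The normalized `quant_table` (flag set; a second call errors).
#' @export
normalize_q95 <- function(qt, q = 0.95) {
  stopifnot(inherits(qt, "quant_table"))
  if (qt$normalized)
    stop_invalid("table is already normalized")
  values <- qt$values
  for (exp_name in unique(qt$conditions$experiment)) {
    cols <- qt$conditions$condition[qt$conditions$experiment == exp_name]
    pooled <- as.vector(values[, cols, drop = FALSE])
    qv <- quantile(pooled, q, na.rm = TRUE, names = FALSE, type = 7)
    if (!is.finite(qv) || qv <= 0)
      stop_invalid("degenerate data: 0.95 quantile of experiment `",
                   exp_name, "` is not positive")
    values[, cols] <- values[, cols, drop = FALSE] / qv
  }
  quant_table(values, qt$conditions, normalized = TRUE)
}

#' Per-protein scalar scores with an orientation convention
#'
#' @param protein_ids character identifiers.
#' @param values numeric scores, one per id.
#' @param orientation text stating which direction means "more squeezing /
#'   more LLPS-like".
#' @return An object of class `score_vector`.
#' @export
score_vector <- function(protein_ids, values, orientation) {
  stopifnot(length(protein_ids) == length(values),
            is.character(orientation), nzchar(orientation))
  structure(list(protein_ids = as.character(protein_ids),
                 values = setNames(as.numeric(values), protein_ids),
                 orientation = orientation),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector: %d proteins (%d missing); orientation: %s\n",
              length(x$values), sum(!is.finite(x$values)), x$orientation))
  invisible(x)
}

#' @export
as.data.frame.score_vector <- function(x, ...) {
  data.frame(protein_id = x$protein_ids, score = unname(x$values),
             stringsAsFactors = FALSE)
}

#' Log2 ratio between two conditions
#'
#' Per protein, `log2(value_a / value_b)`; missing whenever either input is
#' missing. Zero denominators are reported as missing with a warning that
#' counts them. Used e.g. for top-versus-bottom sedimentation ratios.
#'
#' @param qt a [quant_table()].
#' @param cond_a,cond_b condition column names.
#' @return A [score_vector()] oriented "higher = more in `cond_a`".
#' @export
condition_ratio <- function(qt, cond_a, cond_b) {
  stopifnot(inherits(qt, "quant_table"))
  for (cn in c(cond_a, cond_b))
    if (!cn %in% colnames(qt$values))
      stop_invalid("condition not in table: ", cn)
  a <- qt$values[, cond_a]
  b <- qt$values[, cond_b]
  zero_den <- !is.na(b) & b == 0
  if (any(zero_den))
    warning(sum(zero_den), " zero denominator(s) in condition_ratio; reported as NA")
  r <- log2(a / b)
  r[zero_den] <- NA_real_
  score_vector(rownames(qt$values), r,
               orientation = paste0("higher = more in ", cond_a))
}

#' Extract a log2 scatter of two conditions
#'
#' Convenience accessor returning named log2 fold-change vectors for two
#' condition columns, the form consumed by [fit_edge()] and
#' [liquid_behavior()].
#'
#' @param qt a [quant_table()].
#' @param cond_x,cond_y condition column names for the x and y axes.
#' @return list with named numeric vectors `x` and `y`.
#' @export
log2_scatter <- function(qt, cond_x, cond_y) {
  stopifnot(inherits(qt, "quant_table"))
  for (cn in c(cond_x, cond_y))
    if (!cn %in% colnames(qt$values))
      stop_invalid("condition not in table: ", cn)
  list(x = log2(setNames(qt$values[, cond_x], rownames(qt$values))),
       y = log2(setNames(qt$values[, cond_y], rownames(qt$values))))
}

#' Match replicate condition pairs by correlation
#'
#' Lists all cross-pairs of comparable conditions -- conditions that share the
#' same experimental key (by default pore size, dilution and elution window)
#' but are distinct columns -- whose pairwise-complete Pearson correlation of
#' log2 values exceeds `r_min`. Pairs sharing fewer than 3 finite proteins
#' are skipped with a message. The pooled line-fit residuals of the matched
#' pairs are the raw material of the empirical noise model.
#'
#' @param tables a `quant_table` or list of them.
#' @param r_min correlation threshold in (0,1); default 0.8.
#' @param key_cols metadata columns defining comparability.
#' @return An object of class `replicate_pairs`: a list of pairs, each with
#'   the two condition labels, the shared key, `r`, and the paired log2
#'   vectors `x`, `y`.
#' @export
match_replicates <- function(tables, r_min = 0.8,
                             key_cols = c("pore_nm", "dilution",
                                          "window_start", "window_end")) {
  if (inherits(tables, "quant_table")) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, TRUE, "quant_table")),
            r_min > 0, r_min < 1)
  cols <- list()
  for (ti in seq_along(tables)) {
    qt <- tables[[ti]]
    use <- intersect(key_cols, names(qt$conditions))
    for (j in seq_len(ncol(qt$values))) {
      key <- paste(vapply(use, function(k) as.character(qt$conditions[[k]][j]), ""),
                   collapse = "|")
      cols[[length(cols) + 1L]] <- list(
        label = paste0("t", ti, ":", colnames(qt$values)[j]),
        key = key, v = log2(setNames(qt$values[, j], rownames(qt$values))))
    }
  }
  pairs <- list()
  n_skipped <- 0L
  if (length(cols) >= 2L) {
    for (i in seq_len(length(cols) - 1L)) {
      for (j in (i + 1L):length(cols)) {
        if (cols[[i]]$key != cols[[j]]$key) next
        ids <- intersect(names(cols[[i]]$v), names(cols[[j]]$v))
        x <- cols[[i]]$v[ids]; y <- cols[[j]]$v[ids]
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) < 3L) { n_skipped <- n_skipped + 1L; next }
        r <- cor(x[ok], y[ok])
        if (is.finite(r) && r > r_min)
          pairs[[length(pairs) + 1L]] <- list(
            a = cols[[i]]$label, b = cols[[j]]$label, key = cols[[i]]$key,
            r = r, x = x[ok], y = y[ok])
      }
    }
  }
  if (n_skipped)
    message(n_skipped, " candidate pair(s) skipped: fewer than 3 shared proteins")
  structure(pairs, class = "replicate_pairs")
}

#' @export
print.replicate_pairs <- function(x, ...) {
  cat(sprintf("replicate_pairs: %d matched pair(s)\n", length(x)))
  invisible(x)
}
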