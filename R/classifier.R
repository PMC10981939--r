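#' Assemble the complete feature matrix for the LLPS predictor
#'
#' Experimental features are the normalized filtrate fold changes in the
#' selected conditions; sequence features are disorder, nucleic-acid-binding
#' and composition columns. Only proteins present with finite values in
#' every source are kept, so the matrix has no missing values; the class-1
#' label (LLPS reference membership) is attached for every row.
#'
#' @param tables a [quant_table()] (or list) supplying the experimental
#'   feature columns.
#' @param seq_features data.frame with `protein_id` and numeric feature
#'   columns, e.g. from [generate_sequence_features()].
#' @param llps_ids protein ids of the LLPS reference (class 1).
#' @param conditions which condition columns to use; default all.
#' @return An object of class `feature_set`: `features` (complete numeric
#'   matrix), `labels` (logical, class 1), `protein_ids`.
#' @export
assemble_features <- function(tables, seq_features, llps_ids, conditions = NULL) {
  if (inherits(tables, "quant_table")) tables <- list(tables)
  qt <- if (length(tables) == 1L) tables[[1]] else cbind_quant(tables)
  cols <- conditions %||% colnames(qt$values)
  exp_mat <- qt$values[, cols, drop = FALSE]
  seq_mat <- as.matrix(seq_features[setdiff(names(seq_features), "protein_id")])
  storage.mode(seq_mat) <- "double"
  rownames(seq_mat) <- seq_features$protein_id
  ids <- intersect(rownames(exp_mat), rownames(seq_mat))
  x <- cbind(exp_mat[ids, , drop = FALSE], seq_mat[ids, , drop = FALSE])
  complete <- rowSums(!is.finite(x)) == 0
  x <- x[complete, , drop = FALSE]
  if (!nrow(x)) stop_invalid("empty intersection of feature sources")
  structure(list(features = x, labels = rownames(x) %in% llps_ids,
                 protein_ids = rownames(x)),
            class = "feature_set")
}

# Ridge-regularized two-class linear discriminant with shared covariance.
fit_ldc <- function(x, y, ridge = 1e-2) {
  x1 <- x[y, , drop = FALSE]; x0 <- x[!y, , drop = FALSE]
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  center <- function(m, mu) sweep(m, 2, mu)
  s <- (crossprod(center(x1, mu1)) + crossprod(center(x0, mu0))) / (nrow(x) - 2)
  s <- s + diag(ridge * mean(diag(s)) + 1e-12, ncol(x))
  w <- solve(s, mu1 - mu0)
  b <- -0.5 * sum(w * (mu1 + mu0)) + log(nrow(x1) / nrow(x0))
  list(w = w, b = b)
}

predict_ldc <- function(fit, x) plogis(drop(x %*% fit$w) + fit$b)

# Grow an rpart tree with the leaf-size constraint, then prune it back to at
# most `max_splits` splits via the complexity table.
fit_tree <- function(data, min_leaf, max_splits) {
  fit <- rpart::rpart(.y ~ ., data = data, method = "class",
                      control = rpart::rpart.control(
                        minbucket = min_leaf, minsplit = 2 * min_leaf,
                        cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0))
  cpt <- fit$cptable
  if (max(cpt[, "nsplit"]) > max_splits) {
    row <- max(which(cpt[, "nsplit"] <= max_splits))
    fit <- rpart::prune(fit, cp = cpt[row, "CP"])
  }
  fit
}

#' Train a bagged tree / linear-discriminant ensemble
#'
#' The ensemble alternates decision trees and linear discriminants, each fit
#' on a bootstrap resample of the training rows. Trees are constrained to a
#' minimum leaf size and to at most `floor(0.75 * n_features)` splits; the
#' linear discriminant is a two-class Gaussian discriminant with shared,
#' ridge-regularized covariance. The ensemble score of a protein is the mean
#' of the learners' class-1 probabilities (values in `[0,1]`).
#'
#' @param x numeric feature matrix (complete).
#' @param y logical class-1 labels; both classes must be present.
#' @param n_learners number of learners; default 500.
#' @param min_leaf minimum proteins per tree leaf; default 32.
#' @param max_splits maximum tree splits; default `floor(0.75 * ncol(x))`.
#' @param ridge ridge strength of the discriminant covariance.
#' @param seed integer seed.
#' @return An object of class `bagged_ensemble` with a [predict][predict.bagged_ensemble] method.
#' @export
train_bagged_ensemble <- function(x, y, n_learners = 500, min_leaf = 32,
                                  max_splits = floor(0.75 * ncol(x)),
                                  ridge = 1e-2, seed = NULL) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  y <- as.logical(y)
  if (length(unique(y)) < 2)
    stop_invalid("training set must contain both classes")
  with_seed(seed, {
    df_all <- as.data.frame(x)
    learners <- vector("list", n_learners)
    for (l in seq_len(n_learners)) {
      type <- if (l %% 2L == 1L) "tree" else "ldc"
      for (attempt in 1:10) {
        idx <- sample.int(nrow(x), replace = TRUE)
        if (length(unique(y[idx])) == 2) break
      }
      if (length(unique(y[idx])) < 2) {
        learners[[l]] <- list(type = "const", fit = mean(y))
      } else if (type == "tree") {
        d <- df_all[idx, , drop = FALSE]
        d$.y <- factor(y[idx], levels = c(FALSE, TRUE))
        learners[[l]] <- list(type = "tree",
                              fit = fit_tree(d, min_leaf, max_splits))
      } else {
        learners[[l]] <- list(type = "ldc",
                              fit = fit_ldc(x[idx, , drop = FALSE], y[idx], ridge))
      }
    }
    structure(list(learners = learners, feature_names = colnames(x),
                   min_leaf = min_leaf, max_splits = max_splits),
              class = "bagged_ensemble")
  })
}

#' Predict ensemble class-1 scores
#'
#' @param object a [train_bagged_ensemble()] model.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return numeric scores in `[0,1]`, one per row of `newdata`.
#' @export
predict.bagged_ensemble <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  newdata <- newdata[, object$feature_names, drop = FALSE]
  df <- as.data.frame(newdata)
  acc <- numeric(nrow(newdata))
  for (l in object$learners) {
    acc <- acc + switch(l$type,
      tree = predict(l$fit, df, type = "prob")[, "TRUE"],
      ldc = predict_ldc(l$fit, newdata),
      const = rep(l$fit, nrow(newdata)))
  }
  unname(acc / length(object$learners))
}

#' Cross-validated ensemble scores over random data partitions
#'
#' Trains `n_ensembles` ensembles, each on a random partition using
#' `class1_frac` of the class-1 proteins and `class2_frac` of the class-2
#' proteins, scores every protein with every ensemble, and reports each
#' protein's median score over the ensembles in which it was *not* a
#' training row. The training-membership matrix is recorded, so the
#' out-of-training guarantee is auditable: `n_eval` equals `n_ensembles`
#' minus the protein's training appearances, exactly.
#'
#' @param features a `feature_set` from [assemble_features()], or a matrix
#'   (then `labels` must be given).
#' @param labels logical class-1 labels (ignored if `features` is a
#'   `feature_set`).
#' @param n_ensembles number of partitions; default 600.
#' @param class1_frac,class2_frac training fractions per class.
#' @param n_learners learners per ensemble (see [train_bagged_ensemble()]).
#' @param seed integer seed; identical seeds reproduce scores exactly.
#' @param ... passed to [train_bagged_ensemble()].
#' @return An object of class `ensemble_scores`: `score` (named median
#'   out-of-training score; `NA` with a warning for proteins trained in every
#'   ensemble), `n_eval`, and the logical `trained` matrix
#'   (ensembles x proteins).
#' @export
crossval_scores <- function(features, labels = NULL, n_ensembles = 600,
                            class1_frac = 0.8, class2_frac = 0.1,
                            n_learners = 500, seed = NULL, ...) {
  if (inherits(features, "feature_set")) {
    labels <- features$labels
    x <- features$features
  } else x <- features
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  labels <- as.logical(labels)
  i1 <- which(labels); i2 <- which(!labels)
  n1 <- max(0L, floor(class1_frac * length(i1)))
  n2 <- max(0L, floor(class2_frac * length(i2)))
  if (n1 < 1 || n2 < 1)
    stop_invalid("training fractions leave an empty class")
  with_seed(seed, {
    scores <- matrix(NA_real_, n_ensembles, nrow(x))
    trained <- matrix(FALSE, n_ensembles, nrow(x),
                      dimnames = list(NULL, rownames(x)))
    for (e in seq_len(n_ensembles)) {
      tr <- c(sample(i1, n1), sample(i2, n2))
      model <- train_bagged_ensemble(x[tr, , drop = FALSE], labels[tr],
                                     n_learners = n_learners, seed = NULL, ...)
      s <- predict(model, x)
      s[tr] <- NA_real_
      scores[e, ] <- s
      trained[e, tr] <- TRUE
    }
    n_eval <- colSums(!trained)
    med <- apply(scores, 2, median, na.rm = TRUE)
    med[n_eval == 0] <- NA_real_
    if (any(n_eval == 0))
      warning(sum(n_eval == 0), " protein(s) were trained in every ensemble; score missing")
    structure(list(score = setNames(med, rownames(x)),
                   n_eval = setNames(n_eval, rownames(x)),
                   trained = trained, n_ensembles = n_ensembles),
              class = "ensemble_scores")
  })
}

#' Combine experiment- and sequence-trained scores by Euclidean distance
#'
#' With ensembles trained separately on experimental (`s_exp`) and sequence
#' (`s_seq`) features, the combined score of protein i is the Euclidean
#' distance to the best-scoring corner,
#' `d_i = sqrt((max(s_exp) - s_exp_i)^2 + (max(s_seq) - s_seq_i)^2)`,
#' negated so that higher always means more LLPS-like.
#'
#' @param s_exp,s_seq named numeric score vectors (shared ids used).
#' @return data.frame with `protein_id`, `s_exp`, `s_seq`, `s_combined`
#'   (= `-d`); orientation recorded in attribute `"orientation"`.
#' @export
combine_scores <- function(s_exp, s_seq) {
  if (inherits(s_exp, "ensemble_scores")) s_exp <- s_exp$score
  if (inherits(s_seq, "ensemble_scores")) s_seq <- s_seq$score
  ids <- intersect(names(s_exp), names(s_seq))
  ids <- ids[is.finite(s_exp[ids]) & is.finite(s_seq[ids])]
  if (!length(ids)) stop_invalid("no proteins with both scores")
  e <- s_exp[ids]; q <- s_seq[ids]
  d <- sqrt((max(e) - e)^2 + (max(q) - q)^2)
  out <- data.frame(protein_id = ids, s_exp = unname(e), s_seq = unname(q),
                    s_combined = -unname(d), stringsAsFactors = FALSE)
  attr(out, "orientation") <- "higher = more LLPS-like"
  out
}
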