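#' Bundle sites, windows and feature blocks for one kinase group
#'
#' A kinase dataset holds the positive and negative sites of one kinase
#' group together with their raw feature material: the sequence windows
#' (kept as strings so the positional weighted matrix can be re-estimated
#' on training folds only) and the precomputed per-site feature blocks.
#' The `aac`, `asa` and `ss` blocks depend only on the site itself; the
#' `pwm` block is encoded at training time from the fold's positive
#' windows; the `spatial` block comes from the mapped 3D structure.
#'
#' @param group Kinase group name.
#' @param sites Site data frame ([phospho_sites()]) with a `label` column
#'   containing both classes.
#' @param windows Character vector of sequence windows, one per site row.
#' @param blocks Named list of numeric matrices (`aac`, `asa`, `ss`,
#'   `spatial`), each with one row per site; blocks not needed by the
#'   preset may be omitted.
#' @param preset Feature preset (see [preset_blocks()]).
#' @return Object of class `kinase_dataset`.
#' @export
kinase_dataset <- function(group, sites, windows, blocks = list(),
                           preset = c("combined", "sequence_only",
                                      "structure_only")) {
  preset <- match.arg(preset)
  n <- nrow(sites)
  stopifnot(length(windows) == n)
  if (!all(sites$label %in% c("positive", "negative"))) {
    stop("site labels must be 'positive'/'negative'", call. = FALSE)
  }
  key <- paste(sites$protein_id, sites$position)
  dup <- intersect(key[sites$label == "positive"],
                   key[sites$label == "negative"])
  if (length(dup)) {
    stop("site(s) appear in both classes: ",
         paste(utils::head(dup, 3L), collapse = "; "), call. = FALSE)
  }
  need <- setdiff(preset_blocks(preset), "pwm")
  missing <- setdiff(need, names(blocks))
  if (length(missing)) {
    stop("preset '", preset, "' requires feature block(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (b in need) {
    blocks[[b]] <- as.matrix(blocks[[b]])
    if (nrow(blocks[[b]]) != n) {
      stop("block '", b, "' has ", nrow(blocks[[b]]), " rows for ", n,
           " sites", call. = FALSE)
    }
    colnames(blocks[[b]]) <- paste0(b, ".", seq_len(ncol(blocks[[b]])))
  }
  structure(list(group = group, sites = sites, windows = windows,
                 blocks = blocks[need], preset = preset),
            class = "kinase_dataset")
}

#' @export
print.kinase_dataset <- function(x, ...) {
  cat(sprintf("<kinase_dataset> %s [%s]: %d positives, %d negatives\n",
              x$group, x$preset, sum(x$sites$label == "positive"),
              sum(x$sites$label == "negative")))
  invisible(x)
}

# Subset a kinase_dataset by row indices.
dataset_subset <- function(dataset, idx) {
  dataset$sites <- dataset$sites[idx, , drop = FALSE]
  dataset$windows <- dataset$windows[idx]
  dataset$blocks <- lapply(dataset$blocks, function(m) m[idx, , drop = FALSE])
  dataset
}

# Assemble the numeric feature matrix for a dataset under its preset.
# `pwm` is required whenever the preset includes the pwm block.
dataset_feature_matrix <- function(dataset, pwm = NULL) {
  parts <- list()
  if ("pwm" %in% preset_blocks(dataset$preset)) {
    if (is.null(pwm)) stop("a PWM is required to encode this preset",
                           call. = FALSE)
    enc <- t(vapply(dataset$windows, encode_window_pwm,
                    numeric(ncol(pwm)), pwm = pwm))
    colnames(enc) <- paste0("pwm.", seq_len(ncol(enc)))
    rownames(enc) <- NULL
    parts$pwm <- enc
  }
  mat <- do.call(cbind, c(parts, dataset$blocks))
  rownames(mat) <- NULL
  mat
}

dataset_labels <- function(dataset) {
  factor(dataset$sites$label, levels = c("negative", "positive"))
}

# Per-feature min-max scaling fit on a training matrix.
fit_minmax <- function(mat) {
  mins <- apply(mat, 2L, min)
  rng <- apply(mat, 2L, max) - mins
  rng[rng == 0] <- 1
  list(min = mins, range = rng)
}

apply_minmax <- function(mat, scaling) {
  sweep(sweep(mat, 2L, scaling$min, "-"), 2L, scaling$range, "/")
}

#' Train an RBF-kernel SVM on a kinase dataset
#'
#' Features are min-max scaled to `[0, 1]` with parameters fitted on the
#' training data and stored for prediction. When the preset includes the
#' PWM block, the positional weighted matrix is built from the training
#' positives (unless supplied). The classifier is libsvm's C-classification
#' with the radial basis kernel `exp(-gamma * ||Si - Sj||^2)`.
#'
#' @param dataset A [kinase_dataset()] with at least 2 sites per class.
#' @param C Cost parameter (> 0).
#' @param gamma RBF width (> 0); default `1 / n_features`.
#' @param seed Integer seed (training is deterministic given data and seed).
#' @param pwm Optional pre-built [build_pwm()] matrix.
#' @return Object of class `phos_svm` holding the fitted model, the PWM,
#'   the scaling parameters and the feature schema.
#' @export
train_svm <- function(dataset, C = 1, gamma = NULL, seed = 1L, pwm = NULL) {
  stopifnot(C > 0)
  y <- dataset_labels(dataset)
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("training needs at least 2 examples in each class", call. = FALSE)
  }
  if (is.null(pwm) && "pwm" %in% preset_blocks(dataset$preset)) {
    pwm <- build_pwm(dataset$windows[dataset$sites$label == "positive"])
  }
  x <- dataset_feature_matrix(dataset, pwm)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  stopifnot(gamma > 0)
  scaling <- fit_minmax(x)
  xs <- apply_minmax(x, scaling)
  set.seed(seed)
  fit <- e1071::svm(x = xs, y = y, type = "C-classification",
                    kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, pwm = pwm, scaling = scaling,
                 schema = colnames(x), preset = dataset$preset,
                 group = dataset$group, C = C, gamma = gamma,
                 train_keys = paste(dataset$sites$protein_id,
                                    dataset$sites$position)),
            class = "phos_svm")
}

#' @export
print.phos_svm <- function(x, ...) {
  cat(sprintf("<phos_svm> group %s [%s]: RBF SVM (C=%g, gamma=%g), %d features\n",
              x$group, x$preset, x$C, x$gamma, length(x$schema)))
  invisible(x)
}

#' Predict site labels with a trained SVM
#'
#' @param object A `phos_svm` from [train_svm()].
#' @param newdata A [kinase_dataset()] with the same preset, or a numeric
#'   feature matrix matching the model's schema.
#' @param ... Unused.
#' @return Factor of predicted labels (`negative`/`positive`).
#' @export
predict.phos_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "kinase_dataset")) {
    if (newdata$preset != object$preset) {
      stop("dataset preset '", newdata$preset,
           "' does not match model preset '", object$preset, "'",
           call. = FALSE)
    }
    x <- dataset_feature_matrix(newdata, object$pwm)
  } else {
    x <- as.matrix(newdata)
  }
  if (ncol(x) != length(object$schema) ||
      !identical(colnames(x), object$schema)) {
    stop("feature schema mismatch: model expects ",
         length(object$schema), " features (",
         paste(utils::head(object$schema, 3L), collapse = ", "),
         ", ...)", call. = FALSE)
  }
  stats::predict(object$fit, apply_minmax(x, object$scaling))
}

# ---- metrics ---------------------------------------------------------------

#' Performance metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/(TP+FP+TN+FN)` and precision `TP/(TP+FP)`. A metric whose
#' denominator is zero is reported as `NA`, never as 0.
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return Object of class `performance_report`: list with the four counts
#'   and `sn`, `sp`, `acc`, `pre`.
#' @export
compute_metrics <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 sn = ratio(TP, TP + FN),
                 sp = ratio(TN, TN + FP),
                 acc = ratio(TP + TN, sum(counts)),
                 pre = ratio(TP, TP + FP)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> TP=%d FP=%d TN=%d FN=%d | Sn=%.3f Sp=%.3f Acc=%.3f Pre=%.3f",
              x$TP, x$FP, x$TN, x$FN, x$sn, x$sp, x$acc, x$pre))
  if (!is.null(x$repeats)) {
    cat(sprintf(" | %d repeats (Acc sd %.3f)", x$repeats, x$acc_sd))
  }
  cat("\n")
  invisible(x)
}

confusion_counts <- function(truth, predicted) {
  list(TP = sum(truth == "positive" & predicted == "positive"),
       FP = sum(truth == "negative" & predicted == "positive"),
       TN = sum(truth == "negative" & predicted == "negative"),
       FN = sum(truth == "positive" & predicted == "negative"))
}

# ---- cross-validation ------------------------------------------------------

# Number of folds under the automatic protocol rule: 5-fold for groups with
# at least 30 substrate sites, jackknife (one fold per positive) below that.
resolve_folds <- function(folds, n_pos) {
  if (identical(folds, "auto")) {
    if (n_pos >= 30L) 5L else n_pos
  } else {
    as.integer(folds)
  }
}

#' Balanced, repeated cross-validation of a kinase dataset
#'
#' Implements the evaluation protocol for per-kinase models: in every
#' repeat the negatives are randomly subsampled to match the positives
#' (1:1 balance), the balanced set is split into folds — 5 stratified folds
#' for groups with 30 or more positive sites, otherwise a jackknife in
#' which each fold holds out one positive with its matched negative — and
#' each fold is predicted by a model trained on the remaining folds. The
#' positional weighted matrix and the min-max scaling are re-fitted on each
#' training fold so no held-out site informs its own encoding. Confusion
#' counts are pooled within a repeat and the metrics averaged over repeats.
#'
#' @param dataset A [kinase_dataset()].
#' @param folds `"auto"` (protocol rule) or an integer fold count.
#' @param repeats Number of repeats (default 10).
#' @param C,gamma SVM hyperparameters (see [train_svm()]).
#' @param seed Master seed; per-repeat seeds are derived from it, so a rerun
#'   with the same seed is bit-identical.
#' @return A `performance_report` whose metrics are means over repeats, with
#'   extra fields `repeats`, `folds`, `acc_sd` and `per_repeat` (data frame
#'   of per-repeat pooled counts and metrics).
#' @export
cross_validate <- function(dataset, folds = "auto", repeats = 10L,
                           C = 1, gamma = NULL, seed = 1L) {
  lab <- dataset$sites$label
  pos_idx <- which(lab == "positive")
  neg_idx <- which(lab == "negative")
  n_pos <- length(pos_idx)
  if (length(neg_idx) < n_pos) {
    stop("balanced cross-validation needs at least as many negatives (",
         length(neg_idx), ") as positives (", n_pos, ")", call. = FALSE)
  }
  k <- resolve_folds(folds, n_pos)
  if (n_pos < k || n_pos < 2L) {
    stop("too few positives (", n_pos, ") for ", k, "-fold cross-validation",
         call. = FALSE)
  }
  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max, repeats)
  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(repeat_seeds[r])
    neg_bal <- sample(neg_idx, n_pos)
    pos_fold <- sample(rep_len(seq_len(k), n_pos))
    neg_fold <- if (k == n_pos) pos_fold else
      sample(rep_len(seq_len(k), n_pos))
    counts <- list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (f in seq_len(k)) {
      test_rows <- c(pos_idx[pos_fold == f], neg_bal[neg_fold == f])
      train_rows <- c(pos_idx[pos_fold != f], neg_bal[neg_fold != f])
      model <- train_svm(dataset_subset(dataset, train_rows),
                         C = C, gamma = gamma, seed = repeat_seeds[r])
      pred <- predict(model, dataset_subset(dataset, test_rows))
      cc <- confusion_counts(lab[test_rows], as.character(pred))
      counts <- Map(`+`, counts, cc)
    }
    m <- compute_metrics(counts$TP, counts$FP, counts$TN, counts$FN)
    per_repeat[[r]] <- data.frame(repeat_id = r, TP = m$TP, FP = m$FP,
                                  TN = m$TN, FN = m$FN, sn = m$sn,
                                  sp = m$sp, acc = m$acc, pre = m$pre)
  }
  per_repeat <- do.call(rbind, per_repeat)
  out <- compute_metrics(sum(per_repeat$TP), sum(per_repeat$FP),
                         sum(per_repeat$TN), sum(per_repeat$FN))
  # headline metrics are the means of per-repeat pooled ratios
  out$sn <- mean(per_repeat$sn)
  out$sp <- mean(per_repeat$sp)
  out$acc <- mean(per_repeat$acc)
  out$pre <- mean(per_repeat$pre, na.rm = TRUE)
  out$acc_sd <- stats::sd(per_repeat$acc)
  out$repeats <- repeats
  out$folds <- k
  out$jackknife <- (k == n_pos)
  out$per_repeat <- per_repeat
  out
}

#' Evaluate a trained model on an independent test set
#'
#' Negatives are subsampled so the test set has a 1:2 positive:negative
#' ratio (the convention for comparison with published site predictors).
#' Any overlap between test sites and the model's training sites is an
#' error.
#'
#' @param model A `phos_svm`.
#' @param test_dataset A [kinase_dataset()] disjoint from the training data
#'   by (protein_id, position).
#' @param ratio Positive:negative ratio as `"1:k"` (default `"1:2"`).
#' @param seed Seed for the negative subsample.
#' @return A `performance_report`.
#' @export
independent_test <- function(model, test_dataset, ratio = "1:2", seed = 1L) {
  key <- paste(test_dataset$sites$protein_id, test_dataset$sites$position)
  overlap <- intersect(key, model$train_keys)
  if (length(overlap)) {
    stop("test set overlaps the training set at ", length(overlap),
         " site(s): ", paste(utils::head(overlap, 5L), collapse = "; "),
         call. = FALSE)
  }
  parts <- as.integer(strsplit(ratio, ":", fixed = TRUE)[[1]])
  if (length(parts) != 2L || any(is.na(parts)) || parts[1] != 1L) {
    stop("ratio must be of the form '1:k'", call. = FALSE)
  }
  k <- parts[2]
  lab <- test_dataset$sites$label
  pos_idx <- which(lab == "positive")
  neg_idx <- which(lab == "negative")
  n_neg <- k * length(pos_idx)
  if (length(neg_idx) < n_neg) {
    stop("test set has too few negatives (", length(neg_idx), ") for a ",
         ratio, " ratio with ", length(pos_idx), " positives", call. = FALSE)
  }
  set.seed(seed)
  rows <- c(pos_idx, sample(neg_idx, n_neg))
  pred <- predict(model, dataset_subset(test_dataset, rows))
  cc <- confusion_counts(lab[rows], as.character(pred))
  compute_metrics(cc$TP, cc$FP, cc$TN, cc$FN)
}

#' Cross-classification specificity matrix between kinase groups
#'
#' Entry `[m, g]` is the specificity of group-m's model on group-g's true
#' positive sites treated as negatives: the fraction of group-g positives
#' that model m rejects. Low off-diagonal values reveal substrate-motif
#' confusion between kinase groups; the diagonal is `NA` (self).
#'
#' @param models_by_group Named list of `phos_svm` models.
#' @param datasets_by_group Named list of [kinase_dataset()] objects with
#'   the same names and a shared feature schema.
#' @return Numeric matrix (models as rows, datasets as columns) of class
#'   `cross_spec_matrix`.
#' @export
cross_classification_matrix <- function(models_by_group, datasets_by_group) {
  groups <- names(models_by_group)
  if (!identical(sort(groups), sort(names(datasets_by_group)))) {
    stop("models and datasets must cover the same groups", call. = FALSE)
  }
  sp <- matrix(NA_real_, length(groups), length(groups),
               dimnames = list(model = groups, data = groups))
  for (m in groups) {
    for (g in groups) {
      if (g == m) next
      ds <- datasets_by_group[[g]]
      pos <- dataset_subset(ds, which(ds$sites$label == "positive"))
      pred <- predict(models_by_group[[m]], pos)
      sp[m, g] <- mean(pred == "negative")
    }
  }
  class(sp) <- c("cross_spec_matrix", class(sp))
  sp
}

#' Grid search over SVM hyperparameters
#'
#' Evaluates every (C, gamma) pair with an inner balanced cross-validation
#' and returns the pair with the highest mean accuracy; ties are broken by
#' smaller C, then smaller gamma, so the result does not depend on grid
#' ordering.
#'
#' @param dataset A [kinase_dataset()].
#' @param C_grid,gamma_grid Numeric vectors of candidate values.
#' @param seed Master seed (shared across grid points).
#' @param folds,repeats Inner cross-validation settings (default 3-fold,
#'   1 repeat).
#' @return List with `C`, `gamma` and the winning `report`.
#' @export
grid_search <- function(dataset, C_grid = 2^seq(-2, 6, 2),
                        gamma_grid = 2^seq(-8, 0, 2), seed = 1L,
                        folds = 3L, repeats = 1L) {
  stopifnot(length(C_grid) > 0, length(gamma_grid) > 0)
  grid <- expand.grid(C = sort(unique(C_grid)),
                      gamma = sort(unique(gamma_grid)))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    rep_i <- cross_validate(dataset, folds = folds, repeats = repeats,
                            C = grid$C[i], gamma = grid$gamma[i],
                            seed = seed)
    cand <- list(C = grid$C[i], gamma = grid$gamma[i], report = rep_i)
    if (is.null(best) || rep_i$acc > best$report$acc ||
        (rep_i$acc == best$report$acc &&
         (cand$C < best$C || (cand$C == best$C && cand$gamma < best$gamma)))) {
      best <- cand
    }
  }
  best
}

#' Write a performance report as TSV and JSON
#'
#' @param report A `performance_report`.
#' @param path Output path without extension; `.tsv` and `.json` are added.
#' @return The two paths, invisibly.
#' @export
write_performance_report <- function(report, path) {
  core <- data.frame(TP = report$TP, FP = report$FP, TN = report$TN,
                     FN = report$FN, sn = report$sn, sp = report$sp,
                     acc = report$acc, pre = report$pre)
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(core, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- unclass(report)
  payload$per_repeat <- NULL
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(tsv = tsv, json = json))
}
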