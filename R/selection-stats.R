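#' F-score of a single feature
#'
#' Between-class versus within-class dispersion ratio for one feature
#' column:
#' \deqn{F = \frac{(\bar{x}^{(+)} - \bar{x})^2 + (\bar{x}^{(-)} - \bar{x})^2}
#'   {\frac{1}{n_+ - 1}\sum_k (x^{(+)}_k - \bar{x}^{(+)})^2 +
#'    \frac{1}{n_- - 1}\sum_k (x^{(-)}_k - \bar{x}^{(-)})^2}}
#' where \eqn{\bar{x}} is the mean over the pooled positive and negative
#' values. Larger scores mark features that separate the classes better.
#' Degenerate cases: zero denominator with zero numerator gives 0; zero
#' denominator with positive numerator gives `Inf` (so constant-but-shifted
#' features still rank ahead of uninformative ones).
#'
#' @param pos_values,neg_values Numeric vectors of the feature in each
#'   class; both need at least 2 values (sample variances).
#' @return Non-negative number (possibly `Inf`).
#' @export
f_score <- function(pos_values, neg_values) {
  n_pos <- length(pos_values)
  n_neg <- length(neg_values)
  if (n_pos < 2L || n_neg < 2L) {
    stop("f_score needs at least 2 values per class (got ", n_pos, " / ",
         n_neg, ")", call. = FALSE)
  }
  if (!all(is.finite(pos_values)) || !all(is.finite(neg_values))) {
    stop("f_score requires finite values", call. = FALSE)
  }
  m_all <- mean(c(pos_values, neg_values))
  m_pos <- mean(pos_values)
  m_neg <- mean(neg_values)
  num <- (m_pos - m_all)^2 + (m_neg - m_all)^2
  den <- sum((pos_values - m_pos)^2) / (n_pos - 1L) +
    sum((neg_values - m_neg)^2) / (n_neg - 1L)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}

#' Rank feature columns by F-score
#'
#' Computes [f_score()] column-wise for two feature matrices sharing one
#' column schema and returns the columns in decreasing score order; ties are
#' broken by column index.
#'
#' @param feature_matrix_pos,feature_matrix_neg Numeric matrices (rows =
#'   sites, columns = features) with identical column names (or identical
#'   column counts when unnamed).
#' @return Data frame with columns `feature_id`, `f_score`, `rank`, ordered
#'   by rank.
#' @export
rank_features_by_fscore <- function(feature_matrix_pos, feature_matrix_neg) {
  feature_matrix_pos <- as.matrix(feature_matrix_pos)
  feature_matrix_neg <- as.matrix(feature_matrix_neg)
  if (ncol(feature_matrix_pos) != ncol(feature_matrix_neg) ||
      !identical(colnames(feature_matrix_pos),
                 colnames(feature_matrix_neg))) {
    stop("positive and negative feature matrices must share one column schema",
         call. = FALSE)
  }
  ids <- colnames(feature_matrix_pos)
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(feature_matrix_pos)))
  scores <- vapply(seq_len(ncol(feature_matrix_pos)), function(j) {
    f_score(feature_matrix_pos[, j], feature_matrix_neg[, j])
  }, 0)
  ord <- order(-scores, seq_along(scores))
  data.frame(feature_id = ids[ord], f_score = scores[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Write an F-score ranking as TSV
#'
#' @param ranking Data frame from [rank_features_by_fscore()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fscore_table <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
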