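#' Mean-substitution (drop-out) feature importance
#'
#' For each feature, its values are replaced by the feature's mean and
#' the model's Cox partial log-likelihood is recomputed; the importance
#' score is the original log-likelihood minus the degraded one. A feature
#' the network ignores (all-zero incoming weights, or an already-constant
#' column) scores exactly zero. The forward pass is deterministic
#' (dropout off).
#'
#' The substitution mean should come from the data the model was trained
#' on; by default the column means of `x` are used, so pass the training
#' matrix (or supply training means via `means` when scoring other data).
#'
#' @param object a fitted [coxnnet()] model.
#' @param x feature matrix the importance is evaluated on.
#' @param time,status matching survival response.
#' @param means optional named vector of substitution means (defaults to
#'   `colMeans(x)`).
#' @return data.frame (`feature`, `score`, `rank`) sorted by decreasing
#'   score; ties in score are ordered lexicographically by feature name.
#' @export
feature_importance <- function(object, x, time, status, means = NULL) {
  stopifnot(inherits(object, "coxnnet"))
  x <- as.matrix(x)
  n <- check_survival(time, status)
  if (nrow(x) != n)
    stop("feature matrix and survival data disagree on sample count",
         call. = FALSE)
  if (is.null(means)) means <- colMeans(x)
  if (length(means) != ncol(x))
    stop("`means` must supply one value per feature", call. = FALSE)

  ll0 <- cox_pll(predict(object, x), time, status)
  score <- vapply(seq_len(ncol(x)), function(j) {
    xj <- x
    xj[, j] <- means[j]
    ll0 - cox_pll(predict(object, xj), time, status)
  }, numeric(1))

  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(x)))
  ord <- order(-score, nm)
  out <- data.frame(feature = nm[ord], score = score[ord],
                    rank = seq_along(ord), row.names = NULL)
  out
}

#' Top-k features by importance
#'
#' First `k` rows of an importance table (already sorted by decreasing
#' score with lexicographic tie order, so the selection is deterministic).
#'
#' @param table a data.frame from [feature_importance()].
#' @param k number of features to keep, 0 <= k <= nrow(table).
#' @return the first `k` rows.
#' @export
top_features <- function(table, k) {
  stopifnot(is.data.frame(table), k >= 0)
  if (k > nrow(table))
    stop("k (", k, ") exceeds the number of features (", nrow(table), ")",
         call. = FALSE)
  table[seq_len(k), , drop = FALSE]
}
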