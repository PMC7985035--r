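#' Grid search over the L2 penalty under k-fold cross-validation
#'
#' For each candidate penalty, trains on k-1 folds and scores the held-out
#' fold; the selection criterion is the mean validation Cox partial
#' log-likelihood per event (the training objective itself); validation
#' concordance is reported alongside. Fold assignment is a seeded random
#' permutation, so the partition of samples is reproducible from `seed`.
#' A fold whose validation part contains no events is reshuffled once
#' (with `seed + 1`); if the problem persists the function errors.
#'
#' @inheritParams coxnnet
#' @param lambda_grid candidate L2 penalties (default: five values
#'   log-spaced over 1e-4 .. 1).
#' @param folds number of CV folds (default 5).
#' @param seed seed controlling fold assignment and, offset per grid
#'   point and fold, network initialization.
#' @param ... further arguments passed to [coxnnet()] (dropout, epochs, ...).
#' @return list with `best_lambda`, `scores` (data.frame: lambda,
#'   mean_val_pll, mean_val_cindex), and `fold` (the fold id per sample).
#' @export
coxnnet_cv <- function(x, time, status,
                       lambda_grid = 10^seq(-4, 0, length.out = 5),
                       folds = 5, seed = 1, ...) {
  x <- as.matrix(x)
  n <- check_survival(time, status)
  stopifnot(length(lambda_grid) >= 1, folds >= 2, n >= 2 * folds)

  assign_folds <- function(s) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(s)
    sample(rep_len(seq_len(folds), n))
  }
  fold <- assign_folds(seed)
  if (any(tapply(status, fold, sum) == 0)) {
    fold <- assign_folds(seed + 1L)
    if (any(tapply(status, fold, sum) == 0))
      stop("a cross-validation fold has no events even after reshuffling; ",
           "reduce `folds` or supply more events", call. = FALSE)
  }

  scores <- data.frame(lambda = lambda_grid,
                       mean_val_pll = NA_real_,
                       mean_val_cindex = NA_real_)
  for (gi in seq_along(lambda_grid)) {
    pll <- cidx <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fold != k
      fit <- coxnnet(x[tr, , drop = FALSE], time[tr], status[tr],
                     lambda = lambda_grid[gi],
                     seed = seed + 1000L * gi + k, ...)
      eta_val <- predict(fit, x[!tr, , drop = FALSE])
      pll[k] <- cox_pll(eta_val, time[!tr], status[!tr]) / sum(status[!tr])
      cidx[k] <- tryCatch(cindex(eta_val, time[!tr], status[!tr]),
                          error = function(e) NA_real_)
    }
    scores$mean_val_pll[gi] <- mean(pll)
    scores$mean_val_cindex[gi] <- mean(cidx, na.rm = TRUE)
  }
  best <- which.max(scores$mean_val_pll)
  list(best_lambda = lambda_grid[best], scores = scores, fold = fold)
}

#' Repeated hold-out evaluation of a (possibly multi-modal) network
#'
#' The full evaluation protocol: repeatedly split the samples into a
#' training fraction and a held-out test set; on the training split run
#' the complete modelling procedure (grid-search CV for the penalty, then
#' refit — for multi-modal input the entire two-stage procedure,
#' first-stage models included, runs inside the training split so no test
#' information leaks); then score the test split. Risk groups on the test
#' set are cut at the TRAINING-set median prognostic index — a threshold
#' learned on test data would leak — and compared by the log-rank test.
#'
#' A split whose test part has fewer than 2 events is discarded and
#' redrawn with the next seed (with a warning).
#'
#' @param x feature matrix, or a named list of >= 2 per-modality matrices
#'   sharing row names (triggers the two-stage procedure).
#' @inheritParams coxnnet_cv
#' @param train_fraction fraction of samples used for training (default 0.8).
#' @param repetitions number of random splits (default 20).
#' @return data.frame with one row per repetition: seed used,
#'   `train_cindex`, `test_cindex`, `test_logrank_p`, `best_lambda`
#'   (comma-separated for multi-modal fits). Attribute `"summary"` holds
#'   medians and IQRs.
#' @export
coxnnet_holdout <- function(x, time, status, train_fraction = 0.8,
                            repetitions = 20,
                            lambda_grid = 10^seq(-4, 0, length.out = 5),
                            folds = 5, seed = 1, ...) {
  stopifnot(train_fraction > 0, train_fraction < 1, repetitions >= 1)
  multimodal <- is.list(x) && !is.data.frame(x)
  n <- if (multimodal) nrow(x[[1]]) else nrow(x)
  check_survival(time, status)
  n_train <- round(train_fraction * n)
  if (n_train < 2 * folds || n - n_train < 2)
    stop("dataset too small for this train fraction", call. = FALSE)

  rows <- vector("list", repetitions)
  s <- seed
  for (r in seq_len(repetitions)) {
    tries <- 0L
    repeat {
      old <- .save_rng()
      set.seed(s)
      tr_idx <- sample(n, n_train)
      .restore_rng(old)
      te_idx <- setdiff(seq_len(n), tr_idx)
      if (sum(status[te_idx]) >= 2 && sum(status[tr_idx]) >= folds) break
      warning("degenerate split at seed ", s, "; redrawing with next seed")
      s <- s + 1L
      tries <- tries + 1L
      if (tries > 100L)
        stop("could not draw a split with enough events in both parts; ",
             "too few events for this train fraction", call. = FALSE)
    }
    sub <- function(m, i) m[i, , drop = FALSE]
    if (multimodal) {
      fit <- coxnnet_twostage(lapply(x, sub, tr_idx), time[tr_idx],
                              status[tr_idx], lambda_grid = lambda_grid,
                              folds = folds, seed = s, ...)
      lam <- paste(fit$lambda, collapse = ",")
    } else {
      cv <- coxnnet_cv(sub(x, tr_idx), time[tr_idx], status[tr_idx],
                       lambda_grid = lambda_grid, folds = folds, seed = s, ...)
      fit <- coxnnet(sub(x, tr_idx), time[tr_idx], status[tr_idx],
                     lambda = cv$best_lambda, seed = s, ...)
      lam <- as.character(cv$best_lambda)
    }
    eta_tr <- predict(fit, if (multimodal) lapply(x, sub, tr_idx) else sub(x, tr_idx))
    eta_te <- predict(fit, if (multimodal) lapply(x, sub, te_idx) else sub(x, te_idx))
    thr <- stats::median(eta_tr)
    grp <- dichotomize(eta_te, threshold = thr)
    lr_p <- if (nlevels(droplevels(grp$labels)) == 2L)
      logrank_test(time[te_idx], status[te_idx], grp$labels)$p_value
    else NA_real_
    rows[[r]] <- data.frame(
      repetition = r, seed = s,
      train_cindex = cindex(eta_tr, time[tr_idx], status[tr_idx]),
      test_cindex = cindex(eta_te, time[te_idx], status[te_idx]),
      test_logrank_p = lr_p,
      best_lambda = lam
    )
    s <- s + 1L
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- data.frame(
    metric = c("train_cindex", "test_cindex"),
    median = c(stats::median(out$train_cindex), stats::median(out$test_cindex)),
    iqr = c(stats::IQR(out$train_cindex), stats::IQR(out$test_cindex))
  )
  out
}
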