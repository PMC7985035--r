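#' Two-stage multi-modal network fusion
#'
#' Stage one fits an independent [coxnnet()] model per data modality
#' (penalty chosen by grid-search CV within the supplied data). Stage two
#' extracts each model's hidden-node activations — its learned surrogate
#' features — concatenates them into one matrix, and fits a fresh network
#' on it, again with its own square-root-width hidden layer and
#' grid-search CV. The fused activations are z-scored by the stage-two
#' fit's own standardization (tanh outputs are bounded but not centred).
#'
#' Leakage contract: every model, first and second stage, is trained on
#' exactly the samples passed here. When evaluating on held-out data, call
#' this function on the training split only (as [coxnnet_holdout()] does)
#' and use [predict.coxnnet_twostage()] on the test split.
#'
#' @param xlist named list of >= 2 numeric matrices, one per modality,
#'   with identical row counts; if all carry row names the sample sets
#'   are intersected and aligned by name.
#' @inheritParams coxnnet_cv
#' @param ... passed to [coxnnet()] for every stage (dropout, epochs, ...).
#' @return object of class `"coxnnet_twostage"`: `stage1` (list of fits),
#'   `stage2`, `modalities`, `lambda` (chosen penalties, stage-1 then
#'   stage-2), `hidden_widths`.
#' @examples
#' d <- simulate_modalities(n = 120, p = 16, seed = 2)
#' fit <- coxnnet_twostage(list(img = d$x_a, expr = d$x_b), d$time, d$status,
#'                         lambda_grid = 0.01, epochs = 50, seed = 1)
#' @export
coxnnet_twostage <- function(xlist, time, status,
                             lambda_grid = 10^seq(-4, 0, length.out = 5),
                             folds = 5, seed = 1, ...) {
  if (!is.list(xlist) || length(xlist) < 2L)
    stop("two-stage fusion needs a list of at least two modality matrices",
         call. = FALSE)
  if (is.null(names(xlist)) || any(names(xlist) == ""))
    names(xlist) <- paste0("modality", seq_along(xlist))
  xlist <- lapply(xlist, as.matrix)

  has_names <- all(vapply(xlist, function(m) !is.null(rownames(m)), logical(1)))
  if (has_names) {
    shared <- Reduce(intersect, lapply(xlist, rownames))
    if (length(shared) == 0)
      stop("no samples shared across modalities (empty id intersection)",
           call. = FALSE)
    if (length(shared) < nrow(xlist[[1]]) || length(shared) != length(time))
      stop("modalities and survival data must cover the same samples; ",
           "align them with read_survival_data() first", call. = FALSE)
    xlist <- lapply(xlist, function(m) m[shared, , drop = FALSE])
  } else {
    ns <- vapply(xlist, nrow, integer(1))
    if (length(unique(ns)) != 1L)
      stop("modality matrices have differing row counts and no row names ",
           "to intersect on", call. = FALSE)
  }
  check_survival(time, status)

  stage1 <- vector("list", length(xlist)); names(stage1) <- names(xlist)
  lam <- numeric(0)
  for (m in seq_along(xlist)) {
    cv <- coxnnet_cv(xlist[[m]], time, status, lambda_grid = lambda_grid,
                     folds = folds, seed = seed + 100L * m, ...)
    stage1[[m]] <- coxnnet(xlist[[m]], time, status, lambda = cv$best_lambda,
                           seed = seed + 100L * m, ...)
    lam <- c(lam, cv$best_lambda)
  }
  H <- fuse_hidden(stage1, xlist)
  cv2 <- coxnnet_cv(H, time, status, lambda_grid = lambda_grid,
                    folds = folds, seed = seed, ...)
  stage2 <- coxnnet(H, time, status, lambda = cv2$best_lambda,
                    seed = seed, ...)
  structure(list(
    stage1 = stage1, stage2 = stage2, modalities = names(xlist),
    lambda = c(lam, stage2 = cv2$best_lambda),
    hidden_widths = vapply(stage1, function(f) f$hidden, integer(1))
  ), class = "coxnnet_twostage")
}

#' Fuse hidden-layer activations across modalities
#'
#' Builds the stage-two input matrix: hidden activations of each
#' first-stage model on its modality, concatenated column-wise with
#' provenance column names `<modality>.node<k>`.
#'
#' @param models named list of fitted `coxnnet` models.
#' @param xlist named list of matching feature matrices.
#' @return numeric matrix, samples x sum of hidden widths.
#' @export
fuse_hidden <- function(models, xlist) {
  stopifnot(length(models) == length(xlist))
  H <- mapply(function(f, x, nm) {
    g <- extract_hidden(f, x)
    colnames(g) <- paste0(nm, ".", colnames(g))
    g
  }, models, xlist, names(models), SIMPLIFY = FALSE)
  do.call(cbind, H)
}

#' @rdname coxnnet_twostage
#' @param object fitted two-stage model.
#' @param newdata named list of per-modality matrices (same modalities and
#'   columns as training).
#' @export
predict.coxnnet_twostage <- function(object, newdata, ...) {
  if (!is.list(newdata) || length(newdata) != length(object$stage1))
    stop("`newdata` must be a list with one matrix per modality (",
         paste(object$modalities, collapse = ", "), ")", call. = FALSE)
  if (!is.null(names(newdata)))
    newdata <- newdata[object$modalities]
  predict(object$stage2, fuse_hidden(object$stage1, newdata))
}

#' @export
print.coxnnet_twostage <- function(x, ...) {
  cat("Two-stage neural-network Cox model\n")
  cat("  modalities:", paste(sprintf("%s (p=%d, h=%d)", x$modalities,
      vapply(x$stage1, function(f) f$p, integer(1)), x$hidden_widths),
      collapse = ", "), "\n")
  cat(sprintf("  stage 2: %d fused nodes -> %d hidden -> PH output\n",
              x$stage2$p, x$stage2$hidden))
  cat("  chosen L2 penalties:", paste(signif(x$lambda, 3), collapse = ", "),
      "\n")
  invisible(x)
}
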