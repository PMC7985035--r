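#' Fit a neural-network Cox proportional-hazards model
#'
#' Trains a fully connected two-layer network: one hidden layer of width
#' `hidden` (default: floor of the square root of the number of input
#' features, minimum 1) feeding a linear proportional-hazards output node
#' with no bias (the prognostic index is only identified up to an
#' additive constant). The objective is the Cox partial log-likelihood
#' (Breslow ties) divided by the number of events, minus an L2 penalty
#' `lambda` on all weights, maximized by full-batch gradient ascent with
#' a fixed learning rate. Regularization combines the L2 penalty with
#' inverted node dropout on the hidden layer: each epoch an independent
#' mask drops hidden nodes with probability `dropout` and rescales the
#' survivors by 1/(1 - dropout), so inference needs no rescaling.
#'
#' Features are z-scored column-wise by default using means/SDs of the
#' training data (stored in the fit and re-applied by `predict`);
#' constant columns are centred and left unscaled. Everything random
#' (initialization, dropout masks) is driven by `seed`, so two fits with
#' identical inputs and seed are bit-identical. The caller's RNG state is
#' left untouched.
#'
#' @param x numeric feature matrix, samples in rows.
#' @param time,status survival response (times > 0; status 1 = event,
#'   0 = censored); at least one event required.
#' @param hidden hidden-layer width; `NULL` (default) = floor(sqrt(p)),
#'   minimum 1.
#' @param activation hidden nonlinearity, `"tanh"` (default) or
#'   `"identity"` (with `hidden = p` and `dropout = 0` the model class
#'   then contains linear Cox regression).
#' @param dropout hidden-node dropout rate in \[0, 1); default 0.7.
#' @param lambda L2 penalty on hidden and output weights (not biases).
#' @param learning_rate fixed gradient-ascent step; default 0.01.
#' @param epochs number of full-batch epochs; default 500.
#' @param standardize z-score features on the training data (default TRUE).
#' @param seed integer seed controlling init and dropout masks.
#' @return an object of class `"coxnnet"`; see [predict.coxnnet()],
#'   [extract_hidden()], [feature_importance()].
#' @examples
#' d <- simulate_survival(n = 80, p = 9, seed = 3)
#' fit <- coxnnet(d$x, d$time, d$status, epochs = 50, seed = 1)
#' cindex(predict(fit, d$x), d$time, d$status)
#' @export
coxnnet <- function(x, time, status, hidden = NULL,
                    activation = c("tanh", "identity"),
                    dropout = 0.7, lambda = 0, learning_rate = 0.01,
                    epochs = 500, standardize = TRUE, seed = 1) {
  activation <- match.arg(activation)
  x <- as.matrix(x)
  n <- check_survival(time, status)
  if (nrow(x) != n)
    stop("feature matrix has ", nrow(x), " rows but survival data have ",
         n, " samples", call. = FALSE)
  stopifnot(dropout >= 0, dropout < 1, lambda >= 0, epochs >= 1,
            learning_rate > 0)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  p <- ncol(x)
  h <- if (is.null(hidden)) max(1L, as.integer(floor(sqrt(p))))
       else as.integer(hidden)
  stopifnot(h >= 1)
  n_events <- sum(status)

  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    ctr <- rep(0, p); scl <- rep(1, p)
  }
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")

  act  <- if (activation == "tanh") tanh else identity
  actp <- if (activation == "tanh") function(g) 1 - g^2 else function(g) 1

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  lim_w <- sqrt(6 / (p + h))
  lim_b <- sqrt(6 / (h + 1))
  W <- matrix(stats::runif(p * h, -lim_w, lim_w), p, h)
  b <- rep(0, h)
  beta <- stats::runif(h, -lim_b, lim_b)

  keep <- 1 - dropout
  trace <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    mask <- if (dropout > 0) {
      m <- (stats::runif(h) >= dropout) / keep
      while (all(m == 0)) m <- (stats::runif(h) >= dropout) / keep
      m
    } else rep(1, h)

    Z <- xs %*% W + rep(b, each = n)
    G <- act(Z)
    Gd <- G * rep(mask, each = n)
    eta <- drop(Gd %*% beta)
    if (any(!is.finite(eta)))
      stop("non-finite prognostic index at epoch ", epoch,
           "; reduce the learning rate or increase the penalty",
           call. = FALSE)

    g_eta <- cox_pll_grad(eta, time, status) / n_events
    d_beta <- drop(crossprod(Gd, g_eta)) - 2 * lambda * beta
    dG <- tcrossprod(g_eta, beta * mask)
    dZ <- dG * actp(G)
    dW <- crossprod(xs, dZ) - 2 * lambda * W
    db <- colSums(dZ)

    W <- W + learning_rate * dW
    b <- b + learning_rate * db
    beta <- beta + learning_rate * d_beta

    # dropout-free objective per event, for the retrievable loss trace
    eta_eval <- drop(act(xs %*% W + rep(b, each = n)) %*% beta)
    trace[epoch] <- cox_pll(eta_eval, time, status) / n_events
  }
  if (any(!is.finite(c(W, b, beta))))
    stop("training diverged to non-finite weights", call. = FALSE)

  structure(list(
    W = W, bias = b, beta = beta,
    activation = activation, hidden = h, p = p,
    dropout = dropout, lambda = lambda,
    learning_rate = learning_rate, epochs = epochs, seed = seed,
    xcenter = ctr, xscale = scl, standardize = standardize,
    feature_names = colnames(x),
    n = n, n_events = n_events,
    loss_trace = trace,
    train_median_pi = NA_real_   # filled below
  ), class = "coxnnet") -> fit
  fit$train_median_pi <- stats::median(predict(fit, x))
  fit
}

.check_newdata <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("feature-count mismatch: model expects ", object$p,
         " features, got ", ncol(newdata), call. = FALSE)
  sweep(sweep(newdata, 2, object$xcenter, "-"), 2, object$xscale, "/")
}

#' Predict prognostic indices from a fitted network
#'
#' Deterministic forward pass (dropout off): the prognostic index (log
#' hazard ratio) per sample. Only the ordering of the returned values
#' matters for concordance and risk stratification.
#'
#' @param object a fitted [coxnnet()] model.
#' @param newdata feature matrix with the same columns as training.
#' @param ... unused.
#' @return numeric vector of prognostic indices, named by row names.
#' @export
predict.coxnnet <- function(object, newdata, ...) {
  eta <- drop(extract_hidden(object, newdata) %*% object$beta)
  names(eta) <- rownames(as.matrix(newdata))
  eta
}

#' Hidden-layer activations of a fitted network
#'
#' Returns the deterministic hidden-node activations
#' `activation(x W + b)` per sample — the learned "surrogate features"
#' that the two-stage procedure fuses across modalities.
#'
#' @inheritParams predict.coxnnet
#' @param x feature matrix with the model's training columns.
#' @return numeric matrix, samples x hidden nodes.
#' @export
extract_hidden <- function(object, x) {
  stopifnot(inherits(object, "coxnnet"))
  xs <- .check_newdata(object, x)
  act <- if (object$activation == "tanh") tanh else identity
  G <- act(xs %*% object$W + rep(object$bias, each = nrow(xs)))
  rownames(G) <- rownames(as.matrix(x))
  colnames(G) <- paste0("node", seq_len(object$hidden))
  G
}

#' @export
print.coxnnet <- function(x, ...) {
  cat("Neural-network Cox proportional-hazards model\n")
  cat(sprintf("  architecture: %d features -> %d hidden (%s) -> PH output\n",
              x$p, x$hidden, x$activation))
  cat(sprintf("  training: n = %d (%d events), dropout = %.2f, L2 = %g,\n",
              x$n, x$n_events, x$dropout, x$lambda))
  cat(sprintf("            lr = %g, epochs = %d, seed = %d\n",
              x$learning_rate, x$epochs, x$seed))
  cat(sprintf("  final partial log-likelihood per event: %.4f\n",
              x$loss_trace[x$epochs]))
  invisible(x)
}

#' @export
summary.coxnnet <- function(object, ...) {
  out <- list(
    p = object$p, hidden = object$hidden, n = object$n,
    n_events = object$n_events, dropout = object$dropout,
    lambda = object$lambda,
    initial_objective = object$loss_trace[1],
    final_objective = object$loss_trace[object$epochs],
    output_weights = object$beta
  )
  class(out) <- "summary.coxnnet"
  out
}

#' @export
print.summary.coxnnet <- function(x, ...) {
  cat(sprintf(
    "coxnnet fit: %d -> %d -> 1, n = %d (%d events)\n", x$p, x$hidden,
    x$n, x$n_events))
  cat(sprintf("objective (pll/event): %.4f -> %.4f over training\n",
              x$initial_objective, x$final_objective))
  cat("output-layer weights:\n")
  print(round(x$output_weights, 4))
  invisible(x)
}

#' @export
coef.coxnnet <- function(object, ...) {
  list(W = object$W, bias = object$bias, beta = object$beta)
}

#' Training-objective trace plot
#'
#' Plots the dropout-free partial log-likelihood per event recorded after
#' each training epoch.
#'
#' @param x fitted model; `...` passed to [plot()].
#' @export
plot.coxnnet <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "partial log-likelihood per event", ...)
  invisible(x)
}

#' Analytic gradient of the penalized objective (dropout-free)
#'
#' Flattened gradient of `cox_pll(eta)/n_events - lambda (|W|^2 + |beta|^2)`
#' with respect to `(W, b, beta)` at the supplied parameter values.
#' Used for finite-difference verification of the training gradient.
#'
#' @param object a `coxnnet` fit (supplies architecture and data scaling).
#' @param x,time,status data at which to evaluate.
#' @param params optional list (W, bias, beta) overriding the fitted ones.
#' @return list with `gradient` (numeric vector, order W, bias, beta) and
#'   `objective` (scalar).
#' @keywords internal
#' @export
coxnnet_objective_grad <- function(object, x, time, status, params = NULL) {
  xs <- .check_newdata(object, x)
  n <- nrow(xs)
  W <- if (is.null(params)) object$W else params$W
  b <- if (is.null(params)) object$bias else params$bias
  beta <- if (is.null(params)) object$beta else params$beta
  lambda <- object$lambda
  n_events <- sum(status)
  act  <- if (object$activation == "tanh") tanh else identity
  actp <- if (object$activation == "tanh") function(g) 1 - g^2 else function(g) 1

  G <- act(xs %*% W + rep(b, each = n))
  eta <- drop(G %*% beta)
  obj <- cox_pll(eta, time, status) / n_events -
    lambda * (sum(W^2) + sum(beta^2))
  g_eta <- cox_pll_grad(eta, time, status) / n_events
  d_beta <- drop(crossprod(G, g_eta)) - 2 * lambda * beta
  dZ <- tcrossprod(g_eta, beta) * actp(G)
  dW <- crossprod(xs, dZ) - 2 * lambda * W
  db <- colSums(dZ)
  list(gradient = c(as.numeric(dW), db, d_beta), objective = obj)
}
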