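#' Simulate proportional-hazards survival data with planted signal
#'
#' Generates an n x p feature matrix of standard-normal features in which
#' the first `n_informative` columns form an equicorrelated block
#' (pairwise correlation `rho`) and carry the signal. The true prognostic
#' index is linear, `eta = X[, 1:n_informative] %*% effect` (optionally
#' plus a quadratic term in the first informative feature), event times
#' are exponential with rate `baseline_hazard * exp(eta)` (Weibull via
#' `shape`), and independent exponential censoring is calibrated by
#' bisection so the realized censoring fraction hits `censoring` closely.
#'
#' @param n number of samples.
#' @param p number of features.
#' @param n_informative number of signal-carrying features (<= p).
#' @param effect effect sizes; recycled to length `n_informative`.
#' @param rho pairwise correlation inside the informative block.
#' @param baseline_hazard baseline event rate per day (default 1e-3, i.e.
#'   median uncensored survival around 700 days for eta = 0).
#' @param censoring target censored fraction in \[0, 1).
#' @param shape Weibull shape for event times; 1 (default) = exponential.
#' @param quadratic add `0.5 * effect[1] * x1^2` to the linear predictor.
#' @param seed integer seed; all randomness flows from it.
#' @return list with `x` (matrix with column names f1..fp and row names
#'   s1..sn), `time`, `status`, `eta_true`, `informative` (column names),
#'   and the achieved `censoring_rate`.
#' @examples
#' d <- simulate_survival(n = 50, p = 10, seed = 1)
#' mean(d$status == 0)
#' @export
simulate_survival <- function(n = 500, p = 100, n_informative = 5,
                              effect = 1.0, rho = 0.2,
                              baseline_hazard = 1e-3, censoring = 0.3,
                              shape = 1, quadratic = FALSE, seed = 1) {
  stopifnot(n >= 2, p >= 1, n_informative <= p, n_informative >= 0,
            censoring >= 0, censoring < 1, shape > 0, baseline_hazard > 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("f", seq_len(p))))
  if (n_informative > 1 && rho != 0) {
    # equicorrelated block via a shared latent factor:
    # x_j = sqrt(rho) z + sqrt(1 - rho) x_j keeps unit variance
    z <- stats::rnorm(n)
    idx <- seq_len(n_informative)
    x[, idx] <- sqrt(rho) * z + sqrt(1 - rho) * x[, idx]
  }
  beta <- rep_len(effect, n_informative)
  eta <- if (n_informative > 0) drop(x[, seq_len(n_informative), drop = FALSE] %*% beta)
         else numeric(n)
  if (quadratic && n_informative > 0)
    eta <- eta + 0.5 * beta[1] * (x[, 1]^2 - 1)

  t_event <- (stats::rexp(n) / (baseline_hazard * exp(eta)))^(1 / shape)
  u_cens <- stats::rexp(n)   # unit-rate draws rescaled during calibration

  if (censoring > 0) {
    rate <- .calibrate_censoring(t_event, u_cens, censoring)
    t_cens <- u_cens / rate
  } else {
    t_cens <- rep(Inf, n)
  }
  status <- as.integer(t_event <= t_cens)
  time <- pmin(t_event, t_cens)
  if (sum(status) == 0)
    stop("censoring calibration left no events; lower the target", call. = FALSE)
  list(x = x, time = time, status = status, eta_true = eta,
       informative = colnames(x)[seq_len(n_informative)],
       censoring_rate = mean(status == 0))
}

# Bisection on the censoring rate so that mean(u/rate < t_event) hits the
# target fraction. Monotone in rate, so plain bisection converges.
.calibrate_censoring <- function(t_event, u_cens, target, tol = 0.005,
                                 max_iter = 200L) {
  frac <- function(rate) mean(u_cens / rate < t_event)
  lo <- 1e-12; hi <- 1e12
  if (frac(lo) > target || frac(hi) < target)
    stop("censoring target ", target, " is infeasible for these draws",
         call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)    # bisect on log scale; rates span many decades
    f <- frac(mid)
    if (abs(f - target) <= tol) return(mid)
    if (f < target) lo <- mid else hi <- mid
  }
  mid
}

#' Simulate two modalities carrying complementary survival signal
#'
#' Builds two feature matrices that share one survival response. The true
#' prognostic index is `eta_A + eta_B`; modality A's matrix contains only
#' the drivers of `eta_A` and modality B's only those of `eta_B`, so
#' neither modality alone can reach the concordance of the fused
#' predictor. This is the benchmark used to test that second-stage fusion
#' of hidden-layer features beats either single-modality model.
#'
#' @param n samples; `p` features per modality; `n_informative` signal
#'   features per modality (disjoint between modalities by construction).
#' @inheritParams simulate_survival
#' @param effect_a,effect_b per-modality effect sizes.
#' @return list with `x_a`, `x_b`, `time`, `status`, `eta_a`, `eta_b`,
#'   `eta_true` (= eta_a + eta_b), `censoring_rate`.
#' @export
simulate_modalities <- function(n = 300, p = 40, n_informative = 5,
                                effect_a = 0.7, effect_b = 0.7, rho = 0.2,
                                baseline_hazard = 1e-3, censoring = 0.3,
                                seed = 1) {
  stopifnot(n >= 2, n_informative <= p)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  make_x <- function(tag) {
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(paste0("s", seq_len(n)),
                                paste0(tag, seq_len(p))))
    if (n_informative > 1 && rho != 0) {
      z <- stats::rnorm(n)
      idx <- seq_len(n_informative)
      x[, idx] <- sqrt(rho) * z + sqrt(1 - rho) * x[, idx]
    }
    x
  }
  x_a <- make_x("a"); x_b <- make_x("b")
  beta_a <- rep_len(effect_a, n_informative)
  beta_b <- rep_len(effect_b, n_informative)
  eta_a <- drop(x_a[, seq_len(n_informative), drop = FALSE] %*% beta_a)
  eta_b <- drop(x_b[, seq_len(n_informative), drop = FALSE] %*% beta_b)
  eta <- eta_a + eta_b

  t_event <- stats::rexp(n) / (baseline_hazard * exp(eta))
  u_cens <- stats::rexp(n)
  if (censoring > 0) {
    rate <- .calibrate_censoring(t_event, u_cens, censoring)
    t_cens <- u_cens / rate
  } else t_cens <- rep(Inf, n)
  status <- as.integer(t_event <= t_cens)
  time <- pmin(t_event, t_cens)
  list(x_a = x_a, x_b = x_b, time = time, status = status,
       eta_a = eta_a, eta_b = eta_b, eta_true = eta,
       censoring_rate = mean(status == 0))
}

#' Simulate a synthetic RGB image
#'
#' Deterministic test images for the tiling front end, as an
#' height x width x 3 array of intensities in \[0, 255\].
#' Patterns: `uniform` (constant `value`), `gradient` (intensity grows
#' left to right, so tile densities are strictly ordered along x), and
#' `blobs` (dim background plus bright square hotspots centred in the
#' tiles listed in `hotspots`, guaranteeing those tiles win top-k
#' selection).
#'
#' @param width,height image size in pixels.
#' @param pattern one of "uniform", "gradient", "blobs".
#' @param value intensity for `uniform` (default 255).
#' @param hotspots for `blobs`: 2-column matrix of 0-based tile origins
#'   (row, col) in pixels, each the top-left corner of a `tile_size` tile.
#' @param tile_size tile size the hotspots refer to (default 100).
#' @param noise_sd Gaussian pixel noise added to `blobs` (default 5).
#' @param seed seed for the noise.
#' @return numeric array height x width x 3 in \[0, 255\].
#' @export
simulate_image <- function(width, height, pattern = c("uniform", "gradient",
                                                      "blobs"),
                           value = 255, hotspots = NULL, tile_size = 100,
                           noise_sd = 5, seed = 1) {
  stopifnot(width >= 1, height >= 1)
  pattern <- match.arg(pattern)
  img <- array(0, dim = c(height, width, 3))
  if (pattern == "uniform") {
    img[] <- value
  } else if (pattern == "gradient") {
    col_vals <- seq(10, 250, length.out = width)
    img[] <- rep(matrix(col_vals, height, width, byrow = TRUE), 3)
  } else {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    img[] <- 40 + stats::rnorm(length(img), sd = noise_sd)
    if (!is.null(hotspots)) {
      hotspots <- as.matrix(hotspots)
      for (k in seq_len(nrow(hotspots))) {
        r0 <- hotspots[k, 1]; c0 <- hotspots[k, 2]
        rows <- (r0 + 1):(r0 + tile_size)
        cols <- (c0 + 1):(c0 + tile_size)
        img[rows, cols, ] <- 230 + stats::rnorm(tile_size^2 * 3, sd = noise_sd)
      }
    }
    img[img < 0] <- 0; img[img > 255] <- 255
  }
  img
}

# Preserve the caller's RNG state around seeded simulation calls.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
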