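# tiny trained model whose weights we can overwrite for exact-value checks
toy_fit <- function(p = 4, n = 12, seed = 5) {
  d <- simulate_survival(n = n, p = p, n_informative = 1, censoring = 0.2,
                         seed = seed)
  coxnnet(d$x, d$time, d$status, hidden = 2, dropout = 0, epochs = 1,
          standardize = FALSE, seed = 1)
}

test_that("forward pass reproduces hand matrix arithmetic", {
  fit <- toy_fit()
  fit$W <- matrix(c(0.5, -0.2, 0.1, 0.0,
                    0.3,  0.4, -0.1, 0.2), nrow = 4)
  fit$bias <- c(0.1, -0.3)
  fit$beta <- c(1.5, -0.7)
  x <- rbind(c(1, 0, 2, -1), c(0.5, 0.5, 0, 0))
  # scalar arithmetic per sample and node
  want <- sapply(1:2, function(i) {
    z1 <- sum(x[i, ] * fit$W[, 1]) + 0.1
    z2 <- sum(x[i, ] * fit$W[, 2]) - 0.3
    1.5 * tanh(z1) - 0.7 * tanh(z2)
  })
  expect_equal(unname(predict(fit, x)), want, tolerance = 1e-12)
})

test_that("degenerate forward passes behave as contracted", {
  fit <- toy_fit()
  fit$W[] <- 0; fit$bias <- c(0.2, -0.1); fit$beta <- c(1, 2)
  x <- matrix(rnorm(20), 5, 4)
  eta <- predict(fit, x)
  expect_equal(unname(eta), rep(tanh(0.2) + 2 * tanh(-0.1), 5))

  # duplicated input row duplicates the prediction
  fit2 <- toy_fit()
  x2 <- rbind(x, x[3, ])
  eta2 <- predict(fit2, x2)
  expect_equal(unname(eta2[6]), unname(eta2[3]), tolerance = 1e-14)

  expect_error(predict(fit, matrix(0, 2, 7)),
               "expects 4 features, got 7")
})

test_that("training is deterministic given the seed and leaves the RNG alone", {
  d <- simulate_survival(n = 60, p = 9, seed = 8)
  set.seed(123); before <- runif(1)
  f1 <- coxnnet(d$x, d$time, d$status, epochs = 40, seed = 7)
  f2 <- coxnnet(d$x, d$time, d$status, epochs = 40, seed = 7)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$loss_trace, f2$loss_trace)
  # different seed gives a different trajectory
  f3 <- coxnnet(d$x, d$time, d$status, epochs = 40, seed = 8)
  expect_false(identical(f1$W, f3$W))
  # caller RNG stream untouched by the seeded fit
  set.seed(123)
  expect_identical(runif(1), before)
})

test_that("analytic gradient matches central finite differences", {
  for (s in 1:3) {
    d <- simulate_survival(n = 20 + 3 * s, p = 4 + s, n_informative = 2,
                           censoring = 0.25, seed = 40 + s)
    fit <- coxnnet(d$x, d$time, d$status, dropout = 0, lambda = 0.03,
                   epochs = 2, seed = s)
    got <- coxnnet_objective_grad(fit, d$x, d$time, d$status)
    pars <- c(as.numeric(fit$W), fit$bias, fit$beta)
    p <- fit$p; h <- fit$hidden
    unpack <- function(v) list(W = matrix(v[1:(p * h)], p, h),
                               bias = v[p * h + 1:h],
                               beta = v[p * h + h + 1:h])
    eps <- 1e-6
    fd <- vapply(seq_along(pars), function(i) {
      up <- pars; up[i] <- up[i] + eps
      dn <- pars; dn[i] <- dn[i] - eps
      (coxnnet_objective_grad(fit, d$x, d$time, d$status, unpack(up))$objective -
       coxnnet_objective_grad(fit, d$x, d$time, d$status, unpack(dn))$objective) /
        (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(fd - got$gradient) / pmax(abs(got$gradient), 1e-8)),
              1e-5)
  }
})

test_that("with identity activation the model class recovers linear Cox fits", {
  # data from a linear proportional-hazards model; compare the trained
  # network's held-out concordance with the true linear predictor's
  gap <- vapply(1:10, function(s) {
    d <- simulate_survival(n = 200, p = 4, n_informative = 4, effect = 0.6,
                           rho = 0, censoring = 0.25, seed = 500 + s)
    tr <- seq_len(160); te <- 161:200
    fit <- coxnnet(d$x[tr, ], d$time[tr], d$status[tr],
                   activation = "identity", hidden = 4, dropout = 0,
                   lambda = 1e-3, seed = s)
    c_fit <- cindex(predict(fit, d$x[te, ]), d$time[te], d$status[te])
    c_true <- cindex(d$eta_true[te], d$time[te], d$status[te])
    c_true - c_fit
  }, numeric(1))
  expect_lt(median(gap), 0.05)
})

test_that("training improves the objective on strong-signal data", {
  for (s in 1:5) {
    d <- simulate_survival(n = 150, p = 25, n_informative = 5, effect = 1,
                           censoring = 0.3, seed = 600 + s)
    fit <- coxnnet(d$x, d$time, d$status, lambda = 0.01, epochs = 200,
                   seed = s)
    expect_gt(fit$loss_trace[length(fit$loss_trace)], fit$loss_trace[1])
  }
})

test_that("predictions are invariant under consistent feature permutation", {
  d <- simulate_survival(n = 80, p = 10, seed = 77)
  fit <- coxnnet(d$x, d$time, d$status, epochs = 60, seed = 3)
  perm <- sample(10)
  pfit <- fit
  pfit$W <- fit$W[perm, , drop = FALSE]
  pfit$xcenter <- fit$xcenter[perm]
  pfit$xscale <- fit$xscale[perm]
  pfit$feature_names <- fit$feature_names[perm]
  expect_equal(unname(predict(pfit, d$x[, perm])),
               unname(predict(fit, d$x)), tolerance = 1e-12)
})

test_that("fit-time contracts: hidden width, event requirement, dimensions", {
  d <- simulate_survival(n = 50, p = 26, seed = 9)
  fit <- coxnnet(d$x, d$time, d$status, epochs = 5, seed = 1)
  expect_identical(fit$hidden, 5L)                  # floor(sqrt(26))
  expect_identical(max(1L, as.integer(floor(sqrt(2429)))), 49L)
  expect_error(coxnnet(d$x, d$time, rep(0, 50), epochs = 5), "no events")
  expect_error(coxnnet(d$x[1:10, ], d$time, d$status), "10 rows")
  s <- summary(fit)
  expect_s3_class(s, "summary.coxnnet")
  expect_output(print(fit), "26 features -> 5 hidden")
})
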