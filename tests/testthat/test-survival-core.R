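test_that("partial log-likelihood matches closed forms and the risk-set oracle", {
  # two samples, equal eta: first event contributes -log 2, second -log 1
  expect_equal(cox_pll(c(0, 0), time = c(1, 2), status = c(1, 1)), -log(2))

  # spec'd three-sample case against explicit risk-set enumeration
  eta <- c(1.0, -1.0, 0.5); tm <- c(2, 5, 3); st <- c(1, 0, 1)
  expect_equal(cox_pll(eta, tm, st), bf_cox_pll(eta, tm, st), tolerance = 1e-12)

  # random datasets, with and without tied times (Breslow convention)
  for (s in 1:25) {
    d <- random_survival(n = 5 + s, cens = 0.3, ties = s %% 2 == 0, seed = s)
    expect_equal(cox_pll(d$eta, d$time, d$status),
                 bf_cox_pll(d$eta, d$time, d$status), tolerance = 1e-10)
  }
})

test_that("partial log-likelihood is shift-invariant and rejects event-free data", {
  for (s in 1:10) {
    d <- random_survival(n = 30, seed = s)
    expect_equal(cox_pll(d$eta + 17.3, d$time, d$status),
                 cox_pll(d$eta, d$time, d$status), tolerance = 1e-10)
  }
  expect_error(cox_pll(c(0, 1), time = c(1, 2), status = c(0, 0)),
               "no events")
  expect_error(cox_pll(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("concordance index: perfect ordering, oracle equality, tie conventions", {
  # higher risk dies earlier for every pair -> exactly 1
  expect_identical(cindex(c(3, 2, 1), time = c(1, 2, 3), status = c(1, 1, 1)), 1)
  # reversed risk -> exactly 0
  expect_identical(cindex(c(1, 2, 3), time = c(1, 2, 3), status = c(1, 1, 1)), 0)
  # tied risk scores count as discordant under the strict inequality
  expect_identical(cindex(c(1, 1), time = c(1, 2), status = c(1, 1)), 0)
  # tied times drop the pair: only (T=2, T=1) usable here
  expect_identical(cindex(c(2, 1, 0), time = c(1, 1, 2), status = c(1, 1, 1)), 1)

  for (s in 1:40) {
    d <- random_survival(n = 10 + 2 * s, cens = runif(1, 0, 0.8),
                         ties = s %% 3 == 0, seed = 100 + s)
    expect_equal(cindex(d$eta, d$time, d$status),
                 bf_cindex(d$eta, d$time, d$status))
  }
})

test_that("concordance index invariances", {
  for (s in 1:10) {
    d <- random_survival(n = 40, seed = 200 + s)
    c0 <- cindex(d$eta, d$time, d$status)
    # strictly monotone transform leaves it unchanged
    expect_equal(cindex(exp(2 * d$eta), d$time, d$status), c0)
    expect_equal(cindex(rank(d$eta), d$time, d$status), c0)
    # with continuous eta and times, reversing risk complements it
    expect_equal(cindex(-d$eta, d$time, d$status), 1 - c0)
  }
  expect_error(cindex(c(1, 2), time = c(2, 2), status = c(1, 1)),
               "no comparable pairs")
})

test_that("Kaplan-Meier estimator matches hand-computed product limits", {
  km <- km_curve(time = c(1, 2, 3), status = c(1, 1, 1))
  expect_equal(km$surv[match(c(1, 2, 3), km$time)], c(2/3, 1/3, 0))
  expect_equal(km$surv[1], 1)   # S(0) = 1 anchor

  # all censored: survival never drops
  km2 <- km_curve(time = c(1, 2, 3), status = c(0, 0, 0))
  expect_true(all(km2$surv == 1))

  # mixed 6-sample case: S = 5/6, 5/6*4/5, *2/3, *0 at event times 1,2,4,6
  km3 <- km_curve(time = c(1, 2, 2, 4, 5, 6), status = c(1, 0, 1, 1, 0, 1))
  expect_equal(km3$surv[match(c(1, 2, 4, 6), km3$time)],
               c(5/6, 5/6 * 4/5, 5/6 * 4/5 * 2/3, 0))

  # property: non-increasing, within [0, 1]
  for (s in 1:10) {
    d <- random_survival(n = 25, cens = 0.4, ties = TRUE, seed = 300 + s)
    km <- km_curve(d$time, d$status)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
  }
})

test_that("log-rank test matches the textbook O/E/V computation", {
  # identical groups: statistic ~ 0, p ~ 1
  tm <- c(1, 2, 3, 4, 5); st <- c(1, 1, 0, 1, 1)
  lr0 <- logrank_test(c(tm, tm), c(st, st), rep(c("a", "b"), each = 5))
  expect_lt(lr0$chisq, 1e-8)
  expect_gt(lr0$p_value, 0.999)

  # ten-sample worked case against the hand-built table
  tm10 <- c(1, 3, 4, 6, 8, 2, 5, 7, 9, 12)
  st10 <- c(1, 1, 0, 1, 1, 1, 1, 1, 0, 1)
  gr10 <- rep(c("lo", "hi"), each = 5)
  got <- logrank_test(tm10, st10, gr10)
  want <- bf_logrank(tm10, st10, gr10)
  expect_equal(got$chisq, want$chisq, tolerance = 1e-8)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-8)

  # symmetry under label swap
  swapped <- logrank_test(tm10, st10, rev(gr10))
  expect_equal(swapped$chisq, got$chisq)

  # fully separated event times: p shrinks as n grows
  p_at <- sapply(c(6, 12, 24), function(n) {
    tmn <- c(seq_len(n / 2), seq_len(n / 2) + 100)
    logrank_test(tmn, rep(1, n), rep(c("a", "b"), each = n / 2))$p_value
  })
  expect_true(all(diff(p_at) < 0))
  expect_lt(p_at[3], 1e-4)

  expect_error(logrank_test(tm, st, rep("a", 5)), "two non-empty groups")
})

test_that("median dichotomization follows the documented tie rules", {
  g <- dichotomize(c(1, 2, 3, 4))
  expect_equal(g$threshold, 2.5)
  expect_equal(as.vector(table(g$labels)), c(2, 2))

  # ties straddling the median: <= median is low
  g2 <- dichotomize(c(1, 1, 2, 2))
  expect_equal(unname(table(g2$labels)["low"]), 2L)
  expect_equal(unname(table(g2$labels)["high"]), 2L)

  # odd n: the median sample itself goes low
  g3 <- dichotomize(c(10, 20, 30, 40, 50))
  expect_equal(as.character(g3$labels[3]), "low")
  expect_equal(sum(g3$labels == "high"), 2L)

  # heavy ties at the median trigger the rank fallback, both groups non-empty
  g4 <- dichotomize(c(1, 5, 5, 5, 5, 5))
  expect_true(all(c("low", "high") %in% g4$labels))

  expect_error(dichotomize(rep(2, 4)), "constant")

  # external threshold is honoured verbatim (train-median protocol)
  g5 <- dichotomize(c(0.1, 0.9), threshold = 0.5)
  expect_equal(as.character(g5$labels), c("low", "high"))
})
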