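# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: the C-index enumerates every ordered pair, the
# partial likelihood builds each risk set explicitly, and the log-rank
# statistic is assembled from the textbook O/E/V table.

bf_cindex <- function(eta, time, status) {
  n <- length(eta)
  num <- den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] > time[j] && status[j] == 1) {
      den <- den + 1
      if (eta[i] < eta[j]) num <- num + 1
    }
  }
  num / den
}

bf_cox_pll <- function(eta, time, status) {
  ll <- 0
  for (i in seq_along(eta)) {
    if (status[i] != 1) next
    risk_set <- which(time >= time[i])     # Breslow: ties share the risk set
    ll <- ll + eta[i] - log(sum(exp(eta[risk_set])))
  }
  ll
}

bf_logrank <- function(time, status, group) {
  g <- as.integer(factor(group))           # 1 / 2
  ev_times <- sort(unique(time[status == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d_tot <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d_tot * n1 / n_tot
    if (n_tot > 1)
      V <- V + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p_value = pchisq(chisq, 1, lower.tail = FALSE))
}

# random censored dataset for property tests
random_survival <- function(n, cens = 0.3, ties = FALSE, seed = 1) {
  set.seed(seed)
  time <- if (ties) sample(1:max(2, n %/% 3), n, replace = TRUE)
          else rexp(n) + 0.01
  status <- rbinom(n, 1, 1 - cens)
  if (sum(status) == 0) status[sample(n, 1)] <- 1
  list(time = time, status = status, eta = rnorm(n))
}
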