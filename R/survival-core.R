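#' Validate a survival response
#'
#' Internal helper shared by every function that consumes a survival
#' response. Checks lengths, positivity of times, the 0/1 status coding,
#' and (optionally) that at least one event was observed.
#'
#' @param time positive numeric vector of times to event or censoring.
#' @param status integer/numeric vector in \{0, 1\}; 1 = event observed,
#'   0 = censored.
#' @param require_events error when no events are present (default TRUE);
#'   the Cox partial likelihood and all rank-based metrics are undefined
#'   without events.
#' @return invisibly, the number of samples.
#' @keywords internal
check_survival <- function(time, status, require_events = TRUE) {
  n <- length(time)
  if (n == 0L)
    stop("empty survival data: no samples", call. = FALSE)
  if (length(status) != n)
    stop("`time` and `status` lengths differ (", n, " vs ",
         length(status), ")", call. = FALSE)
  if (anyNA(time) || anyNA(status))
    stop("survival data contain missing values; impute or drop explicitly",
         call. = FALSE)
  if (any(time <= 0))
    stop("all survival times must be positive", call. = FALSE)
  if (!all(status %in% c(0, 1)))
    stop("`status` must be coded 0 (censored) / 1 (event); ",
         "a 1/2 coding must be recoded by the caller", call. = FALSE)
  if (require_events && sum(status) == 0)
    stop("no events observed (all samples censored); ",
         "partial likelihood and concordance are undefined", call. = FALSE)
  invisible(n)
}

#' Cox partial log-likelihood
#'
#' Log partial likelihood of a vector of prognostic indices (log hazard
#' ratios) under the Cox proportional-hazards model, using the Breslow
#' convention for tied event times (all samples with tied times share one
#' risk-set denominator):
#' \deqn{\ell(\eta) = \sum_{i: d_i = 1} \Big[\eta_i -
#'   \log \sum_{j: T_j \ge T_i} e^{\eta_j}\Big].}
#'
#' The value is invariant to adding a constant to all of `eta`, which is
#' why networks maximizing it need no output bias.
#'
#' @param eta numeric vector of prognostic indices, one per sample.
#' @param time,status survival response; see [check_survival()].
#' @return a single finite number (the higher, the better the fit).
#' @examples
#' cox_pll(c(0, 0), time = c(1, 2), status = c(1, 1))  # -log(2)
#' @export
cox_pll <- function(eta, time, status) {
  n <- check_survival(time, status)
  if (length(eta) != n)
    stop("`eta` length (", length(eta), ") does not match number of samples (",
         n, ")", call. = FALSE)
  if (any(!is.finite(eta)))
    stop("`eta` contains non-finite values", call. = FALSE)
  ord <- order(time)
  t_s <- time[ord]
  d_s <- status[ord]
  e_s <- exp(eta[ord] - max(eta))          # centered for stability
  # risk-set sums: sum of e over {j : T_j >= T_i}; ties share the sum at
  # the first index of their tie group in the sorted order
  rs <- rev(cumsum(rev(e_s)))
  first <- match(t_s, t_s)
  denom <- rs[first]
  sum(log(e_s[d_s == 1])) - sum(log(denom[d_s == 1]))
}

#' Gradient of the Cox partial log-likelihood with respect to eta
#'
#' \eqn{\partial \ell / \partial \eta_k = d_k - e^{\eta_k}
#'   \sum_{i: d_i = 1,\, T_k \ge T_i} 1 / \sum_{j: T_j \ge T_i} e^{\eta_j}}
#' (Breslow ties). Used by the network training loop; exported for testing
#' against finite differences.
#'
#' @inheritParams cox_pll
#' @return numeric vector of length n.
#' @keywords internal
cox_pll_grad <- function(eta, time, status) {
  n <- length(eta)
  ord <- order(time)
  t_s <- time[ord]
  d_s <- status[ord]
  e_s <- exp(eta[ord] - max(eta))
  rs <- rev(cumsum(rev(e_s)))
  first <- match(t_s, t_s)
  denom <- rs[first]
  # cumulative hazard increments d_i / denom_i, accumulated over all event
  # positions with T_i <= T_k; tied groups must be fully included, so read
  # the cumsum at the last index of each tie group
  cum <- cumsum(d_s / denom)
  last <- n + 1L - match(t_s, rev(t_s))
  g_s <- d_s - e_s * cum[last]
  g <- numeric(n)
  g[ord] <- g_s
  g
}

#' Harrell's concordance index (literal pair-counting form)
#'
#' Fraction of usable ordered sample pairs whose predicted risk ordering
#' agrees with the observed survival ordering:
#' \deqn{c = \frac{\sum_{i \ne j} 1\{\eta_i < \eta_j\}\, 1\{T_i > T_j\}\, d_j}
#'            {\sum_{i \ne j} 1\{T_i > T_j\}\, d_j}.}
#'
#' A pair is usable when the member with the shorter time experienced the
#' event; pairs with tied times never fire either indicator and are
#' excluded. Note the strict inequality on `eta`: tied risk scores count
#' as discordant under this convention, whereas many packages (for
#' example `survival::concordance`) award ties 1/2. Expect third-decimal
#' differences against such software when risk scores tie.
#'
#' @inheritParams cox_pll
#' @return a number in \[0, 1\]; 1 = perfectly concordant, 0.5 = random.
#' @examples
#' cindex(c(3, 2, 1), time = c(1, 2, 3), status = c(1, 1, 1))  # 1
#' @export
cindex <- function(eta, time, status) {
  n <- check_survival(time, status)
  if (length(eta) != n)
    stop("`eta` length does not match number of samples", call. = FALSE)
  if (n < 2L)
    stop("concordance needs at least two samples", call. = FALSE)
  # usable ordered pairs (i, j): T_i > T_j and d_j = 1
  usable <- outer(time, time, ">") & rep(status == 1, each = n)
  n_usable <- sum(usable)
  if (n_usable == 0L)
    stop("no comparable pairs (check censoring pattern and tied times)",
         call. = FALSE)
  concordant <- sum(usable & outer(eta, eta, "<"))
  concordant / n_usable
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function for one group of
#' samples, computed via [survival::survfit()]. The returned step
#' function starts at S(0) = 1 and drops only at observed event times.
#'
#' @inheritParams cox_pll
#' @return a data.frame with columns `time`, `n_risk`, `n_event`,
#'   `surv`, beginning with the (0, 1) anchor point.
#' @export
km_curve <- function(time, status) {
  check_survival(time, status, require_events = FALSE)
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  data.frame(
    time    = c(0, fit$time),
    n_risk  = c(length(time), fit$n.risk),
    n_event = c(0, fit$n.event),
    surv    = c(1, fit$surv)
  )
}

#' Two-group log-rank test
#'
#' Standard two-sample log-rank test (observed minus expected events
#' across pooled event times, chi-square on 1 df), delegated to
#' [survival::survdiff()].
#'
#' @inheritParams cox_pll
#' @param group vector with exactly two distinct values (e.g. the labels
#'   from [dichotomize()]); both groups must be non-empty.
#' @return list with elements `chisq` and `p_value`.
#' @export
logrank_test <- function(time, status, group) {
  n <- check_survival(time, status, require_events = FALSE)
  if (length(group) != n)
    stop("`group` length does not match number of samples", call. = FALSE)
  g <- factor(group)
  if (nlevels(g) != 2L)
    stop("log-rank test requires exactly two non-empty groups; got ",
         nlevels(g), call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, status) ~ g)
  chisq <- unname(sd$chisq)
  list(chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Dichotomize prognostic indices at the median
#'
#' Splits samples into high- and low-risk groups at the median prognostic
#' index, the stratification used for Kaplan-Meier / log-rank evaluation.
#' Tie rule: `eta <= median` is low risk, `eta > median` is high risk. If
#' that rule empties the high-risk group (possible when the median value
#' is heavily tied), the split falls back to ranks: the floor(n/2)
#' largest values (ties broken by position) form the high-risk group.
#'
#' @param eta numeric vector of prognostic indices (n >= 2, not constant).
#' @param threshold optional externally supplied threshold; when
#'   evaluating a test set, pass the training-set median so no
#'   information leaks from test labels (see the package vignette).
#' @return list with `labels` (factor, levels `low` < `high`) and
#'   `threshold`.
#' @export
dichotomize <- function(eta, threshold = NULL) {
  if (length(eta) < 2L)
    stop("need at least two samples to stratify", call. = FALSE)
  if (any(!is.finite(eta)))
    stop("`eta` contains non-finite values", call. = FALSE)
  internal <- is.null(threshold)
  if (internal) {
    if (diff(range(eta)) == 0)
      stop("constant prognostic index: no risk stratification possible",
           call. = FALSE)
    threshold <- stats::median(eta)
  }
  high <- eta > threshold
  if (internal && (!any(high) || all(high))) {
    # rank fallback: top floor(n/2) by eta are high risk
    n_high <- length(eta) %/% 2L
    high <- rank(-eta, ties.method = "first") <= n_high
  }
  list(labels = factor(ifelse(high, "high", "low"), levels = c("low", "high")),
       threshold = threshold)
}
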