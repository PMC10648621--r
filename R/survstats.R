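#' Negative log partial likelihood (Breslow risk sets)
#'
#' The Cox partial likelihood over event orderings,
#' \deqn{-\sum_{i:\delta_i=1}\Big[r_i - \log\sum_{j:T_j \ge T_i} e^{r_j}\Big],}
#' with the inclusive risk set \eqn{T_j \ge T_i} (Breslow convention for tied
#' event times). Computed with a max-shift inside the log-sum-exp so large
#' risks do not overflow.
#'
#' @param risk Numeric vector of log-risk scores, one per sample.
#' @param time Positive event/censoring times.
#' @param event 0/1 event indicators (1 = event observed).
#' @param average Divide by the number of events? Default FALSE (plain sum).
#' @return A single number, the (optionally averaged) negative log partial
#'   likelihood.
#' @export
neg_log_partial_likelihood <- function(risk, time, event, average = FALSE) {
  n <- length(time)
  stopifnot(length(risk) == n, length(event) == n)
  if (!all(is.finite(risk))) stop("risk scores must be finite")
  d <- as.integer(event)
  if (sum(d) == 0L) stop("no events: the partial likelihood is undefined")
  mx <- max(risk)
  ord <- order(time)
  r_ord <- risk[ord]
  # reverse cumulative sum of exp(risk - mx): position p holds sum over T >= T_(p)
  rcs <- rev(cumsum(rev(exp(r_ord - mx))))
  # tie groups share the risk-set sum of the group's first position
  first <- match(time[ord], time[ord])
  log_denom <- mx + log(rcs[first])
  ll <- sum(d[ord] * (r_ord - log_denom))
  out <- -ll
  if (average) out <- out / sum(d)
  out
}

# Gradient of neg_log_partial_likelihood w.r.t. the risk vector (internal).
# dL/dr_i = -delta_i + exp(r_i) * sum over events k with T_k <= T_i of
#           1 / sum_{j: T_j >= T_k} exp(r_j)   (tie-inclusive on both ends).
nlpl_gradient <- function(risk, time, event) {
  n <- length(time)
  d <- as.integer(event)
  mx <- max(risk)
  ord <- order(time)
  r_ord <- risk[ord]
  d_ord <- d[ord]
  e_ord <- exp(r_ord - mx)
  rcs <- rev(cumsum(rev(e_ord)))
  first <- match(time[ord], time[ord])
  denom <- rcs[first]
  contrib <- d_ord / denom
  # sample at position p is in the risk set of every event with T_k <= T_p,
  # including ties, i.e. all positions up to the LAST index of p's tie group
  last <- n + 1L - match(time[ord], rev(time[ord]))
  A <- cumsum(contrib)[last]
  g_ord <- -d_ord + e_ord * A
  g <- numeric(n)
  g[ord] <- g_ord
  g
}

#' Concordance index for censored survival data
#'
#' Fraction of comparable ordered pairs (j an observed event with
#' \eqn{T_j < T_i}) whose risk ordering agrees with the time ordering:
#' \deqn{C = \frac{\sum_{i,j} 1[T_j<T_i]\,1[r_j>r_i]\,\delta_j}
#'                 {\sum_{i,j} 1[T_j<T_i]\,\delta_j}.}
#' With `ties = "half"` (default, the common convention) tied risks
#' contribute 0.5 to the numerator; `ties = "strict"` scores them 0,
#' reproducing the formula above verbatim.
#'
#' @inheritParams neg_log_partial_likelihood
#' @param ties How risk ties in comparable pairs are credited.
#' @param percent Return on the 0-100 scale? Default FALSE (0-1).
#' @return Concordance in [0, 1] (or [0, 100] with `percent = TRUE`).
#' @export
concordance_index <- function(risk, time, event,
                              ties = c("half", "strict"), percent = FALSE) {
  ties <- match.arg(ties)
  n <- length(time)
  stopifnot(length(risk) == n, length(event) == n)
  d <- as.integer(event)
  # comparable[j, i]: j had an event strictly before i's time
  comparable <- outer(time, time, `<`) & (d == 1L)
  den <- sum(comparable)
  if (den == 0L) stop("no comparable pairs: concordance is undefined")
  agree <- outer(risk, risk, `>`)
  num <- sum(comparable & agree)
  if (ties == "half") num <- num + 0.5 * sum(comparable & outer(risk, risk, `==`))
  c_idx <- num / den
  if (percent) 100 * c_idx else c_idx
}

#' Kaplan-Meier product-limit estimator
#'
#' @inheritParams neg_log_partial_likelihood
#' @return A data.frame of class `km_curve` with one row per distinct event
#'   time: `time`, `n_risk`, `n_event`, `survival` (the product-limit
#'   estimate just after that time). All-censored input yields zero rows
#'   (the curve is constant 1).
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) >= 1L, length(event) == length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep],
                    n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep],
                    survival = fit$surv[keep])
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard chi-square log-rank test with 1 degree of freedom; the p-value is
#' the upper tail of the chi-square distribution.
#'
#' @param time_a,event_a Times and 0/1 indicators of group A.
#' @param time_b,event_b Times and 0/1 indicators of group B.
#' @return List with `statistic` and `p_value`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L) stop("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) == 0L) stop("no events in either group")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("a", "b"), c(length(time_a), length(time_b)))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- sd_fit$chisq
  list(statistic = unname(stat),
       p_value = unname(stats::pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Split samples at the median of a covariate
#'
#' Samples strictly above the median are labelled the high-expression group;
#' values tied with the median go to the low group.
#'
#' @param x Numeric vector, length >= 2.
#' @return Logical vector, TRUE = high group.
#' @export
median_split <- function(x) {
  stopifnot(length(x) >= 2L)
  if (length(unique(x)) == 1L) stop("constant vector: no split possible")
  high <- x > stats::median(x)
  if (!any(high) || all(high)) stop("median split produced an empty group")
  high
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS statistic with the asymptotic p-value (ties are
#' tolerated; the exact method is not attempted).
#'
#' @param a,b Numeric samples.
#' @return List with `statistic` and `p_value`.
#' @export
ks_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided", exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}
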