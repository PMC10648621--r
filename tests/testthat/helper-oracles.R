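# Independent oracles: deliberately naive implementations used only to
# generate expected values. They share no code with the package internals.

# Negative log partial likelihood by explicit double loop, no log-sum-exp.
oracle_nlpl <- function(risk, time, event) {
  out <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      denom <- 0
      for (j in seq_along(time)) if (time[j] >= time[i]) denom <- denom + exp(risk[j])
      out <- out - (risk[i] - log(denom))
    }
  }
  out
}

# Concordance by exhaustive enumeration of ordered pairs.
oracle_cindex <- function(risk, time, event, ties = c("half", "strict")) {
  ties <- match.arg(ties)
  num <- 0; den <- 0
  for (j in seq_along(time)) for (i in seq_along(time)) {
    if (event[j] == 1 && time[j] < time[i]) {
      den <- den + 1
      if (risk[j] > risk[i]) num <- num + 1
      else if (risk[j] == risk[i] && ties == "half") num <- num + 0.5
    }
  }
  num / den
}

# Product-limit estimator applied by hand over distinct event times.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts)); s <- 1
  for (k in seq_along(ts)) {
    n_k <- sum(time >= ts[k])
    d_k <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d_k / n_k)
    surv[k] <- s
  }
  data.frame(time = ts, survival = surv)
}

# Two-group log-rank chi-square from observed minus expected sums.
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b); event <- c(event_a, event_b)
  in_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    n <- sum(time >= t); n_a <- sum(time >= t & in_a)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & in_a)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Sort-and-cut selection of the top n pairs of a score matrix, ties broken by
# (mean weight desc, gene index, pathway index).
oracle_top_pairs <- function(S, n_keep, mean_weights = NULL) {
  df <- data.frame(gene = as.vector(row(S)), pathway = as.vector(col(S)),
                   s = as.vector(S),
                   w = if (is.null(mean_weights)) 0 else as.vector(mean_weights))
  df <- df[order(-df$s, -df$w, df$gene, df$pathway), ]
  R <- matrix(0, nrow(S), ncol(S))
  for (k in seq_len(n_keep)) R[df$gene[k], df$pathway[k]] <- 1
  R
}

# Random censored survival data for oracle-equivalence sweeps.
random_surv <- function(n, seed) {
  set.seed(seed)
  list(risk = round(rnorm(n), 2),
       time = sample(seq_len(max(3L, n %/% 2)), n, replace = TRUE),
       event = rbinom(n, 1, 0.7))
}
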