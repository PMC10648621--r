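#' Specification of a synthetic survival dataset with planted hidden genes
#'
#' The generator emulates preprocessed expression data (i.i.d. standard
#' normal features) with pathway-structured risk: each pathway's activity is
#' the mean expression of its TRUE members - the curated (prior) members plus
#' a few planted "hidden" members that the prior mask omits - scaled to unit
#' variance, so `effect_size` reads as a log-hazard ratio per activity
#' standard deviation. The log-risk is `effect_size` times the sum of
#' activities plus Gaussian noise, event times
#' are exponential with rate `exp(log_risk)` (proportional hazards), and
#' censoring times are exponential with the rate tuned so the realized
#' censoring fraction lands near the target.
#'
#' @param n_samples Number of samples (default 300).
#' @param n_genes Number of genes (default 150).
#' @param pathways List of `c(prior, hidden)` member counts per pathway
#'   (default three pathways of 10 prior + 2 hidden).
#' @param effect_size Per-pathway risk coefficient (default 1.5).
#' @param noise_sd Standard deviation of the residual log-risk noise
#'   (default 0.5).
#' @param censoring_rate_target Desired censored fraction in (0, 1)
#'   (default 0.3).
#' @param baseline One of `"exponential"` (default) or `"weibull"`; Weibull
#'   uses shape 1.5 with the same rate scale.
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 300L, n_genes = 150L,
                           pathways = list(c(10L, 2L), c(10L, 2L), c(10L, 2L)),
                           effect_size = 1.5, noise_sd = 0.5,
                           censoring_rate_target = 0.3,
                           baseline = c("exponential", "weibull"),
                           seed = 1L) {
  baseline <- match.arg(baseline)
  stopifnot(n_samples >= 2L, n_genes >= 1L, length(pathways) >= 1L,
            effect_size >= 0, noise_sd >= 0,
            censoring_rate_target > 0, censoring_rate_target < 1)
  counts <- vapply(pathways, function(p) sum(p[1:2]), numeric(1))
  if (sum(counts) > n_genes)
    stop("pathway member counts exceed the number of genes")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes), pathways = pathways,
                 effect_size = effect_size, noise_sd = noise_sd,
                 censoring_rate_target = censoring_rate_target,
                 baseline = baseline, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Tune the exponential censoring rate so the realized censored fraction is as
# close as possible to the target, given event times and the censoring
# uniforms (internal). Monotone in the rate, so bisection suffices.
tune_censoring <- function(t_event, u, target, tol = 0.1) {
  frac <- function(rate) mean(-log(u) / rate < t_event)
  lo <- 1e-8; hi <- 1e8
  for (it in 1:200) {
    mid <- sqrt(lo * hi)
    if (frac(mid) < target) lo <- mid else hi <- mid
  }
  rate <- sqrt(lo * hi)
  if (abs(frac(rate) - target) > tol)
    stop(sprintf("cannot realize censoring near %.2f (achieved %.2f)",
                 target, frac(rate)))
  rate
}

#' Generate a synthetic survival dataset with known pathway structure
#'
#' @param spec A [synthetic_spec()].
#' @return List with `data` (a [survival_dataset()]), `prior_mask` (hidden
#'   members omitted), `truth_mask` (hidden members included), `log_risk`
#'   (the true per-sample log-risk) and `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; G <- spec$n_genes
  gene_ids <- sprintf("g%03d", seq_len(G))
  sample_ids <- sprintf("s%03d", seq_len(n))
  X <- matrix(stats::rnorm(n * G), n, G, dimnames = list(sample_ids, gene_ids))
  P <- length(spec$pathways)
  pw_names <- sprintf("pathway_%d", seq_len(P))
  prior <- matrix(0, G, P, dimnames = list(gene_ids, pw_names))
  truth <- prior
  nxt <- 1L
  for (j in seq_len(P)) {
    np <- spec$pathways[[j]][1L]; nh <- spec$pathways[[j]][2L]
    idx <- nxt:(nxt + np + nh - 1L)
    nxt <- nxt + np + nh
    prior_idx <- idx[seq_len(np)]
    hidden_idx <- if (nh > 0L) idx[np + seq_len(nh)] else integer(0)
    prior[prior_idx, j] <- 1
    truth[c(prior_idx, hidden_idx), j] <- 1
  }
  # Pathway activity: mean expression of the TRUE members, scaled to unit
  # variance (mean of m iid standard normals has sd 1/sqrt(m)), so that
  # effect_size reads as a log-hazard ratio per activity standard deviation.
  activity <- vapply(seq_len(P), function(j) {
    m <- sum(truth[, j] == 1)
    rowMeans(X[, truth[, j] == 1, drop = FALSE]) * sqrt(m)
  }, numeric(n))
  log_risk <- spec$effect_size * rowSums(activity) +
    stats::rnorm(n, 0, spec$noise_sd)
  rate <- exp(log_risk)
  t_event <- switch(spec$baseline,
                    exponential = stats::rexp(n, rate = rate),
                    weibull = stats::rweibull(n, shape = 1.5,
                                              scale = rate^(-1 / 1.5)))
  u <- stats::runif(n)
  c_rate <- tune_censoring(t_event, u, spec$censoring_rate_target)
  t_cens <- -log(u) / c_rate
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  data <- structure(list(X = X, time = time, event = event,
                         sample_ids = sample_ids),
                    class = "surv_dataset")
  list(data = data, prior_mask = prior, truth_mask = truth,
       log_risk = log_risk, spec = spec)
}

#' Precision and recall of planted hidden pairs
#'
#' Hidden pairs are present in the truth mask but not the prior mask. Recall
#' is the fraction of hidden pairs that the expansion selected; precision is
#' the fraction of selected supplement pairs that are truly hidden.
#'
#' @param expanded An [select_expanded()] result.
#' @param truth_mask,prior_mask Truth and prior masks from
#'   [generate_synthetic()].
#' @return List with `precision`, `recall`, `n_hidden`, `n_supplement`.
#' @export
planted_recovery_report <- function(expanded, truth_mask, prior_mask) {
  stopifnot(all(dim(expanded$R) == dim(truth_mask)),
            all(dim(truth_mask) == dim(prior_mask)))
  hidden <- truth_mask == 1 & prior_mask == 0
  if (sum(hidden) == 0L) stop("no hidden pairs in the truth mask")
  supp <- expanded$R == 1 & prior_mask == 0
  tp <- sum(supp & hidden)
  list(precision = if (sum(supp) == 0L) NA_real_ else tp / sum(supp),
       recall = tp / sum(hidden),
       n_hidden = sum(hidden), n_supplement = sum(supp))
}
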