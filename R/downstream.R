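#' Leave-one-out recoverability testing
#'
#' For each prior gene-pathway pair in the panel, the pair is removed from
#' the mask, a resampled ensemble is fitted, and the "recovering probability"
#' is the fraction of runs in which that link comes back with positive
#' weight. The baseline is the occurrence probability of genuinely non-prior
#' pairs from the same runs (averaged per pair over the leave-one-out
#' experiments). A left-out gene that matters should be recovered far more
#' often than a random outside gene; the two distributions are compared with
#' a two-sample Kolmogorov-Smirnov test.
#'
#' @inheritParams pretrain
#' @param runs_per_gene Resampled fits per left-out pair (default 20; the
#'   full-scale protocol uses 100).
#' @param panel Optional integer matrix (rows: gene index, pathway index)
#'   restricting which prior pairs are left out; default all prior pairs.
#' @param subsample Subsample fraction per run (default 0.9).
#' @return Object of class `recovery_report`: `loo` (data.frame gene,
#'   pathway, recovering_probability, rank, pool_size), `nonprior_probability`
#'   (vector over non-prior pairs), `ks_statistic`, `ks_p`.
#' @export
recoverability_test <- function(data, mask, cfg, runs_per_gene = 20L,
                                panel = NULL, subsample = 0.9) {
  stopifnot(runs_per_gene >= 1L)
  validate_mask(mask)
  prior_pairs <- which(mask == 1, arr.ind = TRUE)
  if (is.null(panel)) panel <- prior_pairs
  panel <- as.matrix(panel)
  loo <- vector("list", nrow(panel))
  np_mask <- mask == 0
  np_sum <- matrix(0, nrow(mask), ncol(mask))
  n_exp <- 0L
  for (r in seq_len(nrow(panel))) {
    i <- panel[r, 1L]; j <- panel[r, 2L]
    if (mask[i, j] != 1) stop("panel entries must be prior pairs")
    mask2 <- mask
    mask2[i, j] <- 0
    if (sum(mask2[, j]) == 0L) {
      warning(sprintf("removing gene %s would empty pathway %s; skipped",
                      rownames(mask)[i], colnames(mask)[j]))
      next
    }
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + 1000L * r
    ens <- run_ensemble(data, mask2, cfg_r, runs = runs_per_gene,
                        subsample = subsample)
    S <- occurrence_probability(ens)
    # candidate pool: all pairs absent from the modified mask, this pathway
    pool <- which(mask2[, j] == 0)
    rank_i <- rank(-S[pool, j], ties.method = "min")[match(i, pool)]
    loo[[r]] <- data.frame(gene = rownames(mask)[i],
                           pathway = colnames(mask)[j],
                           recovering_probability = S[i, j],
                           rank = rank_i, pool_size = length(pool),
                           stringsAsFactors = FALSE)
    np_sum <- np_sum + S
    n_exp <- n_exp + 1L
  }
  loo <- do.call(rbind, loo)
  if (is.null(loo) || nrow(loo) == 0L) stop("no recoverability experiments were run")
  np_mean <- np_sum / n_exp
  nonprior <- np_mean[np_mask]
  ks <- ks_compare(loo$recovering_probability, nonprior)
  structure(list(loo = loo, nonprior_probability = nonprior,
                 ks_statistic = ks$statistic, ks_p = ks$p_value),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("recovery_report: %d leave-one-out pairs, median recovering ",
                     "probability %.2f vs %.2f for %d non-prior pairs; KS D = %.3f, p = %.3g\n"),
              nrow(x$loo), stats::median(x$loo$recovering_probability),
              stats::median(x$nonprior_probability),
              length(x$nonprior_probability), x$ks_statistic, x$ks_p))
  invisible(x)
}

#' Single-gene Kaplan-Meier analysis
#'
#' Splits samples into high/low groups at the median of one gene's
#' expression, estimates a Kaplan-Meier curve per group and tests the
#' difference with the log-rank test.
#'
#' @param data A [survival_dataset()].
#' @param gene Gene identifier (column of `data$X`).
#' @return List with `curve_high`, `curve_low` ([kaplan_meier()] tables),
#'   `logrank_statistic`, `logrank_p` and the logical `high` group labels.
#' @export
single_gene_km <- function(data, gene) {
  if (!gene %in% colnames(data$X)) stop("gene not found: ", gene)
  x <- data$X[, gene]
  high <- median_split(x)
  if (sum(high) < 2L || sum(!high) < 2L)
    stop("median split left a group with fewer than 2 samples")
  lr <- logrank_test(data$time[high], data$event[high],
                     data$time[!high], data$event[!high])
  list(curve_high = kaplan_meier(data$time[high], data$event[high]),
       curve_low = kaplan_meier(data$time[!high], data$event[!high]),
       logrank_statistic = lr$statistic, logrank_p = lr$p_value,
       high = high)
}
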