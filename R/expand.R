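#' Resampled training ensemble for pathway expansion
#'
#' Draws `runs` subsamples of the data (default 90% of samples, without
#' replacement), runs the two-phase training on each, and records for each
#' run the binary occurrence matrix O (1 where the fitted first-layer weight
#' is strictly positive) together with the fitted weights. Run k uses seed
#' `cfg$seed + k` for both the subsample draw and the fit; a subsample
#' without any event is re-drawn.
#'
#' @inheritParams pretrain
#' @param runs Number of resampled fits (default 100).
#' @param subsample Fraction of samples drawn per run, in (0, 1]. Default 0.9.
#' @return Object of class `occurrence_ensemble`: list with `occ` and
#'   `weights` (genes x pathways x runs arrays), `seeds`, `subsample_idx`
#'   (list of index vectors) and the axis names.
#' @export
run_ensemble <- function(data, mask, cfg, runs = 100L, subsample = 0.9) {
  stopifnot(runs >= 1L, subsample > 0, subsample <= 1)
  validate_mask(mask)
  n <- nrow(data$X)
  m <- max(1L, floor(subsample * n))
  G <- nrow(mask); P <- ncol(mask)
  occ <- array(0, dim = c(G, P, runs))
  wts <- array(0, dim = c(G, P, runs))
  seeds <- cfg$seed + seq_len(runs)
  idx_list <- vector("list", runs)
  for (k in seq_len(runs)) {
    set.seed(seeds[k])
    idx <- sample.int(n, m)
    tries <- 0L
    while (sum(data$event[idx]) == 0L && tries < 100L) {
      idx <- sample.int(n, m)
      tries <- tries + 1L
    }
    if (sum(data$event[idx]) == 0L)
      stop(sprintf("run %d: could not draw a subsample containing an event", k))
    idx_list[[k]] <- sort(idx)
    cfg_k <- cfg
    cfg_k$seed <- seeds[k]
    cfg_k$track_cindex <- FALSE
    fit <- tryCatch(run_two_phase(subset_dataset(data, idx_list[[k]]), mask, cfg_k),
                    error = function(e) stop(sprintf("run %d failed: %s", k,
                                                     conditionMessage(e)), call. = FALSE))
    wts[, , k] <- fit$weights$W1
    occ[, , k] <- (fit$weights$W1 > 0) * 1
  }
  dn <- dimnames(mask)
  structure(list(occ = occ, weights = wts, seeds = seeds,
                 subsample_idx = idx_list,
                 gene_ids = dn[[1L]], pathway_names = dn[[2L]]),
            class = "occurrence_ensemble")
}

#' @export
print.occurrence_ensemble <- function(x, ...) {
  cat(sprintf("occurrence_ensemble: %d genes x %d pathways, %d runs\n",
              dim(x$occ)[1L], dim(x$occ)[2L], dim(x$occ)[3L]))
  invisible(x)
}

#' Occurrence-probability matrix of an ensemble
#'
#' Element-wise mean of the binary occurrence matrices: S(i, j) is the
#' fraction of resampled fits in which the link from gene i to pathway j
#' carried strictly positive weight.
#'
#' @param ens An [run_ensemble()] result.
#' @return Genes x pathways matrix with entries in [0, 1].
#' @export
occurrence_probability <- function(ens) {
  stopifnot(inherits(ens, "occurrence_ensemble"))
  S <- apply(ens$occ, c(1L, 2L), mean)
  dimnames(S) <- list(ens$gene_ids, ens$pathway_names)
  S
}

# Mean fitted first-layer weight across runs (internal; used for ranking and
# tie-breaking).
ensemble_mean_weights <- function(ens) {
  W <- apply(ens$weights, c(1L, 2L), mean)
  dimnames(W) <- list(ens$gene_ids, ens$pathway_names)
  W
}

#' Select the expanded pathways from an occurrence-probability matrix
#'
#' Keeps exactly \eqn{n^* = \lfloor (1+\alpha) K + 1/2 \rfloor} gene-pathway
#' pairs with the largest occurrence probabilities, where K is the number of
#' prior pairs (ones of the mask) - i.e. the prior pairs plus roughly
#' \eqn{\alpha K} supplements. Ties at the cut are broken deterministically:
#' larger mean fitted weight first (when supplied), then lower gene index,
#' then lower pathway index.
#'
#' @param S Occurrence-probability matrix (genes x pathways).
#' @param mask Prior mask, same shape.
#' @param alpha Expansion fraction, >= 0 (default 0.2).
#' @param mean_weights Optional matrix of ensemble-mean weights used as the
#'   first tie-break.
#' @return Object of class `expanded_pathways`: list with binary matrix `R`,
#'   `selected_count`, `alpha`, `K` and `S`.
#' @export
select_expanded <- function(S, mask, alpha = 0.2, mean_weights = NULL) {
  stopifnot(is.matrix(S), all(dim(S) == dim(mask)), alpha >= 0)
  K <- sum(mask == 1)
  if (K < 1L) stop("mask has no prior pairs")
  n_star <- floor((1 + alpha) * K + 0.5)
  if (n_star > length(S)) stop("selection size exceeds the number of gene-pathway pairs")
  gi <- row(S); pj <- col(S)
  tie1 <- if (is.null(mean_weights)) rep(0, length(S)) else -as.vector(mean_weights)
  ord <- order(-as.vector(S), tie1, as.vector(gi), as.vector(pj))
  keep <- ord[seq_len(n_star)]
  R <- matrix(0, nrow(S), ncol(S), dimnames = dimnames(S))
  R[keep] <- 1
  prior_lost <- sum(mask == 1 & R == 0)
  structure(list(R = R, selected_count = n_star, alpha = alpha, K = K, S = S,
                 prior_pairs_dropped = prior_lost),
            class = "expanded_pathways")
}

#' @export
print.expanded_pathways <- function(x, ...) {
  cat(sprintf("expanded_pathways: %d pairs kept (K = %d prior, alpha = %g); %d prior pair(s) fell below the cut\n",
              x$selected_count, x$K, x$alpha, x$prior_pairs_dropped))
  invisible(x)
}

#' Supplement genes per pathway
#'
#' Gene-pathway pairs selected into the expanded pathways but absent from the
#' prior mask, listed per pathway in decreasing occurrence probability.
#'
#' @param expanded An [select_expanded()] result.
#' @param mask Prior mask.
#' @return Named list (per pathway) of character vectors of gene ids; the
#'   full table is available via [supplement_table()].
#' @export
supplement_genes <- function(expanded, mask) {
  stopifnot(all(dim(expanded$R) == dim(mask)))
  S <- expanded$S
  out <- lapply(seq_len(ncol(mask)), function(j) {
    i <- which(expanded$R[, j] == 1 & mask[, j] == 0)
    i <- i[order(-S[i, j])]
    rownames(mask)[i]
  })
  names(out) <- colnames(mask)
  out
}

#' Supplement genes as a tidy table
#'
#' @inheritParams supplement_genes
#' @param mean_weights Optional ensemble-mean weight matrix to include.
#' @return Data.frame with columns `pathway`, `gene`,
#'   `occurrence_probability` and (if supplied) `mean_weight`.
#' @export
supplement_table <- function(expanded, mask, mean_weights = NULL) {
  sup <- which(expanded$R == 1 & mask == 0, arr.ind = TRUE)
  df <- data.frame(pathway = colnames(mask)[sup[, 2L]],
                   gene = rownames(mask)[sup[, 1L]],
                   occurrence_probability = expanded$S[sup],
                   stringsAsFactors = FALSE)
  if (!is.null(mean_weights)) df$mean_weight <- mean_weights[sup]
  df[order(df$pathway, -df$occurrence_probability), , drop = FALSE]
}

#' Ranked gene lists per pathway
#'
#' Genes ranked by the ensemble-mean fitted first-layer weight, in decreasing
#' order, per pathway - the input expected by preranked enrichment tools.
#'
#' @param ens An [run_ensemble()] result.
#' @return Named list of data.frames (`gene`, `score`), one per pathway.
#' @export
ranked_gene_lists <- function(ens) {
  W <- ensemble_mean_weights(ens)
  out <- lapply(seq_len(ncol(W)), function(j) {
    ord <- order(-W[, j])
    data.frame(gene = rownames(W)[ord], score = W[ord, j],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- colnames(W)
  out
}

#' Write an occurrence-probability matrix as TSV
#' @param S Matrix from [occurrence_probability()].
#' @param path Output file.
#' @export
write_occurrence_tsv <- function(S, path) {
  df <- data.frame(gene = rownames(S), S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pathways (e.g. expanded pathways) as a GMT file
#' @param pathways Named list of character vectors.
#' @param path Output file.
#' @param description Description field written for every set (default "na").
#' @export
write_gmt <- function(pathways, path, description = "na") {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, description, pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Extract expanded pathways as gene lists
#' @param expanded An [select_expanded()] result.
#' @return Named list of member gene ids per pathway (R column supports).
#' @export
expanded_gene_sets <- function(expanded) {
  R <- expanded$R
  out <- lapply(seq_len(ncol(R)), function(j) rownames(R)[R[, j] == 1])
  names(out) <- colnames(R)
  out
}

#' Write per-pathway ranked gene lists in RNK format
#' @param ranked Result of [ranked_gene_lists()].
#' @param dir Output directory (created if missing); one
#'   `<pathway>.rnk` file per pathway, `gene<TAB>score`.
#' @export
write_rnk <- function(ranked, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(ranked)) {
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]+", "_", nm), ".rnk"))
    utils::write.table(ranked[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
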