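#' Validate a gene-by-pathway mask
#'
#' A mask is a binary genes x pathways matrix; every pathway (column) must
#' contain at least one gene. The all-ones matrix is the valid degenerate
#' case used in the exploration phase.
#'
#' @param mask Matrix with entries in {0, 1}.
#' @return The mask, invisibly, after validation.
#' @export
validate_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 1))) stop("mask entries must be 0 or 1")
  empty <- which(colSums(mask) == 0)
  if (length(empty) > 0L) {
    nm <- colnames(mask)[empty]
    if (is.null(nm)) nm <- as.character(empty)
    stop("mask column(s) with no genes: ", paste(nm, collapse = ", "))
  }
  invisible(mask)
}

# All-ones mask with the same shape/dimnames (internal).
ones_like <- function(mask) {
  E <- matrix(1, nrow(mask), ncol(mask), dimnames = dimnames(mask))
  E
}

#' Network weights for the three-layer survival network
#'
#' @param W1 Genes x pathways matrix, element-wise non-negative (first layer).
#' @param W2 Pathways x 1 matrix (second layer).
#' @return Object of class `network_weights`.
#' @export
network_weights <- function(W1, W2) {
  W2 <- matrix(as.numeric(W2), ncol = 1L)
  stopifnot(is.matrix(W1), ncol(W1) == nrow(W2))
  if (!all(is.finite(W1)) || !all(is.finite(W2))) stop("weights must be finite")
  if (min(W1) < 0) stop("W1 must be element-wise non-negative")
  structure(list(W1 = W1, W2 = W2), class = "network_weights")
}

# Random initialization: prior (mask = 1) first-layer entries uniform on
# (0, 0.1), everything else exactly 0; W2 uniform on (0, 1/sqrt(P)). W2 starts
# non-negative because with W1 clamped to the non-negative orthant a pathway
# whose output weight begins negative can be driven into a dead state (its
# W1 column crushed to 0 before W2 crosses sign); starting aligned with the
# constraint avoids the trap, and genuinely protective pathways can still
# learn a negative W2 through the small-magnitude region. Uses the current
# RNG state.
init_weights <- function(mask) {
  G <- nrow(mask); P <- ncol(mask)
  W1 <- matrix(0, G, P, dimnames = dimnames(mask))
  on <- mask == 1
  W1[on] <- stats::runif(sum(on), 0, 0.1)
  W2 <- matrix(stats::runif(P, 0, 1 / sqrt(P)), ncol = 1L)
  network_weights(W1, W2)
}

#' Forward pass of the masked survival network
#'
#' Computes \eqn{f_W(x) = \tanh(\tanh(x (W_1 \odot M)) W_2)}, one log-risk
#' score per sample, bounded in (-1, 1). Entries of `W1` where the mask is 0
#' cannot influence the output.
#'
#' @param X Samples x genes matrix.
#' @param weights A [network_weights()] object.
#' @param mask Genes x pathways binary mask (prior mask M, or all-ones for
#'   the fully connected variant).
#' @return Numeric vector of risk scores, length `nrow(X)`.
#' @export
forward_risk <- function(X, weights, mask) {
  if (ncol(X) != nrow(mask)) stop("X and mask disagree on the number of genes")
  if (!all(dim(weights$W1) == dim(mask))) stop("W1 and mask shapes differ")
  H <- tanh(X %*% (weights$W1 * mask))
  drop(tanh(H %*% weights$W2))
}

#' Standard-deviation penalty on prior first-layer weights
#'
#' Population standard deviation of the `W1` entries at mask = 1 positions,
#' pooled across pathways. It encodes the assumption that genes within a
#' prior functional module carry comparable importance. With `per_pathway =
#' TRUE` the penalty is instead the sum of per-column standard deviations.
#'
#' @inheritParams forward_risk
#' @param per_pathway Pool over all prior entries (default) or per pathway.
#' @return Non-negative scalar (0 when fewer than 2 entries are in scope).
#' @export
std_penalty <- function(weights, mask, per_pathway = FALSE) {
  if (per_pathway) {
    return(sum(vapply(seq_len(ncol(mask)), function(j) {
      w <- weights$W1[mask[, j] == 1, j]
      if (length(w) < 2L) 0 else sqrt(mean((w - mean(w))^2))
    }, numeric(1))))
  }
  w <- weights$W1[mask == 1]
  if (length(w) < 2L) return(0)
  sqrt(mean((w - mean(w))^2))
}

#' L1 penalty on non-prior first-layer weights
#'
#' Sum of absolute values of `W1` where the prior mask is 0, i.e. the penalty
#' \eqn{\|W_1 \odot (1 - M)\|_1} that keeps exploration sparse.
#'
#' @inheritParams forward_risk
#' @return Non-negative scalar.
#' @export
l1_penalty <- function(weights, mask) {
  sum(abs(weights$W1[mask == 0]))
}

#' Project first-layer weights onto the non-negative orthant
#'
#' @inheritParams forward_risk
#' @return Updated `network_weights` with `W1 = pmax(W1, 0)`; `W2` untouched.
#' @export
project_nonneg <- function(weights) {
  weights$W1[weights$W1 < 0] <- 0
  weights
}

#' Proximal soft-threshold of non-prior first-layer weights
#'
#' Applies the L1 proximal operator `sign(w) * max(|w| - threshold, 0)` to
#' entries with mask = 0 only. Prior entries are never shrunk. This is what
#' makes exact zeros - and hence the binary occurrence indicator - realizable.
#'
#' @inheritParams forward_risk
#' @param threshold Non-negative shrinkage amount: a scalar, or a matrix the
#'   shape of `W1` for per-coordinate thresholds (the trainer passes
#'   `mu_l1 * learning_rate` rescaled by Adam's per-coordinate metric, which
#'   is the exact proximal step for the L1 term under that metric).
#' @return Updated `network_weights`.
#' @export
prox_l1_nonprior <- function(weights, mask, threshold) {
  stopifnot(all(threshold >= 0))
  off <- mask == 0
  thr <- if (length(threshold) == 1L) threshold else threshold[off]
  w <- weights$W1[off]
  weights$W1[off] <- sign(w) * pmax(abs(w) - thr, 0)
  weights
}

# Loss and analytic gradients of the phase loss (internal).
# loss = neg log partial likelihood of forward_risk(X, W, mask)
#        + lambda_std * std_penalty (pretraining phase; pass 0 in phase 2).
# The L1 term is handled proximally by the trainer, never differentiated.
network_grad <- function(X, weights, mask, time, event, lambda_std = 0) {
  A <- weights$W1 * mask
  V <- X %*% A
  H <- tanh(V)
  U <- H %*% weights$W2
  f <- drop(tanh(U))
  loss <- neg_log_partial_likelihood(f, time, event)
  g_f <- nlpl_gradient(f, time, event)
  g_u <- g_f * (1 - f^2)
  gW2 <- crossprod(H, g_u)
  g_H <- tcrossprod(g_u, weights$W2)
  g_V <- g_H * (1 - H^2)
  gW1 <- crossprod(X, g_V) * mask
  if (lambda_std > 0) {
    on <- mask == 1
    w <- weights$W1[on]
    m <- length(w)
    if (m >= 2L) {
      s <- sqrt(mean((w - mean(w))^2))
      loss <- loss + lambda_std * s
      if (s > 0) gW1[on] <- gW1[on] + lambda_std * (w - mean(w)) / (m * s)
    }
  }
  list(loss = loss, gW1 = gW1, gW2 = gW2, risk = f)
}
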