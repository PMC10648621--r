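#' Training configuration
#'
#' Bundles the optimization hyperparameters. Defaults follow the standard
#' recipe for this model: full-batch Adam at learning rate 0.05, 100 epochs
#' per phase, penalty weights lambda = mu = 1.
#'
#' @param learning_rate Adam step size. Default 0.05.
#' @param epochs_pretrain Epochs of the prior-mask (exploitation) phase.
#' @param epochs_train Epochs of the fully connected (exploration) phase.
#' @param lambda_std Weight of the standard-deviation penalty in the
#'   pretraining loss. Default 1.
#' @param mu_l1 Weight of the L1 penalty on non-prior links in the training
#'   loss (applied proximally). Default 1.
#' @param seed Integer seed; fixes initialization, fold splits, resampling.
#' @param track_cindex Record the concordance index per epoch in the history?
#'   Default TRUE (turn off inside large ensembles for speed).
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.05, epochs_pretrain = 100L,
                         epochs_train = 100L, lambda_std = 1, mu_l1 = 1,
                         seed = 1L, track_cindex = TRUE,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(learning_rate > 0, epochs_pretrain >= 1L, epochs_train >= 1L,
            lambda_std >= 0, mu_l1 >= 0)
  structure(list(learning_rate = learning_rate,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_train = as.integer(epochs_train),
                 lambda_std = lambda_std, mu_l1 = mu_l1,
                 seed = as.integer(seed), track_cindex = isTRUE(track_cindex),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

# Adam state and update (internal). state holds first/second moments per
# weight matrix plus the step counter.
adam_init <- function(weights) {
  list(m1 = weights$W1 * 0, v1 = weights$W1 * 0,
       m2 = weights$W2 * 0, v2 = weights$W2 * 0, t = 0L)
}

adam_step <- function(weights, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  state$m1 <- cfg$beta1 * state$m1 + (1 - cfg$beta1) * grads$gW1
  state$v1 <- cfg$beta2 * state$v1 + (1 - cfg$beta2) * grads$gW1^2
  precond1 <- sqrt(state$v1 / bc2) + cfg$eps
  weights$W1 <- weights$W1 - cfg$learning_rate * (state$m1 / bc1) / precond1
  state$m2 <- cfg$beta1 * state$m2 + (1 - cfg$beta1) * grads$gW2
  state$v2 <- cfg$beta2 * state$v2 + (1 - cfg$beta2) * grads$gW2^2
  weights$W2 <- weights$W2 -
    cfg$learning_rate * (state$m2 / bc1) / (sqrt(state$v2 / bc2) + cfg$eps)
  # preconditioner returned so the proximal L1 step can share Adam's metric
  list(weights = weights, state = state, precond1 = precond1)
}

# One recorded epoch row (internal).
history_row <- function(phase, epoch, loss, data, test_data, weights, mask, track) {
  ci_tr <- NA_real_; ci_te <- NA_real_
  if (track) {
    ci_tr <- concordance_index(forward_risk(data$X, weights, mask), data$time, data$event)
    if (!is.null(test_data))
      ci_te <- concordance_index(forward_risk(test_data$X, weights, mask),
                                 test_data$time, test_data$event)
  }
  data.frame(phase = phase, epoch = epoch, loss = loss,
             cindex_train = ci_tr, cindex_test = ci_te)
}

# Core full-batch training loop shared by both phases (internal).
# phase "pretrain": forward under `mask`, std penalty, no prox; non-prior
#   entries stay exactly 0 because the masked gradient is 0 there.
# phase "train": forward under the all-ones mask, no std penalty, proximal
#   L1 step (threshold mu_l1 * lr) on non-prior entries after each update.
run_phase <- function(data, mask, weights, cfg, epochs, phase,
                      test_data = NULL) {
  validate_mask(mask)
  if (sum(data$event) == 0L) stop("training data has no events")
  fwd_mask <- if (phase == "pretrain") mask else ones_like(mask)
  lambda <- if (phase == "pretrain") cfg$lambda_std else 0
  state <- adam_init(weights)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    gr <- network_grad(data$X, weights, fwd_mask, data$time, data$event, lambda)
    if (!is.finite(gr$loss))
      stop(sprintf("non-finite loss at %s epoch %d", phase, ep))
    st <- adam_step(weights, gr, state, cfg)
    weights <- st$weights; state <- st$state
    if (phase == "train")
      weights <- prox_l1_nonprior(weights, mask,
                                  cfg$mu_l1 * cfg$learning_rate / st$precond1)
    weights <- project_nonneg(weights)
    hist[[ep]] <- history_row(phase, ep, gr$loss, data, test_data, weights,
                              fwd_mask, cfg$track_cindex)
  }
  list(weights = weights, history = do.call(rbind, hist))
}

#' Pretraining phase: exploit the prior pathways
#'
#' Minimizes the negative log partial likelihood of the masked network plus
#' `lambda_std` times the standard-deviation penalty, under the prior mask.
#' First-layer entries outside the prior stay exactly zero throughout.
#'
#' @param data A [survival_dataset()].
#' @param mask Prior genes x pathways mask.
#' @param cfg A [train_config()].
#' @param weights Optional warm-start weights; when NULL (default) weights are
#'   drawn from the seeded initializer.
#' @param test_data Optional held-out `surv_dataset` monitored in the history.
#' @return List with `weights` and `history` (data.frame: phase, epoch, loss,
#'   cindex_train, cindex_test).
#' @export
pretrain <- function(data, mask, cfg, weights = NULL, test_data = NULL) {
  if (is.null(weights)) weights <- init_weights(mask)
  run_phase(data, mask, weights, cfg, cfg$epochs_pretrain, "pretrain", test_data)
}

#' Training phase: explore beyond the prior pathways
#'
#' Continues from pretrained weights with the first layer fully connected,
#' handling the L1 penalty on non-prior links proximally (soft threshold
#' `mu_l1 * learning_rate` per step) so that unsupported links are exactly
#' zero, followed by the non-negativity projection.
#'
#' @inheritParams pretrain
#' @param weights Warm-start weights from [pretrain()]; must be element-wise
#'   non-negative.
#' @return List with `weights` and `history`.
#' @export
train_expand_phase <- function(data, mask, weights, cfg, test_data = NULL) {
  if (min(weights$W1) < 0) stop("warm-start W1 has negative entries")
  run_phase(data, mask, weights, cfg, cfg$epochs_train, "train", test_data)
}

#' Two-phase training: exploit, then explore
#'
#' Runs [pretrain()] followed by [train_expand_phase()] from the pretrained
#' weights, with one seed governing the whole run.
#'
#' @inheritParams pretrain
#' @return List with `weights` and the concatenated `history` (length
#'   `epochs_pretrain + epochs_train`).
#' @export
run_two_phase <- function(data, mask, cfg, test_data = NULL) {
  set.seed(cfg$seed)
  p1 <- pretrain(data, mask, cfg, test_data = test_data)
  p2 <- train_expand_phase(data, mask, p1$weights, cfg, test_data = test_data)
  list(weights = p2$weights, history = rbind(p1$history, p2$history),
       weights_pretrain = p1$weights)
}

#' Prior-network baseline
#'
#' The exploitation loss only, under the prior mask, for the full epoch
#' budget (`epochs_pretrain + epochs_train`).
#'
#' @inheritParams pretrain
#' @return List with `weights` and `history`.
#' @export
train_prior_net <- function(data, mask, cfg, test_data = NULL) {
  set.seed(cfg$seed)
  weights <- init_weights(mask)
  run_phase(data, mask, weights, cfg, cfg$epochs_pretrain + cfg$epochs_train,
            "pretrain", test_data)
}

#' Fully connected baseline
#'
#' The exploration loss only (all-ones connectivity with the proximal L1
#' penalty on non-prior links), from random initialization over all entries,
#' for the full epoch budget.
#'
#' @inheritParams pretrain
#' @return List with `weights` and `history`.
#' @export
train_fc_net <- function(data, mask, cfg, test_data = NULL) {
  set.seed(cfg$seed)
  weights <- init_weights(ones_like(mask))
  cfg2 <- cfg
  cfg2$epochs_train <- cfg$epochs_pretrain + cfg$epochs_train
  run_phase(data, mask, weights, cfg2, cfg2$epochs_train, "train", test_data)
}

#' K-fold cross-validation of the held-out concordance index
#'
#' Samples are partitioned into `folds` seeded folds; each fold is held out
#' once while the chosen method trains on the rest. If a training split has
#' no events the folds are re-drawn once before failing.
#'
#' @inheritParams pretrain
#' @param folds Number of folds (default 10, i.e. a 9:1 train:test ratio).
#' @param method One of `"two_phase"`, `"prior_net"`, `"fc_net"`.
#' @return Data.frame with one row per fold: `fold`, `n_test`, `cindex`.
#' @export
cross_validate <- function(data, mask, cfg, folds = 10L,
                           method = c("two_phase", "prior_net", "fc_net")) {
  method <- match.arg(method)
  n <- nrow(data$X)
  stopifnot(folds >= 2L, folds <= n)
  set.seed(cfg$seed)
  assign_folds <- function() sample(rep_len(seq_len(folds), n))
  fold_id <- assign_folds()
  ok <- function(fid) all(vapply(seq_len(folds),
                                 function(k) sum(data$event[fid != k]) >= 1L,
                                 logical(1)))
  if (!ok(fold_id)) {
    fold_id <- assign_folds()
    if (!ok(fold_id)) stop("a training fold has no events even after re-drawing")
  }
  res <- lapply(seq_len(folds), function(k) {
    tr <- subset_dataset(data, which(fold_id != k))
    te <- subset_dataset(data, which(fold_id == k))
    cfg_k <- cfg
    cfg_k$track_cindex <- FALSE
    fit <- switch(method,
                  two_phase = run_two_phase(tr, mask, cfg_k),
                  prior_net = train_prior_net(tr, mask, cfg_k),
                  fc_net = train_fc_net(tr, mask, cfg_k))
    eval_mask <- if (method == "prior_net") mask else ones_like(mask)
    risk <- forward_risk(te$X, fit$weights, eval_mask)
    data.frame(fold = k, n_test = nrow(te$X),
               cindex = concordance_index(risk, te$time, te$event))
  })
  do.call(rbind, res)
}
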