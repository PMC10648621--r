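# Small in-code fixtures shared across test files.

write_tsv_fixture <- function(df, dir = tempdir()) {
  f <- tempfile(tmpdir = dir, fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# 3 samples x 2 genes expression TSV (samples as rows).
expr_fixture <- function() {
  write_tsv_fixture(data.frame(sample = c("s1", "s2", "s3"),
                               gA = c(1, 2, 3), gB = c(4, 5, 6)))
}

gmt_fixture <- function(lines) {
  f <- tempfile(fileext = ".gmt")
  writeLines(lines, f)
  f
}

# Tiny two-pathway mask over 6 genes.
toy_mask <- function() {
  M <- matrix(0, 6, 2, dimnames = list(paste0("g", 1:6), c("pwA", "pwB")))
  M[1:3, 1] <- 1
  M[3:5, 2] <- 1
  M
}

# Small but non-trivial survival dataset with pathway-driven risk over the
# toy mask; gene 6 is a hidden member of pwA. High SNR so short trainings
# behave predictably.
toy_dataset <- function(n = 60, seed = 7, beta = 1.2) {
  set.seed(seed)
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(sprintf("s%02d", 1:n), paste0("g", 1:6)))
  lr <- beta * rowSums(X[, c(1:3, 6)]) / 2
  t_event <- rexp(n, exp(lr))
  t_cens <- rexp(n, 0.25 * mean(exp(lr)))
  structure(list(X = X, time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens),
                 sample_ids = rownames(X)),
            class = "surv_dataset")
}

# Minimal high-SNR planted-gene scenario for training/expansion tests:
# one pathway, 4 prior + 1 hidden member, strong per-gene effect.
mini_planted <- function(seed) {
  generate_synthetic(synthetic_spec(
    n_samples = 150L, n_genes = 40L, pathways = list(c(4L, 1L)),
    effect_size = 2, noise_sd = 0.25, seed = seed))
}

quick_cfg <- function(seed = 1, epochs_pretrain = 30L, epochs_train = 30L, ...) {
  train_config(seed = seed, epochs_pretrain = epochs_pretrain,
               epochs_train = epochs_train, track_cindex = FALSE, ...)
}
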