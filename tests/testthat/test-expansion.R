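test_that("a single full-sample run gives the degenerate occurrence ensemble", {
  d <- toy_dataset()
  M <- toy_mask()
  ens <- run_ensemble(d, M, quick_cfg(seed = 4), runs = 1, subsample = 1.0)
  expect_equal(dim(ens$occ), c(6L, 2L, 1L))
  expect_identical(ens$subsample_idx[[1]], seq_len(nrow(d$X)))
  # occurrence is the strict-positivity indicator of the fitted weights
  expect_equal(ens$occ[, , 1], (ens$weights[, , 1] > 0) * 1)
  S <- occurrence_probability(ens)
  expect_equal(unname(S), ens$occ[, , 1])
})

test_that("resampling is seeded, reproducible, and draws distinct subsets", {
  d <- toy_dataset(n = 80, seed = 3)
  M <- toy_mask()
  cfg <- quick_cfg(seed = 9, epochs_pretrain = 5L, epochs_train = 5L)
  e1 <- run_ensemble(d, M, cfg, runs = 3)
  e2 <- run_ensemble(d, M, cfg, runs = 3)
  expect_identical(e1$occ, e2$occ)
  expect_identical(e1$subsample_idx, e2$subsample_idx)
  keys <- vapply(e1$subsample_idx, paste, character(1), collapse = ",")
  expect_equal(length(unique(keys)), 3L)
  expect_true(all(lengths(e1$subsample_idx) == floor(0.9 * 80)))
})

test_that("occurrence probability is the elementwise run mean", {
  set.seed(12)
  occ <- array(rbinom(4 * 2 * 5, 1, 0.5), dim = c(4, 2, 5))
  ens <- structure(list(occ = occ, weights = occ, seeds = 1:5,
                        subsample_idx = list(), gene_ids = paste0("g", 1:4),
                        pathway_names = c("a", "b")),
                   class = "occurrence_ensemble")
  S <- occurrence_probability(ens)
  direct <- matrix(0, 4, 2)
  for (k in 1:5) direct <- direct + occ[, , k]
  expect_equal(unname(S), direct / 5)
  # entries are run counts over 5 (e.g. present in 3 of 5 runs -> 0.6)
  expect_equal(5 * S, round(5 * S))
})

test_that("a planted hidden gene out-occurs typical non-prior genes", {
  sim <- mini_planted(5)
  ens <- run_ensemble(sim$data, sim$prior_mask,
                      train_config(seed = 50, track_cindex = FALSE), runs = 20)
  S <- occurrence_probability(ens)
  hid <- which(sim$truth_mask == 1 & sim$prior_mask == 0)
  noise <- S[sim$prior_mask == 0 & sim$truth_mask == 0]
  expect_gt(S[hid], median(noise))
  expect_gt(S[hid], 0.6)
})

test_that("expansion keeps exactly floor((1+alpha)K + 1/2) pairs, top-ranked by S", {
  # deterministic S with distinct values, checked against the sort-and-cut oracle
  set.seed(7)
  S <- matrix(runif(12), 6, 2, dimnames = list(paste0("g", 1:6), c("a", "b")))
  M <- matrix(0, 6, 2, dimnames = dimnames(S))
  M[cbind(c(1, 2, 3, 1, 4), c(1, 1, 1, 2, 2))] <- 1   # K = 5
  ex <- select_expanded(S, M, alpha = 0.2)
  n_star <- floor(1.2 * 5 + 0.5)
  expect_equal(ex$selected_count, n_star)
  expect_equal(sum(ex$R), n_star)
  expect_equal(unname(ex$R), oracle_top_pairs(S, n_star))

  # alpha = 0 with saturated prior probabilities reproduces the prior mask
  S1 <- matrix(0, 6, 2, dimnames = dimnames(S))
  S1[M == 1] <- 1
  S1[M == 0] <- runif(sum(M == 0), 0, 0.9)
  ex0 <- select_expanded(S1, M, alpha = 0)
  expect_equal(ex0$R, M)

  expect_error(select_expanded(S, M, alpha = 50), "exceeds")
})

test_that("the LGG-sized prior with alpha 0.2 yields 83 kept pairs (69 + 14)", {
  sizes <- c(19L, 13L, 15L, 13L, 9L)
  G <- 200L
  M <- matrix(0, G, 5)
  start <- 1L
  for (j in 1:5) { M[start:(start + sizes[j] - 1L), j] <- 1; start <- start + sizes[j] }
  set.seed(31)
  S <- matrix(runif(G * 5, 0, 0.99), G, 5)
  S[M == 1] <- 1
  ex <- select_expanded(S, M, alpha = 0.2)
  expect_equal(ex$K, 69L)
  expect_equal(ex$selected_count, 83)
  expect_equal(sum(ex$R == 1 & M == 0), 14)   # the 20% supplement
})

test_that("selections are nested as alpha grows", {
  set.seed(13)
  S <- matrix(runif(50), 10, 5)
  M <- matrix(rbinom(50, 1, 0.3), 10, 5)
  M[1, ] <- 1
  prev <- NULL
  for (a in c(0, 0.1, 0.2, 0.5, 1)) {
    R <- select_expanded(S, M, alpha = a)$R
    if (!is.null(prev)) expect_true(all(R[prev == 1] == 1))
    prev <- R
  }
})

test_that("supplement genes are the selected non-prior pairs, ordered by S", {
  M <- toy_mask()
  S <- matrix(0, 6, 2, dimnames = dimnames(M))
  S[M == 1] <- 1
  ex <- list(R = M, S = S, selected_count = sum(M), alpha = 0, K = sum(M))
  class(ex) <- "expanded_pathways"
  sup <- supplement_genes(ex, M)
  expect_true(all(lengths(sup) == 0))

  R2 <- M; R2["g6", "pwA"] <- 1
  S2 <- S; S2["g6", "pwA"] <- 0.8
  ex2 <- ex; ex2$R <- R2; ex2$S <- S2
  sup2 <- supplement_genes(ex2, M)
  expect_identical(sup2$pwA, "g6")
  expect_identical(sup2$pwB, character(0))
  tab <- supplement_table(ex2, M)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$occurrence_probability, 0.8)
})

test_that("ranked gene lists follow the ensemble-mean weight", {
  W <- array(0, dim = c(3, 1, 3))
  W[, 1, 1] <- c(0.9, 0.0, 0.3)
  W[, 1, 2] <- c(0.7, 0.0, 0.5)
  W[, 1, 3] <- c(0.8, 0.0, 0.1)
  ens <- structure(list(occ = (W > 0) * 1, weights = W, seeds = 1:3,
                        subsample_idx = list(), gene_ids = c("g1", "g2", "g3"),
                        pathway_names = "pw"),
                   class = "occurrence_ensemble")
  rl <- ranked_gene_lists(ens)
  expect_identical(rl$pw$gene, c("g1", "g3", "g2"))
  expect_equal(rl$pw$score, c(0.8, 0.3, 0))
  # a gene with zero weight everywhere ranks below any positive gene
  expect_identical(rl$pw$gene[3], "g2")
})

test_that("expansion artifacts round-trip through their file formats", {
  M <- toy_mask()
  S <- matrix(round(runif(12), 2), 6, 2, dimnames = dimnames(M))
  f <- tempfile(fileext = ".tsv")
  write_occurrence_tsv(S, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), S, ignore_attr = TRUE)

  sets <- list(pwA = c("g1", "g2"), pwB = c("g3"))
  g <- tempfile(fileext = ".gmt")
  write_gmt(sets, g)
  expect_identical(read_gmt(g), sets)

  rl <- list(pw = data.frame(gene = c("g1", "g2"), score = c(0.5, 0.1)))
  d <- tempfile()
  write_rnk(rl, d)
  rnk <- utils::read.delim(file.path(d, "pw.rnk"), header = FALSE)
  expect_identical(rnk$V1, c("g1", "g2"))
})
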