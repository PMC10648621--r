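#' Read a gene-expression matrix from a tab-separated file
#'
#' Expects a header row of gene identifiers and a first column of sample
#' identifiers (the canonical samples-by-genes layout). Files written
#' genes-by-samples can be read with `orientation = "genes_rows"`, which
#' transposes after reading so the returned matrix is always samples x genes.
#'
#' @param path Path to a TSV file.
#' @param orientation Either `"samples_rows"` (default; rows are samples) or
#'   `"genes_rows"` (rows are genes, the transposed layout).
#' @return A numeric matrix, samples as rows and genes as columns, with
#'   dimnames taken from the file in file order.
#' @export
read_expression <- function(path, orientation = c("samples_rows", "genes_rows")) {
  orientation <- match.arg(orientation)
  # read.delim silently uniquifies duplicated header labels, so check the raw
  # header first
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]][-1L]
  .check_dup(hdr, if (orientation == "samples_rows") "gene id" else "sample id")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs an id column plus at least one data column")
  ids <- as.character(df[[1L]])
  cols <- colnames(df)[-1L]
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1L]
      stop(sprintf("non-numeric value in column '%s', data row %d of '%s'",
                   cols[j], if (is.na(bad)) NA_integer_ else bad, path))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "genes_rows") m <- t(m)
  .check_dup(rownames(m), "sample id")
  .check_dup(colnames(m), "gene id")
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  m
}

.check_dup <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d) > 0L)
    stop(sprintf("duplicate %s: %s", what, paste(utils::head(d, 5L), collapse = ", ")))
  invisible(x)
}

#' Read survival outcomes from a tab-separated file
#'
#' The file must have a header with columns `sample`, `time` and `event`
#' (event: 1 = observed, 0 = right-censored).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `sample` (character), `time` (positive
#'   numeric) and `event` (integer 0/1), in file order.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop("survival file is missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(sample = as.character(df$sample),
                    time = as.numeric(df$time),
                    event = as.integer(df$event),
                    stringsAsFactors = FALSE)
  .check_dup(out$sample, "sample id")
  if (any(!is.finite(out$time)) || any(out$time <= 0))
    stop("survival times must be finite and > 0")
  if (!all(out$event %in% c(0L, 1L))) stop("event indicator must be 0 or 1")
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one pathway per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. The description field is
#' discarded. Duplicate members within a pathway are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (pathway -> member gene ids), in
#'   file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  out <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member", k, length(f)))
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("pathway '%s' (line %d): duplicated members de-duplicated", f[1L], k))
      members <- unique(members)
    }
    out[[f[1L]]] <- members
  }
  out
}

#' Preprocess an expression matrix for model fitting
#'
#' Applies the standard chain for count-like expression data: optional
#' log2(x + 1) transform, removal of low-variability genes (across-sample
#' sample standard deviation must exceed `sd_threshold`), then per-gene
#' z-scoring to mean 0, sd 1.
#'
#' @param X Numeric matrix, samples x genes.
#' @param log_transform Apply log2(x + 1) before filtering? Default TRUE
#'   (appropriate for raw counts; set FALSE for data already in log space).
#' @param sd_threshold Keep genes with sd strictly greater than this.
#'   Default 1.
#' @return The filtered, z-scored matrix (samples x retained genes).
#' @export
preprocess_expression <- function(X, log_transform = TRUE, sd_threshold = 1) {
  stopifnot(is.matrix(X), sd_threshold >= 0)
  if (log_transform) {
    if (any(X < 0)) stop("log2(x+1) transform requested but matrix has negative values")
    X <- log2(X + 1)
  }
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > sd_threshold
  if (!any(keep)) stop("all genes removed by the variability filter (sd_threshold = ",
                       sd_threshold, ")")
  X <- X[, keep, drop = FALSE]
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  X
}

#' Build a gene-by-pathway incidence mask
#'
#' Produces the binary matrix M with M[i, j] = 1 iff gene i belongs to
#' pathway j. Pathway members absent from `gene_ids` (e.g. removed by the
#' variability filter) are dropped; the count of dropped members is reported
#' via `message()`.
#'
#' @param pathways Named list of character vectors, as from [read_gmt()].
#' @param gene_ids Character vector of genes defining the row order.
#' @return Binary matrix (genes x pathways) with dimnames.
#' @export
build_pathway_mask <- function(pathways, gene_ids) {
  stopifnot(is.list(pathways), length(pathways) >= 1L)
  if (is.null(names(pathways)) || any(!nzchar(names(pathways))))
    stop("pathways must be a named list")
  M <- matrix(0, nrow = length(gene_ids), ncol = length(pathways),
              dimnames = list(gene_ids, names(pathways)))
  dropped <- 0L
  for (j in seq_along(pathways)) {
    present <- intersect(pathways[[j]], gene_ids)
    dropped <- dropped + length(setdiff(pathways[[j]], gene_ids))
    if (length(present) == 0L)
      stop(sprintf("pathway '%s' has no members among the supplied genes", names(pathways)[j]))
    M[present, j] <- 1
  }
  if (dropped > 0L)
    message(dropped, " pathway member(s) absent from the expression genes were dropped")
  M
}

#' Assemble a model-ready survival dataset
#'
#' Joins an expression matrix with survival outcomes on sample id, keeping the
#' expression row order for samples present in both.
#'
#' @param X Numeric matrix, samples x genes, with rownames.
#' @param outcomes Data.frame with columns `sample`, `time`, `event`.
#' @return An object of class `surv_dataset`: list with `X` (matrix),
#'   `time`, `event` (aligned vectors) and `sample_ids`.
#' @export
survival_dataset <- function(X, outcomes) {
  stopifnot(is.matrix(X), !is.null(rownames(X)))
  idx <- match(rownames(X), outcomes$sample)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no samples shared between expression and outcomes")
  if (!all(keep))
    message(sum(!keep), " expression sample(s) without outcomes were dropped")
  X <- X[keep, , drop = FALSE]
  oc <- outcomes[idx[keep], ]
  structure(list(X = X, time = as.numeric(oc$time), event = as.integer(oc$event),
                 sample_ids = rownames(X)),
            class = "surv_dataset")
}

#' @export
print.surv_dataset <- function(x, ...) {
  cat(sprintf("surv_dataset: %d samples x %d genes, %d events (%.0f%% censored)\n",
              nrow(x$X), ncol(x$X), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

# Subset a surv_dataset by sample indices (internal).
subset_dataset <- function(data, idx) {
  structure(list(X = data$X[idx, , drop = FALSE],
                 time = data$time[idx], event = data$event[idx],
                 sample_ids = data$sample_ids[idx]),
            class = "surv_dataset")
}
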