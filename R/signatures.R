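#' Rank genes sample-wise
#'
#' Within each sample, features are ranked 1..n ascending in expression with
#' ties receiving the average rank, so every column's rank sum equals
#' n(n+1)/2. This is the basis of rank-driven single-sample signature
#' scoring: any strictly monotone transform of a sample's values leaves its
#' ranks, and hence its scores, unchanged.
#'
#' @param mat Sample-matrix tibble with at least 2 features.
#' @return A tibble of the same shape holding ranks.
#' @export
rank_genes <- function(mat) {
  m <- as_feature_matrix(mat)
  if (nrow(m) < 2L) stop("need at least 2 features to rank", call. = FALSE)
  r <- apply(m, 2, rank, ties.method = "average")
  rownames(r) <- rownames(m)
  as_sample_tibble(r, feature_col = names(mat)[1])
}

# Normalized mean-rank score for one sample's rank vector. With n genes
# ranked and m signature genes present, the mean rank of the signature lies
# in [(m+1)/2, (2n-m+1)/2]; the score maps that range onto [0, 1].
score_one_sample <- function(ranks, sig_idx) {
  n <- length(ranks)
  m <- length(sig_idx)
  mean_rank <- mean(ranks[sig_idx])
  lo <- (m + 1) / 2
  hi <- (2 * n - m + 1) / 2
  (mean_rank - lo) / (hi - lo)
}

#' Score gene signatures in single samples
#'
#' Rank-based single-sample scoring: genes are ranked within each sample,
#' each signature is scored by the mean rank of its member genes, normalized
#' by the theoretical extremes so the score lies in [0, 1] — 1 exactly when
#' the signature occupies the top m ranks of the sample, 0 when it occupies
#' the bottom m. Scoring is unidirectional (up-sets only); larger means more
#' signature-like. Gene symbols are matched case-insensitively after
#' whitespace stripping; genes absent from the matrix are dropped from the
#' signature and reported.
#'
#' @param mat Sample-matrix tibble of expression values (any monotone scale).
#' @param signatures Gene sets: a tibble with `set_name`/`gene` columns (see
#'   [read_gmt()]) or a named list of character vectors.
#'
#' @return A tibble, first column `signature`, one numeric score column per
#'   sample, of class `rte_signature_scores`. Attributes: `missing_genes`, a
#'   named list per signature of genes not found; `n_used`, genes scored per
#'   signature.
#' @export
score_signatures <- function(mat, signatures) {
  sets <- as_gene_set_list(signatures)
  if (length(sets) == 0L) stop("no signatures supplied", call. = FALSE)
  ranks <- as_feature_matrix(rank_genes(mat))
  n <- nrow(ranks)
  feat_key <- normalize_symbol(rownames(ranks))

  missing <- vector("list", length(sets))
  names(missing) <- names(sets)
  n_used <- integer(length(sets))
  names(n_used) <- names(sets)

  scores <- matrix(NA_real_, length(sets), ncol(ranks),
                   dimnames = list(names(sets), colnames(ranks)))
  for (nm in names(sets)) {
    idx <- match(normalize_symbol(sets[[nm]]), feat_key)
    missing[[nm]] <- sets[[nm]][is.na(idx)]
    idx <- idx[!is.na(idx)]
    m <- length(idx)
    if (m == 0L) {
      stop("signature '", nm, "' shares no gene with the matrix", call. = FALSE)
    }
    if (m == n) {
      stop("signature '", nm, "' covers every ranked gene; score undefined",
           call. = FALSE)
    }
    n_used[nm] <- m
    scores[nm, ] <- apply(ranks, 2, score_one_sample, sig_idx = idx)
  }
  out <- as_sample_tibble(scores, feature_col = "signature")
  attr(out, "missing_genes") <- missing
  attr(out, "n_used") <- n_used
  class(out) <- c("rte_signature_scores", class(out))
  out
}

normalize_symbol <- function(x) toupper(trimws(x))

#' Report genes missing from scored signatures
#'
#' @param scores A [score_signatures()] result.
#' @return A tibble `signature`, `n_used`, `n_missing`, `missing` (comma
#'   separated symbols).
#' @export
missing_gene_report <- function(scores) {
  mg <- attr(scores, "missing_genes")
  nu <- attr(scores, "n_used")
  if (is.null(mg)) stop("not a signature score object", call. = FALSE)
  tibble(
    signature = names(mg),
    n_used = as.integer(nu[names(mg)]),
    n_missing = unname(lengths(mg)),
    missing = unname(vapply(mg, paste, "", collapse = ","))
  )
}
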