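# Shared fixture builders: everything generated in code, nothing stored.

# tibble sample matrix from a base matrix
as_mat_tbl <- function(m, id = "feature_id") {
  tibble::as_tibble(cbind(stats::setNames(data.frame(rownames(m),
                                                     stringsAsFactors = FALSE), id),
                          as.data.frame(m)))
}

random_matrix_tbl <- function(n_feat, n_samp, seed = 1, prefix = "g") {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * n_samp), n_feat, n_samp,
              dimnames = list(paste0(prefix, seq_len(n_feat)),
                              paste0("s", seq_len(n_samp))))
  as_mat_tbl(m)
}

# random probes/repeats on one chromosome for assignment property tests
random_intervals <- function(n, seed, max_pos = 2000L, max_len = 120L) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = "chr1", start = start, end = start + len, strand = "+")
}

random_probes <- function(n, seed) {
  iv <- random_intervals(n, seed)
  iv$probe_id <- sprintf("p%03d", seq_len(n))
  iv$context <- "intergenic"
  iv[, c("probe_id", "chrom", "start", "end", "strand", "context")]
}

random_repeats <- function(n, seed) {
  iv <- random_intervals(n, seed + 1000L)
  fams <- rteage::rte_taxonomy()
  set.seed(seed + 2000L)
  pick <- sample.int(nrow(fams), n, replace = TRUE)
  iv$repeat_name <- sprintf("rep%03d", seq_len(n))
  iv$repeat_class <- fams$repeat_class[pick]
  iv$repeat_family <- fams$repeat_family[pick]
  iv
}

# literal O(n*m) assignment oracle: max overlap, ties by leftmost repeat
# start then lexicographic repeat_name
brute_force_assign <- function(probes, repeats) {
  res <- list()
  for (i in seq_len(nrow(probes))) {
    best <- NULL
    for (j in seq_len(nrow(repeats))) {
      if (probes$chrom[i] != repeats$chrom[j]) next
      ov <- min(probes$end[i], repeats$end[j]) -
        max(probes$start[i], repeats$start[j])
      if (ov < 1) next
      cand <- list(overlap_bp = ov, start = repeats$start[j],
                   name = repeats$repeat_name[j], j = j)
      if (is.null(best) ||
          cand$overlap_bp > best$overlap_bp ||
          (cand$overlap_bp == best$overlap_bp && cand$start < best$start) ||
          (cand$overlap_bp == best$overlap_bp && cand$start == best$start &&
           cand$name < best$name)) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      res[[length(res) + 1L]] <- tibble::tibble(
        probe_id = probes$probe_id[i],
        repeat_name = repeats$repeat_name[best$j],
        overlap_bp = as.integer(best$overlap_bp)
      )
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out)) out[order(out$probe_id), ] else out
}

# literal-loop oracle for the three-step kernel-CDF enrichment score
gsva_oracle <- function(x, sets) {
  G <- nrow(x); n <- ncol(x)
  h <- matrix(0.5, G, n, dimnames = dimnames(x))
  for (g in seq_len(G)) {
    s <- stats::sd(x[g, ])
    if (s > 0) {
      for (j in seq_len(n)) {
        acc <- 0
        for (k in seq_len(n)) acc <- acc + stats::pnorm((x[g, j] - x[g, k]) / (s / 4))
        h[g, j] <- acc / n
      }
    }
  }
  es <- matrix(NA_real_, length(sets), n,
               dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(n)) {
    ord <- order(h[, j], decreasing = TRUE)
    rnk <- integer(G); rnk[ord] <- seq_len(G)
    w <- abs(G / 2 - rnk)
    for (si in seq_along(sets)) {
      member <- rownames(x) %in% sets[[si]]
      m <- sum(member)
      wsum <- sum(w[member])
      run <- 0; mx <- 0; mn <- 0
      for (g in ord) {
        run <- run + if (member[g]) w[g] / wsum else -1 / (G - m)
        mx <- max(mx, run); mn <- min(mn, run)
      }
      es[si, j] <- mx + mn
    }
  }
  es
}

sc_recovery_once <- function(seed) {
  cfg <- synthetic_config(seed = seed)
  sc <- simulate_single_cell(cfg)
  pb <- suppressMessages(pseudo_bulk(sc$counts, sc$annotation))
  rpm <- combined_rpm(pb)
  sig <- pseudobulk_signature_scores(sc$counts, sc$annotation, sc$signatures)
  sm <- rteage:::as_feature_matrix(sig)
  grp <- median_split(tibble::tibble(sample_id = colnames(sm),
                                     score = sm["SASP", ]), basis = "SASP")
  ct <- celltype_contrast(rpm, grp)
  planted <- ct$p[ct$cell_type == sc$truth$planted$cell_type &
                    ct$rte_id == sc$truth$planted$rte_class]
  nulls <- ct$p[!(ct$cell_type == sc$truth$planted$cell_type &
                    ct$rte_id == sc$truth$planted$rte_class)]
  list(contrasts = ct, planted_p = planted, null_p = nulls,
       top = planted <= min(ct$p), fp = sum(nulls < 0.05))
}
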