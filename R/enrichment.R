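#' Filter MSigDB-style gene-set names
#'
#' Drops direction-specific sets (names ending `_UP` or `_DN`) and a fixed
#' list of redundant sets, mirroring the curation applied before running
#' keyword-selected inflammatory / DNA-repair collections.
#'
#' @param names Character vector of gene-set names (already restricted to the
#'   keyword selection of interest).
#' @param drop_redundant Additional exact names to remove; defaults to the
#'   three near-duplicate acute-inflammation GO sets.
#' @return The retained names, in input order.
#' @export
filter_gene_set_names <- function(
    names,
    drop_redundant = c(
      "GOBP_POSITIVE_REGULATION_OF_ACUTE_INFLAMMATORY_RESPONSE",
      "GOBP_POSITIVE_REGULATION_OF_CYTOKINE_PRODUCTION_INVOLVED_IN_INFLAMMATORY_RESPONSE",
      "GOBP_POSITIVE_REGULATION_OF_ACUTE_INFLAMMATORY_RESPONSE_TO_ANTIGENIC_STIMULUS"
    )) {
  keep <- !grepl("_(UP|DN)$", names) & !(names %in% drop_redundant)
  names[keep]
}

#' Per-sample gene-set variation scores
#'
#' Kernel-CDF based single-sample enrichment, computed in three steps.
#' For each gene g with per-sample values x and standard deviation sd_g,
#' a Gaussian-kernel CDF estimate is taken at each sample s:
#' `h(g,s) = mean_k Phi((x_gs - x_gk) / (sd_g / 4))` (genes with zero
#' variance get h = 0.5). Within each sample genes are ordered by decreasing
#' h; the gene at position r receives the symmetric weight `|G/2 - r|`.
#' Walking down that ordering, the running sum rises by `w / sum_set(w)` at
#' set members and falls by `1 / (G - m)` at non-members; the enrichment
#' score is the maximum positive deviation plus the minimum negative
#' deviation of the walk (difference of extremes), so a set concentrated at
#' the top of the ordering scores positive and its complement scores
#' negative on the same sample.
#'
#' @param mat Sample-matrix tibble (continuous values, e.g. log intensity);
#'   at least 3 samples.
#' @param sets Gene sets (tibble `set_name`/`gene` or named list); each set
#'   must intersect the matrix features in at least 1 and fewer than all
#'   genes.
#' @return A tibble of class `rte_enrichment_scores`: first column
#'   `set_name`, one numeric ES column per sample.
#' @export
gsva_scores <- function(mat, sets) {
  sets <- as_gene_set_list(sets)
  x <- as_feature_matrix(mat)
  G <- nrow(x); n <- ncol(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)

  feat_key <- normalize_symbol(rownames(x))
  members <- lapply(sets, function(g) {
    idx <- match(normalize_symbol(g), feat_key)
    sort(unique(idx[!is.na(idx)]))
  })
  sizes <- lengths(members)
  bad <- names(sets)[sizes == 0L | sizes == G]
  if (length(bad)) {
    stop("gene set(s) with no usable genes after intersection (empty or ",
         "covering the whole matrix): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  # Step 1: kernel CDF estimate per gene across samples (bandwidth sd/4)
  h <- matrix(0.5, G, n, dimnames = dimnames(x))
  for (g in seq_len(G)) {
    s <- stats::sd(x[g, ])
    if (s > 0) {
      h[g, ] <- rowMeans(stats::pnorm(outer(x[g, ], x[g, ], "-") / (s / 4)))
    }
  }

  es <- matrix(NA_real_, length(sets), n,
               dimnames = list(names(sets), colnames(x)))
  member_flag <- matrix(FALSE, G, length(sets))
  for (j in seq_along(sets)) member_flag[members[[j]], j] <- TRUE

  for (s in seq_len(n)) {
    ord <- order(h[, s], decreasing = TRUE)           # rank 1 = largest h
    w <- abs(G / 2 - seq_len(G))                      # weight by rank
    for (j in seq_along(sets)) {
      mem <- member_flag[ord, j]
      m <- sizes[j]
      inc <- ifelse(mem, w / sum(w[mem]), -1 / (G - m))
      run <- cumsum(inc)
      es[j, s] <- max(0, max(run)) + min(0, min(run))
    }
  }
  out <- as_sample_tibble(es, feature_col = "set_name")
  class(out) <- c("rte_enrichment_scores", class(out))
  out
}

#' High-versus-low differential enrichment
#'
#' For each gene set, contrasts enrichment scores of the `high` group against
#' the `low` group: `logFC` is the mean ES difference (high - low), the
#' p-value comes from a two-sided Welch t-test, and a set is called `up` when
#' logFC > `lfc_threshold` and p < `p_threshold`, `down` when
#' logFC < -`lfc_threshold` and p < `p_threshold`, `ns` otherwise. Defaults
#' are the deliberately permissive |logFC| > 0.1 with p < 0.05.
#'
#' @param es Enrichment scores from [gsva_scores()].
#' @param grouping An `rte_grouping`; `high` and `low` groups need at least 2
#'   samples each.
#' @param lfc_threshold,p_threshold Call thresholds.
#' @return A tibble of class `rte_differential`: `set_name`, `logFC`, `p`,
#'   `call`.
#' @export
differential_enrichment <- function(es, grouping,
                                    lfc_threshold = 0.1, p_threshold = 0.05) {
  m <- as_feature_matrix(es)
  hi <- intersect(grouping$sample_id[grouping$label == "high"], colnames(m))
  lo <- intersect(grouping$sample_id[grouping$label == "low"], colnames(m))
  if (length(hi) < 2L || length(lo) < 2L) {
    stop("need at least 2 samples per group (high: ", length(hi),
         ", low: ", length(lo), ")", call. = FALSE)
  }
  out <- purrr::map_dfr(rownames(m), function(set) {
    a <- m[set, hi]; b <- m[set, lo]
    lfc <- mean(a) - mean(b)
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      1  # no variance anywhere: no evidence of difference
    } else {
      stats::t.test(a, b, var.equal = FALSE)$p.value
    }
    tibble(set_name = set, logFC = lfc, p = p)
  })
  out$call <- ifelse(out$p < p_threshold & out$logFC > lfc_threshold, "up",
                     ifelse(out$p < p_threshold & out$logFC < -lfc_threshold,
                            "down", "ns"))
  class(out) <- c("rte_differential", class(out))
  out
}

#' Up-minus-down pathway summary
#'
#' Tallies, for each stratifying RTE group and gene-set category, the number
#' of sets called `up` minus the number called `down` — the quantity behind
#' radar-style summaries of inflammatory versus DNA-repair pathway activity
#' across RTE classes and families.
#'
#' @param calls A tibble of differential calls carrying a `call` column plus
#'   the grouping column named in `by` (e.g. the RTE class whose high/low
#'   split produced each call) and `set_name`.
#' @param categories A tibble `set_name`, `category` covering every set.
#' @param by Name of the grouping column in `calls`; default `"rte_id"`.
#' @return A tibble `by`-column, `category`, `n_up`, `n_down`,
#'   `up_minus_down`, complete over all (group, category) combinations.
#' @export
updown_summary <- function(calls, categories, by = "rte_id") {
  stopifnot(all(c("set_name", "call", by) %in% names(calls)),
            all(c("set_name", "category") %in% names(categories)))
  uncat <- setdiff(unique(calls$set_name), categories$set_name)
  if (length(uncat)) {
    stop("gene set(s) without a category: ", paste(uncat, collapse = ", "),
         call. = FALSE)
  }
  calls |>
    left_join(categories, by = "set_name") |>
    group_by(.data[[by]], .data$category) |>
    summarise(
      n_up = sum(.data$call == "up"),
      n_down = sum(.data$call == "down"),
      .groups = "drop"
    ) |>
    tidyr::complete(.data[[by]], .data$category,
                    fill = list(n_up = 0L, n_down = 0L)) |>
    mutate(up_minus_down = .data$n_up - .data$n_down)
}
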