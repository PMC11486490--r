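#' Pseudo-bulk aggregation of single-cell counts
#'
#' Sums raw counts over all cells sharing a (cell type, sample) combination.
#' Cells present in the count matrix but absent from the annotation are
#' dropped, with a message reporting how many. Summation is exact and
#' integer, so counts are conserved: per feature, the sum over a sample's
#' cell types equals the sample's total.
#'
#' @param counts Cell count tibble (first column `feature_id`, one column per
#'   cell; see [read_cell_counts()]).
#' @param annotation Tibble `cell_id`, `sample_id`, `cell_type` (see
#'   [read_cell_annotation()]).
#' @return A long tibble of class `rte_pseudobulk`: `cell_type`, `sample_id`,
#'   `feature_id`, `count`, with an attribute `n_dropped_cells`.
#' @export
pseudo_bulk <- function(counts, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0L) {
    stop("empty cell annotation", call. = FALSE)
  }
  m <- as_feature_matrix(counts)
  cells <- colnames(m)
  idx <- match(cells, annotation$cell_id)
  dropped <- sum(is.na(idx))
  if (dropped > 0L) {
    message(dropped, " unannotated cell(s) dropped from pseudo-bulk")
  }
  keep <- !is.na(idx)
  if (!any(keep)) stop("no annotated cell found in the count matrix", call. = FALSE)
  m <- m[, keep, drop = FALSE]
  grp <- paste(annotation$cell_type[idx[keep]], annotation$sample_id[idx[keep]],
               sep = "\r")
  agg <- t(rowsum(t(m), group = grp))  # features x (cell_type, sample)
  parts <- stringr::str_split_fixed(colnames(agg), "\r", 2)
  out <- tibble(
    cell_type = rep(parts[, 1], each = nrow(agg)),
    sample_id = rep(parts[, 2], each = nrow(agg)),
    feature_id = rep(rownames(agg), ncol(agg)),
    count = as.vector(agg)
  ) |>
    arrange(.data$cell_type, .data$sample_id, .data$feature_id)
  attr(out, "n_dropped_cells") <- dropped
  class(out) <- c("rte_pseudobulk", class(out))
  out
}

# Features named after taxonomy classes / families are RTE rows; the rest
# are genes. Disjoint namespaces are assumed (gene symbols never collide
# with class or family labels).
feature_kind <- function(feature_id, taxonomy = rte_taxonomy()) {
  ifelse(feature_id %in% unique(taxonomy$repeat_class), "rte_class",
         ifelse(feature_id %in% taxonomy$repeat_family, "rte_family", "gene"))
}

#' RPM normalization with a combined gene + RTE-class denominator
#'
#' Normalizes pseudo-bulk counts per (cell type, sample) to reads per
#' million, where the denominator is the joint total of gene counts and RTE
#' *class* counts for that cell type and sample. RTE family rows, when
#' present, are scaled by the same denominator but excluded from it (their
#' reads are already counted at class level). Combinations with a zero total
#' are dropped with a warning.
#'
#' @param pb A [pseudo_bulk()] result.
#' @param taxonomy Taxonomy used to recognize RTE rows; see [rte_taxonomy()].
#' @return The pseudo-bulk tibble with added `kind` and `rpm` columns; over
#'   the gene + class rows of each (cell type, sample), `rpm` sums to 1e6.
#' @export
combined_rpm <- function(pb, taxonomy = rte_taxonomy()) {
  stopifnot(all(c("cell_type", "sample_id", "feature_id", "count") %in% names(pb)))
  pb <- mutate(pb, kind = feature_kind(.data$feature_id, taxonomy))
  totals <- pb |>
    filter(.data$kind != "rte_family") |>
    group_by(.data$cell_type, .data$sample_id) |>
    summarise(total = sum(.data$count), .groups = "drop")
  zero <- filter(totals, .data$total <= 0)
  if (nrow(zero) > 0L) {
    warning("dropping (cell type, sample) with zero total counts: ",
            paste(zero$cell_type, zero$sample_id, sep = "/", collapse = ", "),
            call. = FALSE)
  }
  pb |>
    inner_join(filter(totals, .data$total > 0),
               by = c("cell_type", "sample_id")) |>
    mutate(rpm = 1e6 * .data$count / .data$total) |>
    select(-"total")
}

#' Sample-level signature scores from single-cell counts
#'
#' Collapses the count matrix to one bulk-like profile per sample by summing
#' gene counts over all of the sample's annotated cells (RTE rows are
#' excluded from ranking), converts to RPM per sample, and scores the
#' signatures with [score_signatures()]. Set `per_cell_type` to restrict the
#' bulk profile to one annotated cell type.
#'
#' @param counts,annotation As for [pseudo_bulk()].
#' @param signatures Gene sets (tibble or named list).
#' @param per_cell_type Optional cell-type label; default uses all cells.
#' @param taxonomy Taxonomy used to recognize and exclude RTE rows.
#' @return A signature score tibble (see [score_signatures()]).
#' @export
pseudobulk_signature_scores <- function(counts, annotation, signatures,
                                        per_cell_type = NULL,
                                        taxonomy = rte_taxonomy()) {
  if (!is.null(per_cell_type)) {
    annotation <- filter(annotation, .data$cell_type %in% per_cell_type)
    if (nrow(annotation) == 0L) {
      stop("no cell annotated as ", paste(per_cell_type, collapse = ", "),
           call. = FALSE)
    }
  }
  pb <- suppressMessages(pseudo_bulk(counts, annotation))
  gene_rows <- pb |>
    mutate(kind = feature_kind(.data$feature_id, taxonomy)) |>
    filter(.data$kind == "gene")
  bulk <- gene_rows |>
    group_by(.data$feature_id, .data$sample_id) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0)
  rpm <- rpm_normalize(bulk)
  score_signatures(rpm, signatures)
}

#' Per-cell-type high-versus-low contrasts of RTE expression
#'
#' For every (cell type, RTE feature) combination, compares RPM values of
#' samples in the `high` group against the `low` group with the two-sided
#' rank-sum test. Cell types lacking at least `min_per_group` samples in
#' either group are skipped with a warning.
#'
#' @param pb_rpm Output of [combined_rpm()].
#' @param grouping An `rte_grouping` over sample ids (e.g. a [median_split()]
#'   of signature scores).
#' @param features RTE features to test; defaults to all `rte_class` rows.
#' @param min_per_group Minimum samples per group per cell type (default 2).
#' @return A tibble of class `rte_celltype_contrast`: `cell_type`, `rte_id`,
#'   `statistic`, `p`, `stars`, `n_high`, `n_low`, `median_rpm_high`,
#'   `median_rpm_low`.
#' @export
celltype_contrast <- function(pb_rpm, grouping, features = NULL,
                              min_per_group = 2L) {
  stopifnot(all(c("cell_type", "sample_id", "feature_id", "rpm") %in% names(pb_rpm)))
  if (is.null(features)) {
    if (!"kind" %in% names(pb_rpm)) {
      pb_rpm <- mutate(pb_rpm, kind = feature_kind(.data$feature_id))
    }
    features <- sort(unique(pb_rpm$feature_id[pb_rpm$kind == "rte_class"]))
  }
  hi <- grouping$sample_id[grouping$label == "high"]
  lo <- grouping$sample_id[grouping$label == "low"]
  dat <- filter(pb_rpm, .data$feature_id %in% features)
  skipped <- character()
  out <- purrr::map_dfr(sort(unique(dat$cell_type)), function(ct) {
    d <- filter(dat, .data$cell_type == ct)
    a_ids <- intersect(hi, d$sample_id)
    b_ids <- intersect(lo, d$sample_id)
    if (length(a_ids) < min_per_group || length(b_ids) < min_per_group) {
      skipped <<- c(skipped, ct)
      return(NULL)
    }
    purrr::map_dfr(features, function(f) {
      a <- d$rpm[d$feature_id == f & d$sample_id %in% a_ids]
      b <- d$rpm[d$feature_id == f & d$sample_id %in% b_ids]
      wt <- wilcoxon_compare(a, b)
      tibble(cell_type = ct, rte_id = f, statistic = wt$statistic, p = wt$p,
             stars = p_stars(wt$p), n_high = length(a), n_low = length(b),
             median_rpm_high = stats::median(a), median_rpm_low = stats::median(b))
    })
  })
  if (length(skipped)) {
    warning("cell type(s) skipped for insufficient group sizes: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  class(out) <- c("rte_celltype_contrast", class(out))
  out
}
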