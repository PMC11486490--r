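#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy score matrices into long form
#'
#' `tidy()` on the package's wide result objects returns one row per
#' (feature, sample) or per test; `glance()` returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name rteage-tidiers
NULL

tidy_score_matrix <- function(x, feature_col, value_col) {
  id <- names(x)[1]
  out <- tidyr::pivot_longer(as_tibble(x), cols = -all_of(id),
                             names_to = "sample_id", values_to = value_col)
  names(out)[names(out) == id] <- feature_col
  out
}

#' @rdname rteage-tidiers
#' @export
tidy.rte_signature_scores <- function(x, ...) {
  tidy_score_matrix(x, "signature", "score")
}

#' @rdname rteage-tidiers
#' @export
glance.rte_signature_scores <- function(x, ...) {
  mg <- attr(x, "missing_genes")
  tibble(
    n_signatures = nrow(x),
    n_samples = ncol(x) - 1L,
    n_missing_genes = sum(lengths(mg)),
    min_score = min(as_feature_matrix(x)),
    max_score = max(as_feature_matrix(x))
  )
}

#' @rdname rteage-tidiers
#' @export
tidy.rte_enrichment_scores <- function(x, ...) {
  tidy_score_matrix(x, "set_name", "es")
}

#' @rdname rteage-tidiers
#' @export
tidy.rte_correlation <- function(x, ...) {
  as_tibble(x)
}

#' @rdname rteage-tidiers
#' @export
glance.rte_correlation <- function(x, ...) {
  off <- x$var1 != x$var2
  tibble(
    n_variables = length(unique(x$var1)),
    n_pairs = sum(off) / 2L,
    n_significant = sum(x$p[off] <= 0.05) / 2L,
    min_n = min(x$n)
  )
}

#' @rdname rteage-tidiers
#' @export
tidy.rte_differential <- function(x, ...) as_tibble(x)

#' @rdname rteage-tidiers
#' @export
glance.rte_differential <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    n_ns = sum(x$call == "ns")
  )
}

#' @rdname rteage-tidiers
#' @export
tidy.rte_celltype_contrast <- function(x, ...) as_tibble(x)

#' @rdname rteage-tidiers
#' @export
glance.rte_celltype_contrast <- function(x, ...) {
  tibble(
    n_cell_types = length(unique(x$cell_type)),
    n_features = length(unique(x$rte_id)),
    n_tests = nrow(x),
    n_significant = sum(x$p < 0.05)
  )
}

#' @rdname rteage-tidiers
#' @export
glance.rte_grouping <- function(x, ...) {
  tibble(
    basis = x$basis[1],
    n = nrow(x),
    n_low = sum(x$label == "low"),
    n_medium = sum(x$label == "medium"),
    n_high = sum(x$label == "high")
  )
}
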