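#' Collapse duplicate features by averaging
#'
#' Rows sharing a `feature_id` are replaced by their per-sample mean; row
#' order of first occurrence is preserved. This is the standard reduction of
#' microarray matrices in which several probes report the same gene symbol.
#'
#' @param mat Sample-matrix tibble (first column `feature_id`, numeric sample
#'   columns).
#' @return A sample-matrix tibble with unique `feature_id`s.
#' @export
collapse_duplicate_features <- function(mat) {
  stopifnot(is.data.frame(mat), ncol(mat) >= 2L)
  if (!anyDuplicated(mat[[1]])) return(mat)
  id <- names(mat)[1]
  mat |>
    mutate(.ord = match(.data[[id]], unique(.data[[id]]))) |>
    group_by(.data[[id]], .ord = .data$.ord) |>
    summarise(across(dplyr::where(is.numeric), mean), .groups = "drop") |>
    arrange(.data$.ord) |>
    select(-".ord")
}

#' Aggregate probe values into RTE class or family scores
#'
#' For each taxonomy group (class or family) the score of a sample is the
#' unweighted mean of the values of all probes assigned to that group. At
#' class level probes are pooled across the class's families (so families
#' contributing more probes weigh more). Works identically for log-intensity
#' expression and methylation beta values; a mean of betas stays in [0, 1].
#'
#' @param mat Sample-matrix tibble keyed by `probe_id`-style feature ids.
#' @param assignments Probe-repeat assignments from
#'   [assign_probes_to_repeats()].
#' @param level `"class"` or `"family"`.
#'
#' @return A tibble, first column `rte_id` (the class or family label),
#'   one numeric column per sample. Groups with no probe present in `mat` are
#'   absent, with a warning naming them; assigned probes missing from `mat`
#'   are skipped with a message.
#' @export
aggregate_rte_scores <- function(mat, assignments, level = c("class", "family")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(mat), ncol(mat) >= 2L)
  key <- if (level == "class") "repeat_class" else "repeat_family"

  present <- assignments$probe_id %in% mat[[1]]
  if (!all(present)) {
    message(sum(!present), " assigned probe(s) absent from the matrix; skipped")
  }
  used <- assignments[present, , drop = FALSE]
  if (nrow(used) == 0L) {
    stop("no assigned probe is present in the matrix", call. = FALSE)
  }
  lost <- setdiff(unique(assignments[[key]]), unique(used[[key]]))
  if (length(lost)) {
    warning("RTE group(s) with no measured probe dropped: ",
            paste(sort(lost), collapse = ", "), call. = FALSE)
  }

  m <- as_feature_matrix(mat)
  groups <- split(used$probe_id, used[[key]])
  scores <- t(vapply(
    groups,
    function(ids) colMeans(m[ids, , drop = FALSE]),
    numeric(ncol(m))
  ))
  out <- as_sample_tibble(scores, feature_col = "rte_id")
  attr(out, "level") <- level
  out
}

#' Count reads falling in repeat intervals
#'
#' Each read is counted at most once, toward its best-overlapping repeat
#' (maximum overlap; ties broken by leftmost repeat start then lexicographic
#' repeat name — the same rule as probe assignment), then tallied per
#' taxonomy group and sample.
#'
#' @param reads Tibble of read intervals: `read_id`, `chrom`, `start`, `end`,
#'   and a `sample_id` column labelling the originating sample.
#' @param repeats Repeat tibble from [read_repeatmasker()].
#' @param level `"class"` or `"family"`.
#'
#' @return A sample-matrix tibble of integer counts, first column `rte_id`;
#'   one column per sample present in `reads`, groups with zero reads
#'   included as zero rows.
#' @export
count_reads_in_repeats <- function(reads, repeats, level = c("class", "family")) {
  level <- match.arg(level)
  stopifnot(all(c("read_id", "chrom", "start", "end", "sample_id") %in% names(reads)))
  key <- if (level == "class") "repeat_class" else "repeat_family"
  samples <- unique(reads$sample_id)
  groups <- unique(repeats[[key]])
  counts <- matrix(0L, length(groups), length(samples),
                   dimnames = list(groups, samples))
  if (nrow(reads) > 0L && nrow(repeats) > 0L) {
    fake_probes <- tibble(
      probe_id = as.character(seq_len(nrow(reads))),
      chrom = reads$chrom, start = reads$start, end = reads$end,
      strand = "*", context = "intergenic"
    )
    hits <- assign_probes_to_repeats(fake_probes, repeats,
                                     contexts_allowed = "intergenic")
    if (nrow(hits) > 0L) {
      idx <- as.integer(hits$probe_id)
      tab <- table(
        factor(hits[[key]], levels = groups),
        factor(reads$sample_id[idx], levels = samples)
      )
      counts <- counts + unclass(tab)
    }
  }
  out <- as_sample_tibble(counts, feature_col = "rte_id")
  attr(out, "level") <- level
  out
}

#' Reads-per-million normalization
#'
#' Scales each sample column so that values are per million: `1e6 * count /
#' total`. With `totals = NULL` the per-sample total is the column sum (after
#' which every column sums to exactly 1e6); supplying `totals` supports
#' denominators computed on a wider feature universe, e.g. genes plus RTE
#' classes jointly.
#'
#' @param counts Sample-matrix tibble of non-negative counts.
#' @param totals Optional named numeric vector of per-sample totals; names
#'   must cover all sample columns.
#' @return A sample-matrix tibble of RPM values with the same shape.
#' @export
rpm_normalize <- function(counts, totals = NULL) {
  m <- as_feature_matrix(counts)
  if (is.null(totals)) {
    totals <- colSums(m)
  } else {
    if (is.null(names(totals)) || !all(colnames(m) %in% names(totals))) {
      stop("totals must be named for every sample column", call. = FALSE)
    }
    totals <- totals[colnames(m)]
  }
  bad <- which(!is.finite(totals) | totals <= 0)
  if (length(bad)) {
    stop("non-positive library total for sample(s): ",
         paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
  }
  rpm <- sweep(m, 2, totals, "/") * 1e6
  out <- counts
  out[, -1] <- as_tibble(rpm)
  out
}
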