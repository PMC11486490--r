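#' Stratify samples by quartiles or the median
#'
#' `quartile_split()` divides samples into `low` (first quartile), `medium`
#' (second and third quartiles) and `high` (fourth quartile) groups of the
#' stratifying score: low is `value <= Q1`, high is `value > Q3`, medium the
#' remainder, with quartiles computed by linear interpolation
#' ([stats::quantile()] type 7). Boundary ties therefore go deterministically
#' to the more extreme group on the low side and to medium on the high side.
#'
#' `median_split()` divides samples into `high` (`value > median`) and `low`
#' (the rest); with odd n the median sample falls in `low`.
#'
#' @param data A data frame with a `sample_id` column and the stratifying
#'   score column.
#' @param value Name of the score column (default: the first numeric column).
#' @param basis Label recorded for the score used; defaults to `value`.
#'
#' @return A tibble `sample_id`, `basis`, `value`, `label`; labels partition
#'   the samples.
#' @export
quartile_split <- function(data, value = NULL, basis = NULL) {
  v <- extract_basis(data, value)
  if (length(v$x) < 8L) stop("quartile split needs at least 8 samples", call. = FALSE)
  if (diff(range(v$x)) == 0) stop("all values identical; no spread to stratify", call. = FALSE)
  q <- stats::quantile(v$x, c(0.25, 0.75), type = 7, names = FALSE)
  label <- ifelse(v$x <= q[1], "low", ifelse(v$x > q[2], "high", "medium"))
  grouping_tibble(v, label, c("low", "medium", "high"), basis %||% v$name)
}

#' @rdname quartile_split
#' @export
median_split <- function(data, value = NULL, basis = NULL) {
  v <- extract_basis(data, value)
  if (length(v$x) < 4L) stop("median split needs at least 4 samples", call. = FALSE)
  if (diff(range(v$x)) == 0) stop("all values identical; no spread to stratify", call. = FALSE)
  label <- ifelse(v$x > stats::median(v$x), "high", "low")
  grouping_tibble(v, label, c("low", "high"), basis %||% v$name)
}

#' Build a sample grouping directly from labels
#'
#' For contrasts whose groups come from study design rather than a score
#' split (e.g. supercentenarians versus normal-aged controls).
#'
#' @param sample_id Character vector of sample ids.
#' @param label Labels, coercible to the levels present (typically `low` /
#'   `high`).
#' @param basis Description of what defined the groups.
#' @return An `rte_grouping` tibble.
#' @export
sample_grouping <- function(sample_id, label, basis = "manual") {
  stopifnot(length(sample_id) == length(label))
  label <- as.factor(label)
  out <- tibble(sample_id = as.character(sample_id), basis = basis,
                value = NA_real_, label = label)
  class(out) <- c("rte_grouping", class(out))
  out
}

extract_basis <- function(data, value) {
  stopifnot(is.data.frame(data), "sample_id" %in% names(data))
  if (is.null(value)) {
    num <- names(data)[vapply(data, is.numeric, TRUE) & names(data) != "sample_id"]
    if (length(num) == 0L) stop("no numeric score column found", call. = FALSE)
    value <- num[1]
  }
  x <- data[[value]]
  if (is.null(x)) stop("no column '", value, "' in data", call. = FALSE)
  keep <- !is.na(x)
  list(x = x[keep], ids = as.character(data$sample_id)[keep], name = value)
}

grouping_tibble <- function(v, label, levels, basis) {
  out <- tibble(
    sample_id = v$ids, basis = basis, value = v$x,
    label = factor(label, levels = levels)
  )
  class(out) <- c("rte_grouping", class(out))
  out
}

#' Pearson correlation with significance
#'
#' Product-moment correlation with a two-sided p-value from the t
#' distribution on n - 2 degrees of freedom. Pairs with a missing value in
#' either vector are deleted (pairwise deletion); the number of pairs used is
#' reported.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A one-row tibble `r`, `p`, `n`.
#' @export
cor_pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' All-pairs correlation table
#'
#' Pearson correlation for every pair of variables (columns), with raw
#' p-values annotated by stars at the 0.05 / 0.01 / 0.001 / 0.0001
#' thresholds. The table contains both orientations of every pair plus the
#' diagonal (r = 1), so it is symmetric by construction. Raw p-values are
#' reported by default, matching the usual figure annotation; `adjust =
#' "BH"` adds a Benjamini-Hochberg adjusted column.
#'
#' @param data A data frame of numeric variable columns, one row per sample
#'   (a `sample_id` column, if present, is ignored as a variable).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble of class `rte_correlation`: `var1`, `var2`, `r`, `p`,
#'   `n`, `stars` (and `p_adj` when requested).
#' @export
correlate_pairs <- function(data, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  vars <- names(data)[vapply(data, is.numeric, TRUE)]
  vars <- setdiff(vars, "sample_id")
  if (length(vars) < 2L) stop("need at least 2 numeric variables", call. = FALSE)
  grid <- tidyr::expand_grid(var1 = vars, var2 = vars)
  res <- purrr::pmap_dfr(grid, function(var1, var2) {
    if (var1 == var2) {
      n <- sum(!is.na(data[[var1]]))
      return(tibble(var1 = var1, var2 = var2, r = 1, p = 0, n = n))
    }
    ct <- cor_pearson(data[[var1]], data[[var2]])
    tibble(var1 = var1, var2 = var2, r = ct$r, p = ct$p, n = ct$n)
  })
  res$stars <- p_stars(res$p)
  if (adjust == "BH") {
    off <- res$var1 != res$var2 & res$var1 < res$var2
    adj <- stats::p.adjust(res$p[off], method = "BH")
    key <- paste(pmin(res$var1, res$var2), pmax(res$var1, res$var2))
    res$p_adj <- adj[match(key, paste(res$var1[off], res$var2[off]))]
    res$p_adj[res$var1 == res$var2] <- 0
  }
  class(res) <- c("rte_correlation", class(res))
  res
}

#' Significance stars for raw p-values
#'
#' @param p Numeric vector of p-values.
#' @param thresholds Descending significance cut-offs.
#' @return Character vector: `"****"` for p <= 1e-4 down to `"*"` for
#'   p <= 0.05, `"ns"` otherwise.
#' @export
p_stars <- function(p, thresholds = c(0.05, 0.01, 0.001, 0.0001)) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  out <- rep("ns", length(p))
  for (i in seq_along(thresholds)) {
    out[p <= thresholds[i]] <- strrep("*", i)
  }
  out[is.na(p)] <- NA_character_
  out
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Two-sided unpaired rank-sum test using the normal approximation with tie
#' and continuity corrections (the continuity-corrected approximation tracks
#' the exact test's rejection rate closely at small group sizes; identical
#' groups still yield p = 1 exactly since the z statistic is 0). Monotone
#' transforms of the pooled data leave the result unchanged.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A one-row tibble `statistic` (the Mann-Whitney U for `a`), `p`,
#'   `n_a`, `n_b`.
#' @export
wilcoxon_compare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # zero-variance ranks (all values tied)
  tibble(statistic = unname(wt$statistic), p = p,
         n_a = length(a), n_b = length(b))
}

#' Contrast a score between stratified groups
#'
#' Runs [wilcoxon_compare()] of `high` versus `low` samples for every row of
#' a feature-by-sample score matrix, the workhorse behind
#' methylation-by-expression-group and related stratified comparisons.
#'
#' @param scores Sample-matrix tibble (e.g. from [aggregate_rte_scores()]).
#' @param grouping An `rte_grouping` from [quartile_split()] or
#'   [median_split()].
#' @return A tibble `feature`, `statistic`, `p`, `stars`, `n_high`, `n_low`,
#'   `median_high`, `median_low`.
#' @export
group_contrast <- function(scores, grouping) {
  m <- as_feature_matrix(scores)
  hi <- grouping$sample_id[grouping$label == "high"]
  lo <- grouping$sample_id[grouping$label == "low"]
  hi <- intersect(hi, colnames(m)); lo <- intersect(lo, colnames(m))
  if (length(hi) == 0L || length(lo) == 0L) {
    stop("grouping shares no high/low samples with the score matrix", call. = FALSE)
  }
  purrr::map_dfr(rownames(m), function(f) {
    a <- m[f, hi]; b <- m[f, lo]
    wt <- wilcoxon_compare(a, b)
    tibble(feature = f, statistic = wt$statistic, p = wt$p,
           stars = p_stars(wt$p), n_high = length(hi), n_low = length(lo),
           median_high = stats::median(a), median_low = stats::median(b))
  })
}
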