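test_that("quartile split yields 25/50/25 with deterministic boundaries", {
  d <- tibble::tibble(sample_id = sprintf("s%03d", 1:100), score = 1:100)
  g <- quartile_split(d)
  expect_equal(unname(table(g$label)["low"]), 25L)
  expect_equal(unname(table(g$label)["medium"]), 50L)
  expect_equal(unname(table(g$label)["high"]), 25L)
  g8 <- quartile_split(tibble::tibble(sample_id = letters[1:8], score = 1:8))
  expect_equal(as.vector(table(g8$label)), c(2L, 4L, 2L))
  # repeated boundary values: still an exhaustive, disjoint partition
  for (seed in 1:20) {
    set.seed(seed)
    x <- sample(1:4, 30, replace = TRUE)
    d2 <- tibble::tibble(sample_id = sprintf("t%02d", 1:30), score = x)
    g2 <- quartile_split(d2)
    expect_setequal(g2$sample_id, d2$sample_id)
    expect_false(anyNA(g2$label))
    expect_equal(nrow(g2), 30L)
  }
  expect_error(quartile_split(tibble::tibble(sample_id = letters[1:7], score = 1:7)),
               "at least 8")
  expect_error(quartile_split(tibble::tibble(sample_id = letters[1:9],
                                             score = rep(1, 9))), "identical")
})

test_that("median split sends the median element low and partitions", {
  d <- tibble::tibble(sample_id = letters[1:4], score = c(1, 2, 3, 4))
  g <- median_split(d)
  expect_setequal(g$sample_id[g$label == "low"], c("a", "b"))
  expect_setequal(g$sample_id[g$label == "high"], c("c", "d"))
  odd <- median_split(tibble::tibble(sample_id = letters[1:5], score = 1:5))
  expect_equal(sum(odd$label == "low"), 3L)   # median goes low
  expect_equal(sum(odd$label == "high") + sum(odd$label == "low"), 5L)
  expect_error(median_split(tibble::tibble(sample_id = letters[1:4],
                                           score = rep(2, 4))), "identical")
})

test_that("pearson returns textbook r and matches planted correlation", {
  x <- c(1, 3, 2, 5, 4, 7)
  expect_equal(cor_pearson(x, x)$r, 1)
  expect_equal(cor_pearson(x, -x)$r, -1)
  expect_error(cor_pearson(x, rep(1, 6)), "constant")
  expect_error(cor_pearson(c(1, 2), c(3, 4)), "at least 3")
  # pairwise deletion
  y <- x + c(0.1, -0.2, 0.3, NA, 0, 0.2)
  expect_equal(cor_pearson(x, y)$n, 5L)
  # planted r = 0.5 at n = 2000: estimate within the Fisher-z 95% band
  set.seed(77)
  n <- 2000
  a <- rnorm(n)
  b <- 0.5 / sqrt(1 - 0.5^2) * a + rnorm(n)
  est <- cor_pearson(a, b)
  expect_lt(abs(est$r - 0.5), 0.05)
  expect_lt(est$p, 1e-10)
})

test_that("the correlation table is symmetric with unit diagonal and matches
           pairwise calls", {
  set.seed(9)
  d <- tibble::tibble(sample_id = sprintf("s%02d", 1:40),
                      v1 = rnorm(40), v2 = rnorm(40), v3 = rnorm(40))
  tab <- correlate_pairs(d)
  diag <- dplyr::filter(tab, var1 == var2)
  expect_equal(nrow(diag), 3L)
  expect_true(all(diag$r == 1))
  for (i in seq_len(nrow(tab))) {
    mirror <- dplyr::filter(tab, var1 == tab$var2[i], var2 == tab$var1[i])
    expect_equal(mirror$r, tab$r[i])
    expect_equal(mirror$p, tab$p[i])
  }
  off <- dplyr::filter(tab, var1 == "v1", var2 == "v2")
  oracle <- cor_pearson(d$v1, d$v2)
  expect_equal(off$r, oracle$r)
  expect_equal(off$p, oracle$p)
  expect_true(all(tab$r >= -1 & tab$r <= 1))
  # BH option adds a symmetric adjusted column
  adj <- correlate_pairs(d, adjust = "BH")
  expect_true(all(adj$p_adj >= adj$p - 1e-12))
})

test_that("star annotation follows the four fixed thresholds", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(p_stars(c(0.05, 0.01)), c("*", "**"))  # boundary inclusive
})

test_that("rank-sum comparison: null case, separation, and symmetry", {
  expect_equal(wilcoxon_compare(c(1, 2, 3), c(1, 2, 3))$p, 1)
  sep <- wilcoxon_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$statistic, 0)  # minimal U for the first group
  # smallest attainable p for 3 vs 3 under this approximation: the most
  # extreme of the C(6,3) = 20 label assignments
  perms <- combn(6, 3)
  pooled <- c(1, 2, 3, 10, 11, 12)
  all_p <- apply(perms, 2, function(idx)
    wilcoxon_compare(pooled[idx], pooled[-idx])$p)
  expect_equal(sep$p, min(all_p))
  expect_error(wilcoxon_compare(numeric(0), 1:3), "non-empty")
  # swapping groups leaves the two-sided p unchanged
  set.seed(12)
  a <- rnorm(20); b <- rnorm(15, 1)
  expect_equal(wilcoxon_compare(a, b)$p, wilcoxon_compare(b, a)$p)
})

test_that("rank-sum p is invariant under monotone transforms and detects
           a two-sigma shift", {
  set.seed(31)
  a <- rnorm(50); b <- rnorm(50, mean = 2)
  base <- wilcoxon_compare(a, b)
  expect_lt(base$p, 0.001)
  mono <- function(x) atan(x / 3) * 5 + 100
  expect_equal(wilcoxon_compare(mono(a), mono(b))$p, base$p)
})

test_that("the continuity-corrected approximation matches the exact test's
           size at small n", {
  # exact null distribution of the Mann-Whitney U for groups of 10 and 11
  n <- 10; m <- 11
  f <- dwilcox(0:(n * m), n, m)
  U <- 0:(n * m)
  mu <- n * m / 2; s <- sqrt(n * m * (n + m + 1) / 12)
  p_corr <- 2 * pnorm(-pmax(0, abs(U - mu) - 0.5) / s)
  p_nocorr <- 2 * pnorm(-abs(U - mu) / s)
  p_exact <- 2 * pmin(pwilcox(U, n, m), 1 - pwilcox(U - 1, n, m))
  size_corr <- sum(f[p_corr < 0.05])
  size_nocorr <- sum(f[p_nocorr < 0.05])
  size_exact <- sum(f[p_exact < 0.05])
  expect_equal(size_corr, size_exact)          # 0.043: correction matches exact
  expect_gt(size_nocorr, 0.05)                 # 0.051: uncorrected inflates
  expect_equal(round(size_corr, 3), 0.043)
  expect_equal(round(size_nocorr, 3), 0.051)
  # and wilcoxon_compare() reproduces the corrected p on untied data
  set.seed(3)
  a <- rnorm(10); b <- rnorm(11)
  got <- wilcoxon_compare(a, b)
  expect_equal(got$p,
               unname(p_corr[match(got$statistic, U)]))
})

test_that("group_contrast runs one test per feature against the split", {
  set.seed(15)
  mat <- random_matrix_tbl(3, 40, seed = 15, prefix = "f")
  g <- median_split(tibble::tibble(sample_id = paste0("s", 1:40),
                                   score = rnorm(40)))
  ct <- group_contrast(mat, g)
  expect_equal(nrow(ct), 3L)
  hi <- g$sample_id[g$label == "high"]
  lo <- g$sample_id[g$label == "low"]
  m <- rteage:::as_feature_matrix(mat)
  expect_equal(ct$p[1], wilcoxon_compare(m["f1", hi], m["f1", lo])$p)
})

test_that("manual groupings feed the same contrast machinery", {
  g <- sample_grouping(paste0("s", 1:10), rep(c("low", "high"), each = 5),
                       basis = "cohort")
  mat <- random_matrix_tbl(2, 10, seed = 8, prefix = "f")
  expect_equal(nrow(group_contrast(mat, g)), 2L)
})
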