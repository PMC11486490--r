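test_that("generators are byte-identical under a fixed seed", {
  cfg <- synthetic_config(seed = 42, n_samples = 30L,
                          sc_n_samples = 4L, sc_cells_per_type = 4L)
  a1 <- simulate_annotation(cfg); a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  e1 <- simulate_expression_cohort(cfg); e2 <- simulate_expression_cohort(cfg)
  expect_identical(e1$expr, e2$expr)
  m1 <- simulate_methylation_cohort(cfg); m2 <- simulate_methylation_cohort(cfg)
  expect_identical(m1$beta, m2$beta)
  s1 <- simulate_single_cell(cfg); s2 <- simulate_single_cell(cfg)
  expect_identical(s1$counts, s2$counts)
  # a different seed changes the draw
  e3 <- simulate_expression_cohort(synthetic_config(seed = 43, n_samples = 30L))
  expect_false(identical(e1$expr, e3$expr))
})

test_that("annotation truth is recovered exactly by the annotation module", {
  cfg <- synthetic_config(seed = 5)
  ann <- simulate_annotation(cfg)
  ctx <- classify_probe_context(ann$probes, ann$genes)
  expect_equal(ctx$context, ann$truth$true_context)
  asg <- assign_probes_to_repeats(ctx, ann$repeats)
  truth <- ann$truth[match(asg$probe_id, ann$truth$probe_id), ]
  expect_equal(asg$repeat_name, truth$true_repeat_name)
  expect_equal(asg$repeat_class, truth$true_repeat_class)
  # only noncoding probes with a repeat are assigned
  assignable <- ann$truth$true_context %in% c("intergenic", "intronic") &
    !is.na(ann$truth$true_repeat_name)
  expect_setequal(asg$probe_id, ann$truth$probe_id[assignable])
  # every modelled family keeps at least 3 probes overall
  fam_counts <- table(ann$truth$true_repeat_family)
  expect_true(all(fam_counts[rteage:::modelled_families()$repeat_family] >= 3))
})

test_that("expression cohort plants signature coupling but no age signal", {
  cfg <- synthetic_config(seed = 1)
  ex <- simulate_expression_cohort(cfg)
  ctx <- classify_probe_context(ex$annotation$probes, ex$annotation$genes)
  asg <- assign_probes_to_repeats(ctx, ex$annotation$repeats)
  cls <- rteage:::as_feature_matrix(
    suppressWarnings(aggregate_rte_scores(ex$expr, asg, "class")))
  b <- ex$truth$latent_b[colnames(cls)]
  # expected attenuation: r = beta / sqrt(beta^2 + noise^2 / n_probes)
  n_line <- sum(asg$repeat_class == "LINE")
  r_theory <- 0.5 / sqrt(0.25 + 1 / n_line)
  r_obs <- cor_pearson(cls["LINE", ], b)
  expect_lt(abs(atanh(r_obs$r) - atanh(r_theory)),
            1.96 / sqrt(cfg$n_samples - 3) + 0.05)
  # age stays uncorrelated by construction
  expect_gt(cor_pearson(ex$metadata$age, b)$p, 0.001)
})

test_that("null couplings give null correlations at the nominal rate", {
  flat <- 0L
  for (seed in 1:10) {
    cfg <- synthetic_config(seed = seed, n_samples = 120L,
                            beta_bar = c(LINE = 0, LTR = 0, SINE = 0,
                                         Satellite = 0))
    ex <- simulate_expression_cohort(cfg)
    ctx <- classify_probe_context(ex$annotation$probes, ex$annotation$genes)
    asg <- assign_probes_to_repeats(ctx, ex$annotation$repeats)
    cls <- rteage:::as_feature_matrix(
      suppressWarnings(aggregate_rte_scores(ex$expr, asg, "class")))
    sig <- rteage:::as_feature_matrix(score_signatures(ex$expr, ex$signatures))
    ps <- sapply(c("LINE", "SINE", "LTR"), function(cl)
      cor_pearson(cls[cl, ], sig["SASP", ])$p)
    if (all(ps > 0.05)) flat <- flat + 1L
  }
  expect_gte(flat, 8L)  # ns in at least ~90% of seeds, binomial slack for 10
})

test_that("methylation cohort: betas bounded, slope planted, coupling split", {
  cfg <- synthetic_config(seed = 1)
  me <- simulate_methylation_cohort(cfg)
  bm <- rteage:::as_feature_matrix(me$beta)
  expect_true(all(bm >= 0 & bm <= 1))
  ctx <- classify_probe_context(me$annotation$probes, me$annotation$genes)
  asg <- assign_probes_to_repeats(ctx, me$annotation$repeats)
  cls <- rteage:::as_feature_matrix(
    suppressWarnings(aggregate_rte_scores(me$beta, asg, "class")))
  for (cl in c("LINE", "SINE", "LTR")) {
    expect_lt(cor_pearson(me$metadata$age, cls[cl, ])$r, -0.3)
  }
  # matched expression is inversely coupled for LINE/LTR, not SINE
  em <- rteage:::as_feature_matrix(
    suppressWarnings(aggregate_rte_scores(me$matched_expr, asg, "class")))
  line_ct <- cor_pearson(em["LINE", ], cls["LINE", ])
  expect_lt(line_ct$r, -0.1)
  expect_lt(line_ct$p, 0.001)
  expect_gt(cor_pearson(em["SINE", ], cls["SINE", ])$p, 0.05)
  # stratifying by expression recovers hypomethylated high groups for the
  # coupled classes only
  for (cl in c("LINE", "SINE")) {
    g <- quartile_split(tibble::tibble(sample_id = colnames(em),
                                       score = em[cl, ]), basis = cl)
    ct <- group_contrast(rteage:::as_sample_tibble(cls[cl, , drop = FALSE],
                                                   "rte_id"), g)
    if (cl == "SINE") {
      expect_gt(ct$p, 0.05)
    } else {
      expect_lt(ct$p, 0.05)
      expect_lt(ct$median_high, ct$median_low)
    }
  }
  # zero slope kills the age correlation
  flat <- simulate_methylation_cohort(
    synthetic_config(seed = 2, n_samples = 100L, beta_age_meth = 0))
  asg2 <- assign_probes_to_repeats(
    classify_probe_context(flat$annotation$probes, flat$annotation$genes),
    flat$annotation$repeats)
  cls2 <- rteage:::as_feature_matrix(
    suppressWarnings(aggregate_rte_scores(flat$beta, asg2, "class")))
  expect_gt(cor_pearson(flat$metadata$age, cls2["LINE", ])$p, 0.01)
})

test_that("single-cell truth: counts conserved and a null factor plants
           nothing", {
  cfg <- synthetic_config(seed = 3, sc_n_samples = 6L, sc_cells_per_type = 5L)
  sc <- simulate_single_cell(cfg)
  pb <- pseudo_bulk(sc$counts, sc$annotation)
  m <- rteage:::as_feature_matrix(sc$counts)
  expect_equal(sum(pb$count), sum(m))
  # planted factor 1: the plasma LINE mean matches other cell types
  null_cfg <- synthetic_config(seed = 4, sc_planted_factor = 1,
                               sc_n_samples = 8L, sc_cells_per_type = 10L)
  null_sc <- simulate_single_cell(null_cfg)
  null_pb <- pseudo_bulk(null_sc$counts, null_sc$annotation)
  line <- dplyr::filter(null_pb, feature_id == "LINE")
  hi <- dplyr::filter(line, sample_id %in% null_sc$truth$high_b_samples,
                      cell_type == "Plasma")
  lo <- dplyr::filter(line, !sample_id %in% null_sc$truth$high_b_samples,
                      cell_type == "Plasma")
  expect_gt(wilcoxon_compare(hi$count, lo$count)$p, 0.05)
})

test_that("fixture bundles land on disk in readable formats", {
  dir <- tempfile()
  cfg <- synthetic_config(seed = 8, n_samples = 12L, n_genes = 200L,
                          sc_n_samples = 4L, sc_cells_per_type = 3L,
                          sc_n_genes = 150L, sc_genes_per_signature = 5L)
  files <- write_fixture_bundle(cfg, dir)
  expect_true(all(file.exists(files)))
  reps <- read_repeatmasker(files[["repeats"]], "bed")
  expect_gt(nrow(reps), 0)
  expr <- read_sample_matrix(files[["expression"]])
  expect_equal(ncol(expr) - 1L, 12L)
  sigs <- read_gmt(files[["signatures"]])
  expect_equal(length(unique(sigs$set_name)), 6L)
  ann <- read_cell_annotation(files[["sc_cells"]])
  expect_equal(nrow(ann), 4L * 5L * 3L)
  # same seed writes identical files
  dir2 <- tempfile()
  files2 <- write_fixture_bundle(cfg, dir2)
  for (nm in setdiff(names(files), "ground_truth")) {
    expect_identical(readLines(files[[nm]]), readLines(files2[[nm]]),
                     info = nm)
  }
})
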