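#' Configuration for the synthetic-cohort generators
#'
#' Bundles every knob of the seeded generators. Defaults emulate the
#' statistical structure of the blood aging cohorts the analysis targets:
#' several hundred samples spanning ages 15-101; a latent biological-age
#' factor B, standard normal and independent of chronological age, that
#' drives both the biological-age-related (BAR) signature genes and RTE probe
#' expression; LINE and LTR probes coupled positively to B and SINE probes
#' negatively in PBMC mode (positively in monocyte mode); methylation beta
#' values declining linearly with age; and a PBMC-like single-cell cohort in
#' which one (cell type, RTE class) combination is amplified in high-B
#' samples only.
#'
#' @param seed Integer seed; fixed seed gives identical output.
#' @param n_samples Cohort size for the expression/methylation generators.
#' @param age_range Two-element numeric, years; ages drawn uniformly.
#' @param n_genes Number of gene rows in the expression matrix.
#' @param genes_per_signature Genes per BAR-like signature (6 signatures).
#' @param probes_per_family RTE probes generated per modelled family (L1, L2,
#'   Alu, MIR, ERV1, ERVL, ERVL-MaLR, ERVK, Satellite); at least 3.
#' @param beta_bar Named coupling of RTE probe expression to B, per class;
#'   defaults depend on `mode`.
#' @param sig_coupling Coupling of signature-gene expression to B.
#' @param noise_sd Residual SD of expression values (log-intensity scale).
#' @param beta_age_expr Slope of expression on age (default 0: no
#'   chronological-age signal).
#' @param beta_age_meth Methylation slope per year (beta units); negative.
#' @param meth_noise_sd Residual SD of beta values.
#' @param meth_expr_coupling Strength of the inverse methylation-expression
#'   coupling for LINE/LTR probes in the matched expression matrix.
#' @param mode `"pbmc"` (SINE inversely coupled to B) or `"monocyte"` (SINE
#'   positively coupled).
#' @param sc_n_samples,sc_cell_types,sc_cells_per_type,sc_n_genes Single-cell
#'   cohort shape.
#' @param sc_genes_per_signature Signature size for the single-cell gene sets.
#' @param sc_planted_celltype,sc_planted_class,sc_planted_factor The planted
#'   single-cell effect: mean counts of that class in that cell type are
#'   multiplied by the factor in samples with above-median B.
#' @param sc_dispersion Negative-binomial size parameter.
#' @param sc_sig_coupling Linear coupling of single-cell signature-gene means
#'   to B (means scale by `1 + cB`); an equally sized decoy gene block scales
#'   by `1 - cB` so expected library sizes are independent of B.
#'
#' @return A list of class `rte_synth_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_samples = 600L,
    age_range = c(15, 101),
    n_genes = 2000L,
    genes_per_signature = 20L,
    probes_per_family = 8L,
    beta_bar = NULL,
    sig_coupling = 1,
    noise_sd = 1,
    beta_age_expr = 0,
    beta_age_meth = -0.002,
    meth_noise_sd = 0.05,
    meth_expr_coupling = 1,
    mode = c("pbmc", "monocyte"),
    sc_n_samples = 21L,
    sc_cell_types = c("Plasma", "BC", "TC", "NK", "M14"),
    sc_cells_per_type = 20L,
    sc_n_genes = 300L,
    sc_genes_per_signature = 10L,
    sc_planted_celltype = "Plasma",
    sc_planted_class = "LINE",
    sc_planted_factor = 3,
    sc_dispersion = 10,
    sc_sig_coupling = 0.4) {
  mode <- match.arg(mode)
  if (is.null(beta_bar)) {
    beta_bar <- c(LINE = 0.5, LTR = 0.5,
                  SINE = if (mode == "pbmc") -0.5 else 0.5,
                  Satellite = 0)
  }
  stopifnot(probes_per_family >= 3L, length(age_range) == 2L,
            all(is.finite(beta_bar)), sc_n_samples >= 4L,
            length(sc_cell_types) >= 2L)
  structure(as.list(environment()), class = "rte_synth_config")
}

signature_names <- function() {
  c("IFN1", "inflammatory_cytokines", "inflammatory_chemokines",
    "inflammaging", "SASP", "senescence")
}

modelled_families <- function() {
  tibble(
    repeat_family = c("L1", "L2", "Alu", "MIR",
                      "ERV1", "ERVL", "ERVL-MaLR", "ERVK", "Satellite"),
    repeat_class = c("LINE", "LINE", "SINE", "SINE",
                     "LTR", "LTR", "LTR", "LTR", "Satellite")
  )
}

#' Simulate genome annotation with known probe truth
#'
#' Lays out a single synthetic chromosome in fixed-size units, each holding
#' one probe with a known genic context and, for most probes, one overlapping
#' repeat of a modelled family. Contexts cycle through intronic, intergenic
#' and exonic so every family receives probes of each kind; additional probes
#' overlap no repeat at all. The layout is deterministic given the seed, and
#' the emitted truth table is sufficient to verify context classification and
#' probe-repeat assignment exactly.
#'
#' @param config An [synthetic_config()].
#' @return A list: `genes` (gene-model tibble as [read_gene_models()]),
#'   `repeats` (as [read_repeatmasker()]), `probes` (manifest tibble),
#'   `truth` (tibble `probe_id`, `true_context`, `true_repeat_name`,
#'   `true_repeat_class`, `true_repeat_family`; NA repeat fields for probes
#'   overlapping no repeat).
#' @export
simulate_annotation <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "rte_synth_config"))
  fams <- modelled_families()
  unit <- 10000L
  contexts <- c("intronic", "intergenic", "exonic")

  rows <- list(); genes <- list(); repeats <- list(); k <- 0L
  add_unit <- function(i, context, fam_row, with_repeat) {
    base <- (i - 1L) * unit
    probe_id <- sprintf("probe_%04d", i)
    pstart <- base + 2000L; pend <- pstart + 50L
    if (context != "intergenic") {
      gid <- sprintf("GENEBODY_%04d", i)
      genes[[length(genes) + 1L]] <<- tibble(
        gene_id = gid, feature = "gene", chrom = "chr1",
        start = base + 500L, end = base + 5500L, strand = "+"
      )
      exon_start <- if (context == "exonic") pstart + 20L else base + 500L
      exon_end <- if (context == "exonic") pend + 200L else base + 700L
      genes[[length(genes) + 1L]] <<- tibble(
        gene_id = gid, feature = "exon", chrom = "chr1",
        start = exon_start, end = exon_end, strand = "+"
      )
      # second exon keeps the gene multi-exonic
      genes[[length(genes) + 1L]] <<- tibble(
        gene_id = gid, feature = "exon", chrom = "chr1",
        start = base + 5300L, end = base + 5500L, strand = "+"
      )
    }
    rep_name <- NA_character_
    if (with_repeat) {
      rep_name <- sprintf("%s_rep_%04d", fam_row$repeat_family, i)
      repeats[[length(repeats) + 1L]] <<- tibble(
        chrom = "chr1", start = pstart - 10L, end = pend + 60L, strand = "+",
        repeat_name = rep_name,
        repeat_class = fam_row$repeat_class,
        repeat_family = fam_row$repeat_family
      )
    }
    rows[[length(rows) + 1L]] <<- tibble(
      probe_id = probe_id, chrom = "chr1", start = pstart, end = pend,
      strand = "+", true_context = context,
      true_repeat_name = rep_name,
      true_repeat_class = if (with_repeat) fam_row$repeat_class else NA_character_,
      true_repeat_family = if (with_repeat) fam_row$repeat_family else NA_character_
    )
  }

  i <- 0L
  for (f in seq_len(nrow(fams))) {
    for (p in seq_len(config$probes_per_family)) {
      i <- i + 1L
      # noncoding contexts first so every family keeps >=3 assignable probes
      ctx <- if (p <= 2L) c("intronic", "intergenic")[p] else
        contexts[(p - 3L) %% 3L + 1L]
      add_unit(i, ctx, fams[f, ], with_repeat = TRUE)
    }
  }
  for (p in seq_len(6L)) {  # repeat-free probes
    i <- i + 1L
    add_unit(i, contexts[(p - 1L) %% 3L + 1L], NULL, with_repeat = FALSE)
  }

  probes <- bind_rows(rows)
  list(
    genes = bind_rows(genes),
    repeats = bind_rows(repeats),
    probes = select(probes, "probe_id", "chrom", "start", "end", "strand"),
    truth = select(probes, "probe_id", "true_context", "true_repeat_name",
                   "true_repeat_class", "true_repeat_family")
  )
}

# Deterministic sub-seeds so each generator has an independent stream.
sub_seed <- function(config, offset) (config$seed %% 2147480000L) + offset

#' Simulate an expression cohort with a latent biological-age factor
#'
#' Draws ages uniformly over `age_range` and an independent standard-normal
#' latent factor B per sample. Signature genes follow
#' `sig_coupling * B + noise`; RTE probe values follow
#' `beta_bar[class] * B + beta_age_expr * (age - mean age) + noise`;
#' remaining genes are pure noise. Because B is independent of age, RTE
#' scores show no chronological-age correlation while correlating with
#' signature scores through B, with the SINE sign set by `mode`.
#'
#' @param config An [synthetic_config()].
#' @param annotation Optional result of [simulate_annotation()] (re-derived
#'   from `config` when NULL).
#' @return A list: `expr` (sample-matrix tibble of gene symbols and probe
#'   ids), `metadata` (tibble `sample_id`, `age`), `signatures` (tibble
#'   `set_name`/`gene`), `annotation`, and `truth` (list with `latent_b`,
#'   `beta_bar`, `sig_coupling`, `probe_classes`).
#' @export
simulate_expression_cohort <- function(config = synthetic_config(),
                                       annotation = NULL) {
  stopifnot(inherits(config, "rte_synth_config"))
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  set.seed(sub_seed(config, 2L))

  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  b <- stats::rnorm(n)

  sig_names <- signature_names()
  gpp <- config$genes_per_signature
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  sig_genes <- split(genes[seq_len(6L * gpp)],
                     rep(sig_names, each = gpp))[sig_names]
  signatures <- tibble(
    set_name = rep(sig_names, each = gpp),
    gene = unlist(sig_genes, use.names = FALSE)
  )

  expr_genes <- matrix(stats::rnorm(length(genes) * n, sd = config$noise_sd),
                       length(genes), n, dimnames = list(genes, samples))
  in_sig <- genes %in% signatures$gene
  expr_genes[in_sig, ] <- expr_genes[in_sig, ] +
    matrix(config$sig_coupling * b, sum(in_sig), n, byrow = TRUE)

  probes <- annotation$truth
  beta <- config$beta_bar[probes$true_repeat_class]
  beta[is.na(beta)] <- 0
  age_c <- age - mean(age)
  expr_probes <- matrix(stats::rnorm(nrow(probes) * n, sd = config$noise_sd),
                        nrow(probes), n,
                        dimnames = list(probes$probe_id, samples)) +
    outer(beta, b) + outer(rep(config$beta_age_expr, nrow(probes)), age_c)

  expr <- as_sample_tibble(rbind(expr_genes, expr_probes))
  list(
    expr = expr,
    metadata = tibble(sample_id = samples, age = age),
    signatures = signatures,
    annotation = annotation,
    truth = list(latent_b = stats::setNames(b, samples),
                 beta_bar = config$beta_bar,
                 sig_coupling = config$sig_coupling,
                 probe_classes = stats::setNames(probes$true_repeat_class,
                                                 probes$probe_id))
  )
}

#' Simulate a methylation cohort with age-linked hypomethylation
#'
#' Per RTE probe, beta values follow
#' `clip(b0 + beta_age_meth * age + noise, 0, 1)` with probe baselines b0
#' drawn from U(0.70, 0.85); the default slope keeps clipping negligible.
#' A matched expression matrix couples LINE/LTR probe expression inversely to
#' the age-independent methylation residual (so stratifying by expression
#' recovers hypomethylated high-expression groups without inducing an
#' age-expression correlation), while SINE and Satellite probe expression is
#' decoupled from methylation.
#'
#' @param config An [synthetic_config()].
#' @param annotation Optional [simulate_annotation()] result.
#' @return A list: `beta` (sample-matrix tibble of probe beta values),
#'   `matched_expr` (probe expression tibble on the same samples),
#'   `metadata`, `annotation`, `truth` (list with `baselines`, `slope`,
#'   `coupled_classes`).
#' @export
simulate_methylation_cohort <- function(config = synthetic_config(),
                                        annotation = NULL) {
  stopifnot(inherits(config, "rte_synth_config"))
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  set.seed(sub_seed(config, 3L))

  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  probes <- annotation$truth
  p <- nrow(probes)
  b0 <- stats::runif(p, 0.70, 0.85)

  resid <- matrix(stats::rnorm(p * n, sd = config$meth_noise_sd), p, n,
                  dimnames = list(probes$probe_id, samples))
  beta <- outer(b0, rep(1, n)) + config$beta_age_meth * outer(rep(1, p), age) +
    resid
  beta <- pmin(pmax(beta, 0), 1)

  coupled <- probes$true_repeat_class %in% c("LINE", "LTR")
  coupled[is.na(probes$true_repeat_class)] <- FALSE
  expr <- matrix(stats::rnorm(p * n, sd = 0.5), p, n,
                 dimnames = list(probes$probe_id, samples))
  expr[coupled, ] <- expr[coupled, ] -
    config$meth_expr_coupling * resid[coupled, ] / config$meth_noise_sd

  list(
    beta = as_sample_tibble(beta),
    matched_expr = as_sample_tibble(expr),
    metadata = tibble(sample_id = samples, age = age),
    annotation = annotation,
    truth = list(baselines = stats::setNames(b0, probes$probe_id),
                 slope = config$beta_age_meth,
                 coupled_classes = c("LINE", "LTR"))
  )
}

#' Simulate an annotated single-cell PBMC-like cohort
#'
#' Generates negative-binomial counts for genes and RTE class features over a
#' panel of annotated cell types. Signature-gene means are scaled by
#' `exp(sc_sig_coupling * B)` per sample (with an equal-size inversely
#' coupled decoy block so library sizes stay balanced); the planted
#' (cell type, RTE class) mean is multiplied by `sc_planted_factor` in
#' samples whose latent B exceeds the cohort median.
#'
#' @param config An [synthetic_config()].
#' @return A list: `counts` (feature-by-cell tibble), `annotation` (tibble
#'   `cell_id`, `sample_id`, `cell_type`), `signatures` (tibble), `truth`
#'   (list with `latent_b`, `high_b_samples`, `planted` =
#'   list(cell_type, rte_class, factor)).
#' @export
simulate_single_cell <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "rte_synth_config"))
  set.seed(sub_seed(config, 4L))

  n <- config$sc_n_samples
  samples <- sprintf("SC%03d", seq_len(n))
  b <- stats::rnorm(n)
  names(b) <- samples
  high_b <- samples[b > stats::median(b)]

  genes <- sprintf("SCG%04d", seq_len(config$sc_n_genes))
  gpp <- config$sc_genes_per_signature
  sig_names <- signature_names()
  n_sig <- 6L * gpp
  stopifnot(config$sc_n_genes >= 2L * n_sig)
  signatures <- tibble(set_name = rep(sig_names, each = gpp),
                       gene = genes[seq_len(n_sig)])
  decoy_idx <- seq.int(n_sig + 1L, 2L * n_sig)  # inversely coupled ballast

  rte <- c(LINE = 5, SINE = 8, LTR = 4)  # RTE reads: a small library fraction
  features <- c(genes, names(rte))
  base_gene <- stats::runif(length(genes), 1, 10)
  base <- c(base_gene, rte)
  names(base) <- features

  ann <- tidyr::expand_grid(
    sample_id = samples,
    cell_type = config$sc_cell_types,
    cell = seq_len(config$sc_cells_per_type)
  ) |>
    mutate(cell_id = sprintf("%s_%s_%03d", .data$sample_id, .data$cell_type,
                             .data$cell)) |>
    select("cell_id", "sample_id", "cell_type")

  mu <- matrix(base, length(features), nrow(ann),
               dimnames = list(features, ann$cell_id))
  # linear balanced coupling: signature genes scale by (1 + cB), the decoy
  # block by (1 - cB), so expected library size is independent of B
  sig_scale <- pmax(0.05, 1 + config$sc_sig_coupling * b[ann$sample_id])
  decoy_scale <- pmax(0.05, 1 - config$sc_sig_coupling * b[ann$sample_id])
  mu[seq_len(n_sig), ] <- sweep(mu[seq_len(n_sig), , drop = FALSE], 2,
                                sig_scale, "*")
  mu[decoy_idx, ] <- sweep(mu[decoy_idx, , drop = FALSE], 2,
                           decoy_scale, "*")
  planted_cells <- ann$cell_type == config$sc_planted_celltype &
    ann$sample_id %in% high_b
  mu[config$sc_planted_class, planted_cells] <-
    mu[config$sc_planted_class, planted_cells] * config$sc_planted_factor

  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = config$sc_dispersion),
    nrow(mu), ncol(mu), dimnames = dimnames(mu)
  )
  list(
    counts = as_sample_tibble(counts),
    annotation = ann,
    signatures = signatures,
    truth = list(latent_b = b, high_b_samples = high_b,
                 planted = list(cell_type = config$sc_planted_celltype,
                                rte_class = config$sc_planted_class,
                                factor = config$sc_planted_factor))
  )
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits every input format the analysis functions read: repeat BED, gene
#' GTF, probe manifest TSV, expression and methylation matrices, sample
#' metadata, signature GMT, single-cell dense counts and cell annotation,
#' plus ground-truth TSV/JSON files for recovery tests.
#'
#' @param config An [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(config = synthetic_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(config)
  ex <- simulate_expression_cohort(config, annotation = ann)
  me <- simulate_methylation_cohort(config, annotation = ann)
  sc <- simulate_single_cell(config)
  p <- function(...) file.path(dir, ...)

  write_bed_intervals(
    mutate(ann$repeats,
           name = paste0(.data$repeat_name, "#", .data$repeat_class, "/",
                         .data$repeat_family)),
    p("repeats.bed"))
  write_gtf(ann$genes, p("genes.gtf"))
  readr::write_tsv(ann$probes, p("probes.tsv"))
  readr::write_tsv(ann$truth, p("truth_annotation.tsv"))
  write_sample_matrix(ex$expr, p("expression.tsv"))
  readr::write_tsv(ex$metadata, p("samples.tsv"))
  write_gmt(ex$signatures, p("signatures.gmt"))
  write_sample_matrix(me$beta, p("methylation.tsv"))
  write_sample_matrix(me$matched_expr, p("methylation_matched_expr.tsv"))
  readr::write_tsv(me$metadata, p("methylation_samples.tsv"))
  write_sample_matrix(sc$counts, p("sc_counts.tsv"))
  readr::write_tsv(sc$annotation, p("sc_cells.tsv"))
  write_gmt(sc$signatures, p("sc_signatures.gmt"))
  truth <- list(
    latent_b = as.list(ex$truth$latent_b),
    beta_bar = as.list(config$beta_bar),
    meth_slope = config$beta_age_meth,
    sc = list(latent_b = as.list(sc$truth$latent_b),
              high_b_samples = sc$truth$high_b_samples,
              planted = sc$truth$planted)
  )
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             p("ground_truth.json"))
  files <- c(repeats = p("repeats.bed"), genes = p("genes.gtf"),
             probes = p("probes.tsv"), truth_annotation = p("truth_annotation.tsv"),
             expression = p("expression.tsv"), samples = p("samples.tsv"),
             signatures = p("signatures.gmt"), methylation = p("methylation.tsv"),
             methylation_matched_expr = p("methylation_matched_expr.tsv"),
             methylation_samples = p("methylation_samples.tsv"),
             sc_counts = p("sc_counts.tsv"), sc_cells = p("sc_cells.tsv"),
             sc_signatures = p("sc_signatures.gmt"),
             ground_truth = p("ground_truth.json"))
  invisible(files)
}

# Minimal GTF writer for the synthetic gene models (0-based half-open in,
# 1-based inclusive out).
write_gtf <- function(genes, path) {
  lines <- sprintf(
    '%s\trteage\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    genes$chrom, genes$feature, genes$start + 1L, genes$end,
    genes$strand, genes$gene_id
  )
  writeLines(lines, path)
  invisible(path)
}
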