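#' Configure an end-to-end analysis run
#'
#' Collects the file paths, analysis level and thresholds used by the
#' orchestration drivers [run_microarray()], [run_methylation()] and
#' [run_single_cell()]. Thresholds default to the permissive differential
#' settings (|logFC| > 0.1, p < 0.05).
#'
#' @param repeats Repeat annotation path (`.out` or `.bed`, by extension).
#' @param genes GTF path defining genic context; `NULL` treats every probe as
#'   intergenic.
#' @param probes Probe manifest TSV path.
#' @param expression,methylation Feature-by-sample matrix TSV paths.
#' @param matched_expression Probe expression TSV on the methylation samples
#'   (optional; enables methylation-by-expression-group contrasts).
#' @param metadata Sample metadata TSV (`sample_id`, `age`).
#' @param signatures Signature GMT path.
#' @param enrichment_sets GMT of pathway sets for enrichment (optional).
#' @param enrichment_categories Sidecar TSV (`set_name`, `category`).
#' @param sc_counts,sc_features,sc_barcodes,sc_annotation Single-cell inputs
#'   (dense TSV, or MTX plus sidecars, and the cell annotation TSV).
#' @param level `"class"`, `"family"`, or both.
#' @param group_mode `"quartile"` or `"median"` for RTE-score stratification.
#' @param sc_basis Signature used for the single-cell median split; `NULL`
#'   contrasts every signature.
#' @param lfc_threshold,p_threshold Differential-call thresholds.
#' @param out_dir Output directory.
#' @param seed Seed recorded in the manifest (the drivers are deterministic;
#'   the seed is set for completeness before any randomized step).
#' @return A list of class `rte_pipeline_config`.
#' @export
pipeline_config <- function(repeats = NULL, genes = NULL, probes = NULL,
                            expression = NULL, methylation = NULL,
                            matched_expression = NULL, metadata = NULL,
                            signatures = NULL, enrichment_sets = NULL,
                            enrichment_categories = NULL,
                            sc_counts = NULL, sc_features = NULL,
                            sc_barcodes = NULL, sc_annotation = NULL,
                            level = c("class", "family"),
                            group_mode = c("quartile", "median"),
                            sc_basis = "SASP",
                            lfc_threshold = 0.1, p_threshold = 0.05,
                            out_dir = ".", seed = 1L) {
  group_mode <- match.arg(group_mode)
  level <- match.arg(level, several.ok = TRUE)
  stopifnot(lfc_threshold > 0, p_threshold > 0)
  structure(as.list(environment()), class = "rte_pipeline_config")
}

require_inputs <- function(config, needed) {
  for (nm in needed) {
    path <- config[[nm]]
    if (is.null(path)) stop("pipeline config lacks input '", nm, "'", call. = FALSE)
    if (!file.exists(path)) {
      stop("input file for '", nm, "' not found: ", path, call. = FALSE)
    }
  }
}

run_stage <- function(state, name, fun) {
  res <- tryCatch(fun(), error = function(e) {
    stop("pipeline stage '", name, "' failed (completed: ",
         paste(state$done, collapse = ", "), "): ", conditionMessage(e),
         call. = FALSE)
  })
  state$done <- c(state$done, name)
  res
}

write_manifest <- function(config, state, path) {
  inputs <- purrr::compact(config[c(
    "repeats", "genes", "probes", "expression", "methylation",
    "matched_expression", "metadata", "signatures", "enrichment_sets",
    "enrichment_categories", "sc_counts", "sc_features", "sc_barcodes",
    "sc_annotation")])
  manifest <- list(
    tool = "rteage",
    version = as.character(utils::packageVersion("rteage")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    thresholds = list(lfc = config$lfc_threshold, p = config$p_threshold),
    group_mode = config$group_mode,
    level = config$level,
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    stages = state$done,
    rows = state$rows,
    warnings = state$warnings
  )
  tmp <- paste0(path, ".tmp")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), tmp)
  file.rename(tmp, path)  # atomic publish
  invisible(path)
}

new_state <- function() {
  env <- new.env(parent = emptyenv())
  env$done <- character(); env$rows <- list(); env$warnings <- character()
  env
}

note_rows <- function(state, name, df) {
  state$rows[[name]] <- nrow(df)
  df
}

load_assignments <- function(config) {
  fmt <- if (grepl("\\.bed$", config$repeats)) "bed" else "rmsk_out"
  repeats <- read_repeatmasker(config$repeats, format = fmt)
  probes <- read_probe_manifest(config$probes)
  genes <- if (is.null(config$genes)) NULL else read_gene_models(config$genes)
  probes <- classify_probe_context(probes, genes)
  list(repeats = repeats,
       assignments = assign_probes_to_repeats(probes, repeats))
}

rte_groupings <- function(scores, mode) {
  m <- as_feature_matrix(scores)
  split_fun <- if (mode == "quartile") quartile_split else median_split
  purrr::map(stats::setNames(rownames(m), rownames(m)), function(f) {
    split_fun(tibble(sample_id = colnames(m), score = m[f, ]), basis = f)
  })
}

#' Run the microarray expression analysis end to end
#'
#' Probe assignment, RTE class/family score aggregation, signature scoring,
#' age and signature correlation tables, quartile (or median) stratification
#' with signature-score contrasts, and — when enrichment sets are supplied —
#' per-sample enrichment scores with high-versus-low differential calls and
#' the up-minus-down category summary. All tables are written as TSV under
#' `out_dir`, followed by an atomically written JSON run manifest.
#'
#' @param config An [pipeline_config()]; needs `repeats`, `probes`,
#'   `expression`, `metadata`, `signatures` (plus optionally `genes` and the
#'   enrichment inputs).
#' @return Named list of the in-memory result tables, invisibly writable;
#'   the `files` element maps outputs to paths.
#' @export
run_microarray <- function(config) {
  stopifnot(inherits(config, "rte_pipeline_config"))
  require_inputs(config, c("repeats", "probes", "expression", "metadata",
                           "signatures"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  state <- new_state()
  out <- list(files = character())
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    readr::write_tsv(df, path)
    out$files[[name]] <<- path
    note_rows(state, name, df)
  }
  capture_warnings <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      state$warnings <- c(state$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  ann <- run_stage(state, "annotate", function() load_assignments(config))
  out$assignments <- ann$assignments
  emit(select(ann$assignments, -"chrom", -"start", -"end", -"strand"),
       "probe_assignments")
  write_assignments(ann$assignments,
                    bed_path = file.path(config$out_dir, "assigned_probes.bed"))

  expr <- run_stage(state, "quantify", function() {
    collapse_duplicate_features(read_sample_matrix(config$expression))
  })
  scores <- list()
  for (lv in config$level) {
    scores[[lv]] <- run_stage(state, paste0("rte_scores_", lv), function() {
      capture_warnings(aggregate_rte_scores(expr, ann$assignments, level = lv))
    })
    emit(scores[[lv]], paste0("rte_scores_", lv))
  }
  out$rte_scores <- scores

  sig <- run_stage(state, "signature_scores", function() {
    score_signatures(expr, read_gmt(config$signatures))
  })
  out$signature_scores <- sig
  emit(sig, "signature_scores")
  emit(missing_gene_report(sig), "missing_genes")

  meta <- readr::read_tsv(config$metadata, show_col_types = FALSE)
  out$correlations <- run_stage(state, "correlations", function() {
    purrr::map_dfr(config$level, function(lv) {
      wide <- correlation_input(meta, scores[[lv]], sig)
      mutate(correlate_pairs(wide), level = lv)
    })
  })
  emit(out$correlations, "correlation_table")

  out$groupings <- list(); out$signature_contrasts <- list()
  for (lv in config$level) {
    grp <- run_stage(state, paste0("grouping_", lv), function() {
      rte_groupings(scores[[lv]], config$group_mode)
    })
    out$groupings[[lv]] <- grp
    emit(bind_rows(grp), paste0("grouping_", lv))
    contr <- purrr::map_dfr(names(grp), function(f) {
      mutate(group_contrast(sig, grp[[f]]), rte_id = f, level = lv)
    })
    out$signature_contrasts[[lv]] <- contr
    emit(contr, paste0("signature_by_rte_group_", lv))
  }

  if (!is.null(config$enrichment_sets)) {
    require_inputs(config, c("enrichment_sets", "enrichment_categories"))
    sets <- read_gmt(config$enrichment_sets)
    cats <- readr::read_tsv(config$enrichment_categories, show_col_types = FALSE)
    keep <- filter_gene_set_names(unique(sets$set_name))
    sets <- filter(sets, .data$set_name %in% keep)
    es <- run_stage(state, "enrichment_scores", function() {
      gsva_scores(expr, sets)
    })
    out$enrichment_scores <- es
    emit(es, "enrichment_scores")
    diffs <- run_stage(state, "differential_enrichment", function() {
      purrr::map_dfr(config$level, function(lv) {
        purrr::map_dfr(names(out$groupings[[lv]]), function(f) {
          mutate(differential_enrichment(es, out$groupings[[lv]][[f]],
                                         config$lfc_threshold,
                                         config$p_threshold),
                 rte_id = f, level = lv)
        })
      })
    })
    out$differential <- diffs
    emit(diffs, "differential_enrichment")
    out$updown <- updown_summary(diffs, cats)
    emit(out$updown, "updown_summary")
  }

  out$manifest <- write_manifest(config, state,
                                 file.path(config$out_dir, "run_manifest.json"))
  out
}

# Metadata + RTE scores + signature scores as one sample-by-variable frame.
correlation_input <- function(meta, rte_scores, sig_scores) {
  rte_w <- pivot_scores(rte_scores)
  sig_w <- pivot_scores(sig_scores)
  meta |>
    select("sample_id", any_of("age")) |>
    inner_join(rte_w, by = "sample_id") |>
    inner_join(sig_w, by = "sample_id")
}

#' Transpose a feature-by-sample score matrix to sample rows
#'
#' Turns a wide score tibble (features in rows, one column per sample) into
#' a tibble with one row per sample and one column per feature — the layout
#' [correlate_pairs()] and the split functions expect.
#'
#' @param scores A sample-matrix tibble (e.g. from [aggregate_rte_scores()]
#'   or [score_signatures()]).
#' @return A tibble with `sample_id` plus one numeric column per feature.
#' @export
pivot_scores <- function(scores) {
  m <- as_feature_matrix(scores)
  dplyr::bind_cols(tibble(sample_id = colnames(m)),
                   as_tibble(t(m), .name_repair = "minimal"))
}

#' Run the methylation analysis end to end
#'
#' Aggregates probe beta values to RTE class/family methylation scores,
#' writes age-methylation correlation tables, and — when a matched probe
#' expression matrix is supplied — stratifies samples by RTE expression and
#' contrasts methylation across the high/low groups. Sample sets of the two
#' matrices are intersected, with the discarded count logged in the manifest.
#'
#' @param config An [pipeline_config()]; needs `repeats`, `probes`,
#'   `methylation`, `metadata` (plus optionally `genes` and
#'   `matched_expression`).
#' @return Named list of result tables; `files` maps outputs to paths.
#' @export
run_methylation <- function(config) {
  stopifnot(inherits(config, "rte_pipeline_config"))
  require_inputs(config, c("repeats", "probes", "methylation", "metadata"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  state <- new_state()
  out <- list(files = character())
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    readr::write_tsv(df, path)
    out$files[[name]] <<- path
    note_rows(state, name, df)
  }

  ann <- run_stage(state, "annotate", function() load_assignments(config))
  beta <- run_stage(state, "read_methylation", function() {
    collapse_duplicate_features(read_sample_matrix(config$methylation))
  })
  meta <- readr::read_tsv(config$metadata, show_col_types = FALSE)

  mscores <- list()
  for (lv in config$level) {
    mscores[[lv]] <- run_stage(state, paste0("meth_scores_", lv), function() {
      suppressWarnings(aggregate_rte_scores(beta, ann$assignments, level = lv))
    })
    emit(mscores[[lv]], paste0("meth_scores_", lv))
  }
  out$meth_scores <- mscores

  out$age_correlations <- run_stage(state, "age_correlations", function() {
    purrr::map_dfr(config$level, function(lv) {
      m <- as_feature_matrix(mscores[[lv]])
      idx <- match(colnames(m), meta$sample_id)
      purrr::map_dfr(rownames(m), function(f) {
        ct <- cor_pearson(meta$age[idx], m[f, ])
        tibble(rte_id = f, level = lv, r = ct$r, p = ct$p, n = ct$n,
               stars = p_stars(ct$p))
      })
    })
  })
  emit(out$age_correlations, "age_methylation_correlation")

  if (!is.null(config$matched_expression)) {
    require_inputs(config, "matched_expression")
    expr <- collapse_duplicate_features(
      read_sample_matrix(config$matched_expression))
    shared <- intersect(names(beta)[-1], names(expr)[-1])
    n_lost <- length(union(names(beta)[-1], names(expr)[-1])) - length(shared)
    if (n_lost > 0) {
      state$warnings <- c(state$warnings,
                          paste0(n_lost, " sample(s) outside the ",
                                 "expression/methylation intersection dropped"))
    }
    out$meth_by_expression <- run_stage(state, "meth_by_expression", function() {
      purrr::map_dfr(config$level, function(lv) {
        escore <- suppressWarnings(
          aggregate_rte_scores(expr[, c(names(expr)[1], shared)],
                               ann$assignments, level = lv))
        grp <- rte_groupings(escore, config$group_mode)
        purrr::map_dfr(names(grp), function(f) {
          mutate(group_contrast(mscores[[lv]][, c(names(mscores[[lv]])[1], shared)],
                                grp[[f]]),
                 expression_group_of = f, level = lv)
        })
      })
    })
    emit(out$meth_by_expression, "methylation_by_expression_group")
  }

  out$manifest <- write_manifest(config, state,
                                 file.path(config$out_dir, "run_manifest.json"))
  out
}

#' Run the single-cell analysis end to end
#'
#' Pseudo-bulk aggregation, combined gene + RTE-class RPM normalization,
#' sample-level signature scoring, median stratification and per-cell-type
#' high-versus-low rank-sum contrasts, written as TSVs plus a JSON manifest.
#'
#' @param config An [pipeline_config()]; needs `sc_counts`, `sc_annotation`,
#'   `signatures` (with `sc_features`/`sc_barcodes` for MTX input).
#' @return Named list of result tables; `files` maps outputs to paths.
#' @export
run_single_cell <- function(config) {
  stopifnot(inherits(config, "rte_pipeline_config"))
  require_inputs(config, c("sc_counts", "sc_annotation", "signatures"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  state <- new_state()
  out <- list(files = character())
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    readr::write_tsv(df, path)
    out$files[[name]] <<- path
    note_rows(state, name, df)
  }

  counts <- run_stage(state, "read_counts", function() {
    read_cell_counts(config$sc_counts, config$sc_features, config$sc_barcodes)
  })
  ann <- read_cell_annotation(config$sc_annotation)
  sigs <- read_gmt(config$signatures)

  pb <- run_stage(state, "pseudo_bulk", function() {
    suppressMessages(pseudo_bulk(counts, ann))
  })
  emit(pb, "pseudobulk_counts")
  pb_rpm <- run_stage(state, "combined_rpm", function() combined_rpm(pb))
  emit(pb_rpm, "pseudobulk_rpm")

  sig <- run_stage(state, "signature_scores", function() {
    pseudobulk_signature_scores(counts, ann, sigs)
  })
  out$signature_scores <- sig
  emit(sig, "sample_signature_scores")

  bases <- config$sc_basis %||% rownames(as_feature_matrix(sig))
  out$contrasts <- run_stage(state, "celltype_contrasts", function() {
    m <- as_feature_matrix(sig)
    purrr::map_dfr(bases, function(basis) {
      grp <- median_split(tibble(sample_id = colnames(m), score = m[basis, ]),
                          basis = basis)
      res <- withCallingHandlers(
        celltype_contrast(pb_rpm, grp),
        warning = function(w) {
          state$warnings <- c(state$warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      mutate(res, signature = basis)
    })
  })
  emit(out$contrasts, "celltype_contrasts")
  out$groupings <- NULL

  out$manifest <- write_manifest(config, state,
                                 file.path(config$out_dir, "run_manifest.json"))
  out
}
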