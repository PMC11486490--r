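#' Classify probes by genic context
#'
#' Labels each probe `exonic` if it overlaps any exon by at least 1 bp,
#' otherwise `intronic` if it falls within any gene body, otherwise
#' `intergenic`. Probes lacking coordinates (NA start/end) are labelled
#' `unknown`. Strand is ignored: expression microarray probes interrogate
#' transcripts regardless of the annotated gene strand.
#'
#' @param probes Probe tibble (`probe_id`, `chrom`, `start`, `end`, `strand`),
#'   coordinates 0-based half-open.
#' @param genes Gene-model tibble from [read_gene_models()]. An empty gene
#'   model classifies everything `intergenic`.
#'
#' @return `probes` with an added `context` column in
#'   `{exonic, intronic, intergenic, unknown}`.
#' @export
classify_probe_context <- function(probes, genes) {
  stopifnot(all(c("probe_id", "chrom", "start", "end") %in% names(probes)))
  known <- !is.na(probes$start) & !is.na(probes$end)
  context <- rep("unknown", nrow(probes))
  if (any(known) && !is.null(genes) && nrow(genes) > 0L) {
    pg <- intervals_to_granges(probes[known, , drop = FALSE])
    exonic <- overlaps_any(pg, intervals_to_granges(genes[genes$feature == "exon", , drop = FALSE]))
    genic <- overlaps_any(pg, intervals_to_granges(genes[genes$feature == "gene", , drop = FALSE]))
    context[known] <- ifelse(exonic, "exonic", ifelse(genic, "intronic", "intergenic"))
  } else {
    context[known] <- "intergenic"
  }
  probes$context <- context
  probes
}

# 0-based half-open tibble -> GRanges (1-based inclusive), strand dropped.
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

overlaps_any <- function(query, subject) {
  if (length(subject) == 0L) return(rep(FALSE, length(query)))
  IRanges::overlapsAny(query, subject, minoverlap = 1L, ignore.strand = TRUE)
}

#' Assign probes to their best-overlapping repeat
#'
#' Restricts probes to the allowed genic contexts (noncoding —
#' intergenic/intronic — by default, so probes measuring annotated exons never
#' enter repeat scores), overlaps them with repeat intervals, and keeps a
#' single best assignment per probe: maximum overlap, ties broken by leftmost
#' repeat start and then lexicographic `repeat_name`. Any overlap of at least
#' 1 bp qualifies; strand is ignored.
#'
#' @param probes Probe tibble carrying a `context` column (see
#'   [classify_probe_context()]).
#' @param repeats Repeat tibble from [read_repeatmasker()].
#' @param contexts_allowed Contexts retained before overlap; default
#'   `c("intergenic", "intronic")`.
#'
#' @return A tibble sorted by `probe_id` with columns `probe_id`,
#'   `repeat_name`, `repeat_class`, `repeat_family`, `overlap_bp`, `context`,
#'   plus the probe interval (`chrom`, `start`, `end`, `strand`); each probe
#'   appears at most once.
#' @export
assign_probes_to_repeats <- function(probes, repeats,
                                     contexts_allowed = c("intergenic", "intronic")) {
  if (!"context" %in% names(probes)) {
    stop("probes must carry a context column; run classify_probe_context() first",
         call. = FALSE)
  }
  empty <- tibble(
    probe_id = character(), repeat_name = character(),
    repeat_class = character(), repeat_family = character(),
    overlap_bp = integer(), context = character(),
    chrom = character(), start = integer(), end = integer(), strand = character()
  )
  probes <- probes[probes$context %in% contexts_allowed, , drop = FALSE]
  if (nrow(probes) == 0L || is.null(repeats) || nrow(repeats) == 0L) return(empty)

  pg <- intervals_to_granges(probes)
  rg <- intervals_to_granges(repeats)
  hits <- GenomicRanges::findOverlaps(pg, rg, minoverlap = 1L, ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)

  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(pg)[qi],
                                           IRanges::ranges(rg)[si]))
  cand <- tibble(
    probe_idx = qi, repeat_idx = si, overlap_bp = as.integer(ov),
    repeat_start = repeats$start[si], repeat_name = repeats$repeat_name[si]
  )
  best <- cand |>
    group_by(.data$probe_idx) |>
    arrange(dplyr::desc(.data$overlap_bp), .data$repeat_start,
            .data$repeat_name, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup()

  tibble(
    probe_id = probes$probe_id[best$probe_idx],
    repeat_name = repeats$repeat_name[best$repeat_idx],
    repeat_class = repeats$repeat_class[best$repeat_idx],
    repeat_family = repeats$repeat_family[best$repeat_idx],
    overlap_bp = best$overlap_bp,
    context = probes$context[best$probe_idx],
    chrom = probes$chrom[best$probe_idx],
    start = probes$start[best$probe_idx],
    end = probes$end[best$probe_idx],
    strand = probes$strand[best$probe_idx]
  ) |>
    arrange(.data$probe_id)
}

#' Write a probe-repeat assignment table and its BED companion
#'
#' @param assignments Output of [assign_probes_to_repeats()].
#' @param tsv_path,bed_path Output paths; either may be `NULL` to skip.
#' @return `assignments`, invisibly.
#' @export
write_assignments <- function(assignments, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    readr::write_tsv(
      select(assignments, "probe_id", "repeat_name", "repeat_class",
             "repeat_family", "overlap_bp", "context"),
      tsv_path
    )
  }
  if (!is.null(bed_path)) {
    write_bed_intervals(
      tibble(chrom = assignments$chrom, start = assignments$start,
             end = assignments$end, name = assignments$probe_id,
             score = assignments$overlap_bp, strand = assignments$strand),
      bed_path
    )
  }
  invisible(assignments)
}
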