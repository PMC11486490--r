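#' @importFrom rlang .data %||%
#' @importFrom dplyr mutate select filter arrange group_by ungroup summarise
#'   left_join inner_join bind_rows rename n across all_of any_of
#' @importFrom tibble tibble as_tibble
NULL

# All genomic intervals are held 0-based half-open internally. Formats that
# are 1-based inclusive on disk (RepeatMasker .out, GTF) are shifted on read;
# BED passes through unchanged.

#' Read a RepeatMasker annotation
#'
#' Parses repeat intervals from either the native RepeatMasker `.out` format
#' (three header lines, whitespace-separated columns, 1-based inclusive
#' coordinates) or a BED6 file whose name field carries the repeat taxonomy as
#' `repeat_name#class/family` (the convention of common RepeatMasker-to-BED
#' converters). The `class/family` string is split on the first `/`; when no
#' family is given the class name doubles as the family (so `Satellite/centr`
#' yields class `Satellite`, family `centr`, while a bare `Satellite` yields
#' family `Satellite`).
#'
#' @param path Path to the annotation file.
#' @param format `"rmsk_out"` or `"bed"`.
#'
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `repeat_name`, `repeat_class`, `repeat_family`.
#' @export
read_repeatmasker <- function(path, format = c("rmsk_out", "bed")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown repeat annotation format: ",
                                              format[1], call. = FALSE))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "rmsk_out") parse_rmsk_out(path) else parse_repeat_bed(path)
}

parse_rmsk_out <- function(path) {
  lines <- readLines(path)
  # native .out files open with two header lines plus one blank line
  body <- lines[-seq_len(min(3L, length(lines)))]
  keep <- which(nzchar(trimws(body)))
  if (length(keep) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), repeat_name = character(),
                  repeat_class = character(), repeat_family = character()))
  }
  fields <- strsplit(trimws(body[keep]), "\\s+")
  bad <- which(lengths(fields) < 11L)
  if (length(bad)) {
    stop("malformed RepeatMasker line ", keep[bad[1]] + 3L, " in ", path,
         ": fewer than 11 fields", call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:11))
  start1 <- suppressWarnings(as.integer(m[, 6]))
  end1   <- suppressWarnings(as.integer(m[, 7]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- which(is.na(start1) | is.na(end1))[1]
    stop("malformed RepeatMasker line ", keep[bad] + 3L, " in ", path,
         ": non-numeric coordinates", call. = FALSE)
  }
  cf <- split_class_family(m[, 11])
  out <- tibble(
    chrom  = m[, 5],
    start  = start1 - 1L,  # 1-based inclusive -> 0-based half-open
    end    = end1,
    strand = ifelse(m[, 9] == "C", "-", m[, 9]),
    repeat_name   = m[, 10],
    repeat_class  = cf$class,
    repeat_family = cf$family
  )
  validate_intervals(out, path)
  out
}

parse_repeat_bed <- function(path) {
  bed <- read_bed_intervals(path)
  if (!"name" %in% names(bed)) stop("repeat BED lacks a name field: ", path, call. = FALSE)
  parts <- stringr::str_split_fixed(bed$name, stringr::fixed("#"), 2)
  cf <- split_class_family(parts[, 2])
  out <- tibble(
    chrom = bed$chrom, start = bed$start, end = bed$end,
    strand = if ("strand" %in% names(bed)) bed$strand else "*",
    repeat_name = parts[, 1], repeat_class = cf$class, repeat_family = cf$family
  )
  validate_intervals(out, path)
  out
}

split_class_family <- function(x) {
  cls <- sub("/.*$", "", x)
  fam <- ifelse(grepl("/", x), sub("^[^/]*/", "", x), cls)
  list(class = cls, family = fam)
}

validate_intervals <- function(df, what = "input") {
  bad <- which(df$end <= df$start | df$start < 0 | !nzchar(df$chrom))
  if (length(bad)) {
    stop("invalid interval in ", what, " (record ", bad[1], "): start=",
         df$start[bad[1]], " end=", df$end[bad[1]], call. = FALSE)
  }
  invisible(df)
}

#' Read a BED file of intervals
#'
#' Headerless BED with at least `chrom`, `start`, `end`; name, score and
#' strand are kept when present. BED is already 0-based half-open, so
#' coordinates pass through unchanged.
#'
#' @param path Path to a BED file.
#' @return A tibble with `chrom`, `start`, `end` and any of `name`, `score`,
#'   `strand` present in the file.
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  lines <- readLines(path)
  # drop track/browser/comment lines; '#' inside fields (e.g. repeat name
  # tags) must survive, so filter whole lines rather than using comment.char
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          comment.char = "", quote = "",
                          stringsAsFactors = FALSE)
  names(df) <- cols[seq_len(min(ncol(df), 6L))]
  df <- as_tibble(df[, seq_len(min(ncol(df), 6L))])
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  validate_intervals(df, path)
  df
}

#' Write intervals to BED
#'
#' @param df Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_intervals <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  col_or <- function(nm, default) {
    if (nm %in% names(df)) df[[nm]] else default
  }
  out <- tibble(
    chrom = df$chrom, start = df$start, end = df$end,
    name = col_or("name", "."),
    score = col_or("score", 0L),
    strand = col_or("strand", "*")
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Imports `gene` and `exon` features. When a GTF carries no explicit `gene`
#' features, gene bodies are reconstructed as the span of each gene's exons.
#' Coordinates are converted from GTF's 1-based inclusive convention to
#' 0-based half-open.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `gene_id`, `feature` (`"gene"` or `"exon"`),
#'   `chrom`, `start`, `end`, `strand`. Every gene has at least one exon row.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!"gene_id" %in% names(df)) stop("GTF lacks gene_id attributes: ", path, call. = FALSE)
  df <- df |>
    filter(.data$type %in% c("gene", "exon")) |>
    mutate(
      chrom = as.character(.data$seqnames),
      start = as.integer(.data$start) - 1L,   # GTF 1-based inclusive
      end = as.integer(.data$end),
      strand = as.character(.data$strand),
      feature = as.character(.data$type)
    ) |>
    select("gene_id", "feature", "chrom", "start", "end", "strand")
  exons <- filter(df, .data$feature == "exon")
  if (nrow(exons) == 0L) stop("GTF contains no exon features: ", path, call. = FALSE)
  genes <- filter(df, .data$feature == "gene")
  missing <- setdiff(exons$gene_id, genes$gene_id)
  if (length(missing)) {
    derived <- exons |>
      filter(.data$gene_id %in% missing) |>
      group_by(.data$gene_id, .data$chrom, .data$strand) |>
      summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
      mutate(feature = "gene") |>
      select("gene_id", "feature", "chrom", "start", "end", "strand")
    genes <- bind_rows(genes, derived)
  }
  bind_rows(genes, exons) |> arrange(.data$chrom, .data$start, .data$gene_id)
}

#' Read a probe manifest
#'
#' Tab-separated manifest with header `probe_id`, `chrom`, `start`, `end` and
#' optionally `strand`; coordinates are taken as 0-based half-open (BED-like).
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with `probe_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_probe_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("probe manifest must have columns ", paste(need, collapse = ", "),
         ": ", path, call. = FALSE)
  }
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe_id in manifest: ",
         df$probe_id[duplicated(df$probe_id)][1], call. = FALSE)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (!"strand" %in% names(df)) df$strand <- "*"
  validate_intervals(df, path)
  select(df, "probe_id", "chrom", "start", "end", "strand")
}

#' Read / write a feature-by-sample matrix as TSV
#'
#' Features in rows, samples in columns; the header row holds sample ids and
#' the first column (named `feature_id`) the feature ids.
#'
#' @param path Path to the TSV.
#' @return `read_sample_matrix()`: a tibble whose first column is
#'   `feature_id`, remaining columns numeric per-sample values.
#' @export
read_sample_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  names(df)[1] <- "feature_id"
  df[[1]] <- as.character(df[[1]])
  df
}

#' @param mat A sample-matrix tibble (see [read_sample_matrix()]).
#' @rdname read_sample_matrix
#' @export
write_sample_matrix <- function(mat, path) {
  readr::write_tsv(mat, path)
  invisible(path)
}

# Tibble sample matrix -> base matrix with feature_id rownames.
as_feature_matrix <- function(mat) {
  stopifnot(is.data.frame(mat), ncol(mat) >= 2L)
  m <- as.matrix(mat[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("sample matrix has non-numeric value columns", call. = FALSE)
  rownames(m) <- as.character(mat[[1]])
  m
}

as_sample_tibble <- function(m, feature_col = "feature_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(!!feature_col := rownames(m)), out)
  out
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set name, description, then member genes,
#'   tab-separated).
#' @return A tibble with columns `set_name` and `gene`, one row per set
#'   membership.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    lines <- strsplit(readLines(path), "\t")
    sets <- stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                            vapply(lines, `[`, "", 1))
  }
  sets <- lapply(sets, function(g) unique(g[nzchar(g)]))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set in ", path, ": ",
         names(sets)[lengths(sets) == 0L][1], call. = FALSE)
  }
  tibble(
    set_name = rep(names(sets), lengths(sets)),
    gene = unlist(sets, use.names = FALSE)
  )
}

#' Write gene sets to a GMT file
#'
#' @param sets A tibble with `set_name` and `gene` columns, or a named list of
#'   character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  sets <- as_gene_set_list(sets)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Accept either the long tibble (set_name, gene) or a named list of vectors.
as_gene_set_list <- function(sets) {
  if (is.data.frame(sets)) {
    stopifnot(all(c("set_name", "gene") %in% names(sets)))
    sets <- split(sets$gene, factor(sets$set_name, levels = unique(sets$set_name)))
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  lapply(sets, function(g) unique(as.character(g)))
}

#' Read a cell-by-feature count matrix
#'
#' Accepts either a MatrixMarket triplet (`.mtx` plus sidecar feature and
#' barcode TSVs, features in rows) or a dense TSV in [read_sample_matrix()]
#' layout with cells as columns.
#'
#' @param path Path to the `.mtx` or dense TSV.
#' @param features,barcodes Paths to one-column TSVs naming rows and columns;
#'   required for MTX input.
#' @return A tibble, first column `feature_id`, one numeric column per cell.
#' @export
read_cell_counts <- function(path, features = NULL, barcodes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.mtx$", path)) {
    if (is.null(features) || is.null(barcodes)) {
      stop("MTX input needs features and barcodes sidecar files", call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    rn <- readr::read_tsv(features, col_names = "feature_id", show_col_types = FALSE)
    cn <- readr::read_tsv(barcodes, col_names = "cell_id", show_col_types = FALSE)
    stopifnot(nrow(m) == nrow(rn), ncol(m) == nrow(cn))
    dimnames(m) <- list(rn$feature_id, cn$cell_id)
    as_sample_tibble(m)
  } else {
    read_sample_matrix(path)
  }
}

#' Read a cell annotation table
#'
#' @param path TSV with header `cell_id`, `sample_id`, `cell_type`.
#' @return A tibble with those three character columns; `cell_id` unique.
#' @export
read_cell_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("cell_id", "sample_id", "cell_type")
  if (!all(need %in% names(df))) {
    stop("cell annotation must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$cell_id)) {
    stop("cell annotated more than once: ",
         df$cell_id[duplicated(df$cell_id)][1], call. = FALSE)
  }
  select(df, all_of(need))
}
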