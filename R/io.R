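# Readers and writers for the plain-text formats the pipeline exchanges:
# BED (0-based half-open, kept native) for genes / frequent-CNV regions /
# probes, and tab-separated matrices for CGH log2 ratios and expression.
# All coordinates are 0-based half-open everywhere inside the package.

id_column <- function(kind) {
  switch(kind,
    gene  = "gene_id",
    cnv   = "source_id",
    probe = "probe_id",
    abort(sprintf("unknown interval kind '%s'", kind))
  )
}

#' Read genomic intervals from a BED file
#'
#' Reads a 3+ column BED file into a tibble, keeping the BED convention of
#' 0-based half-open coordinates. The fourth column, when present, becomes the
#' identifier column named after `kind` (`gene_id`, `source_id` or
#' `probe_id`); records without a name get a positional identifier. A sixth
#' column is interpreted as strand for genes.
#'
#' @param path Path to a BED file (plain text, tab-separated).
#' @param kind One of `"gene"`, `"cnv"`, `"probe"`; decides the id column
#'   name and which extra columns are kept.
#' @return A tibble with columns `chrom`, `start`, `end`, the id column, and
#'   `strand` for genes, sorted by (`chrom`, `start`).
#' @export
read_intervals <- function(path, kind = c("gene", "cnv", "probe")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- tibble(
      chrom = character(), start = integer(), end = integer()
    )
    out[[id_column(kind)]] <- character()
    if (kind == "gene") out$strand <- character()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    bad <- which(n_fields < 3)[1]
    abort(sprintf("malformed BED line %d in %s: fewer than 3 fields", bad, path))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("malformed BED line %d in %s: non-numeric coordinates", bad, path))
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    abort(sprintf(
      "invalid interval at line %d in %s: start (%s) >= end (%s)",
      bad, path, format(start[bad], scientific = FALSE),
      format(end[bad], scientific = FALSE)
    ))
  }
  name <- vapply(seq_along(fields), function(i) {
    if (n_fields[i] >= 4) fields[[i]][4] else sprintf("%s_%d", kind, i)
  }, character(1))
  out <- tibble(chrom = chrom, start = start, end = end)
  out[[id_column(kind)]] <- name
  if (kind == "gene") {
    out$strand <- vapply(seq_along(fields), function(i) {
      if (n_fields[i] >= 6 && fields[[i]][6] %in% c("+", "-")) fields[[i]][6]
      else "unknown"
    }, character(1))
  }
  ids <- out[[id_column(kind)]]
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate %s '%s' in %s", id_column(kind), ids[duplicated(ids)][1], path
    ))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Write intervals to a BED file
#'
#' Counterpart of [read_intervals()]; emits tab-separated, UTF-8, 0-based
#' half-open records with the id in the fourth column (and strand in the
#' sixth for genes).
#'
#' @param x Interval tibble as produced by [read_intervals()] or the
#'   synthetic-cohort generator.
#' @param path Output file path.
#' @param kind One of `"gene"`, `"cnv"`, `"probe"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, kind = c("gene", "cnv", "probe")) {
  kind <- match.arg(kind)
  idc <- id_column(kind)
  stopifnot(all(c("chrom", "start", "end", idc) %in% names(x)))
  cols <- c("chrom", "start", "end", idc)
  body <- x[cols]
  if (kind == "gene") {
    body$score <- 0L
    body$strand <- if ("strand" %in% names(x)) {
      ifelse(x$strand %in% c("+", "-"), x$strand, ".")
    } else "."
  }
  lines <- do.call(paste, c(lapply(body, function(col) {
    if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE) else as.character(col)
  }), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

check_numeric_body <- function(mat_chr, row_ids, col_ids, path) {
  vals <- suppressWarnings(matrix(as.numeric(mat_chr), nrow = nrow(mat_chr)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-numeric value '%s' at row '%s', column '%s' in %s",
      mat_chr[idx[1], idx[2]], row_ids[idx[1]], col_ids[idx[2]], path
    ))
  }
  vals
}

#' Read a probe-by-tumor CGH log2-ratio matrix
#'
#' Expects a tab-separated file with a header; the body holds log2
#' (tumor / reference) fluorescence ratios. Probe coordinates are taken from
#' `probe_id`, `chrom`, `start`, `end` columns when present, otherwise from a
#' separate probe BED supplied via `probes`. Remaining columns are tumors.
#'
#' @param path Path to the TSV file.
#' @param probes Optional probe tibble from [read_intervals()] used when the
#'   matrix file carries only probe ids.
#' @return A long tibble with columns `probe_id`, `chrom`, `start`, `end`,
#'   `tumor_id`, `log2ratio`.
#' @export
read_cgh_matrix <- function(path, probes = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"probe_id" %in% names(raw)) abort(sprintf("no 'probe_id' column in %s", path))
  if (anyDuplicated(raw$probe_id)) {
    abort(sprintf(
      "duplicate probe_id '%s' in %s", raw$probe_id[duplicated(raw$probe_id)][1], path
    ))
  }
  coord_cols <- c("chrom", "start", "end")
  has_coords <- all(coord_cols %in% names(raw))
  if (!has_coords) {
    if (is.null(probes)) {
      abort(sprintf("%s lacks coordinate columns; supply `probes`", path))
    }
    coords <- probes[c("probe_id", coord_cols)]
  } else {
    coords <- tibble(
      probe_id = raw$probe_id,
      chrom = raw$chrom,
      start = as.numeric(raw$start),
      end = as.numeric(raw$end)
    )
  }
  tumor_cols <- setdiff(names(raw), c("probe_id", coord_cols))
  if (length(tumor_cols) == 0) abort(sprintf("no tumor columns in %s", path))
  body <- as.matrix(raw[tumor_cols])
  vals <- check_numeric_body(body, raw$probe_id, tumor_cols, path)
  if (any(!is.finite(vals))) abort(sprintf("non-finite log2 ratio in %s", path))
  out <- tibble(
    probe_id = rep(raw$probe_id, times = length(tumor_cols)),
    tumor_id = rep(tumor_cols, each = nrow(raw)),
    log2ratio = as.vector(vals)
  )
  out <- inner_join(coords, out, by = "probe_id")
  arrange(out, .data$chrom, .data$start, .data$tumor_id)
}

#' Write a CGH matrix to TSV
#'
#' Emits the wide probe-by-tumor layout read back by [read_cgh_matrix()]:
#' `probe_id`, `chrom`, `start`, `end`, then one column per tumor, with '.'
#' as the decimal separator.
#'
#' @param cgh Long CGH tibble (see [read_cgh_matrix()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cgh_matrix <- function(cgh, path) {
  wide <- pivot_wider(
    cgh, id_cols = c("probe_id", "chrom", "start", "end"),
    names_from = "tumor_id", values_from = "log2ratio"
  )
  wide <- arrange(wide, .data$chrom, .data$start)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a gene-by-tumor expression matrix with replicate hybridizations
#'
#' Expects a tab-separated file whose first column is `gene_id` and whose
#' remaining columns are tumors. Replicate hybridizations of the same tumor
#' follow the suffix convention `tumorID.rep1`, `tumorID.rep2`, ...; a column
#' without the suffix is a single replicate. Values must be positive
#' (natural-scale intensities).
#'
#' @param path Path to the TSV file.
#' @return A long tibble with columns `gene_id`, `tumor_id`, `replicate`
#'   (integer) and `value`. Collapse to per-tumor means with [expr_means()].
#' @export
read_expr_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"gene_id" %in% names(raw)) abort(sprintf("no 'gene_id' column in %s", path))
  if (anyDuplicated(raw$gene_id)) {
    abort(sprintf(
      "duplicate gene_id '%s' in %s", raw$gene_id[duplicated(raw$gene_id)][1], path
    ))
  }
  sample_cols <- setdiff(names(raw), "gene_id")
  if (length(sample_cols) == 0) abort(sprintf("no tumor columns in %s", path))
  vals <- check_numeric_body(as.matrix(raw[sample_cols]), raw$gene_id, sample_cols, path)
  if (any(vals <= 0)) abort(sprintf("non-positive expression value in %s", path))
  rep_match <- stringr::str_match(sample_cols, "^(.*)\\.rep(\\d+)$")
  tumor <- ifelse(is.na(rep_match[, 2]), sample_cols, rep_match[, 2])
  repl <- ifelse(is.na(rep_match[, 3]), 1L, as.integer(rep_match[, 3]))
  tibble(
    gene_id = rep(raw$gene_id, times = length(sample_cols)),
    tumor_id = rep(tumor, each = nrow(raw)),
    replicate = rep(repl, each = nrow(raw)),
    value = as.vector(vals)
  ) |>
    arrange(.data$gene_id, .data$tumor_id, .data$replicate)
}

#' Average replicate hybridizations per gene and tumor
#'
#' @param expr Long replicate-level expression tibble from
#'   [read_expr_matrix()] or [simulate_expression()]. A tibble that already
#'   has an `expr` column is returned unchanged.
#' @return Tibble with columns `gene_id`, `tumor_id`, `expr` (arithmetic mean
#'   of the replicates, natural scale).
#' @export
expr_means <- function(expr) {
  if ("expr" %in% names(expr) && !"value" %in% names(expr)) {
    return(expr)
  }
  expr |>
    group_by(.data$gene_id, .data$tumor_id) |>
    summarise(expr = mean(.data$value), .groups = "drop")
}

#' Write an expression matrix to TSV
#'
#' Emits the wide layout read back by [read_expr_matrix()], with replicate
#' columns named `tumorID.repN`.
#'
#' @param expr Long replicate-level expression tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expr_matrix <- function(expr, path) {
  wide <- expr |>
    mutate(column = sprintf("%s.rep%d", .data$tumor_id, .data$replicate)) |>
    pivot_wider(id_cols = "gene_id", names_from = "column", values_from = "value") |>
    arrange(.data$gene_id)
  readr::write_tsv(wide, path)
  invisible(path)
}

# gap between two 0-based half-open intervals; 0 when they overlap or touch
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start1, start2) - pmin(end1, end2))
}
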