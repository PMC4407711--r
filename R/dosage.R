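# Transcriptomic translation of genomic imbalances: normalization of
# expression against non-carrier tumors, per-chromosome window summaries,
# inside/outside region comparisons, and attenuation estimation.

#' Normalize expression inside a region against non-carrier tumors
#'
#' For every gene fully contained in `region` and every tumor, divides the
#' tumor's (replicate-averaged, natural-scale) expression by the mean
#' expression of the tumors that do not carry the alteration. Ratios above /
#' below 1 in carriers indicate that the genomic gain / loss translates to
#' transcription.
#'
#' @param expr Expression tibble (replicate-level or means; see
#'   [expr_means()]).
#' @param genes Gene tibble.
#' @param region List or one-row data frame with `chrom`, `start`, `end`.
#' @param carrier_tumors Tumors carrying the alteration.
#' @param all_tumors Cohort tumor ids; defaults to the tumors in `expr`.
#' @return Tibble `gene_id`, `tumor_id`, `ratio`, `log2_ratio`,
#'   `n_reference_tumors`, `is_carrier`.
#' @export
normalize_to_noncarriers <- function(expr, genes, region, carrier_tumors,
                                     all_tumors = NULL) {
  em <- expr_means(expr)
  if (is.null(all_tumors)) all_tumors <- sort(unique(em$tumor_id))
  ref_tumors <- setdiff(all_tumors, carrier_tumors)
  if (length(ref_tumors) == 0) {
    abort("degenerate cohort: no non-carrier tumors to normalize against")
  }
  inside <- genes$chrom == region$chrom &
    genes$start >= region$start & genes$end <= region$end
  g <- genes$gene_id[inside]
  em <- em[em$gene_id %in% g & em$tumor_id %in% all_tumors, ]
  ref <- em |>
    filter(.data$tumor_id %in% ref_tumors) |>
    group_by(.data$gene_id) |>
    summarise(ref_mean = mean(.data$expr), .groups = "drop")
  if (any(ref$ref_mean <= 0)) abort("reference mean must be positive")
  em |>
    inner_join(ref, by = "gene_id") |>
    mutate(
      ratio = .data$expr / .data$ref_mean,
      log2_ratio = log2(.data$ratio),
      n_reference_tumors = length(ref_tumors),
      is_carrier = .data$tumor_id %in% carrier_tumors
    ) |>
    select("gene_id", "tumor_id", "ratio", "log2_ratio",
           "n_reference_tumors", "is_carrier") |>
    arrange(.data$gene_id, .data$tumor_id)
}

#' Per-chromosome window summary of normalized expression
#'
#' Splits a chromosome into `n_windows` equal-bp windows and averages the
#' normalized ratios of the genes whose midpoint falls in each window (the
#' classic 30-windows-per-chromosome display track). Empty windows are kept
#' with `mean_ratio = NA`.
#'
#' @param normalized Output of [normalize_to_noncarriers()] (any tibble with
#'   `gene_id` and `ratio`); typically filtered to one tumor first.
#' @param genes Gene tibble (for midpoints).
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param n_windows Number of equal-size windows (default 30).
#' @return Tibble `chrom`, `win_start`, `win_end`, `mean_ratio`, `n_genes`.
#' @export
chromosome_window_summary <- function(normalized, genes, chrom, chrom_length,
                                      n_windows = 30) {
  stopifnot(n_windows >= 1, chrom_length > 0)
  g <- genes[genes$chrom == chrom, c("gene_id", "start", "end")]
  dat <- inner_join(normalized, g, by = "gene_id") |>
    mutate(mid = (.data$start + .data$end) / 2)
  bounds <- seq(0, chrom_length, length.out = n_windows + 1)
  idx <- pmin(findInterval(dat$mid, bounds), n_windows)
  agg_m <- tapply(dat$ratio, factor(idx, levels = seq_len(n_windows)), mean)
  agg_n <- tapply(dat$ratio, factor(idx, levels = seq_len(n_windows)), length)
  tibble(
    chrom = chrom,
    win_start = bounds[-(n_windows + 1)],
    win_end = bounds[-1],
    mean_ratio = as.numeric(agg_m),
    n_genes = ifelse(is.na(agg_n), 0L, as.integer(agg_n))
  )
}

#' Compare mean expression inside vs outside an altered region
#'
#' Tests whether normalized expression of genes inside an altered segment
#' differs from genes outside on the same chromosome, with both a two-sided
#' Welch t-test and a two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param values_inside,values_outside Numeric vectors (each length >= 2).
#' @return One-row tibble `n_inside`, `n_outside`, `mean_inside`,
#'   `mean_outside`, `t_p`, `mw_p`.
#' @export
compare_region_means <- function(values_inside, values_outside) {
  if (length(values_inside) < 2 || length(values_outside) < 2) {
    abort("each group needs at least 2 values")
  }
  tt <- t.test(values_inside, values_outside)       # Welch by default
  mw <- suppressWarnings(wilcox.test(values_inside, values_outside))
  tibble(
    n_inside = length(values_inside), n_outside = length(values_outside),
    mean_inside = mean(values_inside), mean_outside = mean(values_outside),
    t_p = tt$p.value, mw_p = mw$p.value
  )
}

#' Estimate dosage attenuation from paired DNA / expression ratios
#'
#' Under an attenuated dosage response, the expression ratio of an altered
#' region is `e = 1 + alpha * (c - 1)` for DNA ratio `c`, so
#' `alpha = (e - 1) / (c - 1)`. A DNA ratio of 1.35 paired with an
#' expression ratio of 1.21 gives alpha of about 0.6.
#'
#' @param c_ratio Mean DNA ratio of the region, natural scale (not 1).
#' @param e_ratio Mean normalized expression ratio of the region.
#' @return The attenuation point estimate.
#' @export
estimate_attenuation <- function(c_ratio, e_ratio) {
  if (any(abs(c_ratio - 1) < .Machine$double.eps^0.5)) {
    abort("attenuation undefined: DNA ratio equals 1")
  }
  (e_ratio - 1) / (c_ratio - 1)
}

#' Region-level attenuation estimate from cohort matrices
#'
#' Convenience composition: averages carrier-tumor CGH ratios (natural scale)
#' over probes in the region, averages carrier normalized expression ratios
#' over genes fully inside the region, and applies [estimate_attenuation()].
#'
#' @param cgh Long CGH tibble.
#' @param expr Expression tibble.
#' @param genes Gene tibble.
#' @param region List with `chrom`, `start`, `end`.
#' @param carrier_tumors Carrier tumor ids.
#' @return One-row tibble `c_ratio`, `e_ratio`, `attenuation`.
#' @export
region_attenuation <- function(cgh, expr, genes, region, carrier_tumors) {
  inside <- cgh$chrom == region$chrom & cgh$start >= region$start &
    cgh$start < region$end & cgh$tumor_id %in% carrier_tumors
  if (!any(inside)) abort("no probes in region for carrier tumors")
  c_ratio <- mean(2^cgh$log2ratio[inside])
  norm <- normalize_to_noncarriers(expr, genes, region, carrier_tumors)
  e_ratio <- mean(norm$ratio[norm$is_carrier])
  tibble(c_ratio = c_ratio, e_ratio = e_ratio,
         attenuation = estimate_attenuation(c_ratio, e_ratio))
}
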