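# The candidate-driver screen: recurrently altered probes mapped to genes,
# a Pearson correlation filter with a sample-size-adjusted significance
# threshold, frequent-CNV and full-inclusion filters, and recurrent
# broken-gene detection from intragenic copy-number breakpoints.

#' Significance threshold for a Pearson correlation coefficient
#'
#' Inverts the t transform `t = R * sqrt((n - 2) / (1 - R^2))` (Student-t
#' with `n - 2` df under the null of zero correlation): the smallest |R|
#' significant at two-sided level `alpha` is
#' `t_crit / sqrt(t_crit^2 + n - 2)`. For 10, 9, 8 and 7 samples at
#' `alpha = 0.05` this gives 0.63, 0.67, 0.71 and 0.75.
#'
#' @param n Sample size (>= 3).
#' @param alpha Two-sided significance level.
#' @return The critical |R|; strictly decreasing in `n`.
#' @export
r_significance_threshold <- function(n, alpha = 0.05) {
  if (any(n < 3)) abort("need n >= 3 for a correlation threshold")
  t_crit <- qt(1 - alpha / 2, df = n - 2)
  t_crit / sqrt(t_crit^2 + n - 2)
}

#' Map recurrently altered probes to nearby genes
#'
#' A probe supports a gene when the gap between the probe interval and the
#' gene interval is at most `max_gap` bp (0 when they overlap). With 13-kb
#' probe spacing a 25-kb margin guarantees every gene has a chance of
#' support.
#'
#' @param probes Probe tibble; typically the output of
#'   [recurrent_altered_probes()] (its `direction`, `n_tumors`, `tumors`
#'   columns are carried through when present).
#' @param genes Gene tibble.
#' @param max_gap Maximum probe-to-gene gap in bp.
#' @return Tibble with one row per (gene, supporting probe): `gene_id`,
#'   `probe_id`, `gap`, plus any probe metadata columns.
#' @export
map_probes_to_genes <- function(probes, genes, max_gap = 25000) {
  extra <- setdiff(names(probes), c("chrom", "start", "end", "probe_id"))
  map(unique(genes$chrom), function(ch) {
    g <- genes[genes$chrom == ch, ]
    p <- probes[probes$chrom == ch, ]
    if (nrow(g) == 0 || nrow(p) == 0) return(NULL)
    # window join on a gap-widened gene interval, then exact gap filter
    pairs <- inner_join(
      mutate(g, lo = .data$start - max_gap, hi = .data$end + max_gap) |>
        select("gene_id", gene_start = "start", gene_end = "end", "lo", "hi"),
      rename(p, probe_start = "start", probe_end = "end") |> select(-"chrom"),
      by = join_by(lo <= probe_end, hi >= probe_start)
    )
    pairs |>
      mutate(gap = interval_gap(.data$gene_start, .data$gene_end,
                                .data$probe_start, .data$probe_end)) |>
      filter(.data$gap <= max_gap) |>
      select("gene_id", "probe_id", "gap", all_of(extra))
  }) |> list_rbind()
}

#' Per-tumor gene-level CGH value
#'
#' Aggregates a gene's supporting probes into one CGH value per tumor: the
#' unweighted mean of the supporting probes' log2 ratios.
#'
#' @param cgh Long CGH tibble.
#' @param probe_ids Supporting probe ids (>= 1).
#' @return Tibble `tumor_id`, `cgh_value`.
#' @export
gene_cgh_summary <- function(cgh, probe_ids) {
  if (length(probe_ids) == 0) abort("no supporting probes")
  sub <- cgh[cgh$probe_id %in% probe_ids, ]
  if (nrow(sub) == 0) abort("supporting probes not found in CGH matrix")
  sub |>
    group_by(.data$tumor_id) |>
    summarise(cgh_value = mean(.data$log2ratio), .groups = "drop")
}

#' Correlation filter between gene-level CGH and expression
#'
#' Pearson correlation over the retained tumors (the cohort minus tumors
#' excluded for carrying an overlapping large-scale imbalance), compared to
#' the sample-size-adjusted threshold of [r_significance_threshold()].
#' Significance requires positive `R >= R_crit` for amplified and deleted
#' candidates alike: dosage and expression move together in both directions.
#'
#' @param gene_cgh,gene_expr Named numeric vectors (names = tumor ids) or
#'   tibbles with `tumor_id` and a value column.
#' @param excluded_tumors Tumors to drop before correlating.
#' @param alpha Two-sided level for the R threshold.
#' @return One-row tibble `R`, `n`, `t`, `R_crit`, `significant`,
#'   `n_excluded`.
#' @export
correlation_filter <- function(gene_cgh, gene_expr, excluded_tumors = character(),
                               alpha = 0.05) {
  as_named <- function(x, col) {
    if (is.data.frame(x)) setNames(x[[col]], x$tumor_id) else x
  }
  x <- as_named(gene_cgh, "cgh_value")
  y <- as_named(gene_expr, "expr")
  common <- setdiff(intersect(names(x), names(y)), excluded_tumors)
  n <- length(common)
  if (n < 3) abort(sprintf("insufficient samples after exclusion (n = %d)", n))
  xv <- x[common]; yv <- y[common]
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("undefined correlation: zero variance in CGH or expression values")
  }
  R <- cor(xv, yv)
  R_crit <- r_significance_threshold(n, alpha)
  tibble(
    R = R, n = n, t = R * sqrt((n - 2) / (1 - R^2)),
    R_crit = R_crit, significant = R >= R_crit,
    n_excluded = length(intersect(excluded_tumors, intersect(names(x), names(y))))
  )
}

#' Is a gene inside a frequent-CNV region?
#'
#' @param gene One-row tibble / list with `chrom`, `start`, `end`.
#' @param cnv_catalog CNV interval tibble.
#' @param rule `"containment"` (default: gene fully inside a catalog region)
#'   or `"overlap"` (any overlap excludes).
#' @return `TRUE` when the gene is excluded by the catalog.
#' @export
cnv_exclusion <- function(gene, cnv_catalog, rule = c("containment", "overlap")) {
  rule <- match.arg(rule)
  on_chr <- cnv_catalog[cnv_catalog$chrom == gene$chrom, ]
  if (nrow(on_chr) == 0) return(FALSE)
  if (rule == "containment") {
    any(gene$start >= on_chr$start & gene$end <= on_chr$end)
  } else {
    any(gene$start < on_chr$end & gene$end > on_chr$start)
  }
}

#' Is a gene fully included in an imbalance call?
#'
#' Checks, per tumor, whether the gene interval lies fully within a single
#' call of the requested direction ("fully amplified or deleted").
#'
#' @param gene One-row tibble / list with `chrom`, `start`, `end`.
#' @param calls Imbalance-call tibble from [call_large_scale()].
#' @param direction `"gain"` or `"loss"`.
#' @return Named logical vector over the tumors present in `calls`.
#' @export
full_inclusion_check <- function(gene, calls, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  tumors <- unique(calls$tumor_id)
  hit <- calls$chrom == gene$chrom & calls$direction == direction &
    calls$start <= gene$start & calls$end >= gene$end
  setNames(tumors %in% calls$tumor_id[hit], tumors)
}

#' Screen for amplified / deleted candidate driver genes
#'
#' The complete screen: (1) probes altered beyond the cell-fraction
#' thresholds in at least `min_tumors` tumors; (2) probes mapped to genes
#' within `max_gap`; (3) per gene, Pearson correlation between the mean
#' supporting-probe CGH value and expression over the tumors, excluding
#' tumors whose large-scale imbalances (whole-chromosome or segment calls)
#' overlap the gene, against the sample-size-adjusted R threshold; (4)
#' frequent-CNV exclusion (containment); (5) full inclusion of the gene in a
#' same-direction call in at least one altered tumor. Tumors excluded from
#' the correlation (large-scale carriers) do not count towards the recurrence
#' requirement either: a candidate must be altered at small scale in at least
#' `min_tumors` tumors. All candidates are returned with their filter flags
#' so pre- and post-filter lists are both inspectable.
#'
#' @param cgh Long CGH tibble.
#' @param expr Expression tibble.
#' @param genes Gene tibble.
#' @param cnv_catalog Frequent-CNV interval tibble.
#' @param large_scale_calls Optional precomputed [call_large_scale()] output;
#'   computed from `cgh` when `NULL`.
#' @param thresholds A [threshold_pair()].
#' @param min_tumors Recurrence requirement on altered probes.
#' @param max_gap Probe-to-gene mapping margin in bp.
#' @param alpha Two-sided level for the correlation threshold.
#' @return An object of class `driver_screen`: a list with `candidates` (one
#'   row per gene x direction, with `passed` and all flags) and `params`.
#'   Use [tidy()] / [glance()] to extract tables.
#' @export
identify_drivers <- function(cgh, expr, genes, cnv_catalog,
                             large_scale_calls = NULL,
                             thresholds = threshold_pair(), min_tumors = 2,
                             max_gap = 25000, alpha = 0.05) {
  params <- list(
    amp_threshold = thresholds$amp_threshold,
    del_threshold = thresholds$del_threshold,
    min_tumors = min_tumors, max_gap = max_gap, alpha = alpha
  )
  empty <- tibble(
    gene_id = character(), status = character(), n_tumors_altered = integer(),
    n_tumors_small_scale = integer(),
    tumors_altered = list(), n_probes = integer(), n_excluded_large_scale = integer(),
    R = numeric(), n = integer(), t = numeric(), R_crit = numeric(),
    significant = logical(), fully_included = logical(),
    cnv_overlap = logical(), passed = logical()
  )
  if (nrow(cgh) == 0) {
    return(new_driver_screen(empty, params))
  }
  em <- expr_means(expr)
  if (is.null(large_scale_calls)) {
    large_scale_calls <- call_large_scale(cgh, thresholds = thresholds)
  }
  ls_calls <- large_scale_calls[
    large_scale_calls$scale %in% c("whole_chromosome", "segment"), , drop = FALSE
  ]
  rec <- recurrent_altered_probes(cgh, thresholds, min_tumors)
  if (nrow(rec) == 0) return(new_driver_screen(empty, params))
  hits <- map_probes_to_genes(rec, genes, max_gap)
  if (is.null(hits) || nrow(hits) == 0) return(new_driver_screen(empty, params))

  gene_dir <- hits |>
    group_by(.data$gene_id, .data$direction) |>
    summarise(
      probe_ids = list(.data$probe_id),
      tumors_altered = list(sort(unique(unlist(.data$tumors)))),
      .groups = "drop"
    )
  rows <- map(seq_len(nrow(gene_dir)), function(i) {
    gid <- gene_dir$gene_id[i]
    dir <- gene_dir$direction[i]
    gene <- genes[genes$gene_id == gid, ]
    tum_alt <- gene_dir$tumors_altered[[i]]
    # tumors carrying an overlapping large-scale imbalance are excluded from
    # the correlation (their dosage signal is chromosome-wide, not focal)
    overl <- ls_calls$chrom == gene$chrom &
      ls_calls$start < gene$end & ls_calls$end > gene$start
    excluded <- unique(ls_calls$tumor_id[overl])
    gcgh <- gene_cgh_summary(cgh, gene_dir$probe_ids[[i]])
    gexp <- em[em$gene_id == gid, ]
    ct <- tryCatch(
      correlation_filter(gcgh, gexp, excluded, alpha),
      error = function(e) tibble(
        R = NA_real_, n = NA_integer_, t = NA_real_, R_crit = NA_real_,
        significant = FALSE, n_excluded = length(excluded)
      )
    )
    direction <- if (dir == "gain") "gain" else "loss"
    incl <- full_inclusion_check(gene, large_scale_calls, direction)
    # recurrence must come from small-scale alterations: tumors whose
    # large-scale imbalance covers the gene do not count towards it
    tum_small <- setdiff(tum_alt, excluded)
    fully_included <- any(incl[names(incl) %in% tum_small])
    cnv_overlap <- cnv_exclusion(gene, cnv_catalog)
    tibble(
      gene_id = gid,
      status = if (dir == "gain") "amplified" else "deleted",
      n_tumors_altered = length(tum_alt),
      n_tumors_small_scale = length(tum_small),
      tumors_altered = list(tum_alt),
      n_probes = length(gene_dir$probe_ids[[i]]),
      n_excluded_large_scale = ct$n_excluded,
      R = ct$R, n = ct$n, t = ct$t, R_crit = ct$R_crit,
      significant = isTRUE(ct$significant),
      fully_included = fully_included,
      cnv_overlap = cnv_overlap,
      passed = isTRUE(ct$significant) && fully_included && !cnv_overlap &&
        length(tum_small) >= min_tumors
    )
  }) |> list_rbind()
  new_driver_screen(arrange(rows, .data$status, .data$gene_id), params)
}

new_driver_screen <- function(candidates, params) {
  structure(list(candidates = candidates, params = params),
            class = "driver_screen")
}

#' @export
print.driver_screen <- function(x, ...) {
  cat(sprintf(
    "driver screen: %d candidate gene/direction pairs, %d passed all filters\n",
    nrow(x$candidates), sum(x$candidates$passed)
  ))
  print(x$candidates, ...)
  invisible(x)
}

#' @rdname identify_drivers
#' @param x A `driver_screen` object.
#' @param ... Unused.
#' @method tidy driver_screen
#' @export
tidy.driver_screen <- function(x, ...) x$candidates

#' @rdname identify_drivers
#' @method glance driver_screen
#' @export
glance.driver_screen <- function(x, ...) {
  cc <- x$candidates
  tibble(
    n_candidates = nrow(cc),
    n_significant = sum(cc$significant, na.rm = TRUE),
    n_passed = sum(cc$passed),
    n_amplified_passed = sum(cc$passed & cc$status == "amplified"),
    n_deleted_passed = sum(cc$passed & cc$status == "deleted")
  )
}

#' Detect recurrently broken genes
#'
#' A gene is broken in a tumor when an intragenic copy-number breakpoint
#' separates an altered flank from an unaltered one (or flanks altered in
#' opposite directions). For every inter-probe gap the mean log2 ratio of up
#' to `flank_probes` probes on each side is classified (gain / neutral /
#' loss) against `flank_frac` times the calling thresholds; a discordant pair
#' of flank states records a breakpoint at the gap midpoint, assigned to the
#' genes overlapping the gap. Flank averaging makes the breakpoint state
#' robust to per-probe noise. A gene passes when distinct tumors contribute
#' at least `min_tumors` breakpoints and no breakpoint lies within
#' `cnv_margin` of a frequent-CNV region.
#'
#' @param cgh Long CGH tibble.
#' @param genes Gene tibble.
#' @param cnv_catalog Frequent-CNV interval tibble.
#' @param thresholds A [threshold_pair()].
#' @param min_tumors Recurrence requirement (2 = the recurrence rule).
#' @param flank_probes Probes averaged on each side of a gap.
#' @param flank_frac Fraction of the thresholds used as the flank state cut.
#' @param cnv_margin Breakpoint-to-CNV distance treated as "near" (bp).
#' @return List with `genes` (tibble `gene_id`, `n_tumors_broken`,
#'   `cnv_proximal`, `passed`) and `breakpoints` (tibble `gene_id`,
#'   `tumor_id`, `breakpoint`, `left_state`, `right_state`).
#' @export
detect_broken_genes <- function(cgh, genes, cnv_catalog,
                                thresholds = threshold_pair(), min_tumors = 2,
                                flank_probes = 6, flank_frac = 0.8,
                                cnv_margin = 25000) {
  amp_cut <- flank_frac * thresholds$amp_threshold
  del_cut <- flank_frac * thresholds$del_threshold
  bps <- list()
  for (tu in unique(cgh$tumor_id)) {
    prof <- cgh_one_tumor(cgh, tu)
    for (ch in unique(prof$chrom)) {
      p <- prof[prof$chrom == ch, ]
      np <- nrow(p)
      if (np < 2) next
      # rolling flank means: left of gap i = probes max(1,i-k+1)..i,
      # right of gap i = probes i+1..min(np, i+k)
      cs <- cumsum(p$log2ratio)
      k <- flank_probes
      i <- seq_len(np - 1)
      l_from <- pmax(1, i - k + 1)
      left_mean <- (cs[i] - c(0, cs)[l_from]) / (i - l_from + 1)
      r_to <- pmin(np, i + k)
      right_mean <- (cs[r_to] - cs[i]) / (r_to - i)
      state <- function(m) ifelse(m >= amp_cut, 1L, ifelse(m <= del_cut, -1L, 0L))
      ls <- state(left_mean); rs <- state(right_mean)
      # only gaps with full k-probe flanks: truncated flanks near chromosome
      # ends are too noisy to classify
      full <- (i - l_from + 1) == k & (r_to - i) == k
      disc <- which(ls != rs & full)
      if (length(disc) == 0) next
      gap_start <- p$end[disc]
      gap_end <- p$start[disc + 1]
      bp_pos <- (gap_start + gap_end) / 2
      g <- genes[genes$chrom == ch, ]
      for (j in seq_along(disc)) {
        hit <- g$start < gap_end[j] & g$end > gap_start[j]
        if (!any(hit)) next
        bps[[length(bps) + 1]] <- tibble(
          gene_id = g$gene_id[hit], tumor_id = tu, chrom = ch,
          breakpoint = bp_pos[j],
          left_state = ls[disc[j]], right_state = rs[disc[j]]
        )
      }
    }
  }
  breakpoints <- if (length(bps) > 0) list_rbind(bps) else tibble(
    gene_id = character(), tumor_id = character(), chrom = character(),
    breakpoint = numeric(), left_state = integer(), right_state = integer()
  )
  near_cnv <- function(chrom, pos) {
    on_chr <- cnv_catalog[cnv_catalog$chrom == chrom, ]
    nrow(on_chr) > 0 &&
      any(interval_gap(pos, pos + 1, on_chr$start, on_chr$end) <= cnv_margin)
  }
  gene_tbl <- breakpoints |>
    group_by(.data$gene_id, .data$chrom) |>
    summarise(
      n_tumors_broken = length(unique(.data$tumor_id)),
      cnv_proximal = any(map_lgl(.data$breakpoint, function(b)
        near_cnv(.data$chrom[1], b))),
      .groups = "drop"
    ) |>
    mutate(passed = .data$n_tumors_broken >= min_tumors & !.data$cnv_proximal) |>
    select("gene_id", "n_tumors_broken", "cnv_proximal", "passed") |>
    arrange(.data$gene_id)
  list(genes = gene_tbl, breakpoints = breakpoints)
}
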