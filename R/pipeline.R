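# Configuration and an end-to-end runner chaining simulate -> call ->
# normalize -> driver screen -> broken genes -> co-occurrence -> network,
# writing per-stage TSV outputs and a JSON run manifest.

#' Pipeline configuration
#'
#' Validates and bundles every tunable of the end-to-end run. Defaults follow
#' the study design this pipeline reimplements: thresholds calibrated to a
#' 50% cell fraction, 25-kb probe-to-gene mapping, recurrence in >= 2 tumors,
#' 130-kb CGH windows, 30 expression windows per chromosome, neighbor cutoff
#' 0.63 and display cutoff 0.90, alpha 0.05.
#'
#' @param cell_fraction Calibrating tumor-cell fraction for the thresholds.
#' @param alpha Two-sided level for correlation significance.
#' @param max_gap Probe-to-gene mapping margin (bp).
#' @param min_tumors Recurrence requirement.
#' @param window CGH sliding-window width (bp).
#' @param n_windows Expression windows per chromosome.
#' @param neighbor_cutoff Correlation cutoff defining transcriptomic
#'   neighbors.
#' @param display_cutoff Correlation cutoff of the display network.
#' @param seed Integer seed for the simulate stage.
#' @param simulate List of arguments forwarded to [simulate_cohort()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cell_fraction = 0.5, alpha = 0.05,
                            max_gap = 25000, min_tumors = 2,
                            window = 130000, n_windows = 30,
                            neighbor_cutoff = 0.63, display_cutoff = 0.90,
                            seed = 1, simulate = list()) {
  if (cell_fraction <= 0 || cell_fraction > 1) {
    abort("config invalid: cell_fraction must be in (0, 1]")
  }
  if (alpha <= 0 || alpha >= 1) abort("config invalid: alpha must be in (0, 1)")
  if (max_gap < 0) abort("config invalid: max_gap must be >= 0")
  if (min_tumors < 1) abort("config invalid: min_tumors must be >= 1")
  if (window <= 0) abort("config invalid: window must be > 0")
  if (n_windows < 1) abort("config invalid: n_windows must be >= 1")
  if (neighbor_cutoff <= 0 || neighbor_cutoff > 1 ||
      display_cutoff <= 0 || display_cutoff > 1) {
    abort("config invalid: correlation cutoffs must be in (0, 1]")
  }
  structure(
    list(cell_fraction = cell_fraction, alpha = alpha, max_gap = max_gap,
         min_tumors = min_tumors, window = window, n_windows = n_windows,
         neighbor_cutoff = neighbor_cutoff, display_cutoff = display_cutoff,
         seed = as.integer(seed), simulate = simulate),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full screen end to end on a synthetic cohort
#'
#' Chains the seven stages (simulate, call-cgh, normalize-expr, find-drivers,
#' find-broken, cooccur, network), writes each stage's output as TSV under
#' `outdir`, and records a JSON manifest (parameters, seed, per-stage record
#' counts). Rerunning with the same config reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   parameters = config[setdiff(names(config), "simulate")],
                   stages = list())
  note <- function(stage, records, files) {
    manifest$stages[[stage]] <<- list(records = records, files = files)
    stage_log(stage, sprintf("%d records", records))
  }

  co <- do.call(simulate_cohort, c(config$simulate, list(seed = config$seed)))
  write_intervals(co$genes, file.path(outdir, "genes.bed"), "gene")
  write_intervals(co$probes, file.path(outdir, "probes.bed"), "probe")
  write_intervals(co$cnv, file.path(outdir, "cnv.bed"), "cnv")
  write_cgh_matrix(co$cgh, file.path(outdir, "cgh.tsv"))
  write_expr_matrix(co$expr, file.path(outdir, "expr.tsv"))
  write_truth(co$events, file.path(outdir, "truth.tsv"))
  note("simulate", nrow(co$events),
       c("genes.bed", "probes.bed", "cnv.bed", "cgh.tsv", "expr.tsv", "truth.tsv"))

  thr <- threshold_pair(config$cell_fraction)
  calls <- call_large_scale(co$cgh, thresholds = thr, window = config$window)
  readr::write_tsv(calls, file.path(outdir, "calls.tsv"))
  note("call-cgh", nrow(calls), "calls.tsv")

  ls_calls <- calls[calls$scale %in% c("whole_chromosome", "segment"), ]
  norm <- if (nrow(ls_calls) > 0) {
    map(seq_len(nrow(ls_calls)), function(i) {
      cl <- ls_calls[i, ]
      normalize_to_noncarriers(
        co$expr, co$genes,
        list(chrom = cl$chrom, start = cl$start, end = cl$end),
        carrier_tumors = cl$tumor_id, all_tumors = co$tumors
      ) |> mutate(region = sprintf("%s:%d-%d:%s", cl$chrom, cl$start, cl$end,
                                   cl$tumor_id))
    }) |> list_rbind()
  } else {
    tibble(gene_id = character(), tumor_id = character(), ratio = numeric(),
           log2_ratio = numeric(), n_reference_tumors = integer(),
           is_carrier = logical(), region = character())
  }
  readr::write_tsv(norm, file.path(outdir, "normalized_expr.tsv"))
  note("normalize-expr", nrow(norm), "normalized_expr.tsv")

  screen <- identify_drivers(
    co$cgh, co$expr, co$genes, co$cnv, large_scale_calls = calls,
    thresholds = thr, min_tumors = config$min_tumors,
    max_gap = config$max_gap, alpha = config$alpha
  )
  cand <- tidy(screen) |>
    mutate(tumors_altered = map_chr(.data$tumors_altered, paste, collapse = ","))
  readr::write_tsv(cand, file.path(outdir, "drivers.tsv"))
  note("find-drivers", nrow(cand), "drivers.tsv")

  broken <- detect_broken_genes(co$cgh, co$genes, co$cnv, thresholds = thr,
                                min_tumors = config$min_tumors)
  readr::write_tsv(broken$genes, file.path(outdir, "broken_genes.tsv"))
  note("find-broken", nrow(broken$genes), "broken_genes.tsv")

  presence <- alteration_presence(calls, co$tumors)
  cooc <- if (ncol(presence) >= 3) cooccurrence_scan(presence) else
    tibble(alt1 = character(), alt2 = character(), a = integer(),
           b = integer(), c = integer(), d = integer(),
           odds_ratio = numeric(), p = numeric())
  readr::write_tsv(cooc, file.path(outdir, "cooccurrence.tsv"))
  note("cooccur", nrow(cooc), "cooccurrence.tsv")

  seeds <- cand$gene_id[cand$passed]
  net_edges <- if (length(seeds) > 0) {
    sets <- map(seeds, function(g) neighbor_set(co$expr, g, config$neighbor_cutoff))
    build_sharing_network(sets, config$display_cutoff)$edges
  } else {
    tibble(driver = character(), neighbor = character(), R = numeric(),
           sign = character())
  }
  readr::write_tsv(net_edges, file.path(outdir, "network_edges.tsv"))
  note("network", nrow(net_edges), "network_edges.tsv")

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Compile a tumor-by-alteration presence table from imbalance calls
#'
#' Labels whole-chromosome and segment calls as `+chrom` / `-chrom` (e.g.
#' `+chr14`, `-chr22`) and marks which tumors carry each label.
#'
#' @param calls Imbalance calls from [call_large_scale()].
#' @param tumors Cohort tumor ids (rows of the table).
#' @return Data frame with `tumor_id` and one 0/1 column per label.
#' @export
alteration_presence <- function(calls, tumors) {
  ls <- calls[calls$scale %in% c("whole_chromosome", "segment"), ]
  out <- tibble(tumor_id = tumors)
  if (nrow(ls) == 0) return(out)
  ls$label <- paste0(ifelse(ls$direction == "gain", "+", "-"), ls$chrom)
  for (lb in unique(ls$label)) {
    out[[lb]] <- as.integer(tumors %in% ls$tumor_id[ls$label == lb])
  }
  out
}
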