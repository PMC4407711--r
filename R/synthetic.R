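# Seeded synthetic cohorts with planted ground truth: a toy genome with
# probes at a stated mean spacing, non-overlapping genes, a frequent-CNV
# catalog, and CGH + expression matrices in which whole-chromosome,
# segmental, focal and gene-breaking events are planted in known tumors at a
# known cell fraction.

EVENT_KINDS <- c(
  "whole_chromosome_gain", "whole_chromosome_loss",
  "segmental_gain", "segmental_loss",
  "focal_amplification", "focal_deletion", "gene_break"
)

#' Dosage model parameters for the synthetic cohort
#'
#' Bundles the three free parameters of the simulated dosage response:
#' the attenuation `alpha` (how much of a DNA copy-number shift shows up in
#' mRNA; 1 = full dosage, 0 = complete compensation), the per-replicate
#' expression noise and the per-probe CGH noise, both standard deviations on
#' the log2 scale.
#'
#' @param attenuation Attenuation in `[0, 1]`. The default 0.6 reproduces a
#'   DNA ratio of 1.35 paired with an expression ratio of 1.21, the behavior
#'   of duplicated segments in adult-type granulosa cell tumor arrays.
#' @param sigma_e Expression noise sd per replicate hybridization, log2 scale.
#' @param sigma_c CGH noise sd per probe, log2 scale.
#' @return A list of class `dosage_model`.
#' @export
dosage_model <- function(attenuation = 0.6, sigma_e = 0.2, sigma_c = 0.15) {
  if (attenuation < 0 || attenuation > 1) abort("attenuation must be in [0, 1]")
  if (sigma_e <= 0 || sigma_c <= 0) abort("noise sds must be positive")
  structure(
    list(attenuation = attenuation, sigma_e = sigma_e, sigma_c = sigma_c),
    class = "dosage_model"
  )
}

#' Construct a planted-event table
#'
#' One row per event. `tumor_ids` is stored as a comma-joined string so the
#' table round-trips through TSV. Gain events have `copy_delta` +1, losses
#' -1; `cell_fraction` is the fraction of sampled cells carrying the event.
#' For `gene_break` events `gene_id` names the broken gene, the region is the
#' gene body, and `breakpoint` is the intragenic breakpoint position (drawn
#' uniformly inside the gene with [plant_gene_break()]).
#'
#' @param kind Event kind; one of
#'   `r paste0('\x60', EVENT_KINDS, '\x60', collapse = ", ")`.
#' @param tumor_ids Character vector of carrier tumors.
#' @param chrom,start,end Event region (0-based half-open).
#' @param cell_fraction Fraction of cells carrying the event, in (0, 1].
#' @param copy_delta Copy-number change per carrier cell (+1 gain, -1 loss).
#' @param gene_id Broken gene (gene_break only), `NA` otherwise.
#' @param breakpoint Breakpoint position (gene_break only), `NA` otherwise.
#' @param coupled Logical; `FALSE` plants a copy-number event whose
#'   expression is simulated independent of dosage (a correlation-filter
#'   negative control).
#' @return One-row tibble.
#' @export
planted_event <- function(kind, tumor_ids, chrom, start, end,
                          cell_fraction, copy_delta,
                          gene_id = NA_character_, breakpoint = NA_real_,
                          coupled = TRUE) {
  if (!kind %in% EVENT_KINDS) abort(sprintf("unknown event kind '%s'", kind))
  if (cell_fraction <= 0 || cell_fraction > 1) {
    abort("cell_fraction must be in (0, 1]")
  }
  if (start >= end) abort("event start must be < end")
  tibble(
    kind = kind,
    tumors = paste(tumor_ids, collapse = ","),
    chrom = chrom, start = start, end = end,
    gene_id = gene_id, breakpoint = breakpoint,
    cell_fraction = cell_fraction, copy_delta = as.integer(copy_delta),
    coupled = coupled
  )
}

#' @rdname planted_event
#' @param gene One-row tibble with `gene_id`, `chrom`, `start`, `end`.
#' @export
plant_gene_break <- function(gene, tumor_ids, cell_fraction = 1, copy_delta = 1L) {
  bp <- floor(runif(1, gene$start + 1, gene$end))
  planted_event(
    "gene_break", tumor_ids, gene$chrom, gene$start, gene$end,
    cell_fraction, copy_delta, gene_id = gene$gene_id, breakpoint = bp
  )
}

event_tumors <- function(events) strsplit(events$tumors, ",", fixed = TRUE)

#' Generate a synthetic genome with probes, genes and a CNV catalog
#'
#' Chromosomes are equal-length; probes are 60-mers placed with exponential
#' inter-probe gaps of mean `probe_spacing`; genes are non-overlapping with
#' lengths uniform on `gene_len_range`; the frequent-CNV catalog covers about
#' `cnv_fraction` of each chromosome while avoiding genes listed in
#' `protected_genes`.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param gene_density Genes per Mb.
#' @param probe_spacing Mean inter-probe spacing in bp (13000 emulates a
#'   13-kb-resolution CGH chip).
#' @param seed Integer seed; identical seeds give identical output.
#' @param cnv_fraction Fraction of each chromosome covered by catalog CNVs.
#' @param cnv_mean_len Mean CNV region length in bp.
#' @param gene_len_range Length-2 numeric, min/max gene length in bp.
#' @param protected_genes Gene ids the CNV catalog must not touch (within
#'   25 kb); defaults to none.
#' @return List with elements `genome` (tibble `chrom`, `length`), `genes`,
#'   `probes`, `cnv` (interval tibbles as in [read_intervals()]).
#' @export
make_genome <- function(n_chrom = 2, chrom_len = 10e6, gene_density = 10,
                        probe_spacing = 13000, seed = 1,
                        cnv_fraction = 0.03, cnv_mean_len = 5e4,
                        gene_len_range = c(5e3, 3e4),
                        protected_genes = character()) {
  stopifnot(n_chrom >= 1, chrom_len > 0, gene_density > 0, probe_spacing > 0)
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  genome <- tibble(chrom = chroms, length = chrom_len)

  probes <- map(chroms, function(ch) {
    pos <- cumsum(rexp(ceiling(2 * chrom_len / probe_spacing) + 2,
                       rate = 1 / probe_spacing))
    pos <- floor(pos[pos < chrom_len - 60])
    tibble(chrom = ch, start = pos, end = pos + 60)
  }) |> list_rbind()
  probes$probe_id <- sprintf("p%06d", seq_len(nrow(probes)))
  probes <- probes[c("chrom", "start", "end", "probe_id")]

  n_genes <- round(gene_density * chrom_len / 1e6)
  genes <- map(chroms, function(ch) {
    lens <- floor(runif(n_genes, gene_len_range[1], gene_len_range[2]))
    if (sum(lens) > 0.7 * chrom_len) {
      abort("gene_density too high: genes cannot be placed without overlap")
    }
    slack <- chrom_len - sum(lens)
    gaps <- floor(slack * diff(c(0, sort(runif(n_genes)))))
    starts <- cumsum(gaps) + cumsum(c(0, head(lens, -1)))
    tibble(
      chrom = ch, start = starts, end = starts + lens,
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
  }) |> list_rbind()
  genes$gene_id <- sprintf("g%05d", seq_len(nrow(genes)))
  genes <- genes[c("chrom", "start", "end", "gene_id", "strand")]

  protected <- genes[genes$gene_id %in% protected_genes, ]
  n_cnv_per_chrom <- max(1, round(cnv_fraction * chrom_len / cnv_mean_len))
  cnv <- map(chroms, function(ch) {
    kept <- list(); tries <- 0
    prot <- protected[protected$chrom == ch, ]
    while (length(kept) < n_cnv_per_chrom && tries < 50 * n_cnv_per_chrom) {
      tries <- tries + 1
      len <- max(1000, floor(rexp(1, 1 / cnv_mean_len)))
      s <- floor(runif(1, 0, chrom_len - len))
      clash <- nrow(prot) > 0 &&
        any(interval_gap(s, s + len, prot$start, prot$end) <= 25000)
      if (!clash) kept[[length(kept) + 1]] <- tibble(chrom = ch, start = s, end = s + len)
    }
    list_rbind(kept)
  }) |> list_rbind()
  cnv$source_id <- sprintf("cnv%04d", seq_len(nrow(cnv)))
  cnv <- arrange(cnv[c("chrom", "start", "end", "source_id")], .data$chrom, .data$start)

  list(genome = genome, genes = arrange(genes, .data$chrom, .data$start),
       probes = arrange(probes, .data$chrom, .data$start), cnv = cnv)
}

# expected log2 ratio of an event: a fraction f of cells moves from 2 to
# (2 + d) copies, so the bulk ratio is (2(1-f) + (2+d)f)/2 = 1 + d*f/2
event_log2_shift <- function(cell_fraction, copy_delta) {
  log2(1 + copy_delta * cell_fraction / 2)
}

# per-tumor shifted regions implied by an event row; gene_break shifts one
# flank of the breakpoint, extending flank_extent bp outward
event_regions_for_tumor <- function(event, tumor_id, flank_extent, flank_right) {
  if (event$kind == "gene_break") {
    bp <- event$breakpoint
    if (flank_right) {
      tibble(chrom = event$chrom, start = bp, end = bp + flank_extent)
    } else {
      tibble(chrom = event$chrom, start = max(0, bp - flank_extent), end = bp)
    }
  } else {
    tibble(chrom = event$chrom, start = event$start, end = event$end)
  }
}

#' Simulate a CGH log2-ratio matrix from planted events
#'
#' Probes whose start falls inside an event region of a carrier tumor get the
#' expected shift `log2(1 + copy_delta * cell_fraction / 2)` (shifts of
#' overlapping events combine on the copy-number scale); every probe then
#' receives Gaussian noise with sd `model$sigma_c`. A `gene_break` event
#' shifts only one flank of its breakpoint, chosen at random per (tumor,
#' event), extending `flank_extent` bp outward.
#'
#' @param events Event tibble from [planted_event()] (zero rows allowed).
#' @param probes Probe tibble from [make_genome()] or [read_intervals()].
#' @param tumors Character vector of tumor ids.
#' @param model A [dosage_model()].
#' @param seed Integer seed.
#' @param flank_extent Extent in bp of the altered flank of a gene break.
#' @return Long CGH tibble (`probe_id`, `chrom`, `start`, `end`, `tumor_id`,
#'   `log2ratio`). Events covered by no probe raise a warning and are listed
#'   in the `unobservable_events` attribute.
#' @export
simulate_cgh <- function(events, probes, tumors, model = dosage_model(),
                         seed = 1, flank_extent = 2e5) {
  set.seed(seed)
  probes <- arrange(probes, .data$chrom, .data$start)
  np <- nrow(probes)
  mu <- matrix(0, nrow = np, ncol = length(tumors),
               dimnames = list(probes$probe_id, tumors))
  unobservable <- character()
  if (nrow(events) > 0) {
    carriers <- event_tumors(events)
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      ev_hit <- FALSE
      for (tu in carriers[[i]]) {
        if (!tu %in% tumors) abort(sprintf("event tumor '%s' not in cohort", tu))
        flank_right <- runif(1) < 0.5
        regs <- event_regions_for_tumor(ev, tu, flank_extent, flank_right)
        inside <- probes$chrom == regs$chrom &
          probes$start >= regs$start & probes$start < regs$end
        if (any(inside)) ev_hit <- TRUE
        # combine on the copy-number scale, then back to log2
        cur <- 2 * (2^mu[inside, tu]) - 2     # current extra copies x f
        mu[inside, tu] <- log2((2 + cur + ev$copy_delta * ev$cell_fraction) / 2)
      }
      if (!ev_hit) unobservable <- c(unobservable, sprintf("%s:%d", ev$kind, i))
    }
  }
  if (length(unobservable) > 0) {
    warn(sprintf("events with no covering probe: %s",
                 paste(unobservable, collapse = ", ")))
  }
  noise <- matrix(rnorm(np * length(tumors), 0, model$sigma_c), nrow = np)
  vals <- mu + noise
  out <- tibble(
    probe_id = rep(probes$probe_id, times = length(tumors)),
    chrom = rep(probes$chrom, times = length(tumors)),
    start = rep(probes$start, times = length(tumors)),
    end = rep(probes$end, times = length(tumors)),
    tumor_id = rep(tumors, each = np),
    log2ratio = as.vector(vals)
  )
  if (length(unobservable) > 0) {
    attr(out, "unobservable_events") <- unobservable
  }
  out
}

#' Simulate an expression matrix from planted events
#'
#' A gene fully contained in an event region of a carrier tumor has DNA ratio
#' `c = 1 + copy_delta * cell_fraction / 2`; its expected expression ratio to
#' baseline is `1 + attenuation * (c - 1)` (attenuated dosage response).
#' Events with `coupled = FALSE` and `gene_break` events leave expression at
#' baseline. Each replicate is the expected value times log-normal noise
#' `exp(N(0, (sigma_e * ln 2)^2))`, so natural-scale values stay positive.
#'
#' @inheritParams simulate_cgh
#' @param genes Gene tibble.
#' @param n_replicates Replicate hybridizations per tumor (two emulates the
#'   paired-hybridization array design).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline expression is
#'   `2^N(baseline_log2_mean, baseline_log2_sd^2)`.
#' @return Long replicate-level expression tibble (`gene_id`, `tumor_id`,
#'   `replicate`, `value`).
#' @export
simulate_expression <- function(events, genes, tumors, model = dosage_model(),
                                seed = 1, n_replicates = 2,
                                baseline_log2_mean = 7, baseline_log2_sd = 1) {
  set.seed(seed + 1L)
  ng <- nrow(genes)
  baseline <- 2^rnorm(ng, baseline_log2_mean, baseline_log2_sd)
  ratio <- matrix(1, nrow = ng, ncol = length(tumors),
                  dimnames = list(genes$gene_id, tumors))
  if (nrow(events) > 0) {
    carriers <- event_tumors(events)
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      if (ev$kind == "gene_break" || !isTRUE(ev$coupled)) next
      contained <- genes$chrom == ev$chrom &
        genes$start >= ev$start & genes$end <= ev$end
      if (!any(contained)) next
      for (tu in intersect(carriers[[i]], tumors)) {
        cur_c <- ratio[contained, tu]  # accumulate DNA ratio across events
        new_c <- cur_c + ev$copy_delta * ev$cell_fraction / 2
        ratio[contained, tu] <- new_c
      }
    }
  }
  expr_ratio <- 1 + model$attenuation * (ratio - 1)
  rows <- expand_grid(tumor_id = tumors, replicate = seq_len(n_replicates))
  out <- map(seq_len(nrow(rows)), function(j) {
    noise <- exp(rnorm(ng, 0, model$sigma_e * log(2)))
    tibble(
      gene_id = genes$gene_id,
      tumor_id = rows$tumor_id[j],
      replicate = rows$replicate[j],
      value = baseline * expr_ratio[, rows$tumor_id[j]] * noise
    )
  }) |> list_rbind()
  arrange(out, .data$gene_id, .data$tumor_id, .data$replicate)
}

#' Write / read the planted-event truth table
#'
#' Machine-readable ground truth: one TSV row per event, used by recovery
#' tests. [read_truth()] restores the exact tibble.
#'
#' @param events Event tibble.
#' @param path Output (input) path.
#' @return `path` invisibly for the writer; the event tibble for the reader.
#' @export
write_truth <- function(events, path) {
  cols <- c("kind", "tumors", "chrom", "start", "end", "gene_id",
            "breakpoint", "cell_fraction", "copy_delta", "coupled")
  if (nrow(events) == 0) {
    events <- tibble(
      kind = character(), tumors = character(), chrom = character(),
      start = numeric(), end = numeric(), gene_id = character(),
      breakpoint = numeric(), cell_fraction = numeric(),
      copy_delta = integer(), coupled = logical()
    )
  }
  readr::write_tsv(events[cols], path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(
    kind = "c", tumors = "c", chrom = "c", start = "d", end = "d",
    gene_id = "c", breakpoint = "d", cell_fraction = "d",
    copy_delta = "i", coupled = "l"
  ))
}

#' Simulate a complete cohort with a default event mix
#'
#' Convenience wrapper used by the pipeline's simulate stage and by recovery
#' experiments: builds a genome, plants a default mix of events (one
#' whole-chromosome trisomy, focal amplified and deleted driver events around
#' randomly chosen CNV-free genes, optional dosage-decoupled decoys, and
#' recurrent gene breaks), then simulates both matrices.
#'
#' @param n_tumors Cohort size.
#' @param n_chrom,chrom_len,gene_density,probe_spacing See [make_genome()].
#' @param n_focal_amp,n_focal_del Planted focal drivers per direction.
#' @param n_decoupled Dosage-decoupled focal events (filter negative controls).
#' @param n_breaks Recurrently broken genes (each planted in
#'   `carriers_per_break` tumors).
#' @param cell_fraction Cell fraction of the planted focal events.
#' @param carriers_per_event,carriers_per_break Carrier tumors per focal
#'   event / per broken gene.
#' @param focal_span Span in bp of each planted focal event, centered on its
#'   target gene.
#' @param trisomy Logical; plant one full-cell-fraction trisomy of the first
#'   chromosome (its genes are not used as focal targets).
#' @param model A [dosage_model()].
#' @param seed Integer seed.
#' @return List with `genome`, `genes`, `probes`, `cnv`, `events`, `cgh`,
#'   `expr`, `tumors`.
#' @export
simulate_cohort <- function(n_tumors = 10, n_chrom = 3, chrom_len = 8e6,
                            gene_density = 10, probe_spacing = 13000,
                            n_focal_amp = 6, n_focal_del = 4, n_decoupled = 0,
                            n_breaks = 1, cell_fraction = 0.6,
                            carriers_per_event = 4, carriers_per_break = 2,
                            focal_span = 2e5, trisomy = TRUE,
                            model = dosage_model(attenuation = 0.8), seed = 1) {
  set.seed(seed)
  tumors <- sprintf("T%02d", seq_len(n_tumors))
  gen_seed <- sample.int(2^30, 1)
  world <- make_genome(
    n_chrom = n_chrom, chrom_len = chrom_len, gene_density = gene_density,
    probe_spacing = probe_spacing, seed = gen_seed
  )
  genes <- world$genes; cnv <- world$cnv
  set.seed(seed + 7L)

  # focal targets: CNV-free genes away from chromosome ends, outside the
  # trisomic chromosome, spaced so planted events cannot overlap
  tris_chrom <- if (trisomy) "chr1" else NA_character_
  cand <- genes |>
    filter(is.na(tris_chrom) | .data$chrom != tris_chrom,
           .data$start > focal_span, .data$end < chrom_len - focal_span)
  cnv_free <- map_lgl(seq_len(nrow(cand)), function(i) {
    on_chr <- cnv[cnv$chrom == cand$chrom[i], ]
    nrow(on_chr) == 0 ||
      all(interval_gap(cand$start[i] - focal_span / 2, cand$end[i] + focal_span / 2,
                       on_chr$start, on_chr$end) > 25000)
  })
  cand <- cand[cnv_free, ]
  n_targets <- n_focal_amp + n_focal_del + n_decoupled + n_breaks
  # greedy spacing: keep a candidate only when clear of the last kept one
  keep <- logical(nrow(cand))
  cand <- arrange(cand, .data$chrom, .data$start)
  last_chrom <- ""; last_end <- -Inf
  for (i in seq_len(nrow(cand))) {
    if (cand$chrom[i] != last_chrom || cand$start[i] - last_end > 2 * focal_span) {
      keep[i] <- TRUE
      last_chrom <- cand$chrom[i]; last_end <- cand$end[i]
    }
  }
  picked <- cand[keep, ]
  if (nrow(picked) < n_targets) abort("not enough well-separated target genes")
  picked <- picked[sample.int(nrow(picked), n_targets), ]

  events <- list()
  if (trisomy) {
    car <- sample(tumors, 1)
    events[[length(events) + 1]] <- planted_event(
      "whole_chromosome_gain", car, "chr1", 0, chrom_len, 1, +1L
    )
  }
  mk_focal <- function(gene, kind, delta, coupled) {
    center <- (gene$start + gene$end) / 2
    s <- max(0, floor(center - focal_span / 2))
    planted_event(
      kind, sample(tumors, carriers_per_event), gene$chrom,
      s, min(chrom_len, s + focal_span), cell_fraction, delta,
      gene_id = gene$gene_id, coupled = coupled
    )
  }
  idx <- 0
  for (k in seq_len(n_focal_amp)) {
    idx <- idx + 1
    events[[length(events) + 1]] <- mk_focal(picked[idx, ], "focal_amplification", +1L, TRUE)
  }
  for (k in seq_len(n_focal_del)) {
    idx <- idx + 1
    events[[length(events) + 1]] <- mk_focal(picked[idx, ], "focal_deletion", -1L, TRUE)
  }
  if (n_decoupled > 0) {
    for (k in seq_len(n_decoupled)) {
      idx <- idx + 1
      kind <- if (k %% 2 == 1) "focal_amplification" else "focal_deletion"
      delta <- if (k %% 2 == 1) +1L else -1L
      events[[length(events) + 1]] <- mk_focal(picked[idx, ], kind, delta, FALSE)
    }
  }
  if (n_breaks > 0) {
    for (k in seq_len(n_breaks)) {
      idx <- idx + 1
      events[[length(events) + 1]] <- plant_gene_break(
        picked[idx, ], sample(tumors, carriers_per_break), cell_fraction = 1
      )
    }
  }
  events <- list_rbind(events)

  cgh <- simulate_cgh(events, world$probes, tumors, model, seed = seed + 11L)
  expr <- simulate_expression(events, genes, tumors, model, seed = seed + 13L)
  c(world, list(events = events, cgh = cgh, expr = expr, tumors = tumors))
}
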