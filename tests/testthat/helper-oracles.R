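# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. Every oracle recomputes the target quantity by
# direct enumeration, independent of the package's code path.

# tiny CGH tibble from a value matrix (probes x tumors) and positions
tiny_cgh <- function(values, starts, chrom = "chr1", tumors = NULL) {
  if (is.null(tumors)) tumors <- sprintf("T%02d", seq_len(ncol(values)))
  np <- nrow(values)
  tibble::tibble(
    probe_id = rep(sprintf("p%03d", seq_len(np)), times = length(tumors)),
    chrom = chrom,
    start = rep(starts, times = length(tumors)),
    end = rep(starts + 60, times = length(tumors)),
    tumor_id = rep(tumors, each = np),
    log2ratio = as.vector(values)
  )
}

# tiny replicate-level expression tibble from a gene x tumor matrix
tiny_expr <- function(values, gene_ids = NULL, tumors = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(tumors)) tumors <- sprintf("T%02d", seq_len(ncol(values)))
  tibble::tibble(
    gene_id = rep(gene_ids, times = length(tumors)),
    tumor_id = rep(tumors, each = length(gene_ids)),
    replicate = 1L,
    value = as.vector(values)
  )
}

# brute-force windowed means: explicit loop over tiled windows
oracle_window_means <- function(starts, values, window, chrom_len) {
  ws <- seq(0, chrom_len - 1, by = window)
  out <- data.frame(win_start = ws, mean = NA_real_, n = 0L)
  for (i in seq_along(ws)) {
    inw <- starts >= ws[i] & starts < ws[i] + window
    out$n[i] <- sum(inw)
    if (any(inw)) out$mean[i] <- mean(values[inw])
  }
  out
}

# brute-force all-pairs probe-to-gene gap mapping
oracle_probe_gene_map <- function(probes, genes, max_gap) {
  hits <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(probes))) {
      if (genes$chrom[i] != probes$chrom[j]) next
      gap <- max(0, max(genes$start[i], probes$start[j]) -
                    min(genes$end[i], probes$end[j]))
      if (gap <= max_gap) {
        hits[[length(hits) + 1]] <- data.frame(
          gene_id = genes$gene_id[i], probe_id = probes$probe_id[j], gap = gap
        )
      }
    }
  }
  if (length(hits) == 0) return(data.frame(gene_id = character(),
                                           probe_id = character(),
                                           gap = numeric()))
  do.call(rbind, hits)
}

# brute-force containment scan of genes in regions
oracle_containment <- function(genes, regions) {
  vapply(seq_len(nrow(genes)), function(i) {
    any(regions$chrom == genes$chrom[i] &
          regions$start <= genes$start[i] &
          regions$end >= genes$end[i])
  }, logical(1))
}

# exhaustive two-sided Fisher p from log-factorials (independent of dhyper)
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  ptab <- function(x) {
    # hypergeometric probability of table (x, r1-x, c1-x, n-r1-c1+x)
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(support, ptab, numeric(1))
  p0 <- ptab(a)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# exhaustive hypergeometric upper tail for set-overlap significance
oracle_overlap_p <- function(shared, size_a, size_b, universe) {
  ks <- shared:min(size_a, size_b)
  sum(vapply(ks, function(k) {
    exp(lchoose(size_a, k) + lchoose(universe - size_a, size_b - k) -
          lchoose(universe, size_b))
  }, numeric(1)))
}

# naive complete-linkage agglomeration on a distance matrix; returns the
# sequence of merge heights
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(j, i) }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# 20-cohort screen-recovery experiment shared by the acceptance test and the
# acceptance script; planted conditions: 10 tumors, 10 focal drivers,
# cell fraction 0.6, attenuation 0.8, default noise, 2 decoys, 1 broken gene
run_screen_recovery <- function(n_seeds = 20, base_seed = 1) {
  per_seed <- lapply(seq_len(n_seeds), function(s) {
    co <- gctscreen::simulate_cohort(seed = base_seed + s, n_decoupled = 2)
    scr <- gctscreen::identify_drivers(co$cgh, co$expr, co$genes, co$cnv)
    cc <- generics::tidy(scr)
    planted <- co$events$gene_id[
      co$events$kind %in% c("focal_amplification", "focal_deletion") &
        co$events$coupled
    ]
    decoys <- co$events$gene_id[!co$events$coupled]
    ev <- co$events[co$events$kind %in% c("focal_amplification",
                                          "focal_deletion") & co$events$coupled, ]
    passed <- cc$gene_id[cc$passed]
    g <- co$genes[match(passed, co$genes$gene_id), ]
    in_planted <- if (nrow(g) > 0) {
      vapply(seq_len(nrow(g)), function(i) {
        any(ev$chrom == g$chrom[i] & ev$start <= g$start[i] &
              ev$end >= g$end[i])
      }, logical(1))
    } else logical(0)
    bro <- gctscreen::detect_broken_genes(co$cgh, co$genes, co$cnv)
    truth_break <- co$events$gene_id[co$events$kind == "gene_break"]
    tris_genes <- co$genes$gene_id[co$genes$chrom == "chr1"]
    list(
      n_planted = length(planted),
      n_recovered = sum(planted %in% passed),
      n_false = sum(!in_planted),
      n_decoys = length(decoys),
      n_decoys_passed = sum(decoys %in% passed),
      break_recovered = all(truth_break %in% bro$genes$gene_id[bro$genes$passed]),
      broken_on_trisomy = sum(bro$genes$passed &
                                bro$genes$gene_id %in% tris_genes)
    )
  })
  agg <- function(f) vapply(per_seed, `[[`, numeric(1), f)
  list(
    sensitivity = sum(agg("n_recovered")) / sum(agg("n_planted")),
    mean_false_positives = mean(agg("n_false")),
    decoy_rejection_rate = 1 - sum(agg("n_decoys_passed")) / sum(agg("n_decoys")),
    break_recovery = sum(agg("break_recovered")),
    n_seeds = n_seeds,
    broken_on_trisomy_total = sum(agg("broken_on_trisomy"))
  )
}

# correlation-filter type-I experiment: dosage-independent expression,
# nominal alpha 0.05, flag rate over n_perm seeded permutations
run_correlation_type1 <- function(n_perm = 1000, n = 10, seed = 1) {
  set.seed(seed)
  flagged <- vapply(seq_len(n_perm), function(i) {
    x <- stats::setNames(rnorm(n), sprintf("T%02d", seq_len(n)))
    y <- stats::setNames(sample(rnorm(n)), names(x))
    ct <- gctscreen::correlation_filter(x, y)
    ct$significant
  }, logical(1))
  mean(flagged)
}

# co-occurrence type-I experiment: two independent alterations in a
# 64-tumor collection, fraction of p < 0.05 over n_sim seeds
run_cooccurrence_type1 <- function(n_sim = 1000, n_tumors = 64, seed = 1) {
  set.seed(seed)
  ps <- vapply(seq_len(n_sim), function(i) {
    presence <- data.frame(
      tumor_id = sprintf("T%03d", seq_len(n_tumors)),
      A = rbinom(n_tumors, 1, 0.4),
      B = rbinom(n_tumors, 1, 0.5),
      check.names = FALSE
    )
    gctscreen::fisher_exact_two_tailed(
      gctscreen::build_table(presence, "A", "B")
    )$p
  }, numeric(1))
  mean(ps < 0.05)
}

# build a vector with exact sample correlation `target` to x, by mixing the
# standardized x with the component of y orthogonal to x
r_mix <- function(x, y, target) {
  zx <- as.vector(scale(x))
  res <- as.vector(scale(residuals(lm(y ~ x))))
  target * zx + sqrt(1 - target^2) * res
}
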