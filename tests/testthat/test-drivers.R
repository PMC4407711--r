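test_that("correlation significance thresholds match the t transform", {
  # printed cutoffs for 10/9/8 samples at two-sided 0.05
  expect_equal(round(r_significance_threshold(10), 2), 0.63)
  expect_equal(round(r_significance_threshold(9), 2), 0.67)
  expect_equal(round(r_significance_threshold(8), 2), 0.71)
  # n = 7: t_crit(5 df) = 2.5706 -> 0.7545
  expect_equal(r_significance_threshold(7), 0.7545, tolerance = 1e-4)
  # n = 3: t_crit(1 df) = 12.706 -> 12.706 / sqrt(12.706^2 + 1)
  expect_equal(r_significance_threshold(3), 12.706 / sqrt(12.706^2 + 1),
               tolerance = 1e-4)
  expect_true(all(diff(r_significance_threshold(3:30)) < 0))
  expect_error(r_significance_threshold(2), "n >= 3")
})

test_that("probe-to-gene mapping respects the 25-kb margin", {
  genes <- tibble::tibble(chrom = "chr1", start = 1e5, end = 1.2e5,
                          gene_id = "gA", strand = "+")
  probes <- tibble::tibble(
    chrom = "chr1",
    start = c(1e5 - 10060, 1.2e5 + 26000, 1.1e5),
    probe_id = c("up10k", "down26k", "inside")
  )
  probes$end <- probes$start + 60
  hits <- map_probes_to_genes(probes, genes, max_gap = 25000)
  expect_setequal(hits$probe_id, c("up10k", "inside"))
  expect_equal(hits$gap[hits$probe_id == "inside"], 0)
  # exactly 25 kb away is still a supporter; 1 bp further is not
  probes2 <- tibble::tibble(chrom = "chr1", start = c(75000 - 60, 75000 - 61),
                            probe_id = c("at25k", "past25k"))
  probes2$end <- probes2$start + 60
  hits2 <- map_probes_to_genes(probes2, genes, max_gap = 25000)
  expect_equal(hits2$probe_id, "at25k")
})

test_that("probe-to-gene mapping equals the all-pairs oracle", {
  set.seed(83)
  n <- 400
  probes <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample.int(3e6, n)
  )
  probes$end <- probes$start + 60
  probes$probe_id <- sprintf("p%03d", seq_len(n))
  m <- 60
  genes <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), m, replace = TRUE),
    start = sample.int(3e6, m)
  )
  genes$end <- genes$start + sample.int(3e4, m)
  genes$gene_id <- sprintf("g%03d", seq_len(m))
  hits <- map_probes_to_genes(probes, genes, max_gap = 25000)
  oracle <- oracle_probe_gene_map(probes, genes, 25000)
  key <- function(d) sort(paste(d$gene_id, d$probe_id, d$gap))
  expect_equal(key(hits), key(oracle))
})

test_that("gene-level CGH summaries average supporting probes", {
  cgh <- tiny_cgh(rbind(c(0.2, 0), c(0.4, 0.1)), c(100, 300))
  both <- gene_cgh_summary(cgh, c("p001", "p002"))
  expect_equal(both$cgh_value[both$tumor_id == "T01"], 0.3)
  expect_equal(both$cgh_value[both$tumor_id == "T02"], 0.05)
  single <- gene_cgh_summary(cgh, "p001")
  expect_equal(single$cgh_value, c(0.2, 0))
  expect_error(gene_cgh_summary(cgh, character()), "no supporting probes")
  expect_error(gene_cgh_summary(cgh, "nosuch"), "not found")
})

test_that("the correlation filter applies the adjusted threshold", {
  tumors <- sprintf("T%02d", 1:10)
  x <- setNames(seq(0, 0.9, by = 0.1), tumors)
  y <- setNames(2 * x + 1, tumors)
  perfect <- correlation_filter(x, y)
  expect_equal(perfect$R, 1)
  expect_true(perfect$significant)
  expect_equal(perfect$n, 10)
  # excluding tumors shrinks n and raises the critical R
  sub <- correlation_filter(x, y, excluded_tumors = c("T01", "T02"))
  expect_equal(sub$n, 8)
  expect_equal(round(sub$R_crit, 2), 0.71)
  # R = 0.70 at n = 8 falls short of the 0.71 cutoff
  set.seed(91)
  repeat {
    a <- rnorm(8); b <- rnorm(8)
    r <- cor(a, b)
    if (abs(r) > 0.1) break
  }
  target <- 0.70
  b_mix <- r_mix(a, b, target)
  ct <- correlation_filter(setNames(a, tumors[1:8]), setNames(b_mix, tumors[1:8]))
  expect_equal(ct$R, 0.70, tolerance = 1e-9)
  expect_false(ct$significant)
  expect_error(correlation_filter(x[1:2], y[1:2]), "insufficient")
  expect_error(correlation_filter(setNames(rep(1, 10), tumors), y),
               "zero variance")
})

test_that("CNV exclusion is containment, not mere overlap", {
  cnv <- tibble::tibble(chrom = "chr1", start = c(1000, 8000),
                        end = c(5000, 9000), source_id = c("c1", "c2"))
  inside <- list(chrom = "chr1", start = 2000, end = 4000)
  partial <- list(chrom = "chr1", start = 4500, end = 8000)
  expect_true(cnv_exclusion(inside, cnv))
  expect_false(cnv_exclusion(partial, cnv))
  expect_true(cnv_exclusion(partial, cnv, rule = "overlap"))
  expect_false(cnv_exclusion(list(chrom = "chr2", start = 2000, end = 4000), cnv))
})

test_that("containment checks equal the brute-force scan", {
  set.seed(97)
  n <- 200
  genes <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample.int(1e6, n)
  )
  genes$end <- genes$start + sample.int(2e4, n)
  genes$gene_id <- sprintf("g%03d", seq_len(n))
  cnv <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
    start = sample.int(1e6, 40)
  )
  cnv$end <- cnv$start + sample.int(1e5, 40)
  cnv$source_id <- sprintf("c%02d", 1:40)
  got <- vapply(seq_len(n), function(i) cnv_exclusion(genes[i, ], cnv), logical(1))
  expect_equal(got, oracle_containment(genes, cnv))
})

test_that("full inclusion requires the gene inside one same-direction call", {
  calls <- tibble::tibble(
    tumor_id = c("T01", "T01", "T02"), chrom = "chr1",
    start = c(1000, 9000, 1000), end = c(5000, 12000, 2000),
    direction = c("gain", "gain", "gain"), scale = "focal",
    mean_log2 = 0.4, probe_count = 3L
  )
  gene_in <- list(chrom = "chr1", start = 2000, end = 4000)
  gene_straddle <- list(chrom = "chr1", start = 4000, end = 10000)
  expect_equal(full_inclusion_check(gene_in, calls, "gain"),
               c(T01 = TRUE, T02 = FALSE))
  expect_false(any(full_inclusion_check(gene_straddle, calls, "gain")))
  expect_false(any(full_inclusion_check(gene_in, calls, "loss")))
})

test_that("an empty CGH matrix produces an empty screen", {
  genes <- tibble::tibble(chrom = "chr1", start = 1, end = 10,
                          gene_id = "gA", strand = "+")
  cnv <- tibble::tibble(chrom = character(), start = numeric(),
                        end = numeric(), source_id = character())
  empty_cgh <- tiny_cgh(matrix(numeric(0), nrow = 0, ncol = 0), numeric(0),
                        tumors = character(0))
  scr <- identify_drivers(empty_cgh, tiny_expr(matrix(1, 1, 3),
                                               gene_ids = "gA"),
                          genes, cnv)
  expect_s3_class(scr, "driver_screen")
  expect_equal(nrow(tidy(scr)), 0)
  expect_equal(glance(scr)$n_passed, 0)
})

test_that("screen output is invariant to probe and tumor order", {
  co <- simulate_cohort(seed = 23, n_chrom = 3, chrom_len = 6e6)
  scr1 <- identify_drivers(co$cgh, co$expr, co$genes, co$cnv)
  shuffled_cgh <- co$cgh[sample.int(nrow(co$cgh)), ]
  shuffled_expr <- co$expr[sample.int(nrow(co$expr)), ]
  scr2 <- identify_drivers(shuffled_cgh, shuffled_expr, co$genes, co$cnv)
  t1 <- tidy(scr1); t2 <- tidy(scr2)
  expect_equal(as.data.frame(t1[setdiff(names(t1), "tumors_altered")]),
               as.data.frame(t2[setdiff(names(t2), "tumors_altered")]))
})

test_that("every passed candidate satisfies the filter conjunction", {
  co <- simulate_cohort(seed = 29, n_decoupled = 1)
  cc <- tidy(identify_drivers(co$cgh, co$expr, co$genes, co$cnv))
  passed <- cc[cc$passed, ]
  expect_true(all(passed$significant))
  expect_true(all(passed$fully_included))
  expect_true(all(!passed$cnv_overlap))
  expect_true(all(passed$n_tumors_small_scale >= 2))
  expect_true(all(cc$significant[!is.na(cc$R)] ==
                    (cc$R[!is.na(cc$R)] >= cc$R_crit[!is.na(cc$R)])))
})

test_that("single-tumor breaks and uniform trisomies are not broken genes", {
  world <- make_genome(n_chrom = 2, chrom_len = 4e6, seed = 37)
  tumors <- sprintf("T%02d", 1:6)
  quiet <- dosage_model(sigma_c = 1e-4, sigma_e = 1e-4)
  target <- world$genes[40, ]
  set.seed(37)
  ev <- dplyr::bind_rows(
    plant_gene_break(target, "T01"),                      # one tumor only
    planted_event("whole_chromosome_gain", "T02",
                  "chr2", 0, 4e6, 1, +1L)                 # uniform trisomy
  )
  cgh <- simulate_cgh(ev, world$probes, tumors, quiet, seed = 37)
  bro <- detect_broken_genes(cgh, world$genes, world$cnv)
  # the break is seen but does not reach recurrence
  row <- bro$genes[bro$genes$gene_id == target$gene_id, ]
  expect_true(nrow(row) == 0 || !row$passed)
  # no gene on the trisomic chromosome is called broken
  chr2_genes <- world$genes$gene_id[world$genes$chrom == "chr2"]
  expect_equal(sum(bro$genes$gene_id %in% chr2_genes & bro$genes$passed), 0)
})

test_that("a recurrent two-tumor break is recovered", {
  world <- make_genome(n_chrom = 2, chrom_len = 4e6, seed = 43)
  tumors <- sprintf("T%02d", 1:10)
  set.seed(43)
  target <- world$genes[world$genes$chrom == "chr1", ][30, ]
  ev <- plant_gene_break(target, c("T01", "T05"))
  cgh <- simulate_cgh(ev, world$probes, tumors, dosage_model(), seed = 43)
  bro <- detect_broken_genes(cgh, world$genes, world$cnv)
  row <- bro$genes[bro$genes$gene_id == target$gene_id, ]
  expect_equal(nrow(row), 1)
  expect_gte(row$n_tumors_broken, 2)
  expect_true(row$passed)
  # recorded breakpoints sit inside (or straddling) the gene body
  bps <- bro$breakpoints[bro$breakpoints$gene_id == target$gene_id, ]
  expect_true(all(bps$breakpoint > target$start - 15000 &
                    bps$breakpoint < target$end + 15000))
})
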