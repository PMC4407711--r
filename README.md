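# gctscreen

Integration of array-CGH copy-number profiles with tumor transcriptomes to
nominate candidate driver genes in small cohorts, modeled on the combined
genomic/transcriptomic analysis of adult-type ovarian granulosa cell tumors
(GCTs) — a sex cord-stromal tumor defined by the *FOXL2* C134W mutation, in
which recurrent chromosomal imbalances (notably +14 and −22) suggest
additional drivers.

The package is aimed at analysts working with small tumor series (around ten
samples) profiled on oligonucleotide CGH arrays (log2 tumor/reference ratios
per probe) and expression arrays with replicate hybridizations. Everything is
tibble-in / tibble-out and pipe-friendly.

## What it computes

**Cell-fraction-calibrated thresholds.** A heterozygous single-copy gain
carried by a fraction *f* of sampled cells shifts the bulk DNA ratio to
1 + *f*/2, a loss to 1 − *f*/2. At *f* = 0.5 the log2-ratio thresholds are
log2(1.25) = 0.322 and log2(0.75) = −0.415 (`logratio_threshold()`).

**Imbalance calling.** 130-kb sliding-window smoothing
(`sliding_window_mean()`), whole-chromosome / segmental / focal calls
(`call_large_scale()`), and recurrently altered probes — beyond threshold in
at least two tumors (`recurrent_altered_probes()`).

**Dosage response.** Expression of genes in an aneuploid region is divided
by its mean in the non-carrier tumors (`normalize_to_noncarriers()`),
summarized in 30 equal windows per chromosome, compared inside vs outside
altered segments with Welch *t* and Mann–Whitney tests
(`compare_region_means()`), and the dosage attenuation α is estimated from
paired DNA/expression ratios: α = (e − 1)/(c − 1)
(`estimate_attenuation()`).

**The driver screen** (`identify_drivers()`). Recurrent altered probes are
mapped to genes within 25 kb; per gene, the Pearson correlation R between
the gene-level CGH value and expression across tumors is tested against the
critical value of the *t* transform

    t = R * sqrt((n - 2) / (1 - R^2)),  t ~ Student-t with n - 2 df,

which gives R ≥ 0.63 for n = 10 and larger cutoffs when tumors carrying
overlapping large-scale imbalances are removed (0.67 at n = 9, 0.71 at
n = 8). Candidates must additionally be fully included in a same-direction
imbalance call and lie outside frequent germline CNVs.

**Broken genes** (`detect_broken_genes()`): genes with an intragenic
copy-number breakpoint (altered flank on one side only) in at least two
tumors, away from frequent CNVs.

**Co-occurrence** (`cooccurrence_scan()`): two-tailed Fisher exact tests of
chromosomal-alteration pairs. **Networks** (`neighbor_set()`,
`build_sharing_network()`, `cluster_drivers()`): transcriptomic neighbors at
|R| ≥ 0.63, neighbor-sharing significance (hypergeometric), a display
network at R ≥ 0.90, and complete-linkage clustering on 1 − R.

**Synthetic cohorts** (`simulate_cohort()`, `make_genome()`,
`simulate_cgh()`, `simulate_expression()`): seeded genomes with probes at
13-kb mean spacing, planted trisomies, focal events, dosage-decoupled decoys
and broken genes, with a machine-readable truth table — so the whole
pipeline is testable without access to the original arrays.

## Worked example

```r
library(gctscreen)

co  <- simulate_cohort(seed = 42, n_decoupled = 1)   # 10 tumors, planted truth
scr <- identify_drivers(co$cgh, co$expr, co$genes, co$cnv)
glance(scr)
#>   n_candidates n_significant n_passed n_amplified_passed n_deleted_passed
#> 1           82            20       18                 12                6

dplyr::filter(tidy(scr), passed)[1:3, c("gene_id", "status", "R", "n", "R_crit")]
#>   gene_id    status         R  n    R_crit
#> 1  g00091 amplified 0.6474714 10 0.6318969
#> 2  g00110 amplified 0.7419176 10 0.6318969
#> 3  g00111 amplified 0.6684617 10 0.6318969
```

82 gene/direction pairs carry a recurrently altered probe within 25 kb; 20
survive the correlation filter at the sample-size-adjusted cutoff, and 18
also pass the full-inclusion and CNV filters. The compiled-cohort
co-occurrence test reproduces the published association of trisomy 14 with
monosomy 22 (18 of 64 tumors carry both):

```r
fisher_exact_two_tailed(18, 7, 16, 23)
#>   odds_ratio      p
#> 1       3.70 0.0213
```

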