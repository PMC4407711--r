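---
title: "Methods: copy-number/expression integration for driver screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number/expression integration for driver screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gctscreen)
```

This vignette is the package's account of its models and of the design
choices made where the underlying study left the procedure open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The copy-number signal model

Array CGH reports, per 60-mer probe, the log2 ratio of tumor to reference
DNA fluorescence. A heterozygous single-copy change (gain `d = +1`, loss
`d = -1`) carried by a cell fraction `f` of the sampled tissue mixes
`(2 + d)`-copy tumor cells with diploid cells, so the expected bulk ratio is

```
c = (2 (1 - f) + (2 + d) f) / 2 = 1 + d f / 2
```

and the expected log2 ratio is `log2(1 + d f / 2)`. The calling thresholds
are this expression evaluated at the calibrating fraction: at `f = 0.5`,
+0.322 for gains and −0.415 for losses (`logratio_threshold()`,
`threshold_pair()`). The mixture model is deliberately minimal: one cell
fraction per event, no allele-specific copy number, no GC waves.

## Imbalance calling

The study this package reimplements presented large-scale calls without a
numeric rule (profiles were inspected in a viewer), so the calling procedure
here is the package's own, chosen for one property: it must recover events
planted at exactly the calibration point, where a single probe is beyond
threshold only about half the time. All smoothing-based decisions therefore
use *half* the threshold on noise-averaged quantities:

1. **Whole chromosome** — at least 80% (`coverage_min`) of non-empty 130-kb
   windows beyond half-threshold *and* the chromosome mean beyond
   half-threshold. The coverage clause keeps one strong focal event from
   promoting a chromosome call.
2. **Window runs** — maximal runs of consecutive windows beyond
   half-threshold with at least `min_probes_segment = 10` probes. Call
   extent is the run's probe extent widened to the midpoints of the
   flanking inter-probe gaps (breakpoints live between probes).
3. **Probe runs** — remaining runs of ≥ 2 consecutive probes beyond the
   full threshold, for events smaller than a window.

Scale is physical: spans of at least `focal_max_span = 1 Mb` are `segment`,
smaller calls `focal`, because the screen's "large-scale" exclusions are
meant for multi-megabase events; classifying a 200-kb amplification as
large-scale would wrongly remove its carriers from the correlation filter.
Probe-count thresholds alone cannot make that distinction at 13-kb spacing.

## Expression and the dosage response

Expression values are natural-scale intensities, with the two replicate
hybridizations per tumor averaged first (`expr_means()`). For genes inside
an altered region, each tumor's value is divided by the gene's mean over the
tumors *not* carrying the alteration (`normalize_to_noncarriers()`);
normalization is done in the natural scale, and log2 ratios are derived
afterwards. Gene membership uses full containment of the gene interval for
normalization (matching the screen's full-inclusion rule) and gene midpoints
for the 30-equal-window chromosome summaries (midpoints cannot double-count
a gene across windows).

Dosage is attenuated: a DNA ratio `c` yields an expected expression ratio
`e = 1 + alpha * (c - 1)` with `alpha` in [0, 1]. `estimate_attenuation()`
inverts this; the generator's default `alpha = 0.6` reproduces the observed
pairing of a 1.35 DNA ratio with a 1.21 expression ratio in duplicated
segments. The inside/outside comparison (`compare_region_means()`) uses a
Welch *t*-test — the unequal-variance form is the safer default when the
study names only "a t-test" — alongside the Mann–Whitney test.

## The driver screen

`identify_drivers()` composes five stages; every candidate is returned with
all its flags so the pre-filter and post-filter lists are both inspectable.

* **Recurrence.** A probe is recurrently altered when beyond threshold in
  ≥ 2 tumors (`min_tumors`); a gene is a candidate when a recurrent probe
  maps within 25 kb (`max_gap`) of it — the gap is interval-to-interval, 0
  when overlapping, and the 25-kb bound is inclusive.
* **Correlation filter.** Per gene, the CGH value is the unweighted mean of
  its supporting probes per tumor (the study does not say which probe value
  enters the correlation; the mean is the neutral choice). Pearson R between
  CGH and expression is computed over tumors *not* carrying an overlapping
  whole-chromosome or segment call, against the critical R from the
  Student-t transform at two-sided `alpha = 0.05`. Significance demands a
  *positive* R for amplified and deleted candidates alike: dosage and
  expression move together in both directions. Under independence the
  realized type-I rate is therefore about `alpha / 2`. No multiple-testing
  correction is applied, deliberately mirroring the original small-cohort
  design.
* **Recurrence at small scale.** Tumors excluded from the correlation do
  not count towards the ≥ 2-tumor recurrence or full inclusion either.
  Without this, a single trisomy carrier plus one noise probe makes every
  gene on the trisomic chromosome a candidate whose fate rests on a chance
  correlation among the remaining tumors.
* **Filters.** Full inclusion: the gene interval lies inside a single
  same-direction call in at least one (small-scale) altered tumor. CNV
  exclusion: the gene is fully contained in a frequent-CNV catalog region
  (containment, not mere overlap; configurable).

## Broken genes

A broken gene carries an intragenic breakpoint: amplification or deletion on
one flank only. At realistic noise a single discordant probe pair is far too
permissive — with per-probe noise sd 0.15 and the 0.322 threshold, a
single-probe state rule produces hundreds of spurious breakpoints per cohort
and decorates trisomic chromosomes with artifacts. `detect_broken_genes()`
therefore classifies the *mean* of up to `flank_probes = 6` probes on each
side of every inter-probe gap (full flanks required; truncated flanks at
chromosome ends are the dominant artifact source) against
`flank_frac = 0.8` times the thresholds; a discordant state pair records a
breakpoint at the gap midpoint, assigned to the genes overlapping the gap.
Recurrence means breakpoints from ≥ 2 distinct tumors in the same gene
("closely mapping" is not quantified in the source study; same-gene is the
operational reading), and breakpoints within 25 kb of a frequent CNV
disqualify the gene — the same margin as probe-to-gene mapping, for
internal consistency.

## Co-occurrence and networks

`fisher_exact_two_tailed()` uses the standard two-sided convention: the sum
of hypergeometric probabilities of all tables with the observed margins at
most as probable as the observed table, with a relative tolerance of 1e-7
absorbing floating-point ties; the odds ratio is the sample `(ad)/(bc)`.
`cooccurrence_scan()` applies it to all alteration pairs with no correction.

Transcriptomic neighbors are genes correlated with a seed beyond ±0.63 (the
n = 10 significance cutoff); the display network keeps |R| ≥ 0.90.
Correlations are computed on log2 expression — the conventional scale for
array co-expression — which is a documented divergence risk, as the source
study does not state its scale. Neighbor-set sharing is scored with the
hypergeometric upper tail on the universe of genes entering the correlation
(the study asserts significance without naming a test). Clustering is
complete-linkage on `1 - R`; `stats::hclust` supplies the deterministic
agglomeration, and dendrograms export to Newick.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 10 tumors, two replicate
hybridizations, probes with exponential inter-probe gaps of mean 13 kb,
~10 genes/Mb, a frequent-CNV catalog covering a few percent of the genome
and kept clear of target genes, one clonal trisomy, focal events of 200 kb
centered on CNV-free genes in 4 of 10 tumors at cell fraction 0.6,
dosage-decoupled decoy events, and genes broken in 2 tumors (breakpoint
uniform in the gene body, altered flank extending 200 kb, flank side random
per tumor). CGH noise is Gaussian on the log2 scale (`sigma_c = 0.15`);
expression noise is log-normal per replicate (`sigma_e = 0.2` log2-scale sd)
so natural-scale values stay positive. Neither noise magnitude is reported
by the source study; both are free parameters at values typical of
two-color oligonucleotide arrays. Overlapping events combine on the
copy-number scale. What the generator does *not* model: spatial
autocorrelation (GC waves), probe-specific biases, tumor-purity variation
beyond the single cell fraction, allele-specific states, and expression
change from gene breakage. Passing recovery tests therefore shows the
statistical machinery is correct under the stated model, not that real
arrays are this clean.

Problem sizes in the tests and in `scripts/acceptance.R` — 3 chromosomes of
8 Mb, ~1 800 probes, 240 genes, 20 replicate cohorts — are chosen so every
planted event is covered by dozens of probes while a full recovery
experiment stays a desk-scale computation; all statistical behavior under
test (per-probe power, correlation-filter power, type-I rates) depends on
per-event probe counts and cohort size, not on genome length.

## Statistical power of the screen, honestly stated

At the recovery experiment's planted conditions — cell fraction 0.6,
attenuation 0.8, default noise, 10 tumors — the expression shift of an
amplified gene is 24% against a per-tumor noise of ~10% after replicate
averaging. The resulting Pearson correlation across 10 tumors has an
expected value around 0.7–0.8, and the n = 10 cutoff of 0.63 then leaves a
per-gene pass probability of roughly 0.75–0.85 (a design-time power
analysis, confirmed by the recovery experiment). Screen sensitivity is
bounded by exactly this quantity: the filter that makes the screen specific
(decoy rejection > 95%, ≤ 1 false positive per cohort) is also what caps
its sensitivity near 0.8 under these conditions. A cohort twice as large,
or clonal focal events, would lift it; at n = 10 and f = 0.6 the trade-off
is intrinsic to the published filter cascade, not to this implementation.

## Degenerate inputs and numerical choices

Zero non-carrier tumors abort normalization (the ratio is undefined);
zero-variance vectors abort correlations (and drop genes from clustering
with a warning); empty windows and empty call sets propagate as typed empty
tibbles; matrices must be finite, expression strictly positive, and missing
values are rejected rather than imputed (the source pipeline never imputes).
Coordinates are 0-based half-open everywhere; BED files are read and written
natively in that convention, and all writers emit '.'-decimal UTF-8 TSV.
Seeds fully determine cohorts; identical seeds give bit-identical matrices.
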