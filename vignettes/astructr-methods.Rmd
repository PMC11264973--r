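---
title: "Calling allele-specific RNA structure from RT-stop probing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling allele-specific RNA structure from RT-stop probing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astructr)
library(dplyr)
```

## The problem

A heterozygous SNP inside a transcript can change how that transcript
folds, so the two alleles expressed in the same cell may carry different
RNA secondary structures (a "riboSNitch", or allele-specific RNA secondary
structure, ASRS). Chemical structure probing read out by reverse
transcription gives a way to see this directly: in icSHAPE/smartSHAPE-type
experiments, flexible (mostly unpaired) nucleotides are acylated by NAI-N3
in vivo, and reverse transcriptase stops one base 3′ of each adduct. The 5′
ends of reads in the treated library therefore mark flexible bases, while a
DMSO control library measures the background stop and coverage pattern.

Because every read that spans the SNP reveals which allele it came from,
the reads around a heterozygous SNP can be split into two allele groups and
probed for a structural difference — within one sample, with both alleles
sharing cell state, expression environment and library preparation.
`astructr` implements this comparison: per-allele reactivity profiles, a
window-level difference statistic with a permutation null, a composite
score used to rank SNPs, and a read simulator with ground-truth labels for
benchmarking.

## From reads to per-allele reactivity

For each candidate SNP we count, across the treated and control arms
pooled, the SNP-spanning reads that carry the reference and the alternate
base. A site is **retained** when it looks genuinely heterozygous and
covered: at least 10 spanning reads with a called allele and at least 2 per
allele. "Total" here means allele-informative spanning reads — the filter
is stated alongside the allele-coverage requirement, and window-coverage
totals would make it depend on window length. Both thresholds are
configurable (`astruct_config()`).

The **SNP window** is the envelope of all allele-informative spanning
reads: from the start of the most upstream to the end of the most
downstream spanning read. Its length `N` is the universe for everything
that follows. Reads overlapping the window but not covering the SNP carry
no allele information and are shared by both alleles; spanning reads with a
third base, a deletion, or a sub-threshold base quality at the SNP are
excluded from both allele groups but still counted in the window total.

For one allele in one arm, every read contributes one **RT-stop** event at
the base immediately 5′ of its alignment start (configurable to the 3′ side
for minus-strand libraries) and **background** at every base it covers.
From the raw stop vector `R` and background vector `B` we compute, per
allele:

1. *Percentile normalisation.* `R` and `B` are each divided by their
   within-window 95th-percentile value, taken as the nearest-rank order
   statistic (the `ceiling(0.95 N)`-th smallest value, not an interpolated
   quantile — bracket-style indexing of the sorted vector, reproducible
   across platforms). An all-zero vector is left unchanged and flagged.
2. *Enrichment.* `ES_i = (R_i^T − s·R_i^C) / B_i^C`, treated stops minus a
   fraction `s` of control stops over control background. The default
   `s = 0.25` follows the icSHAPE scoring lineage; the value is exposed
   because it is a protocol-level choice, not a fitted quantity.
3. *Unit rescaling.* `ES_i` is mapped through
   `max(0, min(1, (ES_i − ES[0.05N]) / (ES[0.95N] − ES[0.05N])))`,
   percentiles again nearest-rank, computed over non-missing values.
   Negative enrichments are preserved up to this step — the 5th-percentile
   shift depends on the negative tail — and clamping happens only here.

Two numerical guards keep the chain total: bases with zero raw control
coverage carry no information and are reported missing rather than
divided by zero, and the normalised control background is floored at
`background_pseudocount` (default 0.25, i.e. a quarter of the
95th-percentile reference coverage) so a handful of barely covered bases
cannot dominate the enrichment scale. If the 5th and 95th enrichment
percentiles coincide the profile is flat: all scores are set to 0 and the
profile flagged degenerate.

## Testing the allelic difference

The two allele profiles are compared by Pearson correlation over their
jointly scored bases, converted to the **experimental structural
disruption coefficient**

$$\mathrm{eSDC} = (1 - {}^{p}CC)\,\sqrt{N},$$

larger values meaning more allelic difference; the `sqrt(N)` factor puts
windows of different lengths on a comparable scale. A zero-variance
profile has no defined correlation; we make the conservative call
(eSDC 0, P 1, score 0) rather than guessing.

Significance comes from a read-label permutation null. In each
permutation the SNP-spanning reads are reassigned to pseudo-ref and
pseudo-alt groups at an expected 1:1 ratio: the pseudo-ref count is drawn
`Poisson(R_d/2)` and redrawn (up to 100 times) whenever it would leave a
pseudo-allele empty, then that many spanning reads are chosen uniformly
without replacement. Treated and control spanning reads are relabelled
jointly — under the null a read's allele is independent of its arm, so the
labels are exchangeable across arms. Non-spanning reads stay shared, and
the *entire* scoring chain is recomputed from raw counts for every
permutation, so the null reflects every normalisation step. The one-sided
tail probability uses the add-one estimator
`P = (1 + #{null ≥ observed}) / (1 + n_perm)`, never exactly zero, so
`−log10 P` is finite and saturates at `log10(n_perm + 1)`.

The composite **AStruct score**

$$-\log_{10} P \times \mathrm{eSDC} \times
  \left(1 - \log_{10}\frac{R_d}{R}\right)$$

multiplies significance, magnitude, and a correction for dilution:
non-spanning window reads are shared by both alleles and smooth the
contrast, so windows where only a small fraction of reads actually span
the SNP get a boost (the factor is exactly 1 when every window read
spans). Scores group as Low (= 0), Medium ((0, 1]) and High (> 1).

Per base, **StrucDiff** is the mean absolute allele difference over a
±2-base neighbourhood (divisor fixed at 5, so edge bases and bases next to
missing values are reported missing rather than renormalised), with an
add-one P value computed from the same permutation replicates as the
window-level test — coherent and much cheaper than a second permutation
pass. No multiple-testing correction is applied across SNPs by default;
the output carries a clearly auxiliary BH-adjusted column for convenience.

## The simulator

`simulate_dataset()` / `astruct_simulate()` generate the benchmark the
caller is tested against. Each transcript (default 500 nt, a SNP at its
middle) gets a paired/unpaired mask from a stochastic stem-loop tiler:
hairpin modules (stems 3–6 bp, loops 3–8 nt, Poisson-length unpaired
spacers) tiled until the sequence is exhausted, with spacer length chosen
so the expected unpaired fraction matches the target (default 0.5). The
tiler also emits the corresponding dot-bracket string, and externally
computed structures can be supplied as dot-bracket via
`parse_dotbracket()` — the pipeline only ever consumes the mask.
Non-ASRS transcripts share one mask between alleles; ASRS transcripts get
an independently resampled alt mask, required to differ at ≥ 10 positions
within ±25 nt of the SNP so the difference is visible inside a
read-length-limited window.

Read counts per transcript, arm and replicate are Poisson. Control reads
start uniformly; a fraction `stop_rate` (default 0.3) of treated reads are
RT-stop reads whose start is one base 3′ of a uniformly chosen unpaired
base of their allele's mask — the stop intervention spread evenly across
unpaired bases — while the rest start uniformly, mimicking background
termination. Reads carry their allele's base at the SNP; alleles are
sampled 1:1. With `astruct_simulate()` the data are written as a reference
FASTA plus sorted, indexed BAM files (two replicates per arm) and a
plain-text truth manifest, so benchmarks exercise the same BAM-reading
path as real data.

What the simulator does *not* emulate: sequencing errors, spliced
alignments, PCR duplication, transcript-abundance variation, strand
mixtures, or thermodynamically realistic structures. Passing benchmarks
therefore demonstrate that the statistical machinery recovers planted
allelic differences at realistic coverage — not that any particular wet
protocol will achieve the same operating point.

## Coverage tiers and problem sizes

Published genome-wide read totals do not translate to a desk-scale
benchmark, so coverage tiers are expressed as mean reads per transcript
per arm per replicate. We calibrated the tier grid on the caller's
AUC-versus-coverage curve: discrimination on this generator leaves chance
level around 400–600 spanning reads per site and saturates near 2,500.
The default grid 2,500 / 5,000 / 10,000 reads per transcript (about 600 /
1,300 / 2,500 SNP-spanning reads per site) therefore starts at the lower
end of the caller's useful operating range — the regime a lowest-depth
experiment occupies — and spans to saturation. The packaged benchmarks use
200 transcripts (50% ASRS) at the lowest tier and 80 transcripts for the
depth series, with 200 permutations per site; the test suite's calibration
check uses 300 structure-sharing sites and verifies that the fraction with
P ≤ 0.05 stays within the binomial 99% band around 0.05.

## Design choices worth knowing about

- **Coordinates** are 1-based closed throughout, the R/Bioconductor
  convention; conversion happens only inside the BAM layer and at the
  bedGraph boundary (0-based half-open).
- **Replicates** are pooled within each arm by default — the retention
  filters are coverage-hungry and the statistics operate on pooled counts.
  `pool_replicates = FALSE` calls each replicate pair separately instead;
  how replicates should best be combined is genuinely open.
- **Strandedness**: the RT-stop base is `start − 1` in transcript
  orientation. For minus-strand libraries set `library_strand = "-"`
  (stop at `end + 1`); the package does not guess per-read strand.
- **Duplicate handling** is assumed done upstream (duplicate-collapsed
  input); duplicate-flagged BAM records are skipped.
- **Window envelope** is computed over allele-informative spanning reads
  only, since those are the reads the statistics use.
- **Permutation granularity**: the null re-runs the full scoring chain per
  permutation rather than permuting finished profiles; the profiles are
  strongly nonlinear in the read sets (percentile normalisation,
  clamping), so permuting profiles would not give a valid exchangeable
  null.

## Limitations

- The method needs deep spanning coverage; at ≤ 10 spanning reads per
  allele the permutation test has little power, and calls are dominated by
  the Low group.
- RT-mutation (mutational-profiling) chemistries encode structure in
  mismatches, not stop positions, and are out of scope.
- Spliced reads are handled by their alignment span when defining windows
  and background, which can overstate background across introns for
  genome-aligned data; transcriptome-space alignments avoid this.
- The per-base StrucDiff P values reuse the window-level permutations;
  they are coherent with the window test but not independent of it.

## A worked example

```{r example}
sim <- simulate_dataset(sim_config(n_transcripts = 12, seed = 7),
                        tier = 2500)
res <- astruct_call(sim$reads, sim$snps, n_perm = 100, seed = 1)
glance(res)
tidy(res) |>
  inner_join(sim$manifest, by = "snp_id") |>
  select(snp_id, esdc, p_value, astruct_score, group, is_asrs) |>
  arrange(desc(astruct_score)) |>
  head()
evaluate_auc(res, sim$manifest)
```
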