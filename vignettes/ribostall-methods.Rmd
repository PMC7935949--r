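---
title: "Detecting ribosome stalling with ribostall: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ribosome stalling with ribostall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostall)
```

## Overview

`ribostall` quantifies where and how strongly ribosomes stall on mRNA,
starting from transcriptome-space alignments of ribosome-protected
fragments (RPFs, Ribo-Seq) and matched RNA-Seq, plus polysome-gradient UV
traces. The pipeline covers six analyses that together characterize a
stalling phenotype:

1. **P-site calibration and periodicity QC** — placing each footprint's
   peptidyl-site codon and checking 3-nt phasing.
2. **Gene-level occupancy counting** — weighted exon-union counts of RPFs
   over CDS and mRNA reads over whole transcripts, TMM-log2 normalized.
3. **Translational-control classification** — per-gene tests of RPF,
   mRNA, and mRNA-adjusted translation changes, sorted into six
   categories.
4. **Single-codon pause calling** — windowed fold-over-background scoring
   with replicate-consensus and genotype-exclusive set logic.
5. **5'/3' density-shift detection** — the center of ribosome density per
   transcript, regressed case against control.
6. **Polysome run-off quantification** — polysome/monosome (PS/MS) area
   ratios over a harringtonine time course.

Every stage is exercised against a synthetic-data generator that plants
known offsets, pauses, skews and effects, so each claim the package makes
is backed by a recovery test with known truth.

## The coordinate model

All internal coordinates are 0-based half-open in transcript space; GTF
input (1-based inclusive) is converted once at the boundary. A transcript
model is `(length, cds_start, cds_end)` with the CDS spanning start codon
through stop codon, length a multiple of 3. Reads are single-end and
forward-strand (transcriptome-space libraries); reverse-strand records
are dropped and tallied.

## P-site assignment

The P-site of a footprint of length `l` with 5' end at `pos5` is
`pos5 + offset(l)`. Two offset modes mirror the two analysis arms:

* **fixed** (default 14 nt for counting): every length maps to 14.
* **metagene** (default for pause calling): for each read length the
  histogram of 5' end distances to the start codon is scanned over
  distances −20..−8 nt; the offset is the negated argmax, i.e. the spike
  produced by initiating ribosomes. Ties break toward the smaller offset
  and are messaged. Lengths with fewer than `min_reads` (default 100)
  window reads fall back to 14 with a warning.

The generator plants an initiation-peak weight (`init_peak_fold`,
default 10) on the start codon — the start-codon accumulation
characteristic of cycloheximide-arrested libraries — because that peak is
precisely the feature metagene calibration locks onto; with a flat
metagene profile there is nothing to calibrate against. An optional
`jitter_merge` flag sums counts at adjacent distances before the argmax
to absorb ±1-nt 5'-end heterogeneity from nuclease trimming; it is off by
default and is a pragmatic stand-in, not a reconstruction of any
particular trimming model.

Weighted P-site mass per nucleotide forms the coverage profile. Unique
reads weigh 1; a read reported at `k` locations weighs `1/k` at each if
`k ≤ 3`, and is discarded entirely beyond that cap. The location count
comes from the `NH` tag when present, otherwise from read-id multiplicity
within the file (aligners that report all alignments emit one line per
location).

## Counting and normalization

RPF counts include a read iff its P-site lies in `[cds_start, cds_end)`;
mRNA counts include a read iff its 5' end lies on the transcript. Counts
are gene-level (exon union): transcript counts are summed over a gene's
isoforms after collapsing duplicate read assignments, so a read hitting
two isoforms of one gene counts once. Fractional weights stay fractional
throughout.

Normalization is trimmed-mean-of-M-values (TMM) with the standard 30%
trim on log-ratios, 5% on abundances, precision weights, and the
reference column whose upper quartile is closest to the mean upper
quartile, computed via edgeR and rescaled to geometric mean 1. The
normalized value is `log2((count + 0.5) / (lib_size * factor) * 1e6)`.
The pseudocount of 0.5 stabilizes low counts but makes exact scale
invariance hold only asymptotically; the package's invariance tests
therefore use deep libraries where the pseudocount is negligible.

## Translational-control classification

For each gene, three statistics are computed on normalized values with
`n ≥ 2` replicates per condition:

* `p_rpf`, `p_mrna`: pooled-variance two-sample t-tests on RPF and mRNA.
* `p_translation`: per-gene analysis of covariance — normalized RPF
  regressed on normalized mRNA plus a condition indicator, testing the
  condition coefficient. This captures the ribosome-occupancy change not
  explained by the mRNA change (analysis of partial variance). We chose a
  plain per-gene ANCOVA rather than a hierarchical random-variance
  shrinkage model: with the three-versus-three designs this package
  targets it is the minimal defensible estimator of the same conceptual
  quantity, its null behavior is exact under normality, and it has no
  tuning parameters. The cost is less power at very small variance genes;
  the type-I simulations in the test suite confirm nominal calibration
  (fraction of null `p_translation < 0.05` within [0.03, 0.07] at 2000
  genes).

Genes with zero within-group variance but unequal means are flagged
(`NA` p) rather than assigned an arbitrary p-value. Benjamini–Hochberg
q-values are computed per test; flagged entries are excluded from the
ranking and reinserted as `NA`.

An axis (RPF or mRNA) counts as changed when `|log2FC| > log2(2)`,
`p < 0.05`, and `q ≤ 0.15` — thresholds exposed as `fc_min`, `p_max`,
`fdr_max`. The `fdr_max` gate is read as a q-value ceiling applied
jointly with the nominal-p gate. The sign pattern of the two axes maps
onto six categories (RPF up/mRNA same, RPF same/mRNA down, RPF down/mRNA
same, RPF same/mRNA up, both up, both down); axes significant in opposite
directions fall outside the six and are reported as `unchanged` with a
`discordant` flag.

## Pause calling

For each position `i` of a P-site profile, the background is the mean
count over a `W = 1000` nt window centered at `i`. Three numerical
choices are deliberate and documented so the worked example is exact
(spike 20 on background 2 scores `20 / ((999*2 + 20)/1000) = 9.911`):

* the window **includes position `i` itself** — simpler and slightly
  conservative, since the spike inflates its own background;
* windows are **clipped at transcript ends** and the clipped window's
  true length divides the sum (no zero padding);
* the score threshold is **inclusive** (`score ≥ 5` is a call).

A call additionally requires window coverage (fraction of window
positions with any read) of at least 5% — the "window coverage 5"
parameter is interpreted as a percentage, and remains configurable since
the upstream tool exposes it ambiguously. Calls are restricted to the
CDS so every pause has a codon identity; within a codon only the
maximal-score nucleotide is kept. Output carries both nt and codon
coordinates because published pause positions do not always state which
system they use.

One caveat the synthetic tests make explicit: on strongly frame-biased
profiles (frame-0 fraction near 1) the centered-mean background averages
over the two near-empty frames, which inflates every in-frame position's
score roughly threefold. Planted-pause recovery is tested on such
profiles (a fold-10 pause scores ≈ 30 and is found in ≥ 95% of runs at
depth 10⁴), while false-positive behavior is assessed on uniform
backgrounds, where the expected false calls per run at fold 5 / coverage
5% is below one. Thresholds on real, frame-periodic data should be read
with that inflation in mind.

Consensus pauses are `(transcript, codon)` pairs called in all `n`
replicates (`k`-of-`n` configurable); exclusive pauses are the case
consensus minus anything called in any control replicate. The
relative-position distribution places each paused codon at
`(codon_index + 0.5) / n_codons`, so a mean below 0.5 indicates pauses
concentrating toward the 5' end.

## Center-of-density shift analysis

The center of ribosome density of a transcript is the CDS-relative
position at which the interpolated cumulative P-site mass reaches half
the total, with per-nucleotide mass treated as uniform over `[j, j+1)`.
When the half-mass point falls on a zero-coverage plateau the plateau
midpoint is used, making the measure exactly antisymmetric under profile
reversal (`rho -> 1 - rho`) and exactly scale-invariant. Transcripts with
CDS mass below `min_mass = 10` are excluded: the sampling variance of the
center explodes at low counts.

Replicate-mean centers for the case condition are regressed on the
control condition by ordinary least squares across transcripts (this
across-transcript reading matches a scatter of per-transcript mean
density positions, case versus control). A transcript is labeled
`shift5` / `shift3` when its residual lies beyond ±2 residual standard
deviations — the published analyses this mirrors do not state their
decision rule, so counts of shifted genes are rule-dependent and the
package treats the `k_sd = 2` boundary as an explicit, tunable choice.
Recovery tests plant a −0.2 center shift (via geometric codon weights
`rate^codon_index`, with `skew_rate_for_rho()` solving the rate for a
target center) in 10% of 500 transcripts and require ≥ 90% of planted
transcripts labeled `shift5` with ≤ 5% of nulls labeled.

## Polysome traces

UV (A254) traces are baseline-corrected either by subtracting the
straight line through the mean levels of the first and last 2% of points
(the signal-free gradient edges; means rather than minima so that noise
does not bias the baseline low and inflate areas) or by a running
minimum; negative residuals clip to zero. Monosome (80S) and polysome
regions are integrated by the trapezoidal rule — robust to irregular
fraction grids — and summarized as the PS/MS ratio, which is invariant
to uniform absorbance scaling. Region boundaries are user input, as in
manual peak-chart workflows; `suggest_boundaries()` proposes the valley
between labeled peaks. The run-off comparison tabulates PS/MS by
condition and timepoint, reports per-timepoint case-minus-control
contrasts, and checks monotone decline — the signature of elongating
ribosomes completing after an initiation block, collapsing polysomes
into monosomes.

## The synthetic-data generator

The generator emulates the features the pipeline measures: 26–32 nt RPFs
with per-length offsets in [10, 16] (defaults centered on 14 at length
29), tunable frame-0 fidelity (default 0.9), a 10× initiation peak,
planted single-codon pauses of known fold, per-transcript geometric
density skew, multi-mapping at 2–4 locations (default 5% of reads,
copies placed uniformly on other transcripts, one true origin), and
Poisson read depth per transcript (default 1000; exact mode for
noise-free checks). Count matrices are negative-binomial (default
dispersion 0.1, log-normal baseline means around 150) with
category effects applied multiplicatively at linear fold 4 in the
standard test configuration of 3 + 3 replicates and 2000 genes. UV
traces are Gaussian peaks plus linear baseline plus white noise, with
analytic areas (`amplitude * sigma * sqrt(2*pi)`) as truth.

What it does **not** emulate — and hence what passing tests do not show
about real data: sequence-dependent ligation and PCR bias, nuclease
footprint-end heterogeneity beyond the optional ±1 jitter, UTR and
stop-codon occupancy structure, isoform-sharing genes (each synthetic
transcript is its own gene, so the isoform-deduplication path is covered
by hand-built fixtures instead), overdispersion structure beyond a single
NB dispersion, and correlated replicate effects. Problem sizes in the
test suite (tens to hundreds of transcripts, depths 300–10⁴, 2000-gene
matrices, 100-seed sensitivity sweeps) were chosen as the smallest at
which the planted signals are statistically decisive.

## Degenerate inputs and edge policies

* Annotation: transcripts without a CDS, or with CDS length not a
  multiple of 3, are excluded with a warning; duplicate ids are an error.
* A read length with no offset entry is an error naming the length —
  silent defaults would corrupt every downstream position.
* Empty profiles yield zero pause scores, flagged (not zero) frame
  fractions, and `NA` centers of density.
* All-zero count columns are an error in TMM; a zero-mass monosome
  region leaves the PS/MS ratio undefined and flagged.
* `run_all()` halts naming the failing stage, retains partial outputs,
  and records per-stage filter tallies and md5 checksums in a JSON
  summary; reruns with the same configuration are checksum-identical.
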