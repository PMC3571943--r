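---
title: "Methods and design notes for readqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for readqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readqc)
```

## Scope and model

`readqc` assesses and filters Illumina short reads in FASTQ form. The
underlying error model it assumes is the standard phenomenology of
sequencing-by-synthesis: per-base errors are *cycle*-correlated (cycle
*i* produces position *i* of every read, and phasing noise accumulates,
so quality decays toward the 3' tail), and *tile*-correlated (a chip
defect or bubble degrades all reads from one physical sub-region of a
lane). Quality is expressed throughout as integer Phred scores
Q = −10·log₁₀(p_error), decoded from FASTQ as `ASCII − offset` with
offset 33 or 64.

The assessment engine is a single-pass accumulator (`qc_stats()` /
`qc_accumulate()`) whose state is a set of count matrices:

* `cycle_qual[c, q]` — reads with score `q` at cycle `c`;
* `cycle_base[c, b]` — reads with base `b` ∈ {A,C,G,T,N} at cycle `c`
  (lowercase is accepted; every non-ACGT character is tallied as N);
* length and floor-of-mean-quality histograms;
* `tile_qual[t, bin]` — reads per tile per mean-quality bin.

Counting has two structural properties the tests rely on: it is
**order-invariant**, and it is **mergeable** — accumulating two disjoint
chunks and adding the accumulators (`qc_merge()`) is identical to a
single pass. The merge property is the contract under which chunked or
parallel processing could be added without changing any result; the
package itself runs single-threaded.

## Definitions and numerical choices

**Read quality.** The quality of a read is the arithmetic mean of its
Phred scores. This matches common QC practice and keeps the statistic
interpretable on the score scale, but note it is *not* the
error-probability average (which would be dominated by the worst bases);
users who need that can derive it from the per-cycle table. A length-0
read has undefined mean quality: it is counted in the length histogram
and in a dedicated `NA` category of the quality distribution, and takes
part in no tile or correlation statistic (0/0 is never formed).

**Per-cycle quantiles.** Quantiles in `cycle_quality_summary()` are
computed from the per-cycle score histogram by weighted linear
interpolation between closest ranks — the convention of
`stats::quantile(type = 7)` — so they are deterministic, exact on small
inputs, and reproducible across platforms. For `{10, 20, 30}` the
summary reports median 20, q1 15, q3 25. The table carries
min/p10/q1/median/q3/p90/max/mean so any whisker convention can be drawn
downstream; the bundled box chart uses p10/p90 whiskers. Cycles reached
by zero reads are emitted with `n = 0` and `NA` statistics rather than
dropped or errored.

**Tile bins.** The per-tile chart bins mean quality into
`[0,10), [10,20), [20,30), [30,∞)`. Decade bins are the conventional
choice for this chart and make a failed tile (mean ≈ 6) visually
unambiguous; the edges are overridable via `qc_stats(bin_edges =)` and
the `--bins` flag.

**Pair correlation.** "Correlation between the two ends" is Pearson's r
on per-read mean quality — the default reading of an unqualified
correlation, and directly comparable across runs. Because r is blind to
nonlinearity, the report also contains the joint histogram of the two
means in unit bins. With fewer than two usable pairs or zero variance on
either end, r is reported as undefined (`r_defined = FALSE`) rather than
`NaN`; the joint histogram is still emitted.

**Encoding detection.** The offset is inferred from the extreme ASCII
codes of up to 10 000 records: any code < 59 proves phred+33 (phred+64
cannot encode below 64, and even Solexa's legacy scale stops at 59); a
minimum ≥ 64 indicates phred+64. Codes confined to the ambiguous band
[59, 63] — possible only for phred+33 data of uniformly very high
quality — default to offset 33 with a warning and a low-confidence flag,
because phred+33 dominates modern data. A `--phred 33|64` override is
always available, and the heuristic is never silently applied to
standard-input streams (no rewinding).

**Trimming.** `trim_reads()` removes the maximal prefix and/or suffix
in which *every* base scores below the threshold, i.e. bases are cut
from the chosen end(s) until the quality score reaches the threshold.
This per-base rule (rather than a sliding-window rule) is the literal
reading of "trim until the threshold is reached"; windowed trimming is
deliberately out of scope. Consequences tested for: the output is always
a contiguous substring, the boundary bases of a non-empty result meet
the threshold, and the operation is idempotent. Tail-only trimming is
the default because tail decay is the motivating defect; head trimming
is opt-in. A read may be trimmed to length 0 and is still emitted —
stages stay pure, and the CLI prints a note when `trim` runs without
`--min-length` — so that a downstream length filter, not the trimmer,
decides its fate.

**Quality filter.** "Low quality read" is implemented as the
conjunction of two individually disableable criteria: mean score below
`min_mean_quality`, and more than `max_low_qual_fraction` of bases below
`lowq_base_threshold`. The second criterion exists because a mean
threshold alone cannot reject a read with a long N-run (30 bases at
score 2 inside an otherwise 38-quality 100-mer still averages ≈ 27)
without also rejecting genuinely acceptable reads.

**Chastity flag.** The CASAVA 1.8 `filtered` field is parsed and
retained but never acted on implicitly; `drop_chastity_failed = TRUE`
(or `--drop-chastity-failed`) enables it explicitly.

**Paired-end routing.** Each end is judged independently; a pair lands
in exactly one of four categories (both kept / end-1 singleton / end-2
singleton / both dropped), so
`pairs_in == pairs_kept + singletons_1 + singletons_2 + dropped` holds
exactly. Singletons — surviving mates of broken pairs — go to
`<prefix>_single_1/2.fastq`, keeping the main outputs synchronized.

**FASTQ dialect.** Only 4-line (unwrapped) FASTQ is supported, and the
parser is positional. This is what makes a `@` or `+` at the start of a
quality line safe — a content-sniffing parser can split or merge records
there. Multi-line FASTQ is rejected with an explicit message. Gzip is
recognized from magic bytes, not the file name. Coordinates and cycles
are 1-based in every table and chart, matching Illumina reporting;
internal storage is 0-based where natural (score histogram columns).

**Report files.** Each statistic is one TSV with a single `#`-prefixed
column-header line (optionally preceded by `#` metadata lines, e.g. the
Pearson r of the correlation table), deterministic row order, numbers
printed with `%.17g` so re-parsing reproduces every double exactly, and
atomic writes (temp file + rename) so a failed run leaves no partial
table. Charts (`draw_chart()` / `draw_all()`) read *only* these files;
the tables are the stable interface and work in any spreadsheet tool.

## The synthetic-read generator

`fixture_spec()` defines the study conditions under which the package is
exercised; `simulate_reads()` / `generate_fixture()` expand them
deterministically from a mandatory seed (there is no unseeded path, and
the caller's RNG state is restored).

The quality model for read *i*, cycle *c* is

> Q(i, c) = round( m(c) + δᵢ + ε ), clipped to [2, 41]

where `m(c)` decays linearly from `qual_start` (default 38) to
`qual_end` (default 20) — the routine tail decay of a long Illumina
run — `δᵢ ~ N(0, read_sd²)` (default sd 2) is a per-read shift making
some reads globally better than others, and `ε ~ U(−noise, noise)`
(default 3) is per-base noise. Because δ and ε are symmetric about zero
and rounding/clipping are monotone, the per-cycle *median* of the
population stays on the specified curve, which is what makes median
recovery a meaningful check. Tiles are uniform on `1:n_tiles`;
`bad_tiles` replaces `m(c)` with a flat override for the affected tiles
(both ends of a pair — mates come from the same cluster). N-runs write
`N` at score 2, the Illumina no-call convention. Bases are otherwise
uniform ACGT: the generator emulates *quality* phenomenology only, not
sequence content, adapters, duplicates or a realistic substitution
model — so passing tests demonstrate correct accounting and recovery of
injected quality defects, not performance on any particular genome.

For a target end correlation ρ the per-pair shifts are generated as
`δ = read_sd · (√ρ′·u + √(1−ρ′)·v)` with shared `u`, using a latent
`ρ′ = ρ·(read_sd² + σ²_ε̄)/read_sd²` that compensates analytically for
the variance the averaged per-base noise `σ²_ε̄ = (noise²/3 + 1/12)/L`
adds to each mean. At 5 000 pairs the realized r lands within ±0.05 of
the target. Two caveats are inherent to the model: heavy clipping (median
curves near 2 or 41) attenuates r slightly, and `bad_tiles` overrides
add a *shared* variance component (both mates collapse together) that
inflates the realized correlation beyond the target — the calibration
deliberately does not try to undo either, since both are faithful to the
physics they emulate.

The truth sidecar records per-read tile, N-run membership and the mean
quality *recomputed from the emitted quality strings* (not the latent
values), plus the median curve as metadata, so tests can cross-check the
FASTQ against it exactly.

## Verification strategy and problem sizes

Every table the accumulator produces is compared cell-for-cell against
independent brute-force recomputations written as plain nested loops
(no shared code) on fixtures of 200–1 000 reads. Trimming is checked
exhaustively against a longest-valid-substring oracle over all quality
strings of length ≤ 6 on scores {2, 20, 40}, and for idempotence on
10 000 random reads. Parameter recovery uses 10 000 reads for the
38→20 median decay (tolerance ±1 score unit at every cycle), 6 000 reads
over 120 tiles for failed-tile isolation (≥95 % of a failed tile's reads
in the lowest bin), 5 000 pairs for correlation recovery (±0.05), and
100 generated files for encoding detection. CLI subcommands are checked
byte-for-byte against the equivalent library calls. These sizes keep the
whole suite under a minute on one core while leaving comfortable margins
over the estimators' sampling noise (the sample median's standard error
at n = 10 000 is far below the ±1 tolerance; the standard error of r at
n = 5 000 is ≈ 0.009 against ±0.05).

## Known limitations

* Single-threaded; the merge property documents how parallelism would be
  added, but none is implemented.
* FASTA, SAM/BAM, color-space, interleaved FASTQ and the Solexa log-odds
  quality scale are out of scope, as are adapter trimming, duplicate
  detection, k-mer statistics and quality recalibration.
* `read_fastq()` materializes a file in memory; files far beyond ~10⁷
  reads should be processed in chunks via `qc_merge()`.
* The generator's bases are content-free (uniform ACGT), so it cannot
  exercise composition-bias diagnostics beyond injected N-runs.
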