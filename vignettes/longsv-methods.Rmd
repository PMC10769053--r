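---
title: "Validating structural variants from long-read alignments: the longsv method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating structural variants from long-read alignments: the longsv method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Long-read SV callers report many candidates that the underlying reads do
not actually carry, and many whose length is badly wrong — both failure
modes concentrated in tandem-repeat regions, where short-window sequence
matching misplaces reads and splinters one variant into several alignment
artifacts. `longsv` treats validation as a read-counting problem: a
candidate SV is real exactly to the extent that individual reads spanning
the whole locus carry alignment evidence of the right type and size.

This vignette is the package's own account of the model, its parameters,
the numerical choices made where the design was open, and the limits of
what the bundled synthetic data can demonstrate.

## The model

For each candidate SV at `[start, end)` with length `L`:

**Screening.** Only reads whose best alignment has MAPQ ≥ 20 are
considered (repeat placements usually carry MAPQ 0), and a read must
traverse the full flanked window — cover both `start − flank_len` and
`end + flank_len − 1`, with `flank_len` = 1000 bp by default — before it
may vote. The union of a read's primary and supplementary segments counts:
a read split into pieces that jointly bridge both flanks still carries
usable evidence, whereas a read touching only one side could at best
witness a partial, possibly wrong variant. The screened reads are the
denominator of everything that follows.

**Length tolerance.** A read never implies an SV length exactly. All
channels accept an implied length `n` for a candidate of length `L` when
`| n − L | ≤ d(L)` with

```
d(L) = 0.2 * L + 2000 / L    [bp]
```

The linear term allows proportional slop on large events; the `2000/L`
term gives small events the absolute slack that noisy long reads need.
The function is minimized at `L = 100` (both terms equal 20 bp), which is
tested analytically.

**CIGAR channel (DEL/INS).** On the read's longest segment, every I/D
operation of ≥ 30 bp whose anchor lies inside the flanked window is
summed, insertions positive and deletions negative. Working with the
*net* is deliberate: in repeats a single 500 bp deletion routinely
appears as 300 + 200 or similar nearby fragments, and the net recovers
the event the fragments jointly encode. Operations under 30 bp are the
ordinary indel noise of long reads and are excluded. The candidate is
supported when the net's sign matches its type (an insertion cluster must
never validate a deletion) and the magnitude passes `d(L)`.

**Split channel (DEL/INS).** For a read aligned in two same-chromosome,
same-strand segments, `diff = read_distance − ref_distance` between the
segments (reference distance measured in the read's direction of travel,
so reverse-sequenced reads give identical answers). `diff > +200` is an
insertion-like signal, `diff < −200` deletion-like; magnitudes within
±200 bp are alignment jitter and never count. A signal of the right sign
passing `d(L)` supports the candidate.

**Inversions.** An inversion changes no lengths, so both indel channels
are blind to it. Two geometries are used instead:

- *Forced-through reads* (one alignment segment covering `[start, end)`):
  the read sequence projected onto the interval is compared with the
  forward reference segment (edit distance `noise1`) and with its reverse
  complement (`noise2`); support requires `noise1/L ≥ 0.3` and
  `noise2/L ≤ 0.2` — unlike the forward strand, like the inverted one.
- *Split reads*: three segments on one chromosome with strand pattern
  (s, −s, s) in query order and the middle segment inside the interval;
  the gap between the outer segments (taken in genomic order) must match
  `L` within `d(L)`. Inversions too large for any read to traverse leave
  two-segment strand-discordant reads at each breakpoint; the distance
  between homologous segment ends is tested the same way.

**Classification.** With `support_rate = support_reads / total_reads`:
rate ≥ 0.8 → `HOMOZYGOUS`; 0.1 ≤ rate < 0.8 → `HETEROZYGOUS`;
rate < 0.1 → `FALSE`. Both boundaries are closed from below (a rate of
exactly 0.8 is homozygous, exactly 0.1 heterozygous); the published rule
prints overlapping ranges, so the tie-break had to be fixed somewhere, and
the closed-lower-bound convention is stated once here and tested. A locus
with zero screened reads is reported as `NO_READS` rather than `FALSE`:
absence of evidence is not evidence of absence.

**Corrected SVs.** When a candidate is `FALSE` but its locus still
carries signal, the non-supporting reads whose implied indel length is
≥ 50 bp in magnitude are pooled. If they agree in sign and exceed 10% of
the screened reads, the rounded mean of their |implied lengths| is
emitted as the corrected SV (typed DEL or INS by the sign). The
sign-agreement requirement is the package's own addition: averaging a
mixture of insertion-like and deletion-like evidence would produce a
number describing nothing.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `flank_len` | 1000 | bp | spanning requirement each side of the SV |
| `mapq_min` | 20 | — | best-segment mapping-quality screen |
| `min_cigar_indel` | 30 | bp | smallest CIGAR op counted as SV evidence |
| `coverage_multiplier` | 5 | × | high-coverage filter threshold (strict) |
| `n_coverage_samples` | 1000 | — | positions behind the coverage estimate |
| `split_diff_threshold` | 200 | bp | split-distance signal gate |
| `hom_threshold` / `false_threshold` | 0.8 / 0.1 | — | genotype boundaries |
| `alt_support_fraction` | 0.1 | — | corrected-SV quorum (strict) |
| `inv_fwd_noise_min` / `inv_rev_noise_max` | 0.3 / 0.2 | — | inversion noise criteria |
| `min_alt_sv_len` | 50 | bp | SV size floor for the corrected cluster |

The coverage filter compares with *strictly greater than* 5 × average
(a region at exactly the threshold is kept), and its region statistic is
the mean over the SV span — for insertions, over ± 500 bp around the
breakpoint — which is robust to single-base spikes. "Sampled positions"
are drawn uniformly over the concatenated genome, contigs weighted by
length; coverage counts primary plus supplementary records of any MAPQ,
since the filter targets pile-up regions where MAPQ is precisely what
cannot be trusted.

## Coordinates and file dialects

All internal positions are 0-based half-open; BED input is read as
0-based half-open (the end column exclusive — the dialect leaves this
ambiguous, and the choice is recorded here), SAM's 1-based positions are
converted at the reader boundary. The SV BED dialect is
`chrom, start, end, type[, length][, id]`; a missing length is derived as
`end − start` for DEL/INV, and insertions are breakpoint records
(`end = start + 1`) with an explicit length. A minimal VCF adapter maps
`SVTYPE`/`SVLEN`/`END` into the same table. Secondary alignments are
dropped (redundant placements), supplementary ones kept (the split
channels need them); query coordinates are normalized to the forward
orientation of the read so both segments of a split read live on one
axis.

## The simulator

The generator exists so that every claim the test suite makes can be
checked against construction-time truth, with no aligner and no external
data. It emulates:

- a single-contig genome (default 200 kb) of i.i.d. ACGT with
  tandem-repeat blocks (random ~24 bp unit, ~2 kb blocks) totalling 30%
  of the sequence;
- 20 homozygous + 20 heterozygous SVs cycling DEL/INS/INV, lengths
  uniform in 200–1000 bp, non-overlapping with 3 kb separation;
- reads of mean 15 kb (sd 1.5 kb) at 30× total depth, emitted directly
  as ground-truth SAM: implanted indels become I/D operations, deletions
  ≥ 2.5 kb split primary/supplementary pairs, inversions > 400 bp
  three-segment strand-discordant reads and smaller ones forced-through
  match segments whose sequence is the reverse complement of the
  reference;
- per-base sequencing errors (60% mismatches, 40% short 1–3 bp indels)
  injected consistently into sequence and CIGAR; an optional
  fragmentation mode splits each implanted indel's CIGAR op in two with a
  20 bp spacer, imitating repeat-region alignment splinters while leaving
  the net length intact.

Two regimes are used throughout: the clean reference condition (30×,
error rate 0) and a stressed condition (5×, 10% per-base error) matching
the low end of long-read accuracy. SV lengths start at 200 bp for a
reason tied to the false-call benchmark: for candidates much below
~150 bp, a ×0.3 or ×0.4 length error still falls inside `d(L)` of the
truth, so the mis-sized call is *correctly* accepted by the model's own
tolerance — the multiplier construction only yields a meaningful
false-call list for SVs of a couple hundred bp and up.

The false-call generator scales each true DEL/INS length by a multiplier
drawn from {0.1, 0.2, 0.3, 0.4, 2, 3, 4, 5}, locus midpoint fixed; the
minimum relative length error over the set is 60% (at ×0.4), so every
false call is at least 50% wrong. Inversions are not used as sources: an
inversion interval scaled down about its own midpoint is, by mirror
symmetry, *itself a real inversion signal* (the reverse complement of the
centred sub-interval matches the read exactly), so such a record is not
false in any evidence-accessible sense.

What the simulator does **not** model: platform-specific error spectra
(homopolymer compression, chimeras), mapping ambiguity (every record
carries MAPQ 60, so the MAPQ screen is exercised only by hand-built
fixtures), soft-clipped reference-allele breakpoint reads, duplications
and translocations, and nested or adjacent complex events. Passing tests
on this data therefore demonstrate the correctness of the decision logic
under controlled evidence, not end-to-end accuracy on real ONT/PacBio
alignments.

## Numerical choices and degenerate inputs

- Tolerance boundaries are inclusive (`≤` throughout), including the
  noise fractions 0.3/0.2 and the ±200 gate (a difference of exactly
  ±200 is *not* a signal).
- The CIGAR channel uses the read's longest segment; when a read could
  support through both channels, CIGAR is tried first and the first
  support wins.
- Insertion anchors are the reference base immediately left of the I
  operation; a deletion op is located by its left edge.
- Edit distances are unit-cost Levenshtein (`utils::adist`); "reverse"
  of the reference segment means reverse *complement* — a genomic
  inversion is the reverse complement, and a plain reversal would never
  match real inversion-carrying reads.
- Windows are clamped at contig boundaries; an SV on a contig absent
  from the BAM yields a warning and `NO_READS`; per-SV internal failures
  degrade to `NO_READS` with a warning rather than aborting the batch.
- Identical inputs and seed give bit-identical outputs, including file
  bytes.

## Evaluation conventions

Truth matching (same type, breakpoint distance ≤ 1000 bp, length ratio
≥ 0.5, greedy nearest-first one-to-one) uses the package's own defaults —
published benchmarks rarely state theirs precisely — and both thresholds
are exposed. `NO_READS` and `FILTERED_HIGH_COVERAGE` count as not-found
for recall: from the caller's point of view the SV was not validated.

The test suite and the acceptance script run the clean condition
(zygosity recovery ≥ 95%, complete false-list rejection, exact
corrected-length recovery) and the stressed condition (≥ 80% zygosity
accuracy at 5× / 10% error, the shortfall coming from binomial noise on
the handful of spanning reads a 5× genome affords — the same
coverage-versus-confidence trade-off any read-counting genotyper shows).
Problem sizes (200 kb, 40 SVs, 30× and 5×) were chosen as the smallest
conditions in which all three SV types, both zygosities, both evidence
channels, and the repeat stratum are each represented many times over.

## Known limitations

- Duplications, translocations and complex adjacent SVs are out of
  scope; the label set is {DEL, INS, INV} only.
- Loci where most alignments carry MAPQ 0 (near-identical segmental
  duplications) are invisible to the method by design of the MAPQ
  screen.
- Very large inversions are only partially covered: screening requires
  double-flank traversal, which no read achieves across an inversion
  longer than the read length, so the two-segment breakpoint geometry is
  exercised as an operation but contributes no votes under the default
  screening. Relaxing screening for that geometry is future work.
- The corrected-SV report assumes a single coherent alternative; loci
  carrying two different real SVs yield either a sign-mixed (suppressed)
  or averaged report.
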