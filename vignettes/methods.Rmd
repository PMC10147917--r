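---
title: "Detecting structural heteroplasmy in mitogenomes from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting structural heteroplasmy in mitogenomes from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoblocks)
```

## The problem

Vertebrate mitochondrial genomes are ~17 kbp circles with a conserved
gene order. In several Antarctic notothenioid fishes the region holding
the ND6 gene, the trnE and trnP tRNAs, and the control region (CR) is
tandemly duplicated, and — because mitochondria are present in thousands
of copies per cell — different molecules within one individual can carry
*different* copy numbers of that block. This structural heteroplasmy is
invisible to a single consensus assembly: the assembler collapses the
mixture into one haplotype. Long reads change the game. A continuous
long read (CLR) of 10–30 kbp spans the entire duplicated region, so each
read reports the copy number of the single molecule it came from, and the
distribution of per-read copy numbers across an individual's reads *is*
the heteroplasmy evidence.

`mitoblocks` implements that read-level analysis, plus the two analyses
expanded mitogenomes invite: tandem-repeat characterisation of control
regions and classification of gene-order rearrangements.

## Copy counting by k-mer matching blocks

Alignment of a 500-nt gene against a 15% of a megabase of noisy read is
overkill; exact k-mer matching is enough. The query gene is indexed as
its overlapping k-mers on both strands (default `k = 19`; k-mers
containing non-ACGT characters are skipped). A read is scanned for exact
occurrences, giving matches `(read_pos, query_pos, strand)`.

Two rules turn matches into gene copies:

1. **Maximum-gap clustering.** Successive matches more than
   `gap_threshold` nt apart in read coordinates belong to different
   blocks (default 800 nt at `k = 19`). This is what separates tandem
   copies of the gene, which in these genomes sit ≥ 1.2 kbp apart
   (separated by trnE, trnP and a ≥ 0.8 kbp control region).
2. **Query-coordinate resets.** If two copies sit closer than the gap
   threshold, their matches fall into one block, but the query offset
   jumps back to the start of the gene at the copy boundary. A drop of
   more than `k` (on the forward strand; a rise on the reverse strand)
   splits the block into copy segments. The gap rule is the primary
   mechanism; the reset rule adds resolution for close copies and makes
   the copy count correct down to single-nucleotide spacers.

When a query contains an internal tandem repeat (a repeat-bearing control
region used as a query during architecture decomposition), one read
k-mer can match several query offsets. A greedy nearest-diagonal pass
keeps, per read position, the match that best continues the current
trajectory, so a repeat-bearing gene is still recovered as one copy
rather than a shredded pile of segments.

### Support filters

A block is counted as a gene copy when it has at least `min_kmers`
member matches (default 5) **and** its matches cover at least
`min_query_coverage` of the query positions (default 0.10). The first
filter is the guard against chance matches: a random 19-mer collision
has probability $4^{-19}$ per pair, so five collisions clustering within
800 nt is effectively impossible. The coverage default deserves a note,
because it is lower than one might naively choose. With
indel-dominated errors at ~11% per base, error-free 19-mers are not
spread uniformly: errors arrive every ~9 nt on average, and an intact
k-mer requires a ≥ 19-nt error-free run, so intact k-mers appear in
bursts separated by "deserts" that routinely reach 150–250 nt. The
*covered fraction* of a fully present 528-nt gene is then only
0.36 ± 0.10, and a half-length truncated copy reaches ~0.18. A coverage
threshold of 0.25 would silently discard a seventh of true copies (and
nearly all noisy truncated copies); 0.10 keeps them while the k-mer
count filter continues to exclude collisions. Both filters are exposed
in `run_config()` and on the command line.

### Properties

Copy counting is orientation-invariant (a read and its reverse
complement give the same count with strands flipped), monotone in all
thresholds (raising the gap threshold never increases the block count;
raising either support filter never increases the copy count), and on
error-free constructed reads recovers 0–5 embedded copies exactly for
any spacer ≥ 1 nt. At 10% total error, ≥ 95% of constructed 3-copy reads
are counted correctly; the test suite checks all of these.

## Screening reads and anchoring the spectrum

From a whole-genome read pool, mitochondrial reads are selected by
requiring a matching block of at least `min_block` nt against the
reference mitogenome (default 5000 nt; 3000 nt is the documented choice
for samples with shorter reads). Requiring a *long* block is the NuMT
defence: nuclear insertions of mtDNA are short, so a read from the
nuclear genome matches in a block bounded by the insertion length. The
reference is doubled head-to-tail before indexing so reads crossing the
circular origin form a single block.

Copy counts are only comparable across reads that span the whole
duplicated region, so the spectrum is restricted to reads containing
both flanking anchor genes — 12S rRNA on one side and CYTB on the other
— and only copies *enclosed between* the two anchor matches are counted.
The enclosure rule matters twice over: it excludes partial gene copies
dangling at read ends, and it gives reads that traversed the far side of
the circle (which legitimately contain both anchors but no ND6 between
them) a well-defined count of zero.

A read "contains" an anchor when its matching block extends over at
least `min_anchor_span` of the gene (default 0.8). A read must
essentially contain the whole gene, not merely brush its edge; because
of the boundary deserts described above, the matched span of a fully
contained ~1 kbp anchor averages ~0.83 of the gene with a heavy left
tail, so the threshold cannot be pushed much higher without discarding
genuine spanning reads.

## The heteroplasmy verdict

The spectrum tabulates spanning reads by copy number. A class supported
by at least `min_support` reads (default 2) is *confident*; classes
below that are reported but flagged `singleton` — a single well-anchored
read can represent a rare variant and the user should see it. Class 0 is
reported but flagged `excluded` and never drives the verdict: far-side
spanning reads produce class 0 in any sample, so a deep homoplasmic run
would otherwise always be called heteroplasmic. (Complete loss of ND6
from a variant is real biology, but it is established by the
architecture module on assembled sequence, not by count-zero reads.)
The verdict is heteroplasmy when two or more confident classes with at
least one copy exist. Reads are finally partitioned by class and
exported per class (`<sample>.copies<k>.fasta`) so each variant can be
assembled independently by an external assembler; assembly itself is out
of scope.

## Tandem repeats in control regions

Control-region length variation in these genomes is driven by tandem
repeats with periods of tens to hundreds of nt and fractional copy
numbers. The finder compares the sequence against itself at every
candidate period `d` (`min_period`–`max_period`, default 10–400 nt): a
per-position agreement profile `seq[i] == seq[i + d]`, a sliding window
of length `d` over it, and maximal regions with windowed identity at or
above `min_identity` (default 0.8). Window statistics smear region
boundaries by up to ~`d/4` into random flanks, so each region is refined
to its maximal-scoring stretch of agreements (match +1, mismatch −4 —
positive drift exactly when local identity exceeds 0.8). The period
reported is the lag; copies are the TRF-style fractional count
`round(length / period, 1)`; the consensus is the column majority over
period-phased windows. A minimum of 25 agreeing positions
(`min_matches`) is required, in the spirit of TRF's minimum alignment
score: a quarter of random positions agree by chance, and short
two-copy candidates below that support are unfalsifiable. Windowed
detection needs two full periods, so fractional copy numbers below ~2.0
(`min_copies` default 1.9) mark partial trailing copies rather than
shorter arrays.

Harmonics need care. A perfect period-`p` array also matches itself at
lag `2p`, `3p`, …, so for two repeats occupying essentially the same
interval with periods `p < q = m·p` the `q`-repeat is dropped when the
`p`-repeat's identity is at least `identity(q) − 0.05`. The exception is
deliberate: when the `q`-unit is near-perfect but its internal `p`
sub-repeats have diverged (identity(q) clearly above identity(p)), both
levels are reported — this is exactly the published two-level geometry
of a 291-bp control-region unit containing three diverged copies of a
97-bp secondary repeat. Boundary resolution is ± a base or two when a
flank base happens to continue the periodicity; the fractional copy
number is stable to ± 0.1 for clean arrays and ± 0.3 under 5% point
mutation.

## Architecture decomposition and rearrangement classification

A target genome (assembly or long read) is decomposed by running the
copy-caller with every reference gene as query. Circular targets are
rotated so the trnF block (the gene conventionally written first) starts
near position 1, then scanned doubled so nothing is lost at the join.
Competing calls overlapping by more than half the shorter block collapse
to the higher-coverage one, except that tRNAs may overlap non-tRNA genes
(nested annotations are normal at rRNA margins).

Classification operates on the ordered gene-label string, not raw
sequence — robust to sequence divergence and matching how architectures
are described in the field. Tandem duplications are maximal runs of a
repeated label subsequence, with the unit taken as the shortest
repeating string (brute force; label strings are ~40 symbols). A run of
`n` unit copies also contains runs of rotated units over overlapping
spans; among rotation-equivalent events the one whose unit is a
contiguous run of the canonical gene order wins, then the leftmost.
Remnant blocks are a proper *suffix* of the duplication unit immediately
adjacent to the run (e.g. trnP/CR beside full ND6/trnE/trnP/CR copies),
reported with the missing prefix named in the evidence. Inversions are
maximal runs of two or more minus-strand blocks whose labels are in
reversed canonical order; the span is the block extent in target
coordinates, which resolves the planned extent to within `k − 1` nt.
Classification is performed on the doubled label sequence for circular
targets, making it invariant under rotation.

## The simulator

Every claim above is tested against synthetic data with known truth, so
the simulator is first-class code. A `genome_plan()` captures the
structural grammar: a duplication unit (default ND6/trnE/trnP/CR)
repeated `n_copies` times after trnT, optional frameshift insertions
into chosen copies (the published 1/3/4-base insertions), an optional
remnant suffix, an optional control-region repeat of given period and
fractional copies, and an optional inversion of a contiguous gene span.
Gene bodies are seeded random DNA at vertebrate-typical lengths (ND6
fixed at 528 nt = 175 codons + stop; CR 1000 nt unless expanded);
genuine gene sequences live in public accessions and are unnecessary for
testing structural logic, which is the module's job. Plans sharing a
seed share gene sequences, so a pool of plans models structural variants
of one individual. Intergenic spacers are 5–40 nt, except ~250 nt
between trnT and the duplicated region, as observed in these genomes.
The bundled canonical gene order places the unit genes after trnT — the
single-copy layout of the genomes being emulated.

Reads are sampled by variant frequency, uniform origin on the circle,
truncated-normal length (default mean 12 kbp, sd 4 kbp, min 1 kbp,
capped at the genome length — a cut circle yields at most a full-length
fragment), random strand, and i.i.d. per-base errors (defaults
substitution 0.01, insertion 0.06, deletion 0.04: an indel-dominated
~11% profile approximating CLR data). The error model is deliberately
the simplest that stresses the gap-threshold clustering; it has no
homopolymer bias, no chimeras, and no quality-score realism, so passing
tests demonstrate robustness to error *rate*, not to every error
*structure* of a real instrument. The truth table records, per read, the
source variant, origin, length, strand, copies wholly inside the arc,
and copies enclosed between the anchors.

### What the spectrum should look like, exactly

Observed class proportions among spanning reads are *not* the pool
frequencies: a variant with more copies has a longer genome and a longer
region to span, so its reads span less often. `expected_spectrum()`
computes the reference distribution by Monte Carlo over the same
(variant, origin, length) geometry the simulator uses — independent of
any k-mer matching — and additionally simulates the measurement: the
matched span of an anchor equals its contiguous covered length minus two
boundary-loss draws (the renewal distance from a gene edge to the first
error-free k-mer, ~83 nt on average at the default error rates, heavy
tailed), thresholded at `min_anchor_span`. A gene split across the two
ends of a near-full-circle read can only be matched by one contiguous
block, and the model respects that. End-to-end runs are then checked by
chi-square goodness-of-fit of the observed spectrum against this
expectation over the classes the generator can produce, with reads in
any other class (instrument miscalls, empirically ~0.3% of spanning
reads) bounded separately.

## Problem sizes and numerical choices

The test battery uses reads of 2000 per pool for end-to-end recovery
(spanning reads number in the hundreds, enough for class proportions),
40 trials for the error-tolerance property, 50000 Monte Carlo draws for
expectations, and single genomes for repeat/architecture recovery; the
full suite runs in about three minutes on one CPU. All randomness is
seeded; simulator outputs are bit-identical across runs with the same
seed, and the RNG state of the caller is never disturbed. Coordinates
are 1-based inclusive everywhere, the R convention. Ties in block strand
go to the member with the smallest query offset; ties in repeat period
go to the smallest period.

## Known limitations

- Exact k-mer matching cannot resolve copy boundaries below `k − 1` nt,
  and measured anchor spans understate geometric coverage by the
  boundary-loss distances described above.
- The repeat finder reports no array shorter than two full periods plus
  the `min_matches` support, and its boundaries are ±2 nt.
- Near-full-genome reads make "the region between the anchors"
  ambiguous (both arcs are present); such reads are rare under the
  default length distribution and follow whichever side the anchor
  blocks delimit.
- The simulator's i.i.d. error model and random gene bodies do not
  reproduce homopolymer error clustering, base composition, or real
  inter-gene sequence similarity; conclusions about real data should be
  drawn after running the pipeline on real reads, using the simulator
  only to validate the machinery.
- Per-variant genome assembly is exported to external tools, not
  performed.
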