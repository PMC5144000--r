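---
title: "circpipe: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circpipe: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the tunable parameters, the
synthetic-data generator and the numerical/design choices behind
`circpipe`. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute.

## 1. The splice-strength model

A back-splice junction (BSJ) joins a splice donor to an *upstream* splice
acceptor. `circpipe` decides whether a candidate junction is plausible
spliceosome output by scoring both sites under a **maximum-entropy
sequence model** and comparing the summed log-odds with a threshold.

**Windows.** A donor is represented by a 9-mer: the last 3 exonic and
first 6 intronic bases. An acceptor is a 23-mer: the last 20 intronic and
first 3 exonic bases. Both are extracted strand-aware, so a site on the
minus strand is the reverse complement of the genomic slice.

**Model family.** For a window of width $k$, the model is the unique
maximum-entropy distribution $P$ over $\{A,C,G,T\}^k$ that reproduces a
set of empirical marginals of the training windows. The default
constraint set is all position singletons plus all adjacent position
pairs. For this *chain* constraint set the solution has an exact closed
form — the first-order Markov chain consistent with the pairwise
marginals:

$$P(x_1,\dots,x_k) = p_{1,2}(x_1,x_2)\prod_{i=2}^{k-1}
  \frac{p_{i,i+1}(x_i,x_{i+1})}{p_i(x_i)}$$

which is also the fixed point of iterative proportional scaling (IPS) on
those constraints. `circpipe` therefore uses the closed form for the
default constraints at any width — this is what keeps the 23-mer acceptor
exact without ever materializing $4^{23}$ outcomes — and falls back to an
IPS loop over the fully materialized table for arbitrary constraint sets
(non-adjacent pairs), which is limited to $k \le 10$. The test suite
verifies both fitters against a brute-force convex-dual optimizer on
small windows (max absolute probability difference $< 10^{-4}$) and
verifies that the IPS fixed point equals the chain closed form.

**Smoothing.** Each imposed marginal table receives a pseudocount of 0.5
per cell before normalization (default; all probabilities strictly
positive). For chain constraints, singleton marginals are implied by the
pseudocounted pairwise tables, which keeps adjacent tables mutually
consistent. For user-supplied constraint sets of mixed arity the implied
sub-marginals can disagree slightly between constraints; IPS then stops
at the achievable deviation and warns.

**Score.** A window $w$ scores $\log_2 P_\text{model}(w) / P_\text{bg}(w)$
bits against a 0th-order background (default uniform; a per-position
background matrix is also accepted). Windows containing `N` are
unscorable and treated as $-\infty$ by callers. The junction score is the
donor score plus the acceptor score; the calling threshold applies to
this **total** (with the per-site scores also reported). The default
threshold is **10 bits**, user-definable, chosen so that the large
majority of annotated canonical junctions pass it;
`calibrate_threshold()` reproduces that check on any genome + exon
annotation by training on a random half of the annotated site windows and
scoring the held-out half. On the bundled synthetic genomes this fraction
exceeds 0.95 (asserted in the test suite); on real annotation the
function can be pointed at a genome FASTA and GTF directly.

**Training data.** The model is trainable rather than shipped as fixed
score tables: `train_splice_model()` accepts any fixed-width donor and
acceptor window sets (e.g. extracted from an annotated genome with
`annotated_site_windows()`). For self-contained use,
`simulate_splice_training()` draws windows from built-in synthetic
position-weight matrices emulating canonical GT..AG composition
(near-invariant GT/AG cores, a pyrimidine-rich tract upstream of the
acceptor); these PWMs are synthetic parameters, not estimates from any
genome. Models serialize to versioned JSON.

## 2. Junction calling

**Preprocessing.** Reads are collapsed to distinct sequences with
multiplicities, so each sequence is aligned once and each original read
(or pair) is counted exactly once downstream. Paired-end mates are merged
into one pseudo-read when the suffix of mate 1 overlaps the
reverse-complemented mate 2 by at least `min_overlap` = 10 nt with at
most `max_mismatch_frac` = 5% mismatches (values are package choices —
configurable — the merging criteria are not prescribed anywhere);
unmergeable pairs are processed as two independent reads carrying weight
0.5 each, so pair-weight totals are conserved.

**Geometry.** Chimeric alignments (primary + supplementary SAM records,
read coordinates reconstructed on the forward read, hard and soft clips
treated identically) are examined pairwise. A segment pair on one
chromosome and strand whose implied junction joins a donor to an upstream
acceptor (in transcription direction) is a BSJ candidate; collinear pairs
are linear splices and are dropped; pairs on different chromosomes or
strands — or same-strand pairs spanning more than `circ_max_span` = 1 Mb —
are examined as fusion junctions. Segments must cover at least
`min_segment` = 15 nt of the read each, and together at least
`min_read_coverage` = 90% of the read. These three values are package
choices (the source method leaves them unspecified), set to suppress
spurious short splits, and all configurable.

**Breakpoint arbitration.** Where the two segments overlap on the read
(microhomology), every partition point in the overlap — capped at
±`microhomology_window` = 10 nt around its midpoint — implies a
different donor/acceptor coordinate pair. All partitions are scored; the
maximum-scoring partition is reported iff it reaches the threshold. Ties
break deterministically: smallest absolute shift from the window
midpoint, then leftmost acceptor coordinate. A read admitting both a BSJ
and a fusion interpretation keeps the higher-scoring one; equal best
scores at different junctions make the read ambiguous and it is dropped
(counted in the run manifest). Calls shorter than `min_circ_len` =
100 nt are rejected, matching the simulator's discard rule for short
circles.

**Fusion circRNAs.** A fusion circle between loci A and B carries two
junctions in fixed reciprocal order: `A_j -> B_m` and `B_n -> A_i` with
`i <= j` and `m <= n` in transcription direction. `pair_fusion_circs()`
emits every junction pair satisfying this geometry with both intra-locus
spans positive and at most `fusion_max_span` = 1 Mb; a junction
participating in several pairings is flagged (`multi_pairing`) rather
than suppressed, since a single junction may genuinely be shared. A lone
fusion junction indicates a linear fusion transcript, not a fusion
circle, and produces no call.

## 3. Quantification

Each called circle gets a **pseudo-circular reference**: the monomer
sequence — concatenated annotated exons of the host transcript
intersected with the circle span when a GTF is supplied, otherwise the
genomic span — repeated twice, with the BSJ image (*seam*) at the monomer
length. All collapsed reads are realigned (exact, both orientations) and
a read counts for a circle iff its alignment crosses the seam with at
least `min_overhang` = 4 nt on both sides. Each read/pair contributes its
pair weight × collapse count to at most one circle; reads whose seam
context matches several circles are ties and left unassigned (never
fractionally distributed), and a read visible at both monomer images of
one circle is counted once. The 4-nt default mirrors the independent
junction-read counting rule used for fusion-junction validation ("at
least 4 nt overlap with the junction"); the quantification step's own
minimum overhang is not stated anywhere, so this is an inference —
configurable.

The bundled aligner used here and for chimeric detection is exact
seed-and-extend (15-nt seeds, no mismatches or indels) — sufficient for
the error-free simulated reads that the offline benchmark produces, and
deliberately minimal. Real libraries should be aligned with an external
split-read aligner (BWA-MEM or similar) and passed in as SAM
(`run_config(sam = ...)`); the calling path is identical from the parser
onward. Realignment-based quantification of real (error-containing) reads
against the pseudo-circular FASTA likewise requires an external aligner;
this integration is a known limitation of the current version.

## 4. The simulator: what it emulates, and what it does not

`make_genome()` builds uniform-random chromosomes carrying multi-exon
genes; each exon boundary is overwritten with a donor or acceptor window
rejection-sampled from the trained model until the site scores at least
$(\text{threshold} + \text{margin})/2$ bits (margin = 2), so any
donor/acceptor pair totals at least threshold + 2. Defaults: 3–6 exons
per gene, exon lengths 150–300 nt, introns 80–150 nt, 500 nt intergenic
gaps, half the genes on the minus strand, genes spread over ≥ 2
chromosomes. The exon-length floor of 150 nt (a realistic median exon
size) guarantees that a junction flank of up to one read length lies
within a single exon, which the bundled (non-spliced) aligner requires.

`simulate_circs()` follows the benchmark construction used for the
method's validation: per transcript with ≥ 3 exons, one or two internal
exons are selected and the circle spans all exons between them; a
fraction (`frac_two_circ` = 0.05, the source says only "a few") of
transcripts receives a second distinct circle; circles shorter than
100 nt are discarded. `simulate_reads()` emits error-free reads: 20 per
circle and per linear transcript (> 300 nt) by default; SE circle reads
are placed uniformly among BSJ-spanning positions; PE inserts are drawn
from N(200, 50) truncated to [read length, monomer length] (≤ 100
redraws, then the circle is skipped) and placed uniformly among
seam-spanning positions. Junction-spanning placements require at least
`min_anchor` = 4 nt on each side of the junction — the same 4-nt
junction-overlap rule the quantifier applies; a "spanning" read with a
1–3 nt overhang would be undetectable by that rule, so exact abundance
recovery is only a meaningful target under this condition.
`simulate_fusions()` builds 10 reciprocal fusion circles by default
(internal exon ranges of two genes on *different* chromosomes, joined
`A_j`→`B_m` and `B_n`→`A_i`) with 10 reads per junction. Genes are drawn
from different chromosomes because at desk scale (intergenic gaps far
below 1 Mb) a same-chromosome fusion is geometrically indistinguishable
from linear splicing under the `circ_max_span` routing rule — and the
motivating translocations are interchromosomal.

Every read id encodes its truth record; truth tables accompany all
outputs; all sampling is seed-deterministic (byte-identical files on
rerun).

**What passing these benchmarks does not show:** the simulation has no
sequencing errors, no expression-level variation (every feature gets the
same read count), no repetitive sequence beyond chance 15-mer collisions,
no intron retention or alternative internal structure, and splice sites
drawn from the same model family the caller scores with. Results on the
synthetic benchmark therefore measure the pipeline's arbitration,
bookkeeping and counting logic — not robustness to noisy real data, where
alignment quality and model mis-specification dominate.

## 5. Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; SAM/GTF convert on read,
  BED is written natively 0-based.
* IPS: tolerance $10^{-6}$ on the maximum absolute marginal deviation,
  ≤ 500 sweeps, warning (not error) on non-convergence.
* Unscorable windows (`N`, off-chromosome) make a partition ineligible;
  a candidate whose every partition is unscorable yields no call.
* Tie-breaks everywhere are deterministic (documented above); aggregated
  outputs are sorted by coordinates, so whole-pipeline reruns are
  byte-identical.
* Empty inputs (no reads, no calls, unattainable threshold) produce
  valid empty outputs, not errors.
* Problem sizes in the test suite are the package's chosen desk scale:
  unit tests use 12–40-gene genomes; the recovery benchmark uses 500
  genes with 200 circles and 20 reads each; the fusion benchmark uses 10
  events × 10 reads per junction at read lengths 50/100/150 nt.

## 6. Known limitations

* The bundled aligner requires exact matches; any sequencing error sends
  a read to the unaligned pool. Real data needs an external aligner.
* Fusion circRNA *abundance* is not quantified by realignment (only
  per-junction read support is reported); the pseudo-circular
  quantification covers canonical circles.
* A read supporting multiple equally-scored junctions is dropped, which
  under-counts in perfectly repetitive regions.
* Relative contribution uses the linear read pool overlapping the host
  gene as the gene-level abundance; it is a read-count ratio, not a
  length-normalized expression estimate.
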