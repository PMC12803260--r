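---
title: "Methods: anchored iCLIP analysis of histone stem-loop binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchored iCLIP analysis of histone stem-loop binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slclip)
```

`slclip` analyses truncation-type iCLIP data for a protein that binds
replication-dependent (RD) histone mRNAs near their 3' stem-loop, and
fits fluorescence-polarization (FP) titrations with the Hill model.
This vignette records the models the package implements, the
assumptions behind them, and the numerical and design choices a
maintainer would want to know about. All constants live in one place,
the packaged configuration (`default_config_path()`), so that every
analysis and every test reads the same study conditions.

## The truncation model and coordinate conventions

In iCLIP, reverse transcription stops at the crosslinked nucleotide,
so a read's insert begins one nucleotide downstream (in read
orientation) of the protein contact. All in-memory coordinates are
0-based half-open; 1-based coordinates appear only in text formats
(GTF-like annotation, SAM), and bedGraph is 0-based half-open as the
format requires. The crosslink rule is:

* `+` strand read `[s, e)` → crosslink at `s - 1` on `+`;
* `-` strand read `[s, e)` → crosslink at `e` on `-`.

The minus-strand case is the classic off-by-one trap: the 5' end of a
minus-strand read is its numerically *largest* base `e - 1`, so the
base 5' of it in transcript orientation is `e`, not `s - 1`. The rule
is pinned by a worked diagram in the source of
`extract_crosslinks()` and by an independent per-read oracle in the
test suite. Reads starting at a chromosome end have no upstream base
and are dropped (counted, never silently). Termination sites — the
3'-most aligned base — are only trusted when at least 6 nt of adapter
were trimmed from the read's 3' end, which proves the read ran
through the genuine RNA 3' end; termination events at chromosome ends
are kept, since a last position always exists.

"N nt upstream of the stem-loop" is measured from the crosslink base
to the stem-loop's 5'-most base in transcription direction, with the
anchor itself at offset 0 and the first upstream base at offset -1.
Whether such distances should instead be measured to the edge of the
upstream sequence element is not decidable from the assay alone; this
package pins the anchor-exclusive convention and uses it consistently
in `window_coverage()` and `peak_offset()`.

## Read processing

The read layout is 5 nt UMI + 6 nt sample barcode (read positions
6-11, 1-based) + 4 nt UMI + insert + 3' adapter. Stage order and
defaults (all configurable in `thresholds`):

1. `quality_filter()` — drop a read iff any base of the 15-nt
   barcode/UMI header has Phred < 10; insert qualities are ignored.
2. `demultiplex()` — exact barcode match; mismatching reads go to an
   unassigned bin. Exact matching is a deliberate choice: the
   generator emits error-free barcodes, and exact matching keeps the
   contract fully testable.
3. `trim_adapters()` — strip the header, then remove the longest read
   suffix that exactly matches a prefix of the adapter (minimum
   overlap 1 nt), recording the removed length; drop inserts < 15 nt.
   The length filter runs after trimming.
4. `deduplicate()` — duplicates are reads identical in insert *and*
   UMI, per sample; the first in input order survives. Note that two
   independent molecules can collide in (insert, UMI) and collapse;
   at the default depths this affects of order one read per library
   and the tests account for it.
5. `align_exact()` — exhaustive exact-substring search of each insert
   against the genome and its reverse complement. Histone genes are
   intronless and the toy genome is error-free, so a splice-aware,
   mismatch-tolerant aligner would add nothing here; real externally
   aligned data can enter through `read_sam()` instead. Reads hitting
   more than 999 loci are dropped; among 2-999 hits one is chosen
   uniformly under the pipeline seed, mirroring random-primary
   selection. Exact matching cannot soft-clip, so 5' ends are never
   clipped and the truncation rule stays valid.

Every stage reports its removals, and `process_library()` asserts the
ledger identity: raw = quality-dropped + too-short + unassigned +
length-dropped + duplicates + unmapped + locus-capped + aligned.

## IP-vs-control enrichment

Reads are counted per gene when they overlap an exon on the same
strand (sense counting); a read overlapping several genes increments
each. Libraries are normalized with median-of-ratios size factors:
the per-gene reference is the geometric mean across libraries (genes
with any zero excluded), and a library's factor is the median of
count/reference. When no gene is positive everywhere, a
pseudo-reference over positive counts only is available
(`pseudo_reference = TRUE`); the pipeline falls back to it
automatically, which matters for very shallow control libraries.

The test itself is a deliberately reduced negative-binomial Wald
test. Per gene, with normalized group means and the NB variance
`Var(K) = mu + alpha * mu^2`:

* gene-wise dispersion by method of moments from the pooled
  within-group variance, floored at `1e-8`;
* the gene-wise estimate is then *moderated* toward the across-gene
  mean dispersion with a prior weight of 20 residual degrees of
  freedom. This is the one place the package departs from the
  simplest possible reduction: with a handful of libraries the raw
  method-of-moments dispersion is so noisy that the Wald statistic
  referred to the standard normal is visibly anti-conservative
  (measured type-I error near 0.10 at nominal 0.05 in a 4-vs-4 null
  simulation). Moderation restores calibration (the suite checks the
  type-I error lands in [0.03, 0.07] under a 2000-gene, 200-replicate
  null); setting `dispersion_prior_df = 0` recovers the unmoderated
  estimator.
* Wald statistic = log2 fold change over its delta-method SE, normal
  reference, two-sided; Benjamini-Hochberg adjustment with all-zero
  genes excluded; significance at adjusted p < 0.01.
* a pseudo-count of 0.5 enters the *reported* fold change only; the
  statistic uses it solely when a group mean is exactly zero, where
  the raw ratio is undefined.

Omitted relative to a full DESeq2-style analysis: independent
filtering, outlier handling, and fold-change shrinkage. Volcano
values on real data will therefore differ numerically from a DESeq2
run even where calls agree.

## Anchored metagene profiles

`window_coverage()` sums sense-strand events over genes at offsets
-100..+100 around one of three anchors (start codon, stop codon,
stem-loop 5' base). `full_gene_profile()` builds the fixed-shape
profile: 100 unbinned upstream positions, the CDS in 100 equal bins,
the stop-codon-to-stem-loop spacer (31-57 nt in RD histone genes) in
31 bins, the stem-loop element unbinned, and 100 unbinned downstream
positions. Bin values are the mean position-wise coverage, so
`sum(value * n_positions)` conserves the total exactly — a property
the suite checks on random vectors. When a region length is not
divisible by the bin count, the leftmost bins take the extra
position; the choice is arbitrary but pinned. The stem-loop segment
is kept unbinned at element length (16 nt by default geometry),
sitting between the binned spacer and the downstream flank. Profiles
are raw event counts, deliberately unnormalised: the control
libraries are shallow by design, and library-size scaling would
inflate them to meaningless levels.

`peak_offset()` reports the modal event position strictly upstream of
the stem-loop anchor as a positive distance in nt; ties break toward
the anchor and are flagged. An all-zero upstream half is an error
("no signal"), not a zero.

`maturity_calls()` classifies termination events in a gene's 3'
window: within ±5 nt of the stem-loop 3' end → mature; further
downstream (to +100 nt) → precursor. The 5 nt tolerance is a choice —
the underlying biology is reported qualitatively — and is exposed as
`thresholds$maturity_tol`.

## Stem-loop detection and gene classes

`detect_stem_loop()` scans all (position, stem length, loop length)
combinations for a hairpin whose 3' arm reverse-complements its 5'
arm up to a mismatch budget, scoring paired bases minus one penalty
per mismatch. Defaults describe the canonical metazoan histone
element: 6 bp stem, 4 nt loop, at most one mismatch, minimum score 4.
Ties break deterministically (higher score, longer stem, leftmost,
smaller loop). This is combinatorial matching, not thermodynamic
folding; it is meant for short 3'-end windows, not genome-wide scans.

Genes are classed RD iff they carry the stem-loop. Histone variants
that carry a stem-loop but are conventionally treated as
replication-independent are handled as explicit overrides: they count
as RI for enrichment labelling yet keep their element for metagene
use. Promoting a gene without a stem-loop to RD is refused, since
nothing could anchor its profile.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the
study conditions. One random-sequence chromosome carries, at random
non-overlapping positions on both strands: 10 RD histone genes (ATG +
random sense codons + TAA; spacer uniform on 31-57 nt ending in a
planted 12-nt motif; perfect 6+4 hairpin), 10 RI histone genes (plain
60 nt 3' UTR), and 30 non-histone background genes. The background
genes are a deliberate addition: real enrichment analyses normalize
against a genome dominated by unbound genes, and without them
median-of-ratios normalization absorbs the IP signal into the size
factors (a compositional artifact, not biology). The planted motif
sequence itself is a free parameter — the real element is not printed
anywhere usable — and nothing downstream depends on its content.

IP libraries mix stem-loop-proximal signal (80% of reads; crosslink
at the configured offset, default 12 nt upstream of the stem-loop 5'
base, optionally jittered ±1 nt) with uniform background along
transcripts; controls are background-only at 10% depth, emulating
no-antibody libraries that differ from the IP only in depth and
signal. Background inserts end at an RNase fragment end (uniform
20-80 nt); signal inserts are protein-protected through the stem-loop
and run to the RNA 3' end — the mature end for 90% of them, a 20-80
nt read-through precursor end otherwise. Reads are UMI1 + barcode +
UMI2 + insert + adapter; 10% are emitted twice as exact duplicates,
and 1% receive one low-Phred header base to exercise the quality
filter. A per-record truth table (crosslink coordinate, placement,
background/mature/duplicate flags) enables every parameter-recovery
test.

What the generator does *not* emulate: sequencing errors in the
bases, PCR amplification bias, splicing, expression differences
between genes, antisense transcription, or barcode errors. Passing
tests therefore demonstrate correctness of the analysis chain under
clean reads with known truth — not robustness to base-call noise or
to mapping ambiguity beyond exact multi-locus repeats.

## Fluorescence polarization

`simulate_fp_titration()` draws `mP(c) = baseline + amplitude * c^h /
(Kd^h + c^h) + N(0, sd)` over a 12-point log-spaced series (1 nM to
10 µM) at a constant 10 nM labelled RNA, plus RNA-only background
wells at baseline. `fp_normalize()` subtracts the mean background
well. `fit_hill()` is Levenberg-Marquardt least squares
(`minpack.lm::nlsLM`) with initialization baseline = min(mP),
amplitude = max - min, Kd = concentration nearest half-amplitude,
h = 1; bounds h in [0.2, 5] and Kd in (0, 10 × max concentration]. A
fit is a `non_binder` when the amplitude is below three residual SDs
or Kd sits at its upper bound; both rules are choices, since the
original curve fitting ran on vendor defaults that are not printed.
Free protein is approximated by total protein — valid when Kd greatly
exceeds the 10 nM RNA, as it does at the default 400 nM truth — so no
ligand-depletion (quadratic) correction is applied; affinities
approaching the RNA concentration would need one.

## Determinism and problem sizes

Every random draw sits behind `withr::with_seed`, so a configuration
plus one integer seed reproduces FASTQ bytes, truth tables, reports
and fits exactly; per-library seeds are derived arithmetically from
the pipeline seed. The shipped test-and-acceptance problem sizes are
chosen as the smallest that still separate signal from noise
comfortably: full-pipeline checks use 6 IP × 10,000 reads on 50 genes
(the packaged default) or 2-4 libraries × ~1,500 reads on 10-15 genes
for unit-level work; the null-calibration Monte Carlo uses 2000 genes
× 8 libraries × 200 replicates; FP recovery uses 50 seeded
titrations. The oracle comparisons (per-read track extraction,
brute-force hairpin scan, step-up BH, median-of-ratios) run on 10^3
to 10^4 random cases under fixed seeds.

## Known limitations

* The aligner is exact-match by design; real reads must be aligned
  externally and imported as minimal SAM.
* The enrichment test has no independent filtering or outlier
  handling; with very few control reads its power and its size-factor
  stability rest on the pseudo-reference fallback.
* Metagene aggregation requires a common stem-loop element length
  across genes (true for the canonical geometry).
* The maturity classification is a windowed heuristic with a
  configurable tolerance, not a transcript-isoform model.
* Binding-site resolution is one nucleotide by construction; nothing
  corrects for crosslinking-efficiency biases at particular bases.
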