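# slclip

Anchored iCLIP analysis of histone mRNA stem-loop binding, in R.

## The scientific problem

Replication-dependent (RD) histone mRNAs are the only metazoan mRNAs
that end in a conserved 3' stem-loop instead of a poly(A) tail. In
*C. elegans* embryos, an RNA-binding complex recognises these
transcripts through a sequence element a fixed distance upstream of
the stem-loop. The evidence for such a binding mode comes from two
assays:

* **iCLIP** (individual-nucleotide-resolution crosslinking and
  immunoprecipitation): reverse transcription truncates at the
  crosslinked residue, so the nucleotide immediately 5' of a mapped
  read's start is the protein-RNA contact. Aggregating crosslink
  events across genes in coordinates anchored on the start codon, stop
  codon and stem-loop reveals *where* along histone mRNAs the protein
  sits, and read 3'-termination sites reveal *which* transcript form
  (mature or read-through precursor) is bound.
* **Fluorescence polarization (FP)**: titrating protein into a
  constant 10 nM labelled RNA and fitting the Hill equation
  `mP(c) = baseline + amplitude * c^h / (Kd^h + c^h)` quantifies the
  binding affinity (Kd).

`slclip` implements that entire computational chain at desk scale and
couples it to a seeded synthetic-data generator, so every stage — read
filtering, demultiplexing, UMI deduplication, alignment, crosslink
extraction, negative-binomial IP-vs-control enrichment, three-anchor
metagene binning, peak-offset recovery, maturity calls and Hill
fitting — can be exercised and verified against ground truth.

## What is in the box

| Stage | Functions |
| --- | --- |
| Study conditions | `slclip_config()`, packaged defaults in `inst/extdata/default_config.yaml` |
| Synthetic data | `simulate_genome()`, `simulate_iclip_library()`, `simulate_fp_titration()` |
| Gene architecture | `detect_stem_loop()`, `classify_genes()`, `gene_anchors()` |
| Read processing | `quality_filter()`, `demultiplex()`, `trim_adapters()`, `deduplicate()`, `align_exact()`, `process_library()` |
| Event tracks | `extract_crosslinks()`, `extract_terminations()`, `write_bedgraph()`/`read_bedgraph()` |
| Enrichment | `count_exonic()`, `size_factors()`, `nb_wald_test()`, `label_and_rank()` |
| Metagene | `window_coverage()`, `bin_region()`, `full_gene_profile()`, `aggregate_profiles()`, `peak_offset()`, `maturity_calls()` |
| FP binding | `fp_normalize()`, `fit_hill()` (+ `tidy()`, `glance()`, `autoplot()`) |
| End to end | `run_iclip_pipeline()`, `plot_volcano()`, `plot_window_profile()`, `plot_full_profile()` |

All user-facing functions take and return tibbles, so stages chain
with the pipe; file interchange uses FASTQ/FASTA, a minimal SAM
dialect, strand-split bedGraph and a GTF-like annotation.

## Worked example

```r
library(slclip)

cfg <- slclip_config(genome = list(n_rd_genes = 4, n_ri_genes = 3,
                                   n_other_genes = 10),
                     iclip = list(n_reads = 2000))
report <- run_iclip_pipeline(cfg, seed = 42)
report
#> iCLIP pipeline report (config 9ec54cebbf9e, seed 42)
#> read ledger:
#>   raw              13613
#>   quality_dropped  148
#>   too_short_raw    0
#>   unassigned       0
#>   length_dropped   0
#>   duplicates       1212
#>   unmapped         0
#>   locus_capped     0
#>   aligned          12253
#> enriched genes (padj < FDR): 4 of 17
#> crosslink peak: 12 nt upstream of the stem-loop (height 9541)
#> mature 3' end fraction (pooled): 0.902
#> FP Hill fit: Kd = 421 nM (h = 1.00)
```

Reading the report: the ledger accounts for every raw read (quality
failures in the barcode/UMI region, unassigned barcodes, <15 nt
inserts, PCR duplicates, unmapped and locus-capped reads, aligned
survivors). Exactly the four RD histone genes come out significantly
enriched in the IP at the 1% FDR; the modal crosslink site sits 12 nt
upstream of the stem-loop 5' base, which is the offset the generator
planted; 90% of termination events sit at the mature 3' end, matching
the simulated mature fraction; and the Hill fit recovers the
configured 400 nM affinity from a noisy titration.

```r
head(dplyr::select(report$enrichment, gene_id, class_label,
                   log2FC, padj, significant))
#>   gene_id class_label log2FC     padj significant
#> 1 rd_g06  RD           3.66  1.60e-34 TRUE
#> 2 rd_g07  RD           3.40  1.60e-34 TRUE
#> 3 rd_g03  RD           3.97  4.31e-33 TRUE
#> 4 rd_g16  RD           3.95  4.31e-33 TRUE
#> 5 oth_g01 other       -0.703 4.68e- 2 FALSE
#> 6 oth_g10 other        0.825 1.60e- 1 FALSE

plot_volcano(report$enrichment)            # Fig-5a-style volcano
plot_full_profile(report$full_profile_total)  # binned metagene
autoplot(report$fp_fit)                    # titration + fitted curve
glance(report$fp_fit)
#>     kd     h baseline amplitude   rss sigma  nobs converged non_binder
#>   421. 0.999    0.189      154.  308.  3.92    24 TRUE      FALSE
```

## Vignette

`vignettes/histone-stemloop-iclip.Rmd` describes the models and the
numerical choices: the truncation-read simulator, the coordinate
conventions (and the classic off-by-one trap in crosslink extraction),
the reduced negative-binomial Wald test and its calibration, the
three-anchor binning scheme, and the Hill-fit initialization and
bounds, along with known limitations.
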