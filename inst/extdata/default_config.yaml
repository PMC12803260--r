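# Packaged default configuration for the slclip pipeline.
# All thresholds are the published processing constants; the simulator
# sections define the default study conditions emulated by the
# synthetic-data generator.
seed: 1
genome:
  n_rd_genes: 10
  n_ri_genes: 10
  n_other_genes: 30              # non-histone genes anchoring normalization
  cds_len_range: [300, 600]      # nt, forced to a multiple of 3
  spacer_range: [31, 57]         # nt, stop codon 3' end to stem-loop 5' base
  stem_len: 6                    # bp, canonical histone stem-loop stem
  loop_len: 4                    # nt, canonical histone stem-loop loop
  motif: GGACCTTTTCAG            # planted upstream motif (free parameter)
  ri_utr3_len: 60                # nt of 3' UTR given to RI variant genes
  margin: 150                    # nt kept gene-free on both sides of a gene
  intergenic_min: 250            # nt minimum gap between neighbouring genes
  max_place_tries: 500
iclip:
  read_len: 150
  umi1_len: 5
  barcode_len: 6
  umi2_len: 4
  adapter: AGATCGGAAGAGCGGTTCAG
  crosslink_offset: 12           # nt upstream of the stem-loop 5' base
  offset_jitter_prob: 0.0        # probability of a +/-1 nt shift of the offset
  signal_fraction: 0.8           # IP reads carrying stem-loop-proximal crosslinks
  mature_fraction: 0.9           # signal reads ending at the mature 3' end
  precursor_ext_range: [20, 80]  # nt read-through beyond the stem-loop
  insert_len_range: [20, 80]     # nt RNase fragment length (3' truncated at the RNA end)
  n_reads: 10000                 # reads per IP library
  duplicate_rate: 0.1            # probability a read is emitted twice
  control_depth_factor: 0.1      # control depth relative to IP depth
  low_qual_rate: 0.01            # reads given one low-Phred header base
  barcodes:
    IP1: AACGTG
    IP2: CCATGA
    IP3: GGTACT
    IP4: TTGCAC
    IP5: ACTGGA
    IP6: CAGTTC
    ctrl1: GTACAG
    ctrl2: TGCATC
  roles:
    IP1: IP
    IP2: IP
    IP3: IP
    IP4: IP
    IP5: IP
    IP6: IP
    ctrl1: control
    ctrl2: control
thresholds:
  phred_min: 10                  # minimum Phred in barcode/UMI region
  min_overlap: 1                 # nt minimal read/adapter overlap
  min_len: 15                    # nt minimum insert length after trimming
  max_loci: 999                  # maximum accepted alignment loci
  min_trim: 6                    # nt 3' trimming required for termination sites
  flank: 100                     # nt anchored-window flank
  cds_bins: 100
  spacer_bins: 31
  fdr: 0.01
  maturity_tol: 5                # nt tolerance around the mature 3' end
fp:
  kd_nm: 400                     # dissociation constant of the simulated binder
  hill: 1.0
  baseline_mp: 20
  amplitude_mp: 150
  rna_conc_nm: 10                # constant labelled-RNA concentration
  conc_min_nm: 1
  conc_max_nm: 10000
  n_conc: 12
  noise_sd_mp: 3
  n_replicates: 2
  n_background_wells: 3
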