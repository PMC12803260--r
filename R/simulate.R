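# Seeded synthetic-data generator: toy genome with RD/RI histone gene
# models, truncation-type iCLIP libraries with truth tables, and
# fluorescence-polarization titrations. Everything is deterministic
# given (config, seed); seeds are applied with withr::with_seed so the
# caller's RNG state is untouched.

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste0,
                    collapse = "")
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

random_dna <- function(n_char) {
  paste(sample(DNA_BASES, n_char, replace = TRUE), collapse = "")
}

#' Simulate a toy genome with histone gene models
#'
#' Builds one random-sequence chromosome and embeds `n_rd_genes`
#' replication-dependent and `n_ri_genes` replication-independent
#' histone gene cassettes at random non-overlapping positions on both
#' strands. Each RD cassette is ATG + random sense codons + TAA, a
#' spacer drawn uniformly from `spacer_range` (31-57 nt by default)
#' whose 3' end carries the planted upstream motif, and a perfect
#' hairpin element (6-bp stem, 4-nt loop by default). RI cassettes end
#' in a plain 3' UTR instead of the stem-loop.
#'
#' @param cfg Configuration from [slclip_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A list with `genome` (a named [Biostrings::DNAStringSet-class])
#'   and `genes` (a classified gene-model tibble, see [validate_genes()]).
#' @export
simulate_genome <- function(cfg = slclip_config(), seed = cfg$seed) {
  g <- cfg$genome
  n_other <- g$n_other_genes %||% 0L
  ng <- g$n_rd_genes + g$n_ri_genes + n_other
  stopifnot(ng >= 1)
  with_seed(as.integer(seed), {
    classes <- sample(c(rep("RD", g$n_rd_genes), rep("RI", g$n_ri_genes),
                        rep("OTHER", n_other)))
    strands <- sample(rep(c("+", "-"), length.out = ng))
    motif <- g$motif
    cass <- vector("list", ng)
    for (i in seq_len(ng)) {
      cds_len <- sample(seq(g$cds_len_range[1], g$cds_len_range[2], by = 3L), 1)
      cds <- paste0("ATG",
                    paste(sample(SENSE_CODONS, cds_len / 3L - 2L,
                                 replace = TRUE), collapse = ""),
                    "TAA")
      if (classes[i] == "RD") {
        spacer_len <- sample(g$spacer_range[1]:g$spacer_range[2], 1)
        stopifnot(spacer_len >= nchar(motif))
        spacer <- paste0(random_dna(spacer_len - nchar(motif)), motif)
        arm <- random_dna(g$stem_len)
        sl <- paste0(arm, random_dna(g$loop_len), revcomp_chr(arm))
        cass[[i]] <- list(seq = paste0(cds, spacer, sl), cds_len = cds_len,
                          spacer_len = spacer_len, sl_len = nchar(sl))
      } else {
        cass[[i]] <- list(seq = paste0(cds, random_dna(g$ri_utr3_len)),
                          cds_len = cds_len, spacer_len = NA_integer_,
                          sl_len = NA_integer_)
      }
    }
    lens <- map_int(cass, ~ nchar(.x$seq))
    margin <- g$margin
    chrom_len <- max(20000L,
                     ceiling(2.2 * sum(lens + 2L * margin + g$intergenic_min)))
    chrom <- random_dna(chrom_len)
    # random non-overlapping placement with bounded retries
    occupied <- matrix(numeric(0), ncol = 2)
    pos <- integer(ng)
    for (i in seq_len(ng)) {
      placed <- FALSE
      for (try in seq_len(g$max_place_tries)) {
        p <- sample.int(chrom_len - lens[i] - 2L * margin, 1) + margin
        lo <- p - margin
        hi <- p + lens[i] + margin
        if (nrow(occupied) == 0 ||
            all(hi <= occupied[, 1] | lo >= occupied[, 2])) {
          occupied <- rbind(occupied, c(lo, hi))
          pos[i] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf("could not place gene %d after %d tries; enlarge genome",
                      i, g$max_place_tries))
      }
    }
    for (i in seq_len(ng)) {
      s <- if (strands[i] == "+") cass[[i]]$seq else revcomp_chr(cass[[i]]$seq)
      stringi::stri_sub(chrom, pos[i] + 1L, pos[i] + lens[i]) <- s
    }
    plus <- strands == "+"
    cds_len <- map_int(cass, "cds_len")
    sl_len <- map_int(cass, "sl_len")
    prefix <- c(RD = "rd", RI = "ri", OTHER = "oth")[classes]
    genes <- tibble(
      gene_id = sprintf("%s_g%02d", unname(prefix), seq_len(ng)),
      chrom = "chrS",
      strand = strands,
      tx_start = pos,
      tx_end = pos + lens,
      cds_start = ifelse(plus, pos, pos + lens - cds_len),
      cds_end = ifelse(plus, pos + cds_len, pos + lens),
      sl_start = ifelse(is.na(sl_len), NA_integer_,
                        ifelse(plus, pos + lens - sl_len, pos)),
      sl_end = ifelse(is.na(sl_len), NA_integer_,
                      ifelse(plus, pos + lens, pos + sl_len))
    )
    genes$biotype <- if_else(classes == "OTHER", "other", "histone")
    genes$exons <- map2(genes$tx_start, genes$tx_end,
                        ~ tibble(start = .x, end = .y))
    genes <- classify_genes(genes)
    genome <- DNAStringSet(setNames(chrom, "chrS"))
    list(genome = genome, genes = genes)
  })
}

#' Simulate one iCLIP library (FASTQ records plus truth table)
#'
#' Emulates truncation-type iCLIP: reverse transcription stops at the
#' crosslinked nucleotide, so each read's genomic insert begins exactly
#' one nt downstream (in read orientation) of the true crosslink site.
#' IP libraries are a mixture of stem-loop-proximal signal — the
#' crosslink sits `crosslink_offset` nt upstream of the stem-loop 5'
#' base on RD genes, optionally jittered by one nt — and uniform
#' background along transcripts. Background inserts end at an RNase
#' fragment end (length drawn from `insert_len_range`, truncated at
#' the RNA 3' end); signal inserts are protected by the bound protein
#' and run through to the RNA 3' end — the mature stem-loop end, or a
#' precursor read-through end for `1 - mature_fraction` of them.
#' Control (no-antibody) libraries are background-only at
#' `control_depth_factor` times the IP depth. Reads
#' are assembled as UMI1 + sample barcode + UMI2 + insert + as much 3'
#' adapter as fits; a `duplicate_rate` fraction of reads is emitted
#' twice (identical sequence, qualities and UMIs), and a `low_qual_rate`
#' fraction receives one low-Phred base in the header to exercise the
#' quality filter.
#'
#' @param genome Named [Biostrings::DNAStringSet-class] (from
#'   [simulate_genome()]).
#' @param genes Classified gene-model tibble.
#' @param cfg Configuration from [slclip_config()].
#' @param role `"IP"` or `"control"`.
#' @param sample Sample name; must appear in `cfg$iclip$barcodes`.
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A list with `reads` (tibble: `read_id`, `sequence`,
#'   `quality`) and `truth` (one row per emitted record; duplicate rows
#'   point at their source via `source_read_id`).
#' @export
simulate_iclip_library <- function(genome, genes, cfg = slclip_config(),
                                   role = c("IP", "control"),
                                   sample = names(cfg$iclip$barcodes)[1],
                                   seed = cfg$seed) {
  role <- match.arg(role)
  ic <- cfg$iclip
  if (!sample %in% names(ic$barcodes)) {
    abort(sprintf("sample '%s' has no barcode in the configuration", sample))
  }
  rd_idx <- which(!is.na(genes$sl_start))
  if (role == "IP" && length(rd_idx) == 0) {
    abort("an IP library needs at least one stem-loop-bearing gene")
  }
  gstrs <- setNames(as.character(genome), names(genome))
  chrom_lens <- setNames(nchar(gstrs), names(gstrs))
  min_insert <- cfg$thresholds$min_len + 1L
  max_insert <- ic$read_len - header_len(cfg)
  with_seed(as.integer(seed), {
    n <- if (role == "IP") ic$n_reads else
      as.integer(round(ic$n_reads * ic$control_depth_factor))
    is_signal <- if (role == "IP") runif(n) < ic$signal_fraction else
      rep(FALSE, n)
    gi <- integer(n)
    gi[is_signal] <- sample(rd_idx, sum(is_signal), replace = TRUE)
    gi[!is_signal] <- sample.int(nrow(genes), sum(!is_signal), replace = TRUE)
    L <- tx_len(genes)[gi]
    t <- integer(n)                     # crosslink, transcript coordinate
    e <- integer(n)                     # last RNA base, transcript coordinate
    nb <- sum(!is_signal)
    t[!is_signal] <- floor(runif(nb) * (L[!is_signal] - min_insert))
    e[!is_signal] <- L[!is_signal] - 1L
    ns <- sum(is_signal)
    is_mature <- rep(TRUE, n)
    if (ns > 0) {
      sl_len_s <- (genes$sl_end - genes$sl_start)[gi[is_signal]]
      jp <- ic$offset_jitter_prob
      t_base <- L[is_signal] - sl_len_s - ic$crosslink_offset
      for (iter in 1:10) {             # re-draw crosslinks landing before 0
        redo <- if (iter == 1) rep(TRUE, ns) else t[is_signal] < 0
        if (!any(redo)) break
        jit <- sample(c(-1L, 0L, 1L), sum(redo), replace = TRUE,
                      prob = c(jp / 2, 1 - jp, jp / 2))
        tt <- t[is_signal]
        tt[redo] <- t_base[redo] - jit
        t[is_signal] <- tt
      }
      if (any(t[is_signal] < 0)) {
        abort("crosslink offset larger than the transcript; check config")
      }
      mature <- runif(ns) < ic$mature_fraction
      ext <- ifelse(mature, 0L,
                    sample(ic$precursor_ext_range[1]:ic$precursor_ext_range[2],
                           ns, replace = TRUE))
      e[is_signal] <- L[is_signal] - 1L + ext
      is_mature[is_signal] <- mature
    }
    # RNase fragmentation of background inserts: the 3' end is the
    # fragment end, truncated at the RNA 3' end and at what fits in
    # the read. Signal inserts are protected through the stem-loop and
    # reach the RNA 3' end.
    drawn <- sample(ic$insert_len_range[1]:ic$insert_len_range[2], n,
                    replace = TRUE)
    drawn[is_signal] <- .Machine$integer.max
    ins_len <- pmin(drawn, e - t, max_insert)
    strand <- genes$strand[gi]
    chrom <- genes$chrom[gi]
    g1 <- tx_to_genomic(strand, genes$tx_start[gi], genes$tx_end[gi], t + 1L)
    g2 <- tx_to_genomic(strand, genes$tx_start[gi], genes$tx_end[gi],
                        t + ins_len)
    ins_start <- pmin(g1, g2)
    ins_end <- pmax(g1, g2) + 1L
    # truncate inserts that would run past a chromosome end (3' side only)
    ins_end <- pmin(ins_end, unname(chrom_lens[chrom]))
    ins_start <- pmax(ins_start, 0L)
    ins_len <- ins_end - ins_start
    xl_pos <- tx_to_genomic(strand, genes$tx_start[gi], genes$tx_end[gi], t)
    insert <- stringi::stri_sub(gstrs[chrom], ins_start + 1L, ins_end)
    minus <- strand == "-"
    if (any(minus)) insert[minus] <- revcomp_chr(insert[minus])
    umi1 <- stringi::stri_rand_strings(n, ic$umi1_len, "[ACGT]")
    umi2 <- stringi::stri_rand_strings(n, ic$umi2_len, "[ACGT]")
    n_adapter <- pmin(nchar(ic$adapter), max_insert - ins_len)
    sequence <- paste0(umi1, ic$barcodes[[sample]], umi2, insert,
                       str_sub(ic$adapter, 1L, n_adapter))
    quality <- strrep("I", nchar(sequence))          # Phred 40 throughout
    lowq <- which(runif(n) < ic$low_qual_rate)
    if (length(lowq) > 0) {
      posq <- sample.int(header_len(cfg), length(lowq), replace = TRUE)
      stringi::stri_sub(quality[lowq], posq, posq) <- "&"   # Phred 5
    }
    read_id <- sprintf("%s_r%06d", sample, seq_len(n))
    reads <- tibble(read_id = read_id, sequence = sequence, quality = quality)
    truth <- tibble(
      read_id = read_id, sample = sample, role = role,
      gene_id = genes$gene_id[gi], chrom = chrom, strand = strand,
      crosslink_pos = xl_pos, insert_start = ins_start,
      insert_end = ins_end, n_adapter = n_adapter,
      is_background = !is_signal, is_mature = is_mature,
      is_duplicate = FALSE, source_read_id = NA_character_
    )
    dup <- which(runif(n) < ic$duplicate_rate)
    if (length(dup) > 0) {
      dr <- reads[dup, ]
      dt <- truth[dup, ]
      dt$source_read_id <- dr$read_id
      dt$is_duplicate <- TRUE
      dr$read_id <- dt$read_id <- paste0(dr$read_id, "_dup")
      reads <- bind_rows(reads, dr)
      truth <- bind_rows(truth, dt)
    }
    ord <- sample.int(nrow(reads))
    list(reads = reads[ord, ], truth = truth[ord, ])
  })
}

#' Simulate a fluorescence-polarization titration
#'
#' A constant concentration of labelled RNA is titrated with increasing
#' protein concentrations; polarization follows the Hill model
#' `mP(c) = baseline + amplitude * c^h / (Kd^h + c^h)` plus Gaussian
#' noise. Background wells (RNA only, no protein) are emitted at
#' `baseline` plus noise and drive the normalization in
#' [fp_normalize()].
#'
#' @param cfg Configuration from [slclip_config()]; the `fp` section
#'   holds Kd (nM), Hill coefficient, baseline and amplitude (mP),
#'   the log-spaced concentration series and the noise SD.
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return Tibble with `replicate`, `well_type` (`"titration"` or
#'   `"background"`), `conc_nm` (0 for background wells) and `mp_raw`.
#'   The constant RNA concentration is attached as attribute
#'   `rna_conc_nm`.
#' @export
simulate_fp_titration <- function(cfg = slclip_config(), seed = cfg$seed) {
  fp <- cfg$fp
  conc <- 10^seq(log10(fp$conc_min_nm), log10(fp$conc_max_nm),
                 length.out = fp$n_conc)
  out <- with_seed(as.integer(seed), {
    tit <- tidyr::crossing(replicate = seq_len(fp$n_replicates),
                           conc_nm = conc) %>%
      mutate(well_type = "titration",
             mp_raw = fp$baseline_mp +
               fp$amplitude_mp * .data$conc_nm^fp$hill /
               (fp$kd_nm^fp$hill + .data$conc_nm^fp$hill) +
               rnorm(n(), 0, fp$noise_sd_mp))
    bg <- tidyr::crossing(replicate = seq_len(fp$n_replicates),
                          well = seq_len(fp$n_background_wells)) %>%
      transmute(.data$replicate, well_type = "background", conc_nm = 0,
                mp_raw = fp$baseline_mp + rnorm(n(), 0, fp$noise_sd_mp))
    bind_rows(tit, bg) %>%
      select("replicate", "well_type", "conc_nm", "mp_raw")
  })
  attr(out, "rna_conc_nm") <- fp$rna_conc_nm
  out
}
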