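# Raw FASTQ to deduplicated aligned reads. Stage functions are
# df-first and composable; each attaches the number of records it
# removed as attributes so process_library() can assemble a counting
# ledger that accounts for every raw read.

# minimum Phred score within the first `len` bases of each read
min_phred_head <- function(quality, len) {
  head_q <- str_sub(quality, 1L, len)
  vapply(head_q, function(s) min(utf8ToInt(s)), integer(1),
         USE.NAMES = FALSE) - 33L
}

#' Filter reads on header base quality
#'
#' A read is removed iff any base in the barcode/UMI region (the first
#' `header_len` bases) has a Phred score below `phred_min`; qualities
#' outside that region are not considered. Reads shorter than the
#' header are dropped and counted separately.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param phred_min Minimum Phred score (default 10).
#' @param header_len Length in nt of the barcode + UMI header
#'   (default 15 = 5 + 6 + 4).
#' @return Filtered tibble; attributes `n_quality_dropped` and
#'   `n_too_short_raw` carry the removal counts.
#' @export
quality_filter <- function(reads, phred_min = 10L, header_len = 15L) {
  long_enough <- str_length(reads$sequence) >= header_len &
    str_length(reads$quality) >= header_len
  kept <- reads[long_enough, ]
  ok <- min_phred_head(kept$quality, header_len) >= phred_min
  out <- kept[ok, ]
  attr(out, "n_quality_dropped") <- sum(!ok)
  attr(out, "n_too_short_raw") <- sum(!long_enough)
  out
}

#' Demultiplex reads on the sample barcode
#'
#' The 6-nt sample barcode occupies read positions 6-11 (1-based); the
#' UMI is the concatenation of the 5 nt before and the 4 nt after it.
#' Assignment is exact-match only; reads whose barcode matches no
#' sample get `sample = NA` (the unassigned bin).
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param barcode_table Named character vector or list, sample name to
#'   6-nt barcode. Barcodes must be unique.
#' @param umi1_len,barcode_len,umi2_len Read-layout lengths in nt.
#' @return `reads` with `sample` and `umi` columns added.
#' @export
demultiplex <- function(reads, barcode_table, umi1_len = 5L,
                        barcode_len = 6L, umi2_len = 4L) {
  bc <- unlist(barcode_table)
  if (anyDuplicated(bc) > 0) abort("duplicate barcodes in barcode table")
  if (length(bc) > 0 && any(nchar(bc) != barcode_len)) {
    abort(sprintf("all barcodes must be %d nt", barcode_len))
  }
  lookup <- if (length(bc) > 0) setNames(names(bc), bc) else
    setNames(character(0), character(0))
  obs <- str_sub(reads$sequence, umi1_len + 1L, umi1_len + barcode_len)
  reads %>%
    mutate(sample = if (length(lookup) > 0) unname(lookup[obs]) else
             NA_character_,
           umi = paste0(str_sub(.data$sequence, 1L, umi1_len),
                        str_sub(.data$sequence,
                                umi1_len + barcode_len + 1L,
                                umi1_len + barcode_len + umi2_len)))
}

#' Trim header and 3' adapter, apply the length filter
#'
#' Removes the barcode/UMI header, then the longest read suffix exactly
#' matching a prefix of the adapter (at least `min_overlap` nt); the
#' removed adapter length is recorded as `n_trimmed_3p`. Inserts
#' shorter than `min_len` after trimming are dropped.
#'
#' @param reads Demultiplexed tibble (with `sample`, `umi`).
#' @param adapter 3' adapter sequence.
#' @param min_overlap Minimum read/adapter overlap in nt (default 1).
#' @param min_len Minimum insert length in nt (default 15).
#' @param header_len Header length to strip (default 15).
#' @return Tibble of tagged reads (`read_id`, `sample`, `umi`,
#'   `insert`, `insert_qual`, `n_trimmed_3p`); attribute
#'   `n_length_dropped` counts removals.
#' @export
trim_adapters <- function(reads, adapter, min_overlap = 1L, min_len = 15L,
                          header_len = 15L) {
  insert <- str_sub(reads$sequence, header_len + 1L)
  insert_qual <- str_sub(reads$quality, header_len + 1L)
  n <- length(insert)
  n_trim <- integer(n)
  pending <- rep(TRUE, n)
  kmax <- min(nchar(adapter), max(nchar(insert), 0L))
  if (n > 0 && kmax >= min_overlap) {
    for (k in seq(kmax, min_overlap)) {
      idx <- which(pending & nchar(insert) >= k)
      if (length(idx) == 0) next
      hit <- str_sub(insert[idx], -k) == str_sub(adapter, 1L, k)
      n_trim[idx[hit]] <- k
      pending[idx[hit]] <- FALSE
    }
  }
  trimmed <- str_sub(insert, 1L, nchar(insert) - n_trim)
  trimmed_qual <- str_sub(insert_qual, 1L, nchar(insert_qual) - n_trim)
  out <- reads %>%
    mutate(insert = trimmed, insert_qual = trimmed_qual,
           n_trimmed_3p = n_trim) %>%
    select(-"sequence", -"quality")
  keep <- nchar(out$insert) >= min_len
  res <- out[keep, ]
  attr(res, "n_length_dropped") <- sum(!keep)
  res
}

#' Remove PCR duplicates
#'
#' Duplicates are reads with identical insert sequence AND identical
#' UMI, per sample; the first occurrence in input order survives.
#'
#' @param reads Tagged-read tibble (with `sample`, `umi`, `insert`).
#' @return Deduplicated tibble; attribute `n_duplicates` counts
#'   removals.
#' @export
deduplicate <- function(reads) {
  out <- reads %>% distinct(.data$sample, .data$insert, .data$umi,
                            .keep_all = TRUE)
  attr(out, "n_duplicates") <- nrow(reads) - nrow(out)
  out
}

# locate every exact occurrence of each unique insert on both genome
# strands; returns tibble(insert, chrom, strand, start, end), 0-based
locate_inserts <- function(inserts, genome) {
  gstrs <- as.character(genome)
  names(gstrs) <- names(genome)
  rc <- revcomp_chr(inserts)
  hits <- imap_dfr(gstrs, function(gseq, chrom_name) {
    plus <- stringi::stri_locate_all_fixed(gseq, inserts, overlap = TRUE)
    minus <- stringi::stri_locate_all_fixed(gseq, rc, overlap = TRUE)
    one <- function(mat, ins, strand) {
      if (all(is.na(mat[, 1]))) return(NULL)
      mat <- mat[!is.na(mat[, 1]), , drop = FALSE]
      tibble(insert = ins, chrom = chrom_name, strand = strand,
             start = as.integer(unname(mat[, 1])) - 1L,
             end = as.integer(unname(mat[, 2])))
    }
    bind_rows(
      map_dfr(seq_along(inserts), ~ one(plus[[.x]], inserts[.x], "+")),
      map_dfr(seq_along(inserts), ~ one(minus[[.x]], inserts[.x], "-"))
    )
  })
  if (nrow(hits) == 0) {
    hits <- tibble(insert = character(), chrom = character(),
                   strand = character(), start = integer(),
                   end = integer())
  }
  hits
}

#' Exhaustive exact-substring alignment against a toy genome
#'
#' Each insert is searched as an exact substring of the genome (plus
#' strand) and of its reverse complement (minus strand); the
#' coordinates reported for a minus-strand alignment are the plus-
#' strand interval of the reverse complement. Reads with no hit are
#' dropped (unmapped); reads with more than `max_loci` hits are dropped
#' (locus-capped); among 2..`max_loci` hits one is chosen uniformly at
#' random under `seed`. Exact matching cannot soft-clip, so 5' ends are
#' never clipped.
#'
#' @param reads Deduplicated tagged-read tibble.
#' @param genome Named [Biostrings::DNAStringSet-class] or named
#'   character vector.
#' @param seed Integer seed for the multi-locus choice.
#' @param max_loci Maximum accepted number of alignment loci
#'   (default 999).
#' @return Alignment tibble (`read_id`, `sample`, `umi`, `chrom`,
#'   `strand`, `start`, `end`, `n_trimmed_3p`); attributes `n_unmapped`
#'   and `n_locus_capped` count removals.
#' @export
align_exact <- function(reads, genome, seed = 1L, max_loci = 999L) {
  if (nrow(reads) == 0) {
    out <- tibble(read_id = character(), sample = character(),
                  umi = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  n_trimmed_3p = integer())
    attr(out, "n_unmapped") <- 0L
    attr(out, "n_locus_capped") <- 0L
    return(out)
  }
  ui <- unique(reads$insert)
  hits <- locate_inserts(ui, genome)
  n_hits <- setNames(integer(length(ui)), ui)
  if (nrow(hits) > 0) {
    tab <- hits %>% count(.data$insert)
    n_hits[tab$insert] <- tab$n
  }
  per_read_hits <- unname(n_hits[reads$insert])
  unmapped <- per_read_hits == 0L
  capped <- per_read_hits > max_loci
  kept <- reads[!unmapped & !capped, ]
  kept_nh <- per_read_hits[!unmapped & !capped]
  hits <- hits %>%
    group_by(.data$insert) %>%
    mutate(.hit = row_number()) %>%
    ungroup()
  choice <- with_seed(as.integer(seed), {
    as.integer(ifelse(kept_nh == 1L, 1L,
                      floor(runif(nrow(kept)) * kept_nh) + 1L))
  })
  out <- kept %>%
    mutate(.hit = choice) %>%
    left_join(hits, by = c("insert", ".hit")) %>%
    select("read_id", "sample", "umi", "chrom", "strand", "start", "end",
           "n_trimmed_3p")
  attr(out, "n_unmapped") <- sum(unmapped)
  attr(out, "n_locus_capped") <- sum(capped)
  out
}

#' Run the full read-processing chain and assemble a counting ledger
#'
#' Quality filter, demultiplex, adapter trim + length filter,
#' deduplicate and align, with every removal accounted for: per
#' library, raw = quality-dropped + too-short-raw + unassigned +
#' length-dropped + duplicates + unmapped + locus-capped + aligned.
#'
#' @param reads Raw read tibble (pooled across samples).
#' @param genome Named [Biostrings::DNAStringSet-class].
#' @param cfg Configuration from [slclip_config()].
#' @param seed Seed for the multi-locus alignment choice.
#' @return List with `alignments` (one tibble, all samples) and
#'   `ledger` (per-sample stage counts).
#' @export
process_library <- function(reads, genome, cfg = slclip_config(),
                            seed = cfg$seed) {
  th <- cfg$thresholds
  ic <- cfg$iclip
  hl <- header_len(cfg)
  qf <- quality_filter(reads, phred_min = th$phred_min, header_len = hl)
  dm <- demultiplex(qf, ic$barcodes, umi1_len = ic$umi1_len,
                    barcode_len = ic$barcode_len, umi2_len = ic$umi2_len)
  assigned <- dm %>% filter(!is.na(.data$sample))
  n_unassigned <- nrow(dm) - nrow(assigned)
  tr <- trim_adapters(assigned, ic$adapter, min_overlap = th$min_overlap,
                      min_len = th$min_len, header_len = hl)
  dd <- deduplicate(tr)
  al <- align_exact(dd, genome, seed = seed, max_loci = th$max_loci)
  ledger <- tibble(
    stage = c("raw", "quality_dropped", "too_short_raw", "unassigned",
              "length_dropped", "duplicates", "unmapped", "locus_capped",
              "aligned"),
    n = c(nrow(reads), attr(qf, "n_quality_dropped"),
          attr(qf, "n_too_short_raw"), n_unassigned,
          attr(tr, "n_length_dropped"), attr(dd, "n_duplicates"),
          attr(al, "n_unmapped"), attr(al, "n_locus_capped"), nrow(al))
  )
  list(alignments = al, ledger = ledger)
}
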