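# File interchange: FASTQ/FASTA (Biostrings), a minimal SAM dialect,
# strand-split single-nucleotide bedGraph (rtracklayer) and a GTF-like
# gene annotation with feature types gene/exon/CDS/stem_loop.
# Coordinates are 1-based inclusive in all text formats except bedGraph
# (0-based half-open, as the format specifies) and 0-based half-open in
# memory.

#' Write reads to a FASTQ file
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- DNAStringSet(setNames(reads$sequence, reads$read_id))
  writeXStringSet(x, filepath = path, format = "fastq",
                  qualities = BStringSet(reads$quality))
  invisible(path)
}

#' Read a FASTQ file into a tibble
#' @param path FASTQ path (4-line records, Phred+33).
#' @return Tibble with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = names(x),
         sequence = unname(as.character(x)),
         quality = unname(as.character(mcols(x)$qualities)))
}

#' Write alignments as a minimal SAM file
#'
#' Emits only the fields the pipeline consumes downstream: QNAME, FLAG
#' (0 or 16 for strand), RNAME, 1-based POS, MAPQ 255, CIGAR `<n>M`,
#' and the optional tags `RG:Z:` (sample), `XU:Z:` (UMI) and `XT:i:`
#' (nt trimmed from the 3' end). SEQ and QUAL are `*`.
#'
#' @param alignments Tibble with `read_id`, `sample`, `umi`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), `n_trimmed_3p`.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tRG:Z:%s\tXU:Z:%s\tXT:i:%d",
                  alignments$read_id,
                  ifelse(alignments$strand == "-", 16L, 0L),
                  alignments$chrom,
                  alignments$start + 1L,
                  alignments$end - alignments$start,
                  alignments$sample,
                  alignments$umi,
                  alignments$n_trimmed_3p)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal SAM file into an alignment tibble
#'
#' Accepts single-end records with CIGAR `<n>M` (as emitted by
#' [write_sam()] or by an external aligner after filtering to primary,
#' unclipped alignments); anything else is rejected. Unmapped records
#' (FLAG 0x4) are skipped. Sample, UMI and 3'-trim length are taken
#' from `RG:Z:`/`XU:Z:`/`XT:i:` tags when present.
#'
#' @param path SAM path.
#' @return Alignment tibble (`read_id`, `sample`, `umi`, `chrom`,
#'   `strand`, `start`, `end`, `n_trimmed_3p`).
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), sample = character(),
                  umi = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  n_trimmed_3p = integer()))
  }
  f <- str_split(lines, "\t")
  flag <- map_int(f, ~ as.integer(.x[2]))
  keep <- bitwAnd(flag, 4L) == 0L
  f <- f[keep]
  flag <- flag[keep]
  cig <- map_chr(f, 6)
  m <- str_match(cig, "^(\\d+)M$")
  if (anyNA(m[, 2])) {
    abort("unsupported CIGAR in SAM input; only '<n>M' records are accepted")
  }
  tag <- function(fields, prefix, default) {
    hit <- fields[startsWith(fields, prefix)]
    if (length(hit) == 0) default else sub(prefix, "", hit[1], fixed = TRUE)
  }
  start <- map_int(f, ~ as.integer(.x[4])) - 1L
  tibble(
    read_id = map_chr(f, 1),
    sample = map_chr(f, tag, prefix = "RG:Z:", default = NA_character_),
    umi = map_chr(f, tag, prefix = "XU:Z:", default = NA_character_),
    chrom = map_chr(f, 3),
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    start = start,
    end = start + as.integer(m[, 2]),
    n_trimmed_3p = as.integer(map_chr(f, tag, prefix = "XT:i:",
                                      default = "0"))
  )
}

#' Write one strand of a crosslink or termination track as bedGraph
#'
#' Each event position becomes a single-nucleotide interval
#' `[pos, pos + 1)` with the event count as value, sorted by position.
#'
#' @param track Track tibble (`chrom`, `strand`, `pos`, `count`).
#' @param path Output path (conventionally `*.plus.bedgraph` /
#'   `*.minus.bedgraph`).
#' @param strand Which strand of `track` to write, `"+"` or `"-"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, strand = c("+", "-")) {
  strand <- match.arg(strand)
  tr <- track %>%
    filter(.data$strand == !!strand) %>%
    arrange(.data$chrom, .data$pos)
  gr <- GRanges(tr$chrom, IRanges(start = tr$pos + 1L, width = 1L),
                score = tr$count)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a track tibble
#'
#' Intervals wider than one nt are expanded to per-position counts
#' (lossless); overlapping or unsorted intervals are rejected.
#'
#' @param path bedGraph path.
#' @param strand Strand to assign to the events, `"+"` or `"-"`.
#' @return Track tibble (`chrom`, `strand`, `pos`, `count`).
#' @export
read_bedgraph <- function(path, strand = c("+", "-")) {
  strand <- match.arg(strand)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) {
    return(tibble(chrom = character(), strand = character(),
                  pos = integer(), count = integer()))
  }
  df <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               count = as.integer(S4Vectors::mcols(gr)$score))
  bad <- df %>%
    group_by(.data$chrom) %>%
    summarise(unsorted = is.unsorted(.data$start, strictly = FALSE),
              overlap = any(.data$start[-1] < .data$end[-length(.data$end)]),
              .groups = "drop")
  if (any(bad$unsorted | bad$overlap, na.rm = TRUE)) {
    abort("bedGraph intervals must be sorted and non-overlapping")
  }
  df %>%
    mutate(width = .data$end - .data$start) %>%
    tidyr::uncount(.data$width, .id = "off") %>%
    transmute(.data$chrom, strand = !!strand,
              pos = .data$start + .data$off - 1L, count = .data$count) %>%
    arrange(.data$chrom, .data$pos)
}

#' Write gene models as a GTF-like annotation file
#'
#' Tab-separated with the usual nine GTF columns and feature types
#' `gene` (transcript span), `exon`, `CDS` (start codon through stop
#' codon) and `stem_loop`. Coordinates 1-based inclusive in the file.
#'
#' @param genes Classified gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  validate_genes(genes)
  attr_str <- function(g) {
    bt <- if (is.null(g$biotype)) "histone" else g$biotype
    sprintf('gene_id "%s"; gene_class "%s"; class_override "%s"; gene_biotype "%s";',
            g$gene_id, g$gene_class, tolower(g$class_override), bt)
  }
  rows <- purrr::pmap(genes, function(...) {
    g <- list(...)
    a <- attr_str(g)
    feat <- function(type, s, e) {
      sprintf("%s\tslclip\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, s + 1L, e, g$strand, a)
    }
    out <- c(feat("gene", g$tx_start, g$tx_end),
             map_chr(seq_len(nrow(g$exons)),
                     ~ feat("exon", g$exons$start[.x], g$exons$end[.x])),
             feat("CDS", g$cds_start, g$cds_end))
    if (!is.na(g$sl_start)) out <- c(out, feat("stem_loop", g$sl_start, g$sl_end))
    out
  })
  readr::write_lines(unlist(rows), path)
  invisible(path)
}

#' Read a GTF-like annotation file into a gene-model tibble
#' @param path Annotation path written by [write_gene_annotation()].
#' @return Classified gene-model tibble.
#' @export
read_gene_annotation <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "source", "feature",
                                            "start", "end", "score",
                                            "strand", "frame", "attributes"),
                        col_types = "ccciicccc", comment = "#")
  att <- function(x, key) str_match(x, paste0(key, ' "([^"]*)"'))[, 2]
  df <- df %>%
    mutate(gene_id = att(.data$attributes, "gene_id"),
           start0 = .data$start - 1L)
  gene_rows <- df %>% filter(.data$feature == "gene")
  cds_rows <- df %>% filter(.data$feature == "CDS")
  sl_rows <- df %>% filter(.data$feature == "stem_loop")
  exon_rows <- df %>% filter(.data$feature == "exon")
  genes <- gene_rows %>%
    transmute(.data$gene_id, .data$chrom, .data$strand,
              tx_start = .data$start0, tx_end = .data$end,
              gene_class = att(.data$attributes, "gene_class"),
              class_override = att(.data$attributes, "class_override") == "true",
              biotype = dplyr::coalesce(att(.data$attributes, "gene_biotype"),
                                        "histone")) %>%
    left_join(cds_rows %>%
                transmute(.data$gene_id, cds_start = .data$start0,
                          cds_end = .data$end),
              by = "gene_id") %>%
    left_join(sl_rows %>%
                transmute(.data$gene_id, sl_start = .data$start0,
                          sl_end = .data$end),
              by = "gene_id")
  ex <- exon_rows %>%
    transmute(.data$gene_id, start = .data$start0, end = .data$end) %>%
    tidyr::nest(exons = c("start", "end"))
  genes <- genes %>% left_join(ex, by = "gene_id")
  classify_genes(genes,
                 overrides = genes$gene_id[isTRUE_vec(genes$class_override)])
}

isTRUE_vec <- function(x) !is.na(x) & x
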