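# Histone gene architecture: stem-loop detection, RD/RI classification
# and metagene anchor coordinates.
#
# Coordinate conventions (used throughout the package):
#   * all in-memory coordinates are 0-based, half-open [start, end);
#   * 1-based inclusive coordinates appear only in annotated text files;
#   * "the 5'-most base of an element in transcription direction" is the
#     numerically smallest coordinate on "+" and the largest on "-".

DNA_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# reverse complement of a character vector of DNA strings
revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Detect the highest-scoring hairpin in a sequence window
#'
#' Exhaustively scans all (position, stem length, loop length)
#' combinations for a hairpin whose 3' arm is the reverse complement of
#' its 5' arm up to `max_mismatches` mismatched base pairs. The score of
#' a candidate is the number of paired bases minus one penalty point per
#' mismatch (`stem_len - 2 * n_mismatches`). Ties are broken by longer
#' stem, then leftmost position, then smaller loop, which makes the
#' result deterministic given sequence and parameters.
#'
#' Defaults describe the canonical metazoan histone stem-loop: a 6-bp
#' stem with a 4-nt loop.
#'
#' @param window DNA string over A/C/G/T/N to scan. N never pairs.
#' @param stem_len_range,loop_len_range Integer pairs (min, max) of stem
#'   and loop lengths, in nt.
#' @param max_mismatches Maximum mismatched base pairs in the stem.
#' @param min_score Minimum score for a hit to be reported.
#' @return A one-row tibble with `arm5_start` (0-based offset within the
#'   window), `stem_len`, `loop_len`, `n_mismatches` and `score`, or
#'   `NULL` when no candidate reaches `min_score`.
#' @examples
#' hp <- paste0("ACGGCT", "TCAT", "AGCCGT")  # perfect 6-bp stem, 4-nt loop
#' detect_stem_loop(paste0("TTTTT", hp, "TTTTT"))
#' @export
detect_stem_loop <- function(window,
                             stem_len_range = c(5L, 7L),
                             loop_len_range = c(3L, 5L),
                             max_mismatches = 1L,
                             min_score = 4L) {
  stopifnot(is.character(window), length(window) == 1, nzchar(window))
  if (str_detect(window, "[^ACGTN]")) {
    abort("window contains non-DNA characters (allowed: A, C, G, T, N)")
  }
  if (stem_len_range[1] > stem_len_range[2] ||
      loop_len_range[1] > loop_len_range[2] || stem_len_range[1] < 1 ||
      loop_len_range[1] < 0) {
    abort("degenerate stem/loop length range")
  }
  cv <- strsplit(window, "")[[1]]
  compv <- unname(COMPLEMENT[cv])
  compv[cv == "N"] <- "."           # N never pairs with anything
  n <- length(cv)
  best <- NULL
  for (s in seq(stem_len_range[1], stem_len_range[2])) {
    for (l in seq(loop_len_range[1], loop_len_range[2])) {
      span <- 2L * s + l
      if (span > n) next
      p0 <- 0:(n - span)            # 0-based arm5 start candidates
      mism <- integer(length(p0))
      for (i in seq_len(s)) {
        # base i of the 5' arm pairs with base (s + 1 - i) of the 3' arm
        mism <- mism + (cv[p0 + span + 1L - i] != compv[p0 + i])
      }
      keep <- mism <= max_mismatches
      if (!any(keep)) next
      cand <- tibble(arm5_start = p0[keep], stem_len = s, loop_len = l,
                     n_mismatches = mism[keep],
                     score = s - 2L * mism[keep])
      best <- bind_rows(best, cand)
    }
  }
  if (is.null(best)) return(NULL)
  best <- best %>%
    filter(.data$score >= min_score) %>%
    arrange(desc(.data$score), desc(.data$stem_len), .data$arm5_start,
            .data$loop_len)
  if (nrow(best) == 0) return(NULL)
  best[1, ]
}

#' Validate a gene-model table
#'
#' A gene-model table has one row per gene with columns `gene_id`,
#' `chrom`, `strand` ("+"/"-"), `tx_start`, `tx_end` (transcript span),
#' `cds_start`, `cds_end` (first base of ATG through last base of the
#' stop codon), `exons` (list column of tibbles with `start`, `end`),
#' `sl_start`, `sl_end` (stem-loop element, `NA` if absent), and after
#' [classify_genes()] also `gene_class` and `class_override`. All
#' coordinates genomic, 0-based half-open.
#'
#' @param genes A gene-model tibble.
#' @return `genes`, invisibly; aborts on violated invariants.
#' @export
validate_genes <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "sl_start", "sl_end")
  missing <- setdiff(need, names(genes))
  if (length(missing) > 0) {
    abort(paste0("gene table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id) > 0) abort("duplicated gene_id")
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  cds_len <- genes$cds_end - genes$cds_start
  if (any(cds_len %% 3L != 0L)) {
    abort("CDS length (start through stop codon) must be divisible by 3")
  }
  sp <- gene_spacer(genes)
  bad <- !is.na(sp) & sp < 0
  if (any(bad)) {
    abort("stem-loop must lie strictly downstream of the stop codon")
  }
  invisible(genes)
}

#' Stop-codon-to-stem-loop spacer length per gene
#'
#' The distance in nt from the base after the stop codon's 3' end to the
#' base before the stem-loop's 5' base (transcription orientation);
#' `NA` for genes without a stem-loop. In RD histone genes this spacer
#' is 31 to 57 nt long.
#'
#' @param genes A gene-model tibble.
#' @return Integer vector, one value per gene.
#' @export
gene_spacer <- function(genes) {
  ifelse(is.na(genes$sl_start), NA_integer_,
         ifelse(genes$strand == "+",
                genes$sl_start - genes$cds_end,
                genes$cds_start - genes$sl_end))
}

#' Classify histone genes as replication-dependent or -independent
#'
#' A gene is RD iff it carries the conserved 3' stem-loop; all other
#' genes are RI. Genes named in `overrides` receive the flipped class
#' with `class_override = TRUE` — this models histone variants that
#' carry a stem-loop but are conventionally treated as RI. Flipping an
#' RI gene (no stem-loop) to RD is rejected, because a metagene profile
#' cannot be anchored without the element.
#'
#' @param genes A gene-model tibble (see [validate_genes()]).
#' @param overrides Character vector of gene ids whose class is flipped.
#' @return `genes` with `gene_class` and `class_override` columns set.
#' @export
classify_genes <- function(genes, overrides = character()) {
  validate_genes(genes)
  unknown <- setdiff(overrides, genes$gene_id)
  if (length(unknown) > 0) {
    abort(paste0("override names unknown gene(s): ",
                 paste(unknown, collapse = ", ")))
  }
  has_sl <- !is.na(genes$sl_start)
  flip <- genes$gene_id %in% overrides
  if (any(flip & !has_sl)) {
    abort("cannot override an RI gene to RD: no stem-loop to anchor on")
  }
  genes %>%
    mutate(gene_class = if_else(xor(has_sl, flip), "RD", "RI"),
           class_override = flip)
}

#' Metagene anchor coordinates for each gene
#'
#' Returns, per gene, the genomic coordinate of the 5'-most base (in
#' transcription direction) of the start codon, the stop codon and the
#' stem-loop element. On the "-" strand the 5'-most base is the
#' numerically larger end of the element. `stemloop_anchor` is `NA` for
#' genes without a stem-loop; downstream code that requires it must
#' fail loudly rather than guess.
#'
#' @param genes A gene-model tibble.
#' @return Tibble with `gene_id`, `chrom`, `strand`, `start_anchor`,
#'   `stop_anchor`, `stemloop_anchor` (0-based genomic positions).
#' @export
gene_anchors <- function(genes) {
  validate_genes(genes)
  plus <- genes$strand == "+"
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    strand = genes$strand,
    start_anchor = ifelse(plus, genes$cds_start, genes$cds_end - 1L),
    stop_anchor = ifelse(plus, genes$cds_end - 3L, genes$cds_start + 2L),
    stemloop_anchor = ifelse(is.na(genes$sl_start), NA_integer_,
                             ifelse(plus, genes$sl_start, genes$sl_end - 1L))
  )
}

# map transcript coordinates (0-based, 0 = first base of the start
# codon here; values may exceed the transcript or be negative for
# flanks) to genomic coordinates, strand-aware; vectorized
tx_to_genomic <- function(strand, tx_start, tx_end, t) {
  ifelse(strand == "+", tx_start + t, tx_end - 1L - t)
}

# transcript length in nt
tx_len <- function(genes) genes$tx_end - genes$tx_start
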