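# Anchored metagene machinery: +/-100 nt windows around start codon,
# stop codon or stem-loop; the three-anchor binned full-gene profile
# (100-nt flank / 100 CDS bins / 31 spacer bins / unbinned stem-loop /
# 100-nt flank); the crosslink peak offset; and mature-vs-precursor
# calls from termination sites.
#
# Offset convention ("N nt upstream of the stem-loop"): the anchor is
# the 5'-most base of the element in transcription direction and sits
# at offset 0; one base 5' of it is offset -1. The recovered peak
# offset is reported as a positive distance in nt upstream.

anchor_column <- c(start = "start_anchor", stop = "stop_anchor",
                   stemloop = "stemloop_anchor")

#' Anchored window coverage across genes
#'
#' Maps every track event within `flank` nt of the chosen anchor of
#' each gene to a transcription-orientation offset (negative =
#' upstream of the anchor) and sums events over genes. Only events on
#' each gene's own strand (sense) are counted. Windows that would
#' extend past a chromosome boundary are truncated; the number of
#' affected genes is attached as attribute `n_truncated_windows` when
#' `chrom_lengths` is supplied.
#'
#' @param track Track tibble from [extract_crosslinks()] or
#'   [extract_terminations()].
#' @param genes Gene-model tibble; genes lacking the requested anchor
#'   are skipped (count in attribute `n_skipped_genes`).
#' @param anchor `"stemloop"`, `"start"` or `"stop"`.
#' @param flank Window half-width in nt (default 100).
#' @param chrom_lengths Optional named vector for boundary accounting.
#' @return Tibble with `offset` (-flank..flank, offset 0 = anchor base)
#'   and `events`.
#' @export
window_coverage <- function(track, genes, anchor = c("stemloop", "start",
                                                     "stop"),
                            flank = 100L, chrom_lengths = NULL) {
  anchor <- match.arg(anchor)
  an <- gene_anchors(genes)
  an$anchor_pos <- an[[anchor_column[[anchor]]]]
  skipped <- sum(is.na(an$anchor_pos))
  an <- an %>% filter(!is.na(.data$anchor_pos))
  if (nrow(an) == 0) abort("no gene carries the requested anchor")
  ev <- track %>%
    inner_join(an %>% select("chrom", "strand", "anchor_pos"),
               by = c("chrom", "strand"),
               relationship = "many-to-many") %>%
    mutate(offset = if_else(.data$strand == "+",
                            .data$pos - .data$anchor_pos,
                            .data$anchor_pos - .data$pos)) %>%
    filter(abs(.data$offset) <= flank) %>%
    count(.data$offset, wt = .data$count, name = "events")
  out <- tibble(offset = seq(-flank, flank)) %>%
    left_join(ev, by = "offset") %>%
    mutate(events = as.integer(replace_na(.data$events, 0L)))
  attr(out, "n_skipped_genes") <- skipped
  if (!is.null(chrom_lengths)) {
    lens <- unname(chrom_lengths[an$chrom])
    attr(out, "n_truncated_windows") <-
      sum(an$anchor_pos - flank < 0 | an$anchor_pos + flank >= lens)
  }
  attr(out, "anchor") <- anchor
  out
}

#' Bin a per-position coverage vector into equal-sized bins
#'
#' Positions are partitioned into `n_bins` contiguous runs whose sizes
#' differ by at most one; when the length is not divisible, the extra
#' positions go to the leftmost bins. Each bin's value is the
#' arithmetic mean of its positions, so
#' `sum(value * n_positions) == sum(values)` exactly.
#'
#' @param values Numeric vector of per-position coverage.
#' @param n_bins Number of bins; must not exceed `length(values)`.
#' @return Tibble with `bin`, `n_positions`, `value`.
#' @export
bin_region <- function(values, n_bins) {
  len <- length(values)
  if (len < n_bins) {
    abort(sprintf("region of %d positions is too short for %d bins",
                  len, n_bins))
  }
  base <- len %/% n_bins
  sizes <- rep(base, n_bins)
  rem <- len %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  assignment <- rep(seq_len(n_bins), sizes)
  means <- as.numeric(tapply(values, assignment, mean))
  tibble(bin = seq_len(n_bins), n_positions = sizes, value = means)
}

# per-position coverage of one gene along transcription-orientation
# offsets t (relative to the start-codon anchor); positions outside the
# chromosome return 0
gene_coverage <- function(track, gene_row, t) {
  dir <- if (gene_row$strand == "+") 1L else -1L
  anchor <- if (gene_row$strand == "+") gene_row$cds_start else
    gene_row$cds_end - 1L
  pos <- anchor + dir * t
  tr <- track %>%
    filter(.data$chrom == gene_row$chrom, .data$strand == gene_row$strand)
  cov <- tr$count[match(pos, tr$pos)]
  replace_na(cov, 0L)
}

#' Three-anchor binned full-gene metagene profile
#'
#' For each stem-loop-bearing gene, the coverage from 100 nt upstream
#' of the start codon to 100 nt downstream of the stem-loop is laid out
#' in transcription orientation and partitioned into five segments:
#' the upstream flank (100 unbinned positions), the CDS (start through
#' stop codon, `cds_bins` bins), the stop-codon-to-stem-loop spacer
#' (`spacer_bins` bins), the stem-loop element (unbinned positions) and
#' the downstream flank (100 unbinned positions). Binned segments carry
#' the average position-wise coverage per bin. Values are raw event
#' counts, deliberately unnormalised.
#'
#' @param track Track tibble (one library).
#' @param genes Gene-model tibble; genes without a stem-loop are
#'   excluded with a warning count in attribute `n_skipped_genes`.
#' @param cds_bins,spacer_bins Bin counts (defaults 100 and 31).
#' @param flank Flank length in nt (default 100).
#' @param per_gene Return one profile per gene instead of the sum over
#'   genes.
#' @return Tibble with `segment` (ordered factor upstream/cds/spacer/
#'   stemloop/downstream), `index` (position or bin within segment) and
#'   `value`; plus `gene_id` when `per_gene = TRUE`.
#' @export
full_gene_profile <- function(track, genes, cds_bins = 100L,
                              spacer_bins = 31L, flank = 100L,
                              per_gene = FALSE) {
  rd <- genes %>% filter(!is.na(.data$sl_start))
  skipped <- nrow(genes) - nrow(rd)
  if (skipped > 0) {
    warn(sprintf("%d gene(s) without a stem-loop excluded from the profile",
                 skipped))
  }
  if (nrow(rd) == 0) abort("no stem-loop-bearing genes to profile")
  sl_lens <- rd$sl_end - rd$sl_start
  if (length(unique(sl_lens)) != 1) {
    abort("stem-loop element lengths differ between genes; cannot aggregate")
  }
  seg_levels <- c("upstream", "cds", "spacer", "stemloop", "downstream")
  profs <- map_dfr(seq_len(nrow(rd)), function(i) {
    g <- rd[i, ]
    cds_len <- g$cds_end - g$cds_start
    spacer_len <- gene_spacer(g)
    sl_len <- g$sl_end - g$sl_start
    t_all <- seq(-flank, cds_len + spacer_len + sl_len + flank - 1L)
    cov <- gene_coverage(track, g, t_all)
    o <- flank                                  # index of t = 0
    up <- cov[seq_len(flank)]
    cds <- cov[o + seq_len(cds_len)]
    spacer <- cov[o + cds_len + seq_len(spacer_len)]
    sl <- cov[o + cds_len + spacer_len + seq_len(sl_len)]
    down <- cov[o + cds_len + spacer_len + sl_len + seq_len(flank)]
    bind_rows(
      tibble(segment = "upstream", index = seq_len(flank),
             n_positions = 1L, value = as.numeric(up)),
      bin_region(cds, cds_bins) %>%
        transmute(segment = "cds", index = .data$bin, .data$n_positions,
                  .data$value),
      bin_region(spacer, spacer_bins) %>%
        transmute(segment = "spacer", index = .data$bin, .data$n_positions,
                  .data$value),
      tibble(segment = "stemloop", index = seq_len(sl_len),
             n_positions = 1L, value = as.numeric(sl)),
      tibble(segment = "downstream", index = seq_len(flank),
             n_positions = 1L, value = as.numeric(down))
    ) %>%
      mutate(gene_id = g$gene_id)
  })
  profs <- profs %>%
    mutate(segment = factor(.data$segment, levels = seg_levels))
  out <- if (per_gene) {
    profs %>% select("gene_id", "segment", "index", "n_positions", "value")
  } else {
    profs %>%
      group_by(.data$segment, .data$index) %>%
      summarise(value = sum(.data$value), .groups = "drop") %>%
      arrange(.data$segment, .data$index)
  }
  attr(out, "n_skipped_genes") <- skipped
  out
}

#' Aggregate per-library metagene profiles
#'
#' @param profiles Tibble of per-library profiles: a `library` column
#'   plus `segment`, `index`, `value` (window profiles use `offset`
#'   instead of `segment`/`index`).
#' @param mode `"total"` sums across libraries; `"mean_sd"` returns the
#'   per-position mean and SD across libraries.
#' @return Aggregated tibble.
#' @export
aggregate_profiles <- function(profiles, mode = c("total", "mean_sd")) {
  mode <- match.arg(mode)
  keys <- intersect(c("segment", "index", "offset"), names(profiles))
  g <- profiles %>% group_by(across(all_of(keys)))
  if (mode == "total") {
    g %>% summarise(value = sum(.data$value), .groups = "drop")
  } else {
    g %>% summarise(mean = mean(.data$value),
                    sd = sd(.data$value), .groups = "drop")
  }
}

#' Modal crosslink offset upstream of the stem-loop
#'
#' Takes a stem-loop-anchored window profile (total over libraries) and
#' returns the modal event position strictly upstream of the anchor as
#' a positive distance in nt. Ties are broken toward the anchor
#' (smallest distance) and flagged.
#'
#' @param profile Tibble with `offset` and `events`, e.g. from
#'   [window_coverage()].
#' @return One-row tibble with `offset_nt`, `peak_height`,
#'   `tie_broken`.
#' @export
peak_offset <- function(profile) {
  up <- profile %>% filter(.data$offset < 0)
  if (nrow(up) == 0 || all(up$events == 0)) {
    abort("no signal upstream of the anchor: cannot locate a peak")
  }
  peak <- max(up$events)
  cand <- up$offset[up$events == peak]
  tibble(offset_nt = -max(cand),       # smallest upstream distance
         peak_height = peak,
         tie_broken = length(cand) > 1)
}

#' Classify termination events as mature or precursor 3' ends
#'
#' Termination events within `tol` nt of a gene's stem-loop 3' end are
#' called mature; events further downstream (up to `flank` nt) are
#' called precursor. Events inside the gene body upstream of that
#' window are not counted.
#'
#' @param term_track Termination track (build with `min_trim >= 6` so
#'   read ends are genuine RNA 3' ends).
#' @param genes Gene-model tibble (stem-loop-bearing genes only are
#'   used).
#' @param tol Tolerance in nt around the mature end (default 5).
#' @param flank Downstream extent of the precursor window (default
#'   100).
#' @return Per-gene tibble with `n_mature`, `n_precursor`,
#'   `mature_fraction`; pooled counts in attribute `pooled`.
#' @export
maturity_calls <- function(term_track, genes, tol = 5L, flank = 100L) {
  rd <- genes %>% filter(!is.na(.data$sl_start))
  if (nrow(rd) == 0) abort("no stem-loop-bearing genes")
  ends <- rd %>%
    transmute(.data$gene_id, .data$chrom, .data$strand,
              end_anchor = if_else(.data$strand == "+",
                                   .data$sl_end - 1L, .data$sl_start))
  ev <- term_track %>%
    inner_join(ends, by = c("chrom", "strand"),
               relationship = "many-to-many") %>%
    mutate(d = if_else(.data$strand == "+",
                       .data$pos - .data$end_anchor,
                       .data$end_anchor - .data$pos)) %>%
    filter(.data$d >= -tol, .data$d <= flank)
  calls <- ev %>%
    group_by(.data$gene_id) %>%
    summarise(n_mature = sum(.data$count[abs(.data$d) <= tol]),
              n_precursor = sum(.data$count[.data$d > tol]),
              .groups = "drop")
  out <- ends %>%
    select("gene_id") %>%
    left_join(calls, by = "gene_id") %>%
    mutate(across(c("n_mature", "n_precursor"),
                  ~ as.integer(replace_na(.x, 0L))),
           mature_fraction = .data$n_mature /
             (.data$n_mature + .data$n_precursor))
  pooled_m <- sum(out$n_mature)
  pooled_p <- sum(out$n_precursor)
  attr(out, "pooled") <- list(n_mature = pooled_m, n_precursor = pooled_p,
                              mature_fraction = pooled_m /
                                (pooled_m + pooled_p))
  out
}
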