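# Strand-resolved single-nucleotide event tracks.
#
# Crosslink sites (truncation iCLIP): reverse transcription stops at
# the crosslinked nucleotide, so the contact point is the base
# immediately 5' of the read in transcript orientation:
#
#          + strand read  [s, e)     events at  s - 1  on "+"
#          - strand read  [s, e)     events at  e      on "-"
#
#   genomic coords:   ... s-1 | s  .....  e-1 | e ...
#   "+" read 5'----------^    |================|
#   "-" read 5'--------------------------------^   (read runs e-1 -> s)
#
# A "-" strand read's 5' end is its numerically largest base (e - 1),
# so the base 5' of it in transcript orientation is e. Off-by-one
# errors here are the classic iCLIP bug, hence the diagram.

new_track <- function(df, n_dropped_at_ends = 0L) {
  out <- df %>%
    count(.data$chrom, .data$strand, .data$pos, name = "count") %>%
    arrange(.data$chrom, .data$strand, .data$pos)
  attr(out, "n_dropped_at_ends") <- n_dropped_at_ends
  attr(out, "total_events") <- sum(out$count)
  out
}

#' Extract crosslink sites from aligned reads
#'
#' The event position is one nt upstream of each read's 5' end in
#' transcript orientation (see the diagram in the source). Reads mapped
#' directly at a chromosome end have no upstream base; they are removed
#' and counted in the `n_dropped_at_ends` attribute.
#'
#' @param alignments Alignment tibble (`chrom`, `strand`, `start`,
#'   `end`, 0-based half-open).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return Track tibble (`chrom`, `strand`, `pos`, `count`) with
#'   attributes `total_events` and `n_dropped_at_ends`.
#' @export
extract_crosslinks <- function(alignments, chrom_lengths) {
  len <- unname(chrom_lengths[alignments$chrom])
  if (anyNA(len) || any(alignments$start < 0) ||
      any(alignments$end > len)) {
    abort("alignment outside chromosome bounds: corrupt input")
  }
  at_end <- ifelse(alignments$strand == "+",
                   alignments$start == 0L,
                   alignments$end == len)
  kept <- alignments[!at_end, ]
  events <- kept %>%
    transmute(.data$chrom, .data$strand,
              pos = if_else(.data$strand == "+",
                            .data$start - 1L, .data$end))
  new_track(events, n_dropped_at_ends = sum(at_end))
}

#' Extract read-termination sites from aligned reads
#'
#' The 3'-most aligned base of a read marks the 3' end of its RNA
#' insert, but only when enough adapter was trimmed from the read's 3'
#' end to prove the read ran into the adapter (at least `min_trim` nt).
#' Reads trimmed less contribute nothing.
#'
#' @param alignments Alignment tibble carrying `n_trimmed_3p`.
#' @param min_trim Minimum 3'-trimmed length in nt (default 6).
#' @return Track tibble with attributes `total_events`,
#'   `n_dropped_at_ends` (always 0) and `min_trim_used`.
#' @export
extract_terminations <- function(alignments, min_trim = 6L) {
  kept <- alignments %>% filter(.data$n_trimmed_3p >= min_trim)
  events <- kept %>%
    transmute(.data$chrom, .data$strand,
              pos = if_else(.data$strand == "+",
                            .data$end - 1L, .data$start))
  out <- new_track(events)
  attr(out, "min_trim_used") <- min_trim
  out
}
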