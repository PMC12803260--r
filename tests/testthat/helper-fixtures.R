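# Shared fixtures: a small simulated study cached per seed, and
# constructors for hand-built gene models and count tables.

tiny_cfg <- function(...) {
  slclip_config(genome = list(n_rd_genes = 3, n_ri_genes = 2,
                              n_other_genes = 5),
                iclip = list(n_reads = 1500), ...)
}

.fixture_cache <- new.env(parent = emptyenv())

tiny_sim <- function(seed = 5) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_genome(tiny_cfg(), seed = seed)
  }
  .fixture_cache[[key]]
}

tiny_library <- function(seed = 5, role = "IP", sample = "IP1") {
  key <- paste0("lib", seed, role, sample)
  if (is.null(.fixture_cache[[key]])) {
    sim <- tiny_sim(seed)
    .fixture_cache[[key]] <- simulate_iclip_library(
      sim$genome, sim$genes, tiny_cfg(), role = role, sample = sample,
      seed = seed + 17)
  }
  .fixture_cache[[key]]
}

chrom_lengths_of <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

mk_gene <- function(gene_id = "g1", chrom = "chrS", strand = "+",
                    tx_start, tx_end, cds_start, cds_end,
                    sl_start = NA_integer_, sl_end = NA_integer_) {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    sl_start = as.integer(sl_start), sl_end = as.integer(sl_end),
    exons = list(tibble::tibble(start = as.integer(tx_start),
                                end = as.integer(tx_end))))
}

count_tbl <- function(m, libs = paste0("L", seq_len(ncol(m)))) {
  df <- tibble::as_tibble(m, .name_repair = ~libs)
  dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", seq_len(nrow(m)))),
                   df)
}

mk_track <- function(chrom = "chrS", strand = "+", pos, count = 1L) {
  tibble::tibble(chrom = chrom, strand = strand, pos = as.integer(pos),
                 count = as.integer(count)) |>
    dplyr::count(chrom, strand, pos, wt = count, name = "count") |>
    dplyr::arrange(chrom, strand, pos)
}

revcomp_test <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

counts_mat_test <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  m
}

# drop custom attributes so content comparisons ignore bookkeeping
plain_df <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[intersect(names(attributes(x)),
                                           c("names", "row.names", "class"))]
  rownames(x) <- NULL
  x
}
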