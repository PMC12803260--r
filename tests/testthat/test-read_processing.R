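phred_chr <- function(q) intToUtf8(q + 33)

test_that("quality filter inspects only the barcode/UMI region", {
  seq40 <- strrep("A", 40)
  q_ok <- strrep("I", 40)
  q_bc <- paste0(strrep("I", 6), phred_chr(9), strrep("I", 33))   # pos 7
  q_ins <- paste0(strrep("I", 20), phred_chr(2), strrep("I", 19)) # pos 21
  reads <- tibble::tibble(
    read_id = c("ok", "bad_bc", "bad_ins", "short"),
    sequence = c(seq40, seq40, seq40, "ACGT"),
    quality = c(q_ok, q_bc, q_ins, "IIII"))
  out <- quality_filter(reads, phred_min = 10, header_len = 15)
  expect_setequal(out$read_id, c("ok", "bad_ins"))
  expect_equal(attr(out, "n_quality_dropped"), 1)
  expect_equal(attr(out, "n_too_short_raw"), 1)
})

test_that("demultiplexing is exact-match on positions 6-11 with UMI capture", {
  mk <- function(umi1, bc, umi2) {
    tibble::tibble(read_id = "r1",
                   sequence = paste0(umi1, bc, umi2, strrep("A", 30)),
                   quality = strrep("I", 45))
  }
  tab <- c(S1 = "ACGTAC")
  hit <- demultiplex(mk("GATCA", "ACGTAC", "TTGG"), tab)
  expect_equal(hit$sample, "S1")
  expect_equal(hit$umi, "GATCATTGG")
  miss <- demultiplex(mk("GATCA", "ACGTAA", "TTGG"), tab)  # one mismatch
  expect_true(is.na(miss$sample))
  none <- demultiplex(mk("GATCA", "ACGTAC", "TTGG"), character(0))
  expect_true(is.na(none$sample))
  expect_error(demultiplex(mk("GATCA", "ACGTAC", "TTGG"),
                           c(S1 = "ACGTAC", S2 = "ACGTAC")),
               "duplicate")
})

test_that("adapter trimming records removed length and enforces min length", {
  adapter <- "AGATCGGAAGAG"
  mk <- function(insert, tail = "") {
    tibble::tibble(read_id = paste0("r", seq_along(insert)),
                   sample = "S1", umi = "AAAAACCCC",
                   sequence = paste0(strrep("G", 15), insert, tail),
                   quality = strrep("I", 15 + nchar(insert) + nchar(tail)))
  }
  # full adapter after a 20-nt insert
  full <- trim_adapters(mk(strrep("C", 20), adapter), adapter)
  expect_equal(full$n_trimmed_3p, nchar(adapter))
  expect_equal(nchar(full$insert), 20)
  # post-trim insert of 14 nt is removed
  short <- trim_adapters(mk(strrep("C", 14), adapter), adapter)
  expect_equal(nrow(short), 0)
  expect_equal(attr(short, "n_length_dropped"), 1)
  # a single terminal base matching the adapter start is trimmed
  one <- trim_adapters(mk(paste0(strrep("C", 19), "A")), adapter)
  expect_equal(one$n_trimmed_3p, 1)
  expect_equal(one$insert, strrep("C", 19))
  # no adapter, no trimming
  none <- trim_adapters(mk(strrep("C", 20)), adapter)
  expect_equal(none$n_trimmed_3p, 0)
})

test_that("deduplication keeps the first read and distinguishes UMIs", {
  reads <- tibble::tibble(
    read_id = c("a", "b", "c"),
    sample = "S1",
    umi = c("AAAAACCCC", "AAAAACCCC", "AAAAACCCG"),
    insert = rep(strrep("A", 20), 3),
    insert_qual = rep(strrep("I", 20), 3),
    n_trimmed_3p = 0L)
  dd <- deduplicate(reads)
  expect_equal(dd$read_id, c("a", "c"))   # same UMI collapses, first kept
  expect_equal(attr(dd, "n_duplicates"), 1)
  expect_equal(as.list(deduplicate(dd))[names(reads)],
               as.list(dd)[names(reads)])  # idempotent
  # different samples never collapse
  reads2 <- reads |> dplyr::mutate(sample = c("S1", "S2", "S1"))
  expect_equal(nrow(deduplicate(reads2)), 3)
})

test_that("exact alignment handles strands, multimaps, caps and misses", {
  u <- "ACGTTGCAAGGCTATCGGAT"              # unique 20-mer
  r <- "TTGACCGTAGCACTGAAG"                # planted twice
  genome <- Biostrings::DNAStringSet(setNames(
    paste0(strrep("C", 10), u, strrep("C", 10), r, strrep("C", 10), r,
           strrep("C", 10)), "chrT"))
  mk <- function(id, insert) {
    tibble::tibble(read_id = id, sample = "S1", umi = "AAAAACCCC",
                   insert = insert, insert_qual = strrep("I", nchar(insert)),
                   n_trimmed_3p = 6L)
  }
  # minus-strand hit: the read is the reverse complement of u
  al <- align_exact(mk("m", revcomp_test(u)), genome, seed = 1)
  expect_equal(al$strand, "-")
  expect_equal(al$start, 10)
  expect_equal(al$end, 30)
  # multi-locus read: exactly one alignment, reproducible under the seed
  al1 <- align_exact(mk("r", r), genome, seed = 7)
  al2 <- align_exact(mk("r", r), genome, seed = 7)
  expect_equal(nrow(al1), 1)
  expect_identical(al1, al2)
  expect_true(al1$start %in% c(40, 68))
  # unmapped and locus-capped
  gone <- align_exact(mk("x", strrep("T", 20)), genome, seed = 1)
  expect_equal(nrow(gone), 0)
  expect_equal(attr(gone, "n_unmapped"), 1)
  capped <- align_exact(mk("r", r), genome, seed = 1, max_loci = 1)
  expect_equal(nrow(capped), 0)
  expect_equal(attr(capped, "n_locus_capped"), 1)
})

test_that("the counting ledger balances and alignments match the truth", {
  cfg <- tiny_cfg()
  sim <- tiny_sim(5)
  lib <- tiny_library(5)
  proc <- process_library(lib$reads, sim$genome, cfg, seed = 3)
  led <- setNames(proc$ledger$n, proc$ledger$stage)
  expect_equal(led[["raw"]], nrow(lib$reads))
  expect_equal(led[["raw"]],
               sum(led[c("quality_dropped", "too_short_raw", "unassigned",
                         "length_dropped", "duplicates", "unmapped",
                         "locus_capped", "aligned")]))
  # every aligned read sits exactly where the truth table placed it
  al <- proc$alignments
  tr <- lib$truth[match(al$read_id, lib$truth$read_id), ]
  expect_identical(al$chrom, tr$chrom)
  expect_identical(al$strand, tr$strand)
  expect_equal(al$start, tr$insert_start)
  # noise-free headers: aligned count equals non-duplicate truth rows
  cfg0 <- tiny_cfg(iclip = list(low_qual_rate = 0, n_reads = 800))
  lib0 <- simulate_iclip_library(sim$genome, sim$genes, cfg0, role = "IP",
                                 sample = "IP2", seed = 21)
  proc0 <- process_library(lib0$reads, sim$genome, cfg0, seed = 4)
  expect_equal(nrow(proc0$alignments), sum(!lib0$truth$is_duplicate))
})

test_that("SAM round-trips alignments through the minimal dialect", {
  sim <- tiny_sim(5)
  lib <- tiny_library(5)
  proc <- process_library(lib$reads, sim$genome, tiny_cfg(), seed = 3)
  al <- proc$alignments |> dplyr::slice_head(n = 50)
  path <- tempfile(fileext = ".sam")
  write_sam(al, chrom_lengths_of(sim$genome), path)
  back <- read_sam(path)
  expect_equal(as.list(back)[names(back)], as.list(al)[names(back)])
  expect_error(read_sam({
    p <- tempfile()
    writeLines(c("@HD\tVN:1.6",
                 "r\t0\tchrS\t5\t255\t10M2S\t*\t0\t0\t*\t*"), p)
    p
  }), "CIGAR")
})
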