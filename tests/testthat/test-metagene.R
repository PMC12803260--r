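# one RD gene per strand for window tests: + anchor at 430, - at 119
wgene_plus <- function() {
  mk_gene("p", strand = "+", tx_start = 200, tx_end = 446,
          cds_start = 200, cds_end = 398, sl_start = 430, sl_end = 446)
}
wgene_minus <- function() {
  mk_gene("m", strand = "-", tx_start = 104, tx_end = 350,
          cds_start = 152, cds_end = 350, sl_start = 104, sl_end = 120)
}

test_that("window coverage maps events to strand-aware anchor offsets", {
  g <- wgene_plus()
  at_anchor <- window_coverage(mk_track(pos = 430), g, "stemloop")
  expect_equal(at_anchor$events[at_anchor$offset == 0], 1)
  expect_equal(sum(at_anchor$events), 1)
  expect_equal(nrow(at_anchor), 201)
  up12 <- window_coverage(mk_track(pos = 418), g, "stemloop")
  expect_equal(up12$events[up12$offset == -12], 1)
  gm <- wgene_minus()                      # stem-loop anchor at 119
  m5 <- window_coverage(mk_track(strand = "-", pos = 124), gm, "stemloop")
  expect_equal(m5$events[m5$offset == -5], 1)
  # antisense events are not counted
  anti <- window_coverage(mk_track(strand = "-", pos = 430), g, "stemloop")
  expect_equal(sum(anti$events), 0)
})

test_that("binning is conservative with remainder to the left", {
  b <- bin_region(rep(1, 62), 31)
  expect_equal(b$n_positions, rep(2, 31))
  expect_equal(b$value, rep(1, 31))
  withr::with_seed(12, {
    v <- runif(300)
    b2 <- bin_region(v, 100)
    expect_equal(sum(b2$value * b2$n_positions), sum(v))
    v3 <- runif(317)                       # remainder 17 spread leftmost
    b3 <- bin_region(v3, 100)
    expect_equal(b3$n_positions, c(rep(4, 17), rep(3, 83)))
    expect_equal(sum(b3$value * b3$n_positions), sum(v3))
    expect_equal(b3$value[1], mean(v3[1:4]))
  })
  expect_error(bin_region(1:30, 31), "too short")
})

test_that("the full-gene profile has the fixed segment structure", {
  g <- wgene_plus()
  empty <- full_gene_profile(mk_track(pos = 1)[0, ], g)
  lens <- table(empty$segment)
  expect_equal(as.integer(lens[c("upstream", "cds", "spacer", "stemloop",
                                 "downstream")]),
               c(100, 100, 31, 16, 100))
  expect_true(all(empty$value == 0))
  # a second gene with a different CDS/spacer yields identical structure
  sim <- tiny_sim(5)
  tr <- mk_track(pos = 5)[0, ]
  prof <- full_gene_profile(tr, sim$genes |>
                              dplyr::filter(!is.na(sl_start)))
  expect_equal(nrow(prof), 100 + 100 + 31 + 16 + 100)
  # mean/sd aggregation over identical libraries has zero SD
  two <- dplyr::bind_rows(prof |> dplyr::mutate(library = "a"),
                          prof |> dplyr::mutate(library = "b"))
  agg <- aggregate_profiles(two, "mean_sd")
  expect_true(all(agg$sd == 0))
})

test_that("profile values land in the expected segments", {
  g <- wgene_plus()
  # events at the planted crosslink position (12 nt upstream of the
  # stem-loop at 430) fall in the last spacer bin
  tr <- mk_track(pos = rep(418, 10))
  prof <- full_gene_profile(tr, g)
  spacer <- prof |> dplyr::filter(segment == "spacer")
  expect_equal(sum(spacer$value > 0), 1)
  expect_equal(which(spacer$value > 0), 20)  # (418-398+1)th of 32 spacer nt
  expect_equal(sum(prof$value[prof$segment != "spacer"]), 0)
})

test_that("metagene outputs are invariant under genome reverse-complement", {
  cfg <- tiny_cfg(iclip = list(n_reads = 800))
  sim <- tiny_sim(5)
  lib <- simulate_iclip_library(sim$genome, sim$genes, cfg, role = "IP",
                                sample = "IP1", seed = 13)
  proc <- process_library(lib$reads, sim$genome, cfg, seed = 3)
  cl <- chrom_lengths_of(sim$genome)
  L <- unname(cl[1])
  flip_al <- proc$alignments |>
    dplyr::mutate(start2 = L - end, end2 = L - start,
                  strand = ifelse(strand == "+", "-", "+")) |>
    dplyr::mutate(start = start2, end = end2) |>
    dplyr::select(-start2, -end2)
  flip <- function(a, b) list(start = L - b, end = L - a)
  gf <- sim$genes |>
    dplyr::mutate(strand = ifelse(strand == "+", "-", "+"),
                  tx_start2 = L - tx_end, tx_end2 = L - tx_start,
                  cds_start2 = L - cds_end, cds_end2 = L - cds_start,
                  sl_start2 = L - sl_end, sl_end2 = L - sl_start) |>
    dplyr::mutate(tx_start = tx_start2, tx_end = tx_end2,
                  cds_start = cds_start2, cds_end = cds_end2,
                  sl_start = sl_start2, sl_end = sl_end2) |>
    dplyr::select(-dplyr::ends_with("2"))
  gf$exons <- purrr::map(gf$exons,
                         ~ tibble::tibble(start = L - .x$end,
                                          end = L - .x$start))
  tr <- extract_crosslinks(proc$alignments, cl)
  trf <- extract_crosslinks(flip_al, cl)
  w <- window_coverage(tr, sim$genes, "stemloop", chrom_lengths = cl)
  wf <- window_coverage(trf, gf, "stemloop", chrom_lengths = cl)
  expect_equal(plain_df(w), plain_df(wf))
  p <- full_gene_profile(tr, sim$genes |> dplyr::filter(!is.na(sl_start)))
  pf <- full_gene_profile(trf, gf |> dplyr::filter(!is.na(sl_start)))
  expect_equal(plain_df(p), plain_df(pf))
  te <- extract_terminations(proc$alignments)
  tef <- extract_terminations(flip_al)
  mat <- maturity_calls(te, sim$genes)
  matf <- maturity_calls(tef, gf)
  expect_equal(plain_df(mat), plain_df(matf))
})

test_that("the peak offset is the modal upstream position with tie rules", {
  g <- wgene_plus()
  all12 <- window_coverage(mk_track(pos = rep(418, 7)), g, "stemloop")
  pk <- peak_offset(all12)
  expect_equal(pk$offset_nt, 12)
  expect_equal(pk$peak_height, 7)
  expect_false(pk$tie_broken)
  tie <- window_coverage(mk_track(pos = c(425, 425, 421, 421)), g,
                         "stemloop")
  pt <- peak_offset(tie)                   # -5 and -9 tie; toward anchor
  expect_equal(pt$offset_nt, 5)
  expect_true(pt$tie_broken)
  single <- window_coverage(mk_track(pos = 429), g, "stemloop")
  expect_equal(peak_offset(single)$offset_nt, 1)
  flat <- window_coverage(mk_track(pos = 500), g, "stemloop")
  expect_error(peak_offset(flat), "no signal")
})

test_that("planted offsets are recovered across magnitudes and jitter", {
  g <- wgene_plus()
  anchor <- 430
  for (delta in c(1, 5, 12, 40)) {
    tr <- mk_track(pos = rep(anchor - delta, 50))
    pk <- peak_offset(window_coverage(tr, g, "stemloop"))
    expect_equal(pk$offset_nt, delta)
  }
  # +/-1 nt jitter: the mode still equals delta in >= 95 of 100 runs
  delta <- 12
  hits <- 0
  for (k in 1:100) {
    withr::with_seed(3000 + k, {
      jit <- sample(c(-1, 0, 1), 400, replace = TRUE,
                    prob = c(0.15, 0.7, 0.15))
    })
    tr <- mk_track(pos = anchor - delta - jit)
    pk <- peak_offset(window_coverage(tr, g, "stemloop"))
    if (pk$offset_nt == delta) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("termination sites classify mature versus precursor ends", {
  g <- wgene_plus()                        # stem-loop 3' end base = 445
  mat <- maturity_calls(mk_track(pos = rep(445, 20)), g)
  expect_equal(mat$mature_fraction, 1)
  pre <- maturity_calls(mk_track(pos = rep(495, 20)), g)
  expect_equal(pre$mature_fraction, 0)
  expect_equal(pre$n_precursor, 20)
  both <- maturity_calls(mk_track(pos = c(rep(445, 3), rep(495, 1))), g)
  expect_equal(attr(both, "pooled")$mature_fraction, 0.75)
  # events inside the gene body are not part of the 3' window
  body <- maturity_calls(mk_track(pos = 300), g)
  expect_equal(body$n_mature + body$n_precursor, 0)
})

test_that("simulated maturity is recovered from termination tracks", {
  cfg <- tiny_cfg(iclip = list(n_reads = 3000))
  sim <- tiny_sim(5)
  lib <- simulate_iclip_library(sim$genome, sim$genes, cfg, role = "IP",
                                sample = "IP1", seed = 55)
  proc <- process_library(lib$reads, sim$genome, cfg, seed = 3)
  te <- extract_terminations(proc$alignments, min_trim = 6)
  mat <- maturity_calls(te, sim$genes)
  pooled <- attr(mat, "pooled")
  expect_lt(abs(pooled$mature_fraction - cfg$iclip$mature_fraction), 0.04)
})
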