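test_that("exonic counting is sense-stranded with multi-gene overlap", {
  genes <- dplyr::bind_rows(
    mk_gene("a", strand = "+", tx_start = 100, tx_end = 300,
            cds_start = 100, cds_end = 250),
    mk_gene("b", strand = "-", tx_start = 280, tx_end = 500,
            cds_start = 320, cds_end = 500))
  al <- tibble::tibble(
    read_id = c("in_a", "anti_a", "nowhere", "both"),
    sample = c("L1", "L1", "L1", "L2"),
    umi = "AAAAACCCC",
    chrom = "chrS",
    strand = c("+", "-", "+", "+"),
    start = c(150L, 150L, 600L, 290L),
    end = c(180L, 180L, 630L, 299L),
    n_trimmed_3p = 0L)
  cm <- count_exonic(al, genes)
  expect_equal(cm$L1[cm$gene_id == "a"], 1)      # sense read counts
  expect_equal(sum(cm$L1), 1)                    # antisense+nowhere do not
  expect_equal(cm$L2[cm$gene_id == "a"], 1)      # one read, both genes...
  expect_equal(cm$L2[cm$gene_id == "b"], 0)      # ...but only sense ones
  expect_equal(as.integer(attr(cm, "n_unassigned")["L1"]), 2)
})

test_that("size factors match the brute-force median-of-ratios oracle", {
  # symmetry and scaling
  two <- count_tbl(matrix(c(10, 20, 30, 10, 20, 30), ncol = 2))
  expect_equal(unname(size_factors(two)), c(1, 1))
  dbl <- count_tbl(matrix(c(10, 20, 30, 20, 40, 60), ncol = 2))
  sf <- size_factors(dbl)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # 500-gene random matrix against the oracle
  withr::with_seed(21, {
    m <- matrix(rnbinom(500 * 6, mu = 50, size = 5), ncol = 6)
  })
  cm <- count_tbl(m)
  expect_equal(size_factors(cm), sf_brute(counts_mat_test(cm)))
  # independent cross-check against DESeq2's implementation
  skip_if_not_installed("DESeq2")
  expect_equal(unname(size_factors(cm)),
               unname(DESeq2::estimateSizeFactorsForMatrix(
                 counts_mat_test(cm))),
               tolerance = 1e-6)
  # all-zero-containing reference must be flagged
  z <- count_tbl(rbind(c(0, 5, 5, 5), c(5, 0, 5, 5)))
  expect_error(size_factors(z), "pseudo_reference")
  expect_silent(size_factors(z, pseudo_reference = TRUE))
})

test_that("fold changes are zero for proportional counts and scale-invariant", {
  roles <- setNames(rep(c("IP", "control"), each = 2), paste0("L", 1:4))
  sf <- setNames(c(1, 2, 1, 4), paste0("L", 1:4))
  m <- outer(c(20, 50, 80), unname(sf))
  res <- nb_wald_test(count_tbl(m), roles, sf = sf)
  expect_equal(res$log2FC, rep(0, 3), tolerance = 1e-9)
  # multiplying one library and its size factor leaves log2FC unchanged
  withr::with_seed(8, {
    m2 <- matrix(rnbinom(200 * 4, mu = 60, size = 8), ncol = 4)
  })
  r1 <- nb_wald_test(count_tbl(m2), roles,
                     sf = setNames(rep(1, 4), paste0("L", 1:4)))
  m3 <- m2
  m3[, 2] <- m3[, 2] * 5
  r2 <- nb_wald_test(count_tbl(m3), roles,
                     sf = setNames(c(1, 5, 1, 1), paste0("L", 1:4)))
  expect_equal(r2$log2FC, r1$log2FC, tolerance = 1e-9)
})

test_that("the NB Wald test is calibrated under the null", {
  roles <- setNames(rep(c("IP", "control"), each = 4), paste0("L", 1:8))
  sf1 <- setNames(rep(1, 8), paste0("L", 1:8))
  withr::with_seed(424, {
    nreps <- 200
    frac <- numeric(nreps)
    for (r in seq_len(nreps)) {
      mu <- exp(runif(2000, log(20), log(200)))
      m <- matrix(rnbinom(2000 * 8, mu = rep(mu, 8), size = 1 / 0.1),
                  ncol = 8)
      frac[r] <- mean(nb_wald_test(count_tbl(m), roles, sf = sf1)$p < 0.05,
                      na.rm = TRUE)
    }
    expect_gt(mean(frac), 0.03)
    expect_lt(mean(frac), 0.07)
  })
})

test_that("planted eight-fold enrichment is detected with high power", {
  roles <- setNames(rep(c("IP", "control"), each = 4), paste0("L", 1:8))
  withr::with_seed(99, {
    ngene <- 2000
    base <- rep(1e5 / ngene, ngene)
    planted <- seq_len(50)
    mu <- sapply(seq_len(8), function(j) {
      mm <- base
      if (j <= 4) mm[planted] <- mm[planted] * 8
      mm
    })
    m <- matrix(rnbinom(ngene * 8, mu = mu, size = 1 / 0.1), ncol = 8)
  })
  res <- nb_wald_test(count_tbl(m), roles)
  expect_gte(mean(res$significant[planted]), 0.9)
  expect_lt(mean(res$significant[-planted]), 0.02)
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  withr::with_seed(3, {
    for (i in 1:1000) {
      p <- runif(sample(3:60, 1))^sample(1:3, 1)
      expect_equal(p.adjust(p, "BH"), bh_brute(p))
    }
  })
})

test_that("all-zero genes are excluded from testing and BH", {
  roles <- setNames(rep(c("IP", "control"), each = 2), paste0("L", 1:4))
  m <- rbind(c(40, 44, 5, 6), c(0, 0, 0, 0), c(12, 9, 11, 13))
  res <- nb_wald_test(count_tbl(m), roles,
                      sf = setNames(rep(1, 4), paste0("L", 1:4)))
  expect_true(is.na(res$p[2]))
  expect_true(is.na(res$padj[2]))
  expect_false(res$significant[2])
  expect_equal(res$padj[c(1, 3)], p.adjust(res$p[c(1, 3)], "BH"))
  expect_true(all(res$padj >= res$p, na.rm = TRUE))
})

test_that("labelling maps histone classes and flags other genes", {
  sim <- tiny_sim(5)
  res <- tibble::tibble(gene_id = c(sim$genes$gene_id, "ghost"),
                        baseMean = 1, log2FC = 0, dispersion = 0.1,
                        wald_stat = 0, p = 0.5, padj = 0.9,
                        significant = FALSE)
  lab <- label_and_rank(res, sim$genes)
  expect_setequal(unique(lab$class_label), c("RD", "RI", "other"))
  rd_ids <- sim$genes$gene_id[sim$genes$gene_class == "RD" &
                                sim$genes$biotype == "histone"]
  expect_true(all(lab$class_label[lab$gene_id %in% rd_ids] == "RD"))
  expect_equal(lab$class_label[lab$gene_id == "ghost"], "other")
  oth_ids <- sim$genes$gene_id[sim$genes$biotype == "other"]
  expect_true(all(lab$class_label[lab$gene_id %in% oth_ids] == "other"))
})
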