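# IP-vs-control binding enrichment: stranded exonic counting,
# median-of-ratios normalization and a reduced negative-binomial Wald
# test (gene-wise method-of-moments dispersion, no shrinkage, no
# independent filtering) with Benjamini-Hochberg correction.

#' Count exonic reads per gene and library
#'
#' A read is assigned to a gene when its interval overlaps any exon of
#' that gene on the same strand (sense counting). A read overlapping
#' exons of several genes increments each of them; with the exact
#' aligner every read carries exactly one (primary) alignment, so each
#' alignment is counted once per overlapped gene.
#'
#' @param alignments Alignment tibble with a `sample` column.
#' @param genes Gene-model tibble.
#' @return Wide count tibble: `gene_id` plus one integer column per
#'   sample (all genes present, zero-filled); attribute `n_unassigned`
#'   gives per-sample counts of reads overlapping no annotation.
#' @export
count_exonic <- function(alignments, genes) {
  samples <- sort(unique(alignments$sample))
  exons <- genes %>%
    select("gene_id", "chrom", "strand", "exons") %>%
    tidyr::unnest("exons")
  ex_gr <- GRanges(exons$chrom, IRanges(exons$start + 1L, exons$end),
                   strand = exons$strand)
  rd_gr <- GRanges(alignments$chrom,
                   IRanges(alignments$start + 1L, alignments$end),
                   strand = alignments$strand)
  ov <- findOverlaps(rd_gr, ex_gr)         # strand-aware by default
  assign_tbl <- tibble(read = queryHits(ov),
                       gene_id = exons$gene_id[subjectHits(ov)]) %>%
    distinct()
  counts <- assign_tbl %>%
    mutate(sample = alignments$sample[.data$read]) %>%
    count(.data$gene_id, .data$sample) %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "n",
                       values_fill = 0L)
  out <- tibble(gene_id = genes$gene_id) %>%
    left_join(counts, by = "gene_id")
  for (s in samples) {
    if (!s %in% names(out)) out[[s]] <- 0L
    out[[s]] <- as.integer(replace_na(out[[s]], 0L))
  }
  out <- out %>% select("gene_id", all_of(samples))
  assigned_reads <- unique(assign_tbl$read)
  unassigned <- alignments$sample[setdiff(seq_len(nrow(alignments)),
                                          assigned_reads)]
  attr(out, "n_unassigned") <- table(factor(unassigned, levels = samples))
  out
}

counts_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

#' Median-of-ratios library size factors
#'
#' The reference for each gene is its geometric mean across libraries
#' (genes with any zero count are excluded); each library's size factor
#' is the median over genes of count/reference. With
#' `pseudo_reference = TRUE` the geometric mean is taken over positive
#' counts only (for sparse data without a single all-positive gene).
#'
#' @param counts Wide count tibble from [count_exonic()].
#' @param pseudo_reference Use the positive-count geometric mean.
#' @return Named numeric vector of per-library size factors.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- counts_matrix(counts)
  logm <- log(m)
  if (pseudo_reference) {
    log_ref <- apply(logm, 1, function(x) mean(x[is.finite(x)]))
  } else {
    log_ref <- rowMeans(logm)         # -Inf for genes with any zero
  }
  usable <- is.finite(log_ref)
  if (!any(usable)) {
    abort(paste0("no gene has positive counts in all libraries; ",
                 "re-run with pseudo_reference = TRUE"))
  }
  ref <- exp(log_ref)
  sf <- apply(m, 2, function(cc) {
    r <- (cc / ref)[usable & cc > 0]
    median(r)
  })
  sf
}

#' Reduced negative-binomial Wald test of IP versus control binding
#'
#' Per gene: counts are normalized by the size factors; the fold change
#' is `log2(mu_IP / mu_ctrl)` (a pseudo-count `epsilon` is used for the
#' reported fold change, and for the test statistic only when a group
#' mean is zero); a gene-wise NB dispersion is estimated by method of
#' moments from the pooled within-group variance, moderated toward the
#' across-gene mean dispersion with prior weight `dispersion_prior_df`
#' residual degrees of freedom, and floored at `alpha_floor`; the Wald
#' statistic is the fold change over its delta-method standard error
#' under the NB variance function `Var(K) = mu + alpha * mu^2`,
#' referred to the standard normal; p-values are Benjamini-Hochberg
#' adjusted, with all-zero genes excluded from the correction.
#'
#' This is a deliberately reduced reimplementation of the DESeq2-style
#' analysis (no independent filtering, no outlier handling, no fold-
#' change shrinkage). The dispersion moderation is required for
#' calibration: with a handful of libraries the raw gene-wise
#' method-of-moments estimate is so noisy that the Wald statistic is
#' anti-conservative against its normal reference. Type-I error
#' calibration is checked by simulation in the test suite.
#'
#' @param counts Wide count tibble from [count_exonic()].
#' @param roles Named character vector mapping each library column to
#'   `"IP"` or `"control"`; at least two libraries per group.
#' @param sf Size factors; computed from `counts` when `NULL`.
#' @param fdr Significance threshold on the adjusted p-value
#'   (default 0.01).
#' @param epsilon Pseudo-count for the reported fold change
#'   (default 0.5).
#' @param alpha_floor Lower bound for the dispersion estimate.
#' @param dispersion_prior_df Prior weight (in residual degrees of
#'   freedom) pulling gene-wise dispersions toward the across-gene
#'   mean; 0 disables moderation.
#' @return Tibble with `gene_id`, `baseMean`, `log2FC`, `dispersion`,
#'   `wald_stat`, `p`, `padj`, `significant`.
#' @export
nb_wald_test <- function(counts, roles, sf = NULL, fdr = 0.01,
                         epsilon = 0.5, alpha_floor = 1e-8,
                         dispersion_prior_df = 20) {
  m <- counts_matrix(counts)
  roles <- unlist(roles)
  if (!all(colnames(m) %in% names(roles))) {
    abort("every count column needs a role")
  }
  roles <- roles[colnames(m)]
  ip <- which(roles == "IP")
  ct <- which(roles == "control")
  if (length(ip) < 2 || length(ct) < 2) {
    abort("need at least two IP and two control libraries")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  sf <- sf[colnames(m)]
  x <- sweep(m, 2, sf, "/")           # normalized counts
  mu1 <- rowMeans(x[, ip, drop = FALSE])
  mu0 <- rowMeans(x[, ct, drop = FALSE])
  base_mean <- rowMeans(x)
  # pooled within-group method-of-moments dispersion:
  # Var(x_j) = mu_g / s_j + alpha * mu_g^2 on the normalized scale
  ss <- function(idx, mu) {
    rowSums((x[, idx, drop = FALSE] - mu)^2)
  }
  c1 <- mean(1 / sf[ip])
  c0 <- mean(1 / sf[ct])
  n1 <- length(ip)
  n0 <- length(ct)
  pooled_var <- (ss(ip, mu1) + ss(ct, mu0)) / (n1 + n0 - 2)
  mu_bar <- (n1 * mu1 + n0 * mu0) / (n1 + n0)
  c_bar <- (n1 * c1 + n0 * c0) / (n1 + n0)
  alpha_gene <- pmax((pooled_var - mu_bar * c_bar) / mu_bar^2, alpha_floor)
  alpha_gene[!is.finite(alpha_gene)] <- alpha_floor
  # moderate the noisy gene-wise estimate toward the across-gene mean;
  # with a handful of libraries the raw method-of-moments dispersion
  # makes the Wald test anti-conservative against its normal reference
  d_resid <- n1 + n0 - 2
  alpha_central <- mean(alpha_gene[rowSums(m) > 0])
  if (!is.finite(alpha_central)) alpha_central <- alpha_floor
  alpha <- pmax((dispersion_prior_df * alpha_central +
                   d_resid * alpha_gene) /
                  (dispersion_prior_df + d_resid), alpha_floor)
  # fold change and Wald statistic
  lfc_display <- log2((mu1 + epsilon) / (mu0 + epsilon))
  both_pos <- mu1 > 0 & mu0 > 0
  m1 <- ifelse(both_pos, mu1, mu1 + epsilon)
  m0 <- ifelse(both_pos, mu0, mu0 + epsilon)
  lfc_test <- log2(m1 / m0)
  var_mean <- function(mu, cc, nn) (mu * cc + alpha * mu^2) / nn
  se2 <- (var_mean(m1, c1, n1) / m1^2 + var_mean(m0, c0, n0) / m0^2) /
    log(2)^2
  wald <- lfc_test / sqrt(se2)
  p <- 2 * pnorm(-abs(wald))
  all_zero <- rowSums(m) == 0
  p[all_zero] <- NA_real_
  wald[all_zero] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[!all_zero] <- p.adjust(p[!all_zero], method = "BH")
  tibble(
    gene_id = rownames(m),
    baseMean = unname(base_mean),
    log2FC = unname(lfc_display),
    dispersion = unname(alpha),
    wald_stat = unname(wald),
    p = unname(p),
    padj = unname(padj),
    significant = unname(!is.na(padj) & padj < fdr)
  )
}

#' Attach RD/RI class labels and build a volcano-ready table
#'
#' @param results Tibble from [nb_wald_test()].
#' @param genes Classified gene-model tibble; genes absent from it, or
#'   carrying a `biotype` other than `"histone"`, are labelled
#'   `"other"`.
#' @return `results` with `class_label` and `neg_log10_padj`, ordered
#'   by adjusted p-value.
#' @export
label_and_rank <- function(results, genes) {
  labels <- genes %>%
    mutate(class_label = if ("biotype" %in% names(genes)) {
      if_else(.data$biotype == "histone", .data$gene_class, "other")
    } else {
      .data$gene_class
    }) %>%
    select("gene_id", "class_label")
  results %>%
    left_join(labels, by = "gene_id") %>%
    mutate(class_label = replace_na(.data$class_label, "other"),
           neg_log10_padj = -log10(.data$padj)) %>%
    arrange(.data$padj)
}
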