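# Independent brute-force oracles, deliberately naive (plain loops,
# no shared code with the implementation).

# exhaustive hairpin scan; returns c(arm5_start, stem_len, loop_len,
# n_mismatches, score) of the best candidate under the same ordering
# as detect_stem_loop, plus the number of top-score candidates, or
# NULL when nothing reaches min_score
oracle_hairpin <- function(w, stem_range = c(5, 7), loop_range = c(3, 5),
                           max_mm = 1, min_score = 4) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = ".")
  cv <- strsplit(w, "")[[1]]
  n <- length(cv)
  best <- NULL
  n_best_score <- 0
  for (p in 0:(n - 1)) {
    for (s in stem_range[1]:stem_range[2]) {
      for (l in loop_range[1]:loop_range[2]) {
        if (p + 2 * s + l > n) next
        mm <- 0
        for (i in 1:s) {
          if (cv[p + 2 * s + l + 1 - i] != comp[[cv[p + i]]]) mm <- mm + 1
        }
        if (mm > max_mm) next
        sc <- s - 2 * mm
        if (sc < min_score) next
        cand <- c(p, s, l, mm, sc)
        if (is.null(best)) {
          best <- cand
          n_best_score <- 1
        } else {
          if (sc == best[5]) n_best_score <- n_best_score + 1
          if (sc > best[5]) n_best_score <- 1
          b <- best
          better <- sc > b[5] ||
            (sc == b[5] && (s > b[2] ||
              (s == b[2] && (p < b[1] ||
                (p == b[1] && l < b[3])))))
          if (better) best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(hit = best, n_top = n_best_score)
}

# per-read loop recomputing crosslink and termination tracks
oracle_tracks <- function(al, chrom_lengths, min_trim = 6) {
  xl <- character(0)
  te <- character(0)
  dropped <- 0
  for (i in seq_len(nrow(al))) {
    ch <- al$chrom[i]
    st <- al$strand[i]
    s <- al$start[i]
    e <- al$end[i]
    if (st == "+") {
      if (s == 0) {
        dropped <- dropped + 1
      } else {
        xl <- c(xl, paste(ch, st, s - 1))
      }
    } else {
      if (e == chrom_lengths[[ch]]) {
        dropped <- dropped + 1
      } else {
        xl <- c(xl, paste(ch, st, e))
      }
    }
    if (al$n_trimmed_3p[i] >= min_trim) {
      te <- c(te, paste(ch, st, if (st == "+") e - 1 else s))
    }
  }
  to_track <- function(keys) {
    if (length(keys) == 0) {
      return(tibble::tibble(chrom = character(), strand = character(),
                            pos = integer(), count = integer()))
    }
    tab <- table(keys)
    parts <- strsplit(names(tab), " ")
    tibble::tibble(chrom = vapply(parts, `[`, "", 1),
                   strand = vapply(parts, `[`, "", 2),
                   pos = as.integer(vapply(parts, `[`, "", 3)),
                   count = as.integer(tab)) |>
      dplyr::arrange(chrom, strand, pos)
  }
  list(crosslink = to_track(xl), termination = to_track(te),
       n_dropped_at_ends = dropped)
}

# Benjamini-Hochberg by the literal step-up definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * po[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# median-of-ratios size factors, written out gene by gene
sf_brute <- function(m) {
  ref <- numeric(nrow(m))
  for (g in seq_len(nrow(m))) {
    ref[g] <- exp(mean(log(m[g, ])))        # 0 if any count is zero
  }
  ok <- ref > 0 & is.finite(ref)
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    out[j] <- median(m[ok, j] / ref[ok])
  }
  setNames(out, colnames(m))
}
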