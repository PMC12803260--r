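# ggplot2 figures for the main result types.

#' Volcano plot of IP-vs-control binding enrichment
#'
#' Binding fold change (log2) versus statistical significance
#' (-log10 adjusted p), with histone genes coloured by RD/RI class.
#'
#' @param results Labelled enrichment tibble from [label_and_rank()].
#' @param fdr Significance threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, fdr = 0.01) {
  df <- results %>% filter(is.finite(.data$neg_log10_padj))
  ggplot(df, aes(x = .data$log2FC, y = .data$neg_log10_padj,
                 colour = .data$class_label)) +
    geom_point(alpha = 0.8) +
    geom_hline(yintercept = -log10(fdr), linetype = "dashed") +
    labs(x = "binding fold change (log2, IP / control)",
         y = "-log10 adjusted p", colour = "class") +
    theme_bw()
}

#' Anchored window profile plot
#'
#' Event totals against the offset from the anchor (negative =
#' upstream), one line per library when a `library` column is present.
#'
#' @param profile Window-profile tibble from [window_coverage()],
#'   optionally with a `library` column.
#' @return A ggplot object.
#' @export
plot_window_profile <- function(profile) {
  p <- if ("library" %in% names(profile)) {
    ggplot(profile, aes(x = .data$offset, y = .data$events,
                        colour = .data$library))
  } else {
    ggplot(profile, aes(x = .data$offset, y = .data$events))
  }
  p + geom_line() +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = "offset from anchor (nt)", y = "events") +
    theme_bw()
}

#' Full-gene metagene profile plot
#'
#' Lays the five segments (upstream flank, binned CDS, binned spacer,
#' stem-loop, downstream flank) along one axis. For a `mean_sd`
#' aggregate a ribbon of +/- 1 SD is drawn around the mean.
#'
#' @param profile Aggregated profile from [aggregate_profiles()].
#' @return A ggplot object.
#' @export
plot_full_profile <- function(profile) {
  df <- profile %>%
    arrange(.data$segment, .data$index) %>%
    mutate(x = row_number())
  breaks <- df %>%
    group_by(.data$segment) %>%
    summarise(at = min(.data$x), .groups = "drop")
  if ("mean" %in% names(df)) {
    p <- ggplot(df, aes(x = .data$x, y = .data$mean)) +
      geom_ribbon(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd),
                  fill = "grey80") +
      geom_line() +
      labs(y = "events (mean +/- SD across libraries)")
  } else {
    p <- ggplot(df, aes(x = .data$x, y = .data$value)) +
      geom_line() +
      labs(y = "events (total)")
  }
  p + geom_vline(xintercept = breaks$at, linetype = "dotted") +
    labs(x = "position (flank / CDS bins / spacer bins / stem-loop / flank)") +
    theme_bw()
}
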