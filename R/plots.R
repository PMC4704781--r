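# ggplot2 visualisations for the main result types.

#' Plot an mtDNA coverage profile with the detected deletion arc
#'
#' @param profile Coverage tibble (`pos`, `depth`).
#' @param deletion Optional one-row [detect_large_deletion()] result to
#'   shade.
#' @return A ggplot.
#' @export
plot_mt_coverage <- function(profile, deletion = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "grey30") +
    ggplot2::labs(x = "rCRS position (bp)", y = "depth",
                  title = "mtDNA coverage") +
    ggplot2::theme_minimal()
  if (!is.null(deletion) && nrow(deletion) == 1) {
    shade <- if (deletion$last_deleted >= deletion$first_deleted) {
      tibble(xmin = deletion$first_deleted, xmax = deletion$last_deleted)
    } else {
      tibble(xmin = c(deletion$first_deleted, 1),
             xmax = c(MT_GENOME_LENGTH, deletion$last_deleted))
    }
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    ) +
      ggplot2::labs(subtitle = sprintf(
        "m.%d_%ddel%d", deletion$first_deleted, deletion$last_deleted,
        deletion$length))
  }
  p
}

#' Plot array log2 ratios for one sample/chromosome with called segments
#'
#' @param probes Probe tibble for one sample.
#' @param segments Optional [segment_copy_number()] output to overlay.
#' @param chrom Chromosome to show (default: first in `probes`).
#' @return A ggplot.
#' @export
plot_cnv_segments <- function(probes, segments = NULL, chrom = NULL) {
  chrom <- chrom %||% probes$chrom[1]
  p <- ggplot2::ggplot(probes[probes$chrom == chrom, ],
                       ggplot2::aes(x = .data$pos, y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = sprintf("%s position (bp)", chrom), y = "log2 ratio") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    sg <- segments[segments$chrom == chrom, , drop = FALSE]
    if (nrow(sg) > 0) {
      p <- p + ggplot2::geom_segment(
        data = sg,
        ggplot2::aes(x = .data$start, xend = .data$end,
                     y = if_else(.data$state == "deletion", -1, 0.58)),
        yend = NULL, colour = "firebrick", linewidth = 1.5,
        inherit.aes = FALSE
      )
    }
  }
  p
}

#' Funnel plot of the filter cascade
#'
#' Number of variants surviving after each successive filter, in trace
#' order, summed over patients.
#'
#' @param trace Filter trace tibble from [prioritize_cohort()].
#' @param cfg The [filter_config()] used (for the filter order).
#' @return A ggplot.
#' @export
plot_filter_cascade <- function(trace, cfg = filter_config()) {
  surviving <- rep(TRUE, nrow(trace))
  counts <- purrr::map_int(cfg$filter_order, function(f) {
    surviving <<- surviving & trace[[paste0("pass_", f)]]
    sum(surviving)
  })
  df <- tibble(
    step = factor(c("input", cfg$filter_order),
                  levels = c("input", cfg$filter_order)),
    n = c(nrow(trace), counts)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "variants surviving",
                  title = "Exome filter cascade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @describeIn summarize_cohort Bar chart of the per-category breakdown.
#' @param object A `mitodx_cohort_summary`.
#' @param ... Unused.
#' @export
autoplot.mitodx_cohort_summary <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)", .data$n,
                                                    .data$pct)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "patients",
                  title = "Diagnostic category breakdown") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @describeIn run_enrichment Case/control percentages per gene set with
#'   the random-set null as mean +/- SD.
#' @param object A `mitodx_enrichment`.
#' @param ... Unused.
#' @export
autoplot.mitodx_enrichment <- function(object, ...) {
  df <- object$by_set %>%
    tidyr::pivot_longer(c("pct_cases", "pct_controls"),
                        names_to = "group", values_to = "pct") %>%
    mutate(group = sub("pct_", "", .data$group))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$pct,
                                        fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% individuals with prioritized gene",
                  title = "Prioritized-gene enrichment") +
    ggplot2::theme_minimal()
  nr <- object$null
  p + ggplot2::annotate(
    "errorbar",
    x = "random", ymin = max(0, nr$null_mean - nr$null_sd),
    ymax = nr$null_mean + nr$null_sd, width = 0.2, colour = "grey20"
  )
}
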