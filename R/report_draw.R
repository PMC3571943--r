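# Chart rendering for the report tables.
#
# Charts read ONLY the tab-delimited tables, never the accumulator, so the
# tables remain the stable public contract and any external plotting tool
# can consume them instead.  Rendering is native (ggplot2); SVG is the
# default output because structured vector output is easy to inspect.

CHART_KINDS <- c("cycle_heatmap", "cycle_box", "base_composition",
                 "length_dist", "quality_dist", "tile_stacked",
                 "pair_correlation")

CHART_COLUMNS <- list(
  cycle_heatmap    = c("cycle", "score", "count"),
  cycle_box        = c("cycle", "n", "min", "p10", "q1", "median", "q3",
                       "p90", "max", "mean"),
  base_composition = c("cycle", "A", "C", "G", "T", "N"),
  length_dist      = c("length", "count"),
  quality_dist     = c("quality", "count"),
  tile_stacked     = "tile",
  pair_correlation = c("end1_bin", "end2_bin", "n_pairs"))

# table file stem -> chart kind
TABLE_CHARTS <- c(cycle_quality = "cycle_heatmap",
                  cycle_summary = "cycle_box",
                  base_composition = "base_composition",
                  length_dist = "length_dist",
                  read_quality_dist = "quality_dist",
                  tile_quality = "tile_stacked",
                  pair_correlation = "pair_correlation")

no_data_plot <- function() {
  ggplot2::ggplot() +
    ggplot2::annotate("text", x = 0, y = 0, label = "no data", size = 8) +
    ggplot2::theme_void()
}

build_chart <- function(kind, df) {
  if (nrow(df) == 0L) return(no_data_plot())
  aes <- ggplot2::aes
  switch(kind,
    cycle_heatmap = ggplot2::ggplot(df, aes(x = .data$cycle, y = .data$score,
                                            fill = .data$count)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "cycle", y = "Phred score", fill = "reads",
                    title = "Read quality along read"),
    cycle_box = {
      df$cycle <- factor(df$cycle, levels = df$cycle)
      ggplot2::ggplot(df, aes(x = .data$cycle)) +
        ggplot2::geom_boxplot(aes(ymin = .data$p10, lower = .data$q1,
                                  middle = .data$median, upper = .data$q3,
                                  ymax = .data$p90),
                              stat = "identity", fill = "steelblue") +
        ggplot2::geom_line(aes(y = .data$mean, group = 1), colour = "red") +
        ggplot2::scale_x_discrete(
          breaks = df$cycle[seq(1, nrow(df), by = max(1, nrow(df) %/% 20))]) +
        ggplot2::labs(x = "cycle", y = "Phred score",
                      title = "Read quality along read (p10/q1/median/q3/p90; mean in red)")
    },
    base_composition = {
      long <- data.frame(
        cycle = rep(df$cycle, 5L),
        base = factor(rep(c("A", "C", "G", "T", "N"), each = nrow(df)),
                      levels = c("A", "C", "G", "T", "N")),
        fraction = c(df$A, df$C, df$G, df$T, df$N))
      long <- long[!is.na(long$fraction), , drop = FALSE]
      ggplot2::ggplot(long, aes(x = .data$cycle, y = .data$fraction,
                                fill = .data$base)) +
        ggplot2::geom_area(position = "stack") +
        ggplot2::labs(x = "cycle", y = "fraction",
                      title = "Base composition along read")
    },
    length_dist = ggplot2::ggplot(df, aes(x = .data$length, y = .data$count)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "read length (bp)", y = "reads",
                    title = "Read length distribution"),
    quality_dist = {
      df <- df[!is.na(df$quality), , drop = FALSE]
      if (nrow(df) == 0L) return(no_data_plot())
      ggplot2::ggplot(df, aes(x = .data$quality, y = .data$count)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(x = "mean Phred score", y = "reads",
                      title = "Read quality distribution")
    },
    tile_stacked = {
      bins <- setdiff(names(df), "tile")
      long <- data.frame(
        tile = factor(rep(df$tile, length(bins)), levels = df$tile),
        bin = factor(rep(bins, each = nrow(df)), levels = bins),
        count = unlist(df[bins], use.names = FALSE))
      ggplot2::ggplot(long, aes(x = .data$tile, y = .data$count,
                                fill = .data$bin)) +
        ggplot2::geom_col(position = "stack") +
        ggplot2::labs(x = "tile", y = "reads", fill = "mean quality",
                      title = "Read quality on different tiles") +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                           vjust = 0.5))
    },
    pair_correlation = {
      r_lab <- attr(df, "r_label")
      if (is.null(r_lab)) r_lab <- "r = NA"
      ggplot2::ggplot(df, aes(x = .data$end1_bin, y = .data$end2_bin,
                              fill = .data$n_pairs)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_viridis_c() +
        ggplot2::annotate("text", x = min(df$end1_bin), y = max(df$end2_bin),
                          label = r_lab, hjust = 0, vjust = 1, size = 6) +
        ggplot2::labs(x = "end 1 mean Phred", y = "end 2 mean Phred",
                      fill = "pairs",
                      title = "Correlation between two read ends")
    },
    stop("unknown chart kind: ", kind))
}

#' Draw one QC chart from a report table
#'
#' Validates that the table carries the columns the chart kind requires,
#' builds the chart and writes it to `out_path`.  An empty table yields a
#' "no data" placeholder chart rather than an error.  For
#' `pair_correlation` the Pearson r stored in the table's metadata is
#' annotated on the chart.
#'
#' @param kind one of `"cycle_heatmap"`, `"cycle_box"`,
#'   `"base_composition"`, `"length_dist"`, `"quality_dist"`,
#'   `"tile_stacked"`, `"pair_correlation"`.
#' @param table_path path to the corresponding `.tsv` report table.
#' @param out_path output image path; defaults to the table path with its
#'   extension replaced by the format.
#' @param format `"svg"` or `"png"`.
#' @param width,height canvas size in inches.
#' @return the ggplot object, invisibly, with the output path in
#'   attribute `"path"`.
#' @export
draw_chart <- function(kind, table_path, out_path = NULL,
                       format = c("svg", "png"), width = 8, height = 5) {
  kind <- match.arg(kind, CHART_KINDS)
  format <- match.arg(format)
  df <- read_qc_table(table_path)
  need <- CHART_COLUMNS[[kind]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("table %s lacks column '%s' required by chart '%s'",
                 table_path, missing_cols[1], kind))
  if (kind == "pair_correlation") {
    meta <- attr(df, "meta")
    rline <- grep("^#pearson_r\t", meta, value = TRUE)
    if (length(rline)) {
      rv <- suppressWarnings(as.numeric(sub("^#pearson_r\t", "", rline[1])))
      attr(df, "r_label") <- if (is.na(rv)) "r undefined"
                             else sprintf("r = %.2f", rv)
    }
  }
  p <- build_chart(kind, df)
  if (is.null(out_path))
    out_path <- paste0(sub("\\.tsv$", "", table_path), ".", format)
  if (format == "svg") {
    grDevices::svg(out_path, width = width, height = height)
  } else {
    grDevices::png(out_path, width = width * 100, height = height * 100,
                   res = 100)
  }
  on.exit(grDevices::dev.off())
  print(p)
  attr(p, "path") <- out_path
  invisible(p)
}

#' Draw every chart for a report directory
#'
#' Scans `report_dir` for the standard table files (including the `_1` /
#' `_2` per-end suffixes of a paired run) and renders one chart per table
#' found.  Absent optional tables (e.g. the pair-correlation table of a
#' single-end run) are skipped silently; an empty directory yields a
#' warning and an empty result.  Tables are never modified, so the
#' operation is idempotent.
#'
#' @param report_dir directory holding tables from [write_qc_report()].
#' @param out_dir output directory for images (default: `report_dir`).
#' @param format `"svg"` or `"png"`.
#' @return character vector of image paths written.
#' @export
draw_all <- function(report_dir, out_dir = report_dir, format = c("svg", "png")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  out <- character()
  for (stem in names(TABLE_CHARTS)) {
    for (suffix in c("", "_1", "_2")) {
      tab <- file.path(report_dir, paste0(stem, suffix, ".tsv"))
      if (!file.exists(tab)) next
      img <- file.path(out_dir, paste0(stem, suffix, ".", format))
      draw_chart(TABLE_CHARTS[[stem]], tab, img, format = format)
      out <- c(out, img)
    }
  }
  if (!length(out))
    warning("no report tables found in ", report_dir)
  out
}
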