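category_palette <- function() {
  stats::setNames(
    c("#2c2c54", "#9b59b6", "#e67e22", "#f1c40f", "#c0392b", "#2980b9",
      "#16a085", "#7f8c8d", "#27ae60", "#e84393", "#34495e"),
    activity_categories())
}

#' Render one of the five standard figures
#'
#' Writes a figure file (PNG or SVG by extension) for one of the five
#' graph kinds and, alongside it, the underlying numeric table as a CSV
#' (same path, `.csv` extension) so results can be checked from data, not
#' pixels. Kinds: `"tempogram"` (stacked slot-by-category area),
#' `"paths"` (sequence-index plot: one horizontal line of 96 colored
#' cells per diary, diaries stacked), `"transitions"` (heatmap with
#' percent annotations), `"totals"` (bar chart of percent of total time),
#' `"state_map"` (sorted per-state bar table of average minutes; the
#' canonical output is the table, not choropleth artwork).
#'
#' @param figure_kind One of `"tempogram"`, `"paths"`, `"transitions"`,
#'   `"totals"`, `"state_map"`.
#' @param x The matching summary object — a `tempogram`,
#'   `transition_matrix`, `totals_table` or `state_averages` — or a
#'   `sequence_set` for `"paths"`.
#' @param out_path Output figure path ending in `.png` or `.svg`.
#' @param activity For `"state_map"`: which activity's averages to show.
#' @param width,height Device size in pixels (PNG) or inches (SVG).
#' @return Metadata list `{kind, n, dimensions, figure, table}`.
#' @export
render_figure <- function(figure_kind = c("tempogram", "paths",
                                          "transitions", "totals",
                                          "state_map"),
                          x, out_path, activity = "adult_care",
                          width = 900, height = 600) {
  figure_kind <- match.arg(figure_kind)
  ext <- tolower(tools::file_ext(out_path))
  if (!ext %in% c("png", "svg"))
    stop("out_path must end in .png or .svg")
  pal <- category_palette()
  open_dev <- function() {
    if (ext == "png") grDevices::png(out_path, width, height)
    else grDevices::svg(out_path, width / 100, height / 100)
  }
  tab_path <- paste0(tools::file_path_sans_ext(out_path), ".csv")
  meta <- switch(
    figure_kind,
    tempogram = {
      stopifnot(inherits(x, "tempogram"))
      open_dev()
      graphics::barplot(t(unclass(x)), col = pal, border = NA,
                        names.arg = rep("", 96), space = 0,
                        xlab = "time of day (from 4:00 am)",
                        ylab = attr(x, "mode"),
                        main = sprintf("Tempogram (%s)", attr(x, "mode")))
      at <- seq(1, 96, by = 16)
      graphics::axis(1, at = at - 0.5, labels = rownames(x)[at],
                     las = 2, cex.axis = 0.7)
      graphics::legend("topright", legend = names(pal), fill = pal,
                       cex = 0.6, bg = "white")
      grDevices::dev.off()
      write_summary(x, tab_path)
      list(n = nrow(x), dimensions = dim(x))
    },
    paths = {
      stopifnot(inherits(x, "sequence_set"))
      if (x$resolution != "slot")
        stop("paths figure requires slot resolution")
      open_dev()
      graphics::image(t(x$seq[rev(seq_len(nrow(x$seq))), , drop = FALSE]),
                      col = pal, zlim = c(1, 11), axes = FALSE,
                      xlab = "time of day (from 4:00 am)", ylab = "diary",
                      main = sprintf("Daily paths (n = %d)", nrow(x$seq)))
      graphics::axis(1, at = seq(0, 1, length.out = 7),
                     labels = slot_labels()[seq(1, 96, length.out = 7)],
                     cex.axis = 0.7)
      grDevices::dev.off()
      df <- data.frame(diary_id = x$covariates$diary_id,
                       matrix(x$categories[x$seq], nrow(x$seq)),
                       stringsAsFactors = FALSE)
      names(df) <- c("diary_id", slot_labels())
      utils::write.table(df, tab_path, sep = ",", row.names = FALSE,
                         quote = FALSE)
      list(n = nrow(x$seq), dimensions = dim(x$seq))
    },
    transitions = {
      stopifnot(inherits(x, "transition_matrix"))
      m <- unclass(x); attr(m, "n_effective") <- NULL
      open_dev()
      graphics::image(seq_len(11), seq_len(11),
                      t(m[rev(seq_len(11)), ]),
                      col = grDevices::hcl.colors(64, "YlOrRd",
                                                  rev = TRUE),
                      axes = FALSE, xlab = "to", ylab = "from",
                      main = "Transitions (% of between-activity changes)")
      graphics::axis(1, at = seq_len(11), labels = colnames(m), las = 2,
                     cex.axis = 0.7)
      graphics::axis(2, at = seq_len(11), labels = rev(rownames(m)),
                     las = 1, cex.axis = 0.7)
      for (i in seq_len(11)) for (jj in seq_len(11))
        graphics::text(jj, 12 - i, sprintf("%.2f", m[i, jj]),
                       cex = 0.55)
      grDevices::dev.off()
      write_summary(x, tab_path)
      list(n = attr(x, "n_effective"), dimensions = dim(m))
    },
    totals = {
      stopifnot(inherits(x, "totals_table"))
      open_dev()
      graphics::barplot(as.numeric(x), names.arg = names(x), col = pal,
                        las = 2, ylab = "percent of total time",
                        main = "Percent of total time by activity")
      grDevices::dev.off()
      write_summary(x, tab_path)
      list(n = length(x), dimensions = c(length(x), 1L))
    },
    state_map = {
      stopifnot(inherits(x, "state_averages"))
      activity <- match.arg(activity, activity_categories())
      v <- sort(x$minutes[, activity], decreasing = TRUE)
      open_dev()
      graphics::barplot(v, names.arg = names(v), las = 2, col = "#2980b9",
                        ylab = "average minutes per day",
                        main = sprintf("Average minutes of %s by state",
                                       activity))
      grDevices::dev.off()
      write_summary(x, tab_path)
      list(n = nrow(x$minutes), dimensions = dim(x$minutes))
    }
  )
  c(list(kind = figure_kind, figure = out_path, table = tab_path), meta)
}
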