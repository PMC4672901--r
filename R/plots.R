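# Figure rendering.  Every plot is drawn from an exported table (the CSV
# written next to it), never from internal model state, so figures can be
# regenerated from artifacts alone.  Device is chosen by file extension;
# cairo SVG is preferred and PDF is the fallback when cairo is absent.

.open_device <- function(file, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "svg" && isTRUE(capabilities("cairo")[[1]])) {
    grDevices::svg(file, width = width, height = height)
  } else if (ext == "png" && isTRUE(capabilities("png")[[1]])) {
    grDevices::png(file, width = width * 100, height = height * 100)
  } else {
    if (ext %in% c("svg", "png"))
      file <- paste0(tools::file_path_sans_ext(file), ".pdf")
    grDevices::pdf(file, width = width, height = height)
  }
  file
}

#' Draw a forest plot from a forest table
#'
#' @param tab a [forest_table()] data frame.
#' @param file output file (`.svg`, `.png`, or `.pdf`).
#' @param title plot title.
#' @param xlab x-axis label.
#' @return The file actually written, invisibly.
#' @export
plot_forest <- function(tab, file, title = "", xlab = "effect (%)") {
  file <- .open_device(file, width = 8,
                       height = max(3, 0.28 * nrow(tab) + 1.5))
  on.exit(grDevices::dev.off())
  n <- nrow(tab)
  ys <- rev(seq_len(n))
  finite <- c(tab$ci_low, tab$ci_high, tab$estimate)
  xr <- range(finite[is.finite(finite)])
  op <- graphics::par(mar = c(4, 16, 3, 6))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = xr, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = xlab, ylab = "", main = title, bty = "n")
  graphics::abline(v = 0, col = "grey70", lty = 2)
  for (i in seq_len(n)) {
    y <- ys[i]
    est <- tab$estimate[i]; lo <- tab$ci_low[i]; hi <- tab$ci_high[i]
    if (tab$row_type[i] == "study") {
      graphics::segments(lo, y, hi, y)
      cex <- if (is.na(tab$weight_pct[i])) 0.8
             else 0.5 + tab$weight_pct[i] / 50
      graphics::points(est, y, pch = 15, cex = min(cex, 2.5))
    } else {
      col <- if (tab$row_type[i] == "overall") "red3" else "steelblue4"
      graphics::polygon(c(lo, est, hi, est), y + c(0, 0.25, 0, -0.25),
                        col = col, border = col)
    }
    lab <- if (tab$row_type[i] == "study") tab$label[i]
           else sprintf("%s (k=%d, I2=%.0f%%)", tab$label[i], tab$k[i],
                        tab$i2[i])
    graphics::mtext(lab, side = 2, at = y, las = 1, line = 0.5, cex = 0.7)
    graphics::mtext(sprintf("%.1f [%.1f, %.1f]", est, lo, hi), side = 4,
                    at = y, las = 1, line = 0.5, cex = 0.65)
  }
  invisible(file)
}

#' Bubble plot of driver effects against cell counts
#'
#' Bubble areas are proportional to each driver's regression weight (the
#' number of contributing experiments); the fitted weighted regression
#' line and the no-effect reference line are overlaid.
#'
#' @param effects `"mb_driver_effects"` table.
#' @param model result of [cellcount_regression()].
#' @param file output file.
#' @param title plot title.
#' @return The file written, invisibly.
#' @export
plot_bubble <- function(effects, model, file, title = "") {
  keep <- !is.na(effects$cell_count)
  eff <- effects[keep, , drop = FALSE]
  file <- .open_device(file)
  on.exit(grDevices::dev.off())
  r <- sqrt(eff$n_experiments / pi)  # area proportional to weight
  graphics::plot(eff$cell_count, eff$effect,
                 cex = r / max(r) * 4, pch = 21, bg = "#4477AA66",
                 xlab = "Kenyon cells captured by driver",
                 ylab = "residual learning effect (%)", main = title)
  graphics::abline(h = 0, col = "grey50", lwd = 2)
  graphics::abline(model$intercept, model$slope, col = "blue", lwd = 2)
  graphics::text(eff$cell_count, eff$effect, eff$driver, pos = 3,
                 cex = 0.7)
  invisible(file)
}

#' Per-cell lobe potency plot
#'
#' One marker with CI per lobe category present.
#'
#' @param categories the `categories` data frame of [per_cell_model()].
#' @param file output file.
#' @param title plot title.
#' @return The file written, invisibly.
#' @export
plot_per_cell <- function(categories, file, title = "") {
  file <- .open_device(file, width = 6, height = 4.5)
  on.exit(grDevices::dev.off())
  n <- nrow(categories)
  xs <- seq_len(n)
  yr <- range(c(categories$ci_low, categories$ci_high, 0))
  graphics::plot(xs, categories$estimate, xlim = c(0.5, n + 0.5),
                 ylim = yr, xaxt = "n", pch = 19,
                 xlab = "lobe category", ylab = "effect per cell (%/cell)",
                 main = title)
  graphics::axis(1, at = xs, labels = categories$lobe_category,
                 cex.axis = 0.8)
  graphics::arrows(xs, categories$ci_low, xs, categories$ci_high,
                   angle = 90, code = 3, length = 0.05)
  graphics::abline(h = 0, col = "grey50", lty = 2)
  invisible(file)
}

#' Summary learning-scale plot
#'
#' Markers with CIs for each analysis on the learning-percent scale, with
#' the baseline reference line.
#'
#' @param summary_df data frame with `label`, `learning`, `ci_low`,
#'   `ci_high` columns (learning scale).
#' @param reference baseline learning percentage (horizontal line).
#' @param file output file.
#' @param title plot title.
#' @return The file written, invisibly.
#' @export
plot_learning_summary <- function(summary_df, reference, file,
                                  title = "") {
  file <- .open_device(file, width = 7, height = 4.5)
  on.exit(grDevices::dev.off())
  n <- nrow(summary_df)
  xs <- seq_len(n)
  yr <- range(c(summary_df$ci_low, summary_df$ci_high, reference, 100))
  graphics::plot(xs, summary_df$learning, xlim = c(0.5, n + 0.5),
                 ylim = yr, xaxt = "n", pch = 19,
                 xlab = "", ylab = "learning (% of wild type)",
                 main = title)
  graphics::axis(1, at = xs, labels = summary_df$label, las = 2,
                 cex.axis = 0.7)
  graphics::arrows(xs, summary_df$ci_low, xs, summary_df$ci_high,
                   angle = 90, code = 3, length = 0.05)
  graphics::abline(h = 100, col = "grey60", lty = 3)
  graphics::abline(h = reference, col = "grey30", lty = 2)
  invisible(file)
}
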