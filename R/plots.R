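# Report graphics: radar plot of per-task correlations and per-country
# prediction scatter panels, written as SVG or PNG.

#' Radar plot of per-task correlations for one or more reports
#'
#' @param reports named list of `evaluation_report`s (names label lines).
#' @param path output file ending in `.svg` or `.png`.
#' @param what `"intra_mean_r"` (default), `"global_r"` or `"upper_bound"`
#'   extra ring drawn dashed when bounds are present.
#' @return the path, invisibly.
#' @export
plot_radar <- function(reports, path, what = "intra_mean_r") {
  open_device(path, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  tasks <- names(reports[[1]][[what]])
  k <- length(tasks)
  ang <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), axes = FALSE,
                 xlab = "", ylab = "", asp = 1,
                 main = "per-task correlation")
  for (r in c(0.25, 0.5, 0.75, 1)) {
    graphics::lines(r * cos(ang[c(seq_len(k), 1)]),
                    r * sin(ang[c(seq_len(k), 1)]), col = "grey85")
  }
  graphics::text(1.15 * cos(ang), 1.15 * sin(ang), tasks, cex = 0.55)
  cols <- grDevices::hcl.colors(max(3, length(reports)), "Dark 3")
  for (i in seq_along(reports)) {
    v <- pmax(reports[[i]][[what]], 0)
    v[is.na(v)] <- 0
    graphics::lines(v[c(seq_len(k), 1)] * cos(ang[c(seq_len(k), 1)]),
                    v[c(seq_len(k), 1)] * sin(ang[c(seq_len(k), 1)]),
                    col = cols[i], lwd = 2)
  }
  if (!is.null(reports[[1]]$upper_bound)) {
    b <- pmax(reports[[1]]$upper_bound, 0)
    graphics::lines(b[c(seq_len(k), 1)] * cos(ang[c(seq_len(k), 1)]),
                    b[c(seq_len(k), 1)] * sin(ang[c(seq_len(k), 1)]),
                    col = "blue", lty = 2)
  }
  graphics::legend("topleft", legend = names(reports),
                   col = cols[seq_along(reports)], lwd = 2, bty = "n",
                   cex = 0.7)
  invisible(path)
}

#' Scatter panels of the best-predicted (task, country) cells
#'
#' @param predictions,observed aligned N x T matrices.
#' @param countries country label per sample.
#' @param path output file ending in `.svg` or `.png`.
#' @param n_panels number of panels, ranked by within-country correlation.
#' @param min_n country inclusion cutoff.
#' @return the path, invisibly.
#' @export
plot_best_scatter <- function(predictions, observed, countries, path,
                              n_panels = 9, min_n = 50) {
  ic <- suppressWarnings(
    intra_country_pearson(predictions, observed, countries, min_n = min_n))
  pc <- ic$per_country
  pc <- pc[order(-pc$r), ]
  pc <- utils::head(pc[!is.na(pc$r), ], n_panels)
  open_device(path, width = 8, height = 8)
  on.exit(grDevices::dev.off())
  nr <- ceiling(sqrt(nrow(pc)))
  graphics::par(mfrow = c(nr, nr), mar = c(3, 3, 2, 1), mgp = c(1.8, 0.5, 0))
  tasks <- colnames(observed)
  for (i in seq_len(nrow(pc))) {
    idx <- which(countries == pc$country[i])
    j <- match(pc$task[i], tasks)
    graphics::plot(predictions[idx, j], observed[idx, j],
                   xlab = "predicted", ylab = "observed", pch = 19,
                   cex = 0.5, col = "steelblue",
                   main = sprintf("%s / %s (r=%.2f)", pc$task[i],
                                  pc$country[i], pc$r[i]), cex.main = 0.8)
    graphics::abline(stats::lm(observed[idx, j] ~ predictions[idx, j]),
                     col = "grey40")
  }
  invisible(path)
}

open_device <- function(path, width, height) {
  if (grepl("\\.png$", path)) {
    grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  } else {
    grDevices::svg(path, width = width, height = height)
  }
}
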