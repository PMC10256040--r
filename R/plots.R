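#' Block-detection inspection plot
#'
#' SVM series with detected tapping blocks shaded, for visual QC of the
#' activity segmentation.
#'
#' @param svm an [svm_series()]
#' @param blocks block data.frame from [detect_blocks()]
#' @param path optional PNG path; when NULL, draws on the current device
#' @param title plot title
#' @return `path` (or NULL), invisibly
#' @export
plot_block_detection <- function(svm, blocks, path = NULL, title = "") {
  draw <- function() {
    t <- (seq_along(svm$values) - 1) / svm$rate
    graphics::plot(t, svm$values, type = "l", col = "grey25", lwd = 0.5,
                   xlab = "time (s)", ylab = "SVM (g)", main = title)
    if (nrow(blocks)) {
      ylim <- graphics::par("usr")[3:4]
      for (i in seq_len(nrow(blocks)))
        graphics::rect((blocks$start[i] - 1) / svm$rate,
                       ylim[1], (blocks$end[i] - 1) / svm$rate, ylim[2],
                       col = grDevices::adjustcolor("red", 0.15), border = NA)
    }
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 1200, height = 400)
    on.exit(grDevices::dev.off())
    draw()
  } else draw()
  invisible(path)
}

#' Tap-detection inspection plot
#'
#' Block SVM with detected impact moments dotted.
#'
#' @param svm_block numeric vector of block SVM samples
#' @param impacts impact indices from [detect_impacts()]
#' @param rate sampling rate in Hz
#' @param path optional PNG path
#' @param title plot title
#' @return `path` (or NULL), invisibly
#' @export
plot_tap_detection <- function(svm_block, impacts, rate = 250, path = NULL,
                               title = "") {
  draw <- function() {
    t <- (seq_along(svm_block) - 1) / rate
    graphics::plot(t, svm_block, type = "l", col = "grey25", lwd = 0.7,
                   xlab = "time (s)", ylab = "SVM (g)", main = title)
    if (length(impacts))
      graphics::points((impacts - 1) / rate, svm_block[impacts],
                       col = "dodgerblue3", pch = 19)
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 1000, height = 350)
    on.exit(grDevices::dev.off())
    draw()
  } else draw()
  invisible(path)
}
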