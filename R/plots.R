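#' Spaghetti plot of bootstrap isodars
#'
#' Draws a thinned sample of the bootstrap isodar lines in grey, the mean
#' isodar in black, and the 1:1 line (equal densities, the ideal-free
#' no-quality-difference expectation) dashed.
#'
#' @param result An `"isodar_result"` from [bootstrap_isodars()].
#' @param preds Optional [predict_habitat_counts()] table; if supplied, sets
#'   the axis ranges from the predicted counts and overlays the mean points.
#' @param max_lines Number of bootstrap lines drawn (default 500).
#' @return Invisibly, `result`.
#' @export
plot_isodar <- function(result, preds = NULL, max_lines = 500) {
  if (!inherits(result, "isodar_result")) stop("result must be an isodar_result")
  if (!is.null(preds)) {
    xlim <- range(preds$mean_count[preds$habitat == "core"])
    ylim <- range(preds$mean_count[preds$habitat == "periphery"])
  } else {
    xlim <- ylim <- c(0, max(1, result$intercept_mean + result$slope_mean))
  }
  lim <- range(0, xlim, ylim)
  graphics::plot(NA, xlim = lim, ylim = lim,
                 xlab = "Core count (common offset)",
                 ylab = "Periphery count (common offset)",
                 main = "Bootstrap isodars")
  idx <- seq_len(length(result$slopes))
  if (length(idx) > max_lines)
    idx <- idx[seq.int(1L, length(idx), length.out = max_lines)]
  for (i in idx)
    graphics::abline(result$intercepts[i], result$slopes[i],
                     col = grDevices::grey(0.8))
  graphics::abline(result$intercept_mean, result$slope_mean, lwd = 2)
  graphics::abline(0, 1, lty = 2)
  if (!is.null(preds)) {
    wide <- merge(preds[preds$habitat == "core", c("escapement", "mean_count")],
                  preds[preds$habitat == "periphery", c("escapement", "mean_count")],
                  by = "escapement", suffixes = c("_core", "_periphery"))
    graphics::points(wide$mean_count_core, wide$mean_count_periphery, pch = 19)
  }
  invisible(result)
}

#' Histograms of isodar slope and intercept draws
#'
#' Two panels: the bootstrap slope distribution with a vertical critical
#' line at 1 (habitat quality equal) and the intercept distribution with a
#' line at 0 (habitat quantity equal), each with its percentile confidence
#' interval marked.
#'
#' @param result An `"isodar_result"`.
#' @return Invisibly, `result`.
#' @export
plot_isodar_coefs <- function(result) {
  if (!inherits(result, "isodar_result")) stop("result must be an isodar_result")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(result$slopes, breaks = 40, main = "Slope (quality)",
                 xlab = "Isodar slope", col = grDevices::grey(0.85))
  graphics::abline(v = 1, lwd = 2)
  graphics::abline(v = result$slope_ci90, lty = 3)
  graphics::hist(result$intercepts, breaks = 40, main = "Intercept (quantity)",
                 xlab = "Isodar intercept", col = grDevices::grey(0.85))
  graphics::abline(v = 0, lwd = 2)
  graphics::abline(v = result$intercept_ci90, lty = 3)
  invisible(result)
}
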