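# Base-graphics plot methods for the main result objects.

#' @method plot window_series
#' @export
plot.window_series <- function(x, ...) {
  graphics::plot(x$mid_distance, x$mean_score,
                 xlab = "normalized distance from oriC",
                 ylab = "mean ortholog score (window)",
                 pch = 16, cex = 0.4, col = "grey40",
                 main = attr(x, "strain") %||% "window series", ...)
  invisible(x)
}

#' @method plot conservation_fit
#' @export
plot.conservation_fit <- function(x, ...) {
  plot(x$series)
  graphics::abline(x$intercept, x$slope, col = "red", lwd = 2)
  d <- seq(0, 1, length.out = 100)
  graphics::lines(d, x$quadratic[1] + x$quadratic[2] * d + x$quadratic[3] * d^2,
                  col = "blue", lty = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 2),
                   col = c("red", "blue"),
                   legend = c(sprintf("linear (slope %.2f)", x$slope),
                              "quadratic"))
  invisible(x)
}

#' @method plot slope_population
#' @export
plot.slope_population <- function(x, ...) {
  if (x$degenerate) stop("degenerate slope population: all slopes identical")
  graphics::plot(x$qq$theoretical, x$qq$observed,
                 xlab = "theoretical normal quantiles",
                 ylab = "observed slope", pch = 16,
                 col = ifelse(x$qq$within_band, "grey30", "red"), ...)
  graphics::abline(0, 1, col = "blue", lty = 2)
  graphics::abline(h = 0, col = "blue", lty = 3)
  invisible(x)
}

#' @method plot segment_analysis
#' @export
plot.segment_analysis <- function(x, ...) {
  graphics::barplot(x$summary$mean_score,
                    names.arg = x$summary$segment,
                    xlab = "segment (1 = oriC, clockwise)",
                    ylab = "mean ortholog score", ...)
  invisible(x)
}

#' @method plot disparity_curves
#' @export
plot.disparity_curves <- function(x, ...) {
  graphics::plot(x$positions, x$disparity_gc, type = "l",
                 xlab = "position (bp)", ylab = "detrended cumulative G - C",
                 ...)
  graphics::abline(v = c(x$min_pos, x$max_pos), col = c("red", "blue"),
                   lty = 2)
  invisible(x)
}
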