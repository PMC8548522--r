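#' @importFrom graphics abline hist legend lines points polygon
NULL

#' Plot a velocity autocorrelation curve
#'
#' Empirical VACF with, optionally, the theoretical FBM curve for a given
#' anomalous exponent overlaid — the standard visual adequacy check (a
#' matching negative dip at one frame supports the FBM description).
#'
#' @param x a [VACFCurve-class].
#' @param alpha optional anomalous exponent for the theoretical overlay.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
setMethod("plot", signature(x = "VACFCurve", y = "missing"),
          function(x, alpha = NULL, ...) {
  plot(x@taus, x@values, type = "b", pch = 16,
       xlab = "lag (s)", ylab = "normalized VACF", ...)
  abline(h = 0, lty = 3)
  if (!is.null(alpha)) {
    tt <- seq(0, max(x@taus), length.out = 200)
    lines(tt, theoreticalVACF(alpha, tt, x@epsilon), col = "red3")
    legend("topright", c("empirical", sprintf("FBM, alpha = %.2f", alpha)),
           pch = c(16, NA), lty = c(1, 1), col = c("black", "red3"),
           bty = "n")
  }
  invisible(x)
})

#' Plot an interpolated path with its credible band
#'
#' One spatial coordinate against time: posterior mean line with a shaded
#' pointwise credible band.
#'
#' @param x an [InterpolatedPath-class].
#' @param dim which spatial dimension to draw (default 1).
#' @param obs optional [Trajectory-class] of the observations to overlay.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
setMethod("plot", signature(x = "InterpolatedPath", y = "missing"),
          function(x, dim = 1L, obs = NULL, ...) {
  rng <- range(x@lower[, dim], x@upper[, dim],
               if (!is.null(obs)) coords(obs)[, dim])
  plot(x@times, x@mean[, dim], type = "n", ylim = rng, xlab = "time (s)",
       ylab = sprintf("position (dim %d)", dim), ...)
  polygon(c(x@times, rev(x@times)),
          c(x@lower[, dim], rev(x@upper[, dim])),
          col = "#9ecae180", border = NA)
  lines(x@times, x@mean[, dim], col = "steelblue4")
  if (!is.null(obs))
    points(timePoints(obs), coords(obs)[, dim], pch = 16, cex = 0.5,
           col = "red3")
  invisible(x)
})
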