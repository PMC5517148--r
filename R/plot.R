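#' Mapping plot
#'
#' Plots the anterior-posterior final position of every terminal on the
#' target as a function of its naso-temporal retinal origin, the standard
#' way mapping simulations are displayed. Perfect topography puts all
#' points on the main diagonal (temporal origin, u = 1, maps to the
#' anterior target edge).
#'
#' @param x a `coadapt_sim` object.
#' @param main plot title (defaults to the scenario tag).
#' @param ... passed to [graphics::plot()].
#' @return The input, invisibly.
#' @export
plot.coadapt_sim <- function(x, main = x$tag, ...) {
  fin <- x$final[x$final$mobile, ]
  W <- if (!is.null(x$hints$target_end)) x$hints$target_end else max(fin$x)
  x0 <- if (!is.null(x$hints$target_start)) x$hints$target_start else 0
  graphics::plot(fin$origin_u, fin$x,
                 xlab = "naso-temporal origin u (0 = nasal)",
                 ylab = "final a-p position x (anterior = posteriorward 0)",
                 xlim = c(0, 1), ylim = c(0, W), pch = 21, bg = "grey60",
                 main = main, ...)
  graphics::segments(0, W, 1, x0, lty = 2, col = "grey40")
  invisible(x)
}

# write a mapping plot to PNG if a device is available; never fail a run
# over a missing graphics backend
save_mapping_plot <- function(result, path) {
  ok <- tryCatch({
    grDevices::png(path, width = 700, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(result)
    TRUE
  }, error = function(e) {
    message("plot skipped (", conditionMessage(e), ")")
    FALSE
  })
  invisible(ok)
}
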