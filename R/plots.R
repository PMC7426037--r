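#' Plot a persistence barcode
#'
#' One horizontal bar per interval, grouped and coloured by dimension;
#' open intervals run to the right margin and are marked with an
#' arrowhead.
#'
#' @param bc A `barcode`.
#' @param dims Dimensions to show (default 0:2).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_barcode <- function(bc, dims = 0:2, ...) {
  N <- attr(bc, "n_steps")
  sel <- bc[bc$dim %in% dims, , drop = FALSE]
  sel <- sel[order(sel$dim, sel$birth), , drop = FALSE]
  if (nrow(sel) == 0L) {
    graphics::plot(0, 0, type = "n", xlab = "filtration step", ylab = "",
                   xlim = c(1, N), ylim = c(0, 1), yaxt = "n", ...)
    graphics::text(mean(c(1, N)), 0.5, "no intervals")
    return(invisible(NULL))
  }
  cols <- c("#1b9e77", "#d95f02", "#7570b3")[match(sel$dim, dims)]
  y <- seq_len(nrow(sel))
  graphics::plot(0, 0, type = "n", xlim = c(1, N + 1),
                 ylim = c(0, nrow(sel) + 1), xlab = "filtration step",
                 ylab = "interval", yaxt = "n", ...)
  finite_death <- pmin(sel$death, N + 1)
  graphics::segments(sel$birth, y, finite_death, y, col = cols, lwd = 2)
  open_idx <- which(!is.finite(sel$death))
  if (length(open_idx)) {
    graphics::points(rep(N + 1, length(open_idx)), y[open_idx],
                     pch = ">", col = cols[open_idx])
  }
  graphics::legend("bottomright", legend = paste0("dim ", dims),
                   col = c("#1b9e77", "#d95f02", "#7570b3")[seq_along(dims)],
                   lwd = 2, bty = "n")
  invisible(NULL)
}

#' Plot Betti curves
#'
#' @param curves Data frame from [betti_curves()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_betti_curves <- function(curves, ...) {
  beta_cols <- grep("^beta", names(curves), value = TRUE)
  graphics::matplot(curves$step, curves[, beta_cols, drop = FALSE],
                    type = "s", lty = 1, lwd = 2,
                    col = c("#1b9e77", "#d95f02", "#7570b3"),
                    xlab = "filtration step", ylab = "live cavities", ...)
  graphics::legend("topright", legend = beta_cols,
                   col = c("#1b9e77", "#d95f02", "#7570b3"),
                   lwd = 2, bty = "n")
  invisible(NULL)
}

#' Plot introduction curves
#'
#' @param curves Named list of `introduction_curve` objects (e.g. core
#'   and periphery, or the edge classes).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_introduction_curves <- function(curves, ...) {
  stopifnot(length(curves) >= 1L)
  palette <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e")
  graphics::plot(0, 0, type = "n", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "normalized exposition time t",
                 ylab = "fraction introduced", ...)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    graphics::lines(cv$t, cv$fraction, type = "s",
                    col = palette[(i - 1L) %% length(palette) + 1L],
                    lwd = 2)
  }
  graphics::legend("bottomright", legend = names(curves),
                   col = palette[seq_along(curves)], lwd = 2, bty = "n")
  invisible(NULL)
}
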