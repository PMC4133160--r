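regime_colors <- c(monostable_background = "black",
                   bistable_background_oscillation = "#7EC8E3",
                   monostable_oscillation = "#00008B",
                   bistable_background_upper = "#E3C800",
                   unresolved = "grey60")

#' Plot macrocolumn LFP traces
#'
#' Stacked macrocolumn-average traces (a subset of macrocolumns), the
#' standard way of eyeballing a simulated seizure.
#'
#' @param x a \code{simulation_result}.
#' @param macros macrocolumn indices to draw (default: up to 12, evenly
#'   spaced).
#' @param spacing vertical offset between traces.
#' @param ... passed to \code{matplot}.
#' @export
plot.simulation_result <- function(x, macros = NULL, spacing = 0.5, ...) {
  nm <- ncol(x$macro_u)
  if (is.null(macros))
    macros <- unique(round(seq(1, nm, length.out = min(12, nm))))
  y <- x$macro_u[, macros, drop = FALSE] +
    matrix(rep((seq_along(macros) - 1) * spacing, each = nrow(x$macro_u)),
           nrow(x$macro_u))
  graphics::matplot(x$t_macro / 1000, y, type = "l", lty = 1,
                    col = "black", xlab = "time (s)",
                    ylab = "macrocolumn LFP proxy (offset)", yaxt = "n", ...)
  graphics::axis(2, at = (seq_along(macros) - 1) * spacing,
                 labels = macros, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Snapshot images of the excitatory activity field
#'
#' @param result a \code{simulation_result}.
#' @param times snapshot times, ms (nearest stored frame is used).
#' @param zlim colour range (fixed for comparability across panels).
#' @param file optional PNG path; when set, panels are written there.
#' @export
plot_sheet_snapshots <- function(result, times, zlim = c(0, 1),
                                 file = NULL) {
  geom <- result$geom
  if (!is.null(file)) {
    grDevices::png(file, width = 260 * length(times), height = 280)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, length(times)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (tt in times) {
    i <- which.min(abs(result$t_units - tt))
    m <- matrix(result$u[i, ], geom$n_rows, geom$n_cols, byrow = TRUE)
    graphics::image(t(m)[, geom$n_rows:1], zlim = zlim, axes = FALSE,
                    col = grDevices::hcl.colors(64, "inferno"),
                    main = sprintf("T = %.2f s", result$t_units[i] / 1000))
  }
  invisible(result)
}

#' Plot a regime map
#'
#' Raster with the conventional colour semantics: black = monostable
#' background, light blue = bistable background/oscillation, dark blue =
#' monostable oscillation, yellow = bistable background/upper.
#'
#' @param x a \code{regime_map}.
#' @param ... ignored.
#' @export
plot.regime_map <- function(x, ...) {
  xs <- sort(unique(x$x)); ys <- sort(unique(x$y))
  z <- matrix(NA_integer_, length(xs), length(ys))
  for (k in seq_len(nrow(x)))
    z[match(x$x[k], xs), match(x$y[k], ys)] <-
      match(x$label[k], names(regime_colors))
  graphics::image(xs, ys, z, zlim = c(1, length(regime_colors)),
                  col = regime_colors, xlab = attr(x, "axis_x"),
                  ylab = attr(x, "axis_y"))
  graphics::legend("topright", legend = names(regime_colors),
                   fill = regime_colors, cex = 0.6, bg = "white")
  invisible(x)
}

#' Plot a recruitment time course
#'
#' @param x a \code{recruitment_report}.
#' @param ... passed to \code{plot}.
#' @export
plot.recruitment_report <- function(x, ...) {
  graphics::plot(x$t_window / 1000, 100 * x$fraction, type = "s",
                 xlab = "time (s)", ylab = "% units recruited",
                 ylim = c(0, 100), ...)
  graphics::lines(x$t_window / 1000, 100 * x$fraction_surround,
                  type = "s", lty = 2)
  graphics::legend("topleft", c("all units", "surround"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' Plot a recruitment scan
#'
#' @param x a \code{scan_result}.
#' @param ... ignored.
#' @export
plot.scan_result <- function(x, ...) {
  xs <- sort(unique(x$x)); ys <- sort(unique(x$y))
  axes <- attr(x, "axes")
  if (!is.null(x$label)) {
    labs <- c("monostable_background", "bistable", "monostable_oscillatory",
              "unresolved")
    cols <- c("black", "#7EC8E3", "#00008B", "grey60")
    z <- matrix(NA_integer_, length(xs), length(ys))
    for (k in seq_len(nrow(x)))
      z[match(x$x[k], xs), match(x$y[k], ys)] <- match(x$label[k], labs)
    graphics::image(xs, ys, z, zlim = c(1, 4), col = cols,
                    xlab = axes["x"], ylab = axes["y"])
    graphics::legend("topright", legend = labs, fill = cols, cex = 0.6,
                     bg = "white")
  } else {
    z <- matrix(NA_real_, length(xs), length(ys))
    for (k in seq_len(nrow(x)))
      z[match(x$x[k], xs), match(x$y[k], ys)] <- x$mean[k]
    graphics::image(xs, ys, z, col = grDevices::hcl.colors(64, "viridis"),
                    xlab = axes["x"], ylab = axes["y"])
  }
  invisible(x)
}

#' Write macrocolumn traces of a simulation to CSV
#'
#' Down-sampled exporter for the macrocolumn-average traces.
#'
#' @param result a \code{simulation_result}.
#' @param path CSV output path.
#' @param stride keep every \code{stride}-th step.
#' @return \code{path}, invisibly.
#' @export
write_macro_traces <- function(result, path, stride = 5L) {
  keep <- seq(1, nrow(result$macro_u), by = stride)
  df <- data.frame(t_ms = result$t_macro[keep],
                   result$macro_u[keep, , drop = FALSE])
  names(df) <- c("t_ms", paste0("macro_", seq_len(ncol(result$macro_u))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
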