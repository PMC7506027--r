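#' Plot a bifurcation diagram
#'
#' Mean excitatory membrane of every equilibrium branch against the tonic
#' drive; stable equilibria as filled points, unstable as open points, with
#' the multistable interval shaded.
#'
#' @param x a `bifurcation_diagram`.
#' @param ... passed to [plot()].
#' @export
plot.bifurcation_diagram <- function(x, ...) {
  b <- x$branches
  plot(b$I_o, b$u_e, type = "n", xlab = "tonic drive I_o",
       ylab = "equilibrium u_e", ...)
  iv <- x$multistable_interval
  if (!is.null(iv)) {
    usr <- graphics::par("usr")
    graphics::rect(iv[1], usr[3], iv[2], usr[4], col = "grey92", border = NA)
  }
  graphics::points(b$I_o[!b$stable], b$u_e[!b$stable], pch = 1, col = "grey40")
  graphics::points(b$I_o[b$stable], b$u_e[b$stable], pch = 16)
  invisible(x)
}

#' Plot a simulation result
#'
#' Population-mean membrane traces with the drive-step time marked.
#'
#' @param x a `sim_result`.
#' @param ... passed to [plot()].
#' @export
plot.sim_result <- function(x, ...) {
  t_ms <- (seq_along(x$u_e_mean) - 1) * x$raster$dt
  plot(t_ms, x$u_e_mean, type = "l", xlab = "time (ms)",
       ylab = "population mean membrane",
       ylim = range(x$u_e_mean, x$u_i_mean), ...)
  graphics::lines(t_ms, x$u_i_mean, col = "blue")
  graphics::abline(v = x$protocol$t_step, lty = 2, col = "grey50")
  graphics::legend("topleft", c("excitatory", "inhibitory"),
                   col = c("black", "blue"), lty = 1, bty = "n")
  invisible(x)
}
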