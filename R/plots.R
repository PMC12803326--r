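#' Plot a beta-sweep results table
#'
#' Mutual information versus the normalized substrate production rate, one
#' curve per allosteric condition, with the refined optimum marked by a
#' dashed vertical line.  Plots are conveniences; all downstream analysis
#' reads the CSV tables.
#'
#' @param sw Output of [run_beta_sweep()].
#' @return Invisibly, `sw`.
#' @export
plot_beta_sweep <- function(sw) {
  pairs <- unique(sw[, c("xiK", "xiV")])
  cols <- grDevices::hcl.colors(max(nrow(pairs), 2L), "Dark 3")
  graphics::plot(NA, xlim = range(sw$beta), ylim = c(0, max(sw$mi_ab_nats) * 1.05),
                 log = "x", xlab = expression(beta / gamma[S]),
                 ylab = "MI(sigmaA; sigmaB) [nats]",
                 main = "Steady-state information vs substrate flux")
  opt <- attr(sw, "optima")
  for (i in seq_len(nrow(pairs))) {
    sel <- sw$xiK == pairs$xiK[i] & sw$xiV == pairs$xiV[i]
    graphics::lines(sw$beta[sel], sw$mi_ab_nats[sel], col = cols[i], lwd = 2)
    graphics::points(sw$beta[sel], sw$mi_ab_nats[sel], col = cols[i], pch = 16)
    if (!is.null(opt))
      graphics::abline(v = opt$beta_opt[opt$xiK == pairs$xiK[i] &
                                        opt$xiV == pairs$xiV[i]],
                       col = cols[i], lty = 2)
  }
  graphics::legend("topright", bty = "n", col = cols[seq_len(nrow(pairs))],
                   lwd = 2, legend = sprintf("xiK=%g, xiV=%g",
                                             pairs$xiK, pairs$xiV))
  invisible(sw)
}

#' Plot a xi-sweep results table
#'
#' Three stacked panels (mutual information, mean substrate, mean product)
#' versus the swept allosteric ratio.
#'
#' @param xs Output of [run_xi_sweep()].
#' @return Invisibly, `xs`.
#' @export
plot_xi_sweep <- function(xs) {
  xi <- if (xs$xi_swept[1] == "K") xs$xiK else xs$xiV
  old <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  lab <- sprintf("xi_%s", xs$xi_swept[1])
  graphics::plot(xi, xs$mi_ab_nats, log = "x", type = "b", pch = 16,
                 xlab = lab, ylab = "MI [nats]",
                 main = sprintf("%s-type allostery at beta = %g",
                                xs$xi_swept[1], xs$beta[1]))
  graphics::plot(xi, xs$mean_s, log = "x", type = "b", pch = 16,
                 xlab = lab, ylab = "<S> [molecules]")
  graphics::plot(xi, xs$mean_p, log = "x", type = "b", pch = 16,
                 xlab = lab, ylab = "<P> [molecules]")
  invisible(xs)
}

#' Plot a pulsed-input time-series table
#'
#' Four stacked panels: the square-wave input beta(t), the time-resolved
#' mutual information, and the mean substrate and product copy numbers, one
#' curve per allosteric condition.
#'
#' @param pu Output of [run_pulse()].
#' @return Invisibly, `pu`.
#' @export
plot_pulse <- function(pu) {
  pairs <- unique(pu[, c("xiK", "xiV")])
  cols <- grDevices::hcl.colors(max(nrow(pairs), 2L), "Dark 3")
  old <- graphics::par(mfrow = c(4, 1), mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(old))
  sel1 <- pu$xiK == pairs$xiK[1] & pu$xiV == pairs$xiV[1]
  graphics::plot(pu$time[sel1], pu$beta[sel1], type = "s", lwd = 2,
                 xlab = "", ylab = expression(beta(t)))
  for (what in c("mi_ab_nats", "mean_s", "mean_p")) {
    ylab <- c(mi_ab_nats = "MI [nats]", mean_s = "<S>",
              mean_p = "<P>")[[what]]
    graphics::plot(NA, xlim = range(pu$time),
                   ylim = range(0, pu[[what]]), xlab = "time [1/gammaS]",
                   ylab = ylab)
    for (i in seq_len(nrow(pairs))) {
      sel <- pu$xiK == pairs$xiK[i] & pu$xiV == pairs$xiV[i]
      graphics::lines(pu$time[sel], pu[[what]][sel], col = cols[i], lwd = 2)
    }
    if (what == "mi_ab_nats")
      graphics::legend("topright", bty = "n",
                       col = cols[seq_len(nrow(pairs))], lwd = 2,
                       legend = sprintf("xiK=%g, xiV=%g",
                                        pairs$xiK, pairs$xiV))
  }
  invisible(pu)
}
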