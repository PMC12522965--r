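# Base-graphics plots: cost-effectiveness plane, acceptability curve,
# tornado diagram.

#' Plot the cost-effectiveness plane from a PSA sample
#'
#' Incremental effect on x, incremental cost on y, one point per
#' iteration, with the willingness-to-pay threshold line through the
#' origin.
#'
#' @param sample A `psa_sample`.
#' @param wtp Willingness-to-pay (slope of the threshold line).
#' @return NULL, invisibly.
#' @export
plot_ce_plane <- function(sample, wtp = 13002) {
  graphics::plot(sample$delta_effect, sample$delta_cost,
                 pch = 16, cex = 0.5, col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "Incremental QALYs", ylab = "Incremental cost ($)",
                 main = "Cost-effectiveness plane: ICD vs pharmacotherapy")
  graphics::abline(h = 0, v = 0, col = "grey60")
  graphics::abline(a = 0, b = wtp, lty = 2, col = "firebrick")
  graphics::legend("topleft", legend = sprintf("WTP $%s/QALY",
                                               format(wtp, big.mark = ",")),
                   lty = 2, col = "firebrick", bty = "n")
  invisible(NULL)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A `ceac_curve` from [ceac()].
#' @return NULL, invisibly.
#' @export
plot_ceac <- function(curve) {
  graphics::plot(curve$wtp, curve$prob_ce, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = "Willingness-to-pay ($/QALY)",
                 ylab = "Probability ICD is cost-effective",
                 main = "Cost-effectiveness acceptability curve")
  w <- attr(curve, "wtp")
  if (!is.null(w)) {
    graphics::abline(v = w, lty = 2, col = "firebrick")
    graphics::mtext(sprintf("P(CE) at $%s = %.2f", format(w, big.mark = ","),
                            attr(curve, "prob_at_wtp")), side = 3, cex = 0.8)
  }
  invisible(NULL)
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning each parameter's low/high ICER, widest on top,
#' pivoted on the base-case ICER.
#'
#' @param entries A `tornado_result` from [tornado()].
#' @param top Show at most this many bars (default 10).
#' @return NULL, invisibly.
#' @export
plot_tornado <- function(entries, top = 10) {
  e <- utils::head(entries[is.finite(entries$range_width) &
                             entries$range_width > 0, ], top)
  e <- e[rev(seq_len(nrow(e))), ]
  base <- attr(entries, "base_icer")
  xlim <- range(c(e$low_icer, e$high_icer, base), na.rm = TRUE)
  graphics::par(mar = c(5, 12, 4, 2))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, nrow(e) + 0.5),
                 yaxt = "n", xlab = "ICER ($/QALY)", ylab = "",
                 main = "Tornado diagram")
  graphics::axis(2, at = seq_len(nrow(e)), labels = e$parameter_id, las = 1,
                 cex.axis = 0.8)
  for (i in seq_len(nrow(e)))
    graphics::rect(min(e$low_icer[i], e$high_icer[i]), i - 0.35,
                   max(e$low_icer[i], e$high_icer[i]), i + 0.35,
                   col = "steelblue", border = NA)
  graphics::abline(v = base, lty = 2, col = "firebrick")
  invisible(NULL)
}
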