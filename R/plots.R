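#' @export
plot.fld_profile <- function(x, ...) {
  graphics::plot(x$n_nt, x$value, type = "l", xlab = "fragment length (nt)",
                 ylab = "mean break-correlation weight",
                 main = sprintf("FLD (lambda = %g nm)", attr(x, "lambda_nm")), ...)
  pk <- detect_peaks(x)
  if (nrow(pk) > 0) graphics::abline(v = pk$position, lty = 3, col = "grey40")
  invisible(x)
}

#' @export
plot.linker_scan <- function(x, ...) {
  ok <- !is.na(x$dLk_per_nucleosome)
  fam <- factor(x$family[ok], levels = c("T1", "T2"))
  graphics::plot(x$L[ok], x$dLk_per_nucleosome[ok],
                 col = c("firebrick", "navy")[as.integer(fam)],
                 pch = ifelse(x$rank[ok] == 1, 19, 1),
                 xlab = "linker length L (bp)",
                 ylab = "dLk per nucleosome (turns)",
                 main = "linker-length scan", ...)
  graphics::legend("bottomright", legend = c("T1", "T2"), pch = 19,
                   col = c("firebrick", "navy"), bty = "n")
  invisible(x)
}

#' @export
plot.ensemble <- function(x, ...) {
  step <- seq_along(x$energies) * x$params$record_every
  graphics::plot(step, x$energies, type = "l", xlab = "MC move",
                 ylab = "total energy (kT)",
                 main = sprintf("MC trace (acceptance %.2f)", x$acceptance_rate), ...)
  graphics::abline(v = x$burnin * x$params$record_every, lty = 2, col = "grey50")
  invisible(x)
}
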