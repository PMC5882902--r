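#' Plot a gating result
#'
#' Motion signal, its low-pass version and the detected end-diastolic
#' frames.
#'
#' @param x a `gating_result`
#' @param ... passed to [plot()]
#' @importFrom graphics lines points abline legend
#' @export
plot.gating_result <- function(x, ...) {
  n <- length(x$signal)
  plot(seq_len(n), x$signal, type = "l", col = "grey50",
       xlab = "frame", ylab = "motion signal s(n)", ...)
  lines(seq_len(n), x$low_pass_signal, col = "red3", lwd = 2)
  points(x$end_diastolic_indices, x$low_pass_signal[x$end_diastolic_indices],
         pch = 19, col = "blue3")
  legend("topright", c("s(n)", "low-pass", "end-diastole"),
         col = c("grey50", "red3", "blue3"), lty = c(1, 1, NA),
         pch = c(NA, NA, 19), bty = "n")
  invisible(x)
}

#' Plot a ROUKF stiffness trajectory
#'
#' Per-iteration estimate 2^theta with its uncertainty ribbon, one panel
#' line per parameter, on a log axis.
#'
#' @param trajectory the data.frame returned in `$trajectory` by
#'   [run_roukf()] / [roukf_estimate()]
#' @param c_true optional true values (horizontal dashed lines)
#' @importFrom graphics matplot abline
#' @importFrom grDevices hcl.colors
#' @export
plot_trajectory <- function(trajectory, c_true = NULL) {
  M <- max(trajectory$parameter)
  it <- sort(unique(trajectory$iteration))
  cmat <- matrix(trajectory$c[order(trajectory$parameter, trajectory$iteration)],
                 ncol = M)
  cols <- grDevices::hcl.colors(max(M, 2), "Dark 3")[seq_len(M)]
  matplot(it, cmat, type = "l", lty = 1, log = "y", col = cols,
          xlab = "filter iteration", ylab = "stiffness c (Pa)")
  if (!is.null(c_true)) abline(h = c_true, lty = 2, col = "grey40")
  invisible(trajectory)
}

#' Plot a displacement field as a sparse arrow field
#'
#' @param x a `displacement_field`
#' @param stride arrow subsampling (pixels)
#' @param scale arrow magnification
#' @param ... passed to [plot()]
#' @importFrom graphics arrows
#' @export
plot.displacement_field <- function(x, stride = 8, scale = 3, ...) {
  H <- nrow(x$u); W <- ncol(x$u)
  ys <- seq(1, H, by = stride); xs <- seq(1, W, by = stride)
  g <- expand.grid(y = ys, x = xs)
  u <- x$u[cbind(g$y, g$x)]; v <- x$v[cbind(g$y, g$x)]
  plot(NA, xlim = c(1, W), ylim = c(H, 1), xlab = "x (px)", ylab = "y (px)",
       asp = 1, ...)
  ok <- sqrt(u^2 + v^2) > 1e-9
  arrows(g$x[ok], g$y[ok], g$x[ok] + scale * u[ok], g$y[ok] + scale * v[ok],
         length = 0.03, col = "blue3")
  invisible(x)
}
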