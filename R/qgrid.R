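#' Discretized scattering-momentum grid
#'
#' Builds the q-grid on which intensities and form factors are evaluated.
#' The default covers the momentum range 0 to 0.75 A^-1 with 51 bins of
#' width 0.015 A^-1; intensities are evaluated at the left edge of each bin,
#' starting at q = 0.
#'
#' @param q_min Lower edge of the first bin (A^-1). Default 0.
#' @param dq Bin width (A^-1). Default 0.015.
#' @param n_bins Number of bins. Default 51.
#' @return An object of class `qgrid` with elements `q_min`, `dq`, `n_bins`
#'   and `q`, the vector of left-edge evaluation points.
#' @examples
#' g <- q_grid()
#' range(g$q)  # 0 .. 0.750
#' @export
q_grid <- function(q_min = 0, dq = 0.015, n_bins = 51L) {
  stopifnot(is.numeric(q_min), length(q_min) == 1L, q_min >= 0,
            is.numeric(dq), length(dq) == 1L, dq > 0,
            is.numeric(n_bins), length(n_bins) == 1L, n_bins >= 1)
  n_bins <- as.integer(n_bins)
  structure(list(q_min = q_min, dq = dq, n_bins = n_bins,
                 q = q_min + dq * (seq_len(n_bins) - 1L)),
            class = "qgrid")
}

#' @export
print.qgrid <- function(x, ...) {
  cat(sprintf("q-grid: %d bins of width %g A^-1, left edges %g .. %g A^-1\n",
              x$n_bins, x$dq, x$q[1L], x$q[x$n_bins]))
  invisible(x)
}

grids_match <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(a - b) <= tol)
}
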