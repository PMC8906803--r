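## Zero-phase low-pass smoothing with a Gaussian kernel. A Gaussian is used
## rather than a recursive (Butterworth-type) filter because its step/corner
## response is monotone: flat-passband filters ring near the velocity-program
## knots, which corrupts the sub-cm/s flank tails the phase-boundary
## refinement fits. The Gaussian's effect on a locally quadratic signal is a
## known constant offset c * sigma^2, which the refinement corrects exactly.

#' Equivalent Gaussian kernel SD for a -3 dB cutoff
#'
#' The kernel SD (in seconds) that places the -3 dB point of the Gaussian
#' transfer function exp(-(2 pi f sigma)^2 / 2) at `cutoff` Hz.
#'
#' @param cutoff Hz.
#' @return sigma, seconds.
#' @export
gaussian_sigma_for_cutoff <- function(cutoff) {
  sqrt(log(2)) / (2 * pi * cutoff)
}

#' Zero-phase Gaussian low-pass
#'
#' Smooths a uniformly sampled series by convolution with a truncated
#' Gaussian kernel (radius 4 sigma), using odd reflection padding at the
#' ends. `NA` runs split the series; each contiguous observed run is
#' smoothed on its own, and runs shorter than the kernel are returned
#' unchanged.
#'
#' @param x numeric vector (may contain `NA` runs).
#' @param frame_rate sampling rate, frames/s.
#' @param cutoff -3 dB cutoff, Hz. `Inf` or `>= frame_rate / 2` disables
#'   smoothing.
#' @return smoothed vector, `NA` where `x` was `NA`.
#' @export
lowpass <- function(x, frame_rate, cutoff) {
  if (!is.finite(cutoff) || cutoff >= frame_rate / 2) return(x)
  stopifnot(cutoff > 0)
  sig <- gaussian_sigma_for_cutoff(cutoff) * frame_rate   # in frames
  rad <- max(1L, ceiling(4 * sig))
  kern <- stats::dnorm(seq(-rad, rad), sd = sig)
  kern <- kern / sum(kern)
  out <- x
  for (run in na_runs(!is.na(x))) {
    seg <- x[run[1]:run[2]]
    n <- length(seg)
    if (n < rad + 2) next
    p <- min(rad, n - 1)
    ext <- c(2 * seg[1] - seg[(p + 1):2], seg, 2 * seg[n] - seg[(n - 1):(n - p)])
    sm <- stats::filter(ext, kern, sides = 2)
    out[run[1]:run[2]] <- as.numeric(sm[(p + 1):(p + n)])
  }
  out
}

# contiguous TRUE runs of a logical vector, as list of c(start, end)
na_runs <- function(flag) {
  if (!any(flag)) return(list())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  lapply(keep, function(k) c(starts[k], ends[k]))
}

# smooth an n-by-3 position matrix per axis
smooth_positions <- function(p, frame_rate, cutoff) {
  apply(p, 2, lowpass, frame_rate = frame_rate, cutoff = cutoff)
}
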