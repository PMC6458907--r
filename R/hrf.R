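#' Canonical double-gamma hemodynamic response function
#'
#' The stereotyped BOLD impulse response used both to synthesize evoked
#' signals and to build GLM regressors: a gamma density peaking at 6 s minus
#' an undershoot gamma peaking at 16 s scaled by 1/6, normalized so the
#' response peak equals 1 (an event of amplitude A then produces a peak
#' signal change of A).
#'
#' @param t times in seconds (>= 0 contribute; negative times return 0).
#' @param peak time-to-peak of the positive lobe in s.
#' @param undershoot time-to-peak of the undershoot in s.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return numeric vector of HRF values at `t`.
#' @examples
#' t <- seq(0, 30, 0.5)
#' h <- hrf_double_gamma(t)
#' t[which.max(h)]  # 6 s
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  # gamma densities with scale 1 peak at (shape - 1): shape = peak + 1
  g1 <- stats::dgamma(tp, shape = peak + 1, rate = 1)
  g2 <- stats::dgamma(tp, shape = undershoot + 1, rate = 1)
  h[pos] <- g1 - g2 / ratio
  # normalize to unit peak on a fine grid (analytic peak is at t = peak)
  h / (stats::dgamma(peak, shape = peak + 1, rate = 1) -
         stats::dgamma(peak, shape = undershoot + 1, rate = 1) / ratio)
}

# HRF sampled on the volume grid, truncated at 32 s
hrf_kernel <- function(tr, span = 32) {
  hrf_double_gamma(seq(0, span, by = tr))
}

# convolve a stick series (one value per volume) with a kernel, causal,
# truncated to the series length
convolve_sticks <- function(sticks, kernel) {
  n <- length(sticks)
  out <- numeric(n)
  ev <- which(sticks != 0)
  for (e in ev) {
    idx <- e:min(n, e + length(kernel) - 1L)
    out[idx] <- out[idx] + sticks[e] * kernel[seq_along(idx)]
  }
  out
}
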