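#' One-sided amplitude spectrum of a time course
#'
#' Amplitude of the fast Fourier transform: \eqn{A_k = |X_k| / n}, doubled
#' for strictly interior frequencies so that the one-sided spectrum carries
#' the full signal power (\eqn{\sum_{k>0} A_k^2 / c_k} with \eqn{c_k = 2}
#' for doubled bins recovers the signal's mean-square deviation, Parseval's
#' identity). The frequency axis is in Hz given the sampling interval
#' (e.g. TR = 2 s for typical resting-state fMRI time courses).
#'
#' @param x numeric vector, length >= 4.
#' @param samplingInterval time between samples in seconds (default 2).
#' @return data.frame with columns \code{frequency} (Hz, from 0 to the
#'   Nyquist frequency) and \code{amplitude}.
#' @export
amplitudeSpectrum <- function(x, samplingInterval = 2) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 samples")
  if (samplingInterval <= 0) stop("samplingInterval must be positive")
  A <- Mod(stats::fft(x)) / n
  half <- floor(n / 2)
  k <- 0:half
  amp <- A[k + 1L]
  interior <- k > 0 & (2 * k < n)   # not DC, not Nyquist
  amp[interior] <- 2 * amp[interior]
  data.frame(frequency = k / (n * samplingInterval), amplitude = amp)
}
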