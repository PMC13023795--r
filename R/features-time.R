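#' Time-domain statistical features
#'
#' The seven classical amplitude statistics: minimum, maximum, mean,
#' variance (divisor n-1), RMS, skewness and kurtosis.  Skewness is
#' m3/m2^(3/2) and kurtosis m4/m2^2 (non-excess; a normal distribution gives
#' 3), with central moments using divisor n; a zero-variance series returns
#' skewness 0 and kurtosis 0 by convention.
#'
#' @param x numeric vector, length >= 2.
#' @return named numeric vector `min, max, mean, variance, rms, skewness,
#'   kurtosis`.
#' @export
time_domain_features <- function(x) {
  n <- length(x)
  if (n < 2) stop("time-domain features need at least 2 samples")
  mu <- mean(x)
  centred <- x - mu
  m2 <- mean(centred^2)
  m3 <- mean(centred^3)
  m4 <- mean(centred^4)
  c(min = min(x), max = max(x), mean = mu,
    variance = sum(centred^2) / (n - 1),
    rms = sqrt(mean(x^2)),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0)
}
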