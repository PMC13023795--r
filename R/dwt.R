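# Multilevel discrete wavelet transform with periodized boundary handling.
#
# Periodization keeps the transform orthonormal (coefficient energy equals
# signal energy and reconstruction is exact) whenever the input length is
# even at every level; odd-length inputs are periodically extended by one
# sample before filtering, which preserves exact invertibility but not the
# energy identity at that level.

# Daubechies scaling (low-pass) filters, standard published coefficients.
.wavelet_dec_lo <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db6 = c(-0.0010773010853084796, 0.004777257510945511,
          0.0005538422011614961, -0.03158203931748603,
          0.027522865530305727, 0.09750160558732304,
          -0.12976686756726194, -0.22626469396543983,
          0.31525035170919763, 0.7511339080210954,
          0.49462389039845306, 0.11154074335010947))

#' Orthogonal wavelet filter pair
#'
#' @param wavelet_name `"db6"` (default throughout the pipeline) or `"haar"`.
#' @return list with low-pass `lo` and high-pass `hi` decomposition filters,
#'   the quadrature-mirror pair `hi[i] = (-1)^i lo[L - i + 1]`.
#' @export
wavelet_filters <- function(wavelet_name = "db6") {
  lo <- .wavelet_dec_lo[[wavelet_name]]
  if (is.null(lo))
    stop("unknown wavelet `", wavelet_name, "`; available: ",
         paste(names(.wavelet_dec_lo), collapse = ", "))
  L <- length(lo)
  hi <- (-1)^(seq_len(L)) * lo[L - seq_len(L) + 1]
  list(lo = lo, hi = hi, length = L)
}

# One periodized analysis step.  Returns approximation and detail
# coefficient vectors of length ceiling(n / 2) plus the input length (needed
# to undo the odd-length extension on reconstruction).
.dwt_step <- function(x, filt) {
  n0 <- length(x)
  if (n0 %% 2 == 1) x <- c(x, x[n0])
  n <- length(x)
  L <- filt$length
  half <- n / 2
  idx <- outer(seq(0, n - 2, by = 2), 0:(L - 1), "+") %% n + 1
  xm <- matrix(x[idx], nrow = half, ncol = L)
  list(a = drop(xm %*% filt$lo), d = drop(xm %*% filt$hi), input_length = n0)
}

# Inverse of .dwt_step.
.idwt_step <- function(a, d, input_length, filt) {
  half <- length(a)
  n <- 2 * half
  L <- filt$length
  x <- numeric(n)
  k0 <- seq(0, n - 2, by = 2)
  for (m in seq_len(L)) {
    j <- (k0 + m - 1) %% n + 1
    contrib <- filt$lo[m] * a + filt$hi[m] * d
    x[j] <- x[j] + contrib
  }
  x[seq_len(input_length)]
}

#' Multilevel periodized DWT
#'
#' Decomposes a signal into detail coefficient bands `d1` (finest) ...
#' `d<levels>` (coarsest) and the final approximation band, the coefficient
#' substrate used for both denoising and feature extraction.
#'
#' @param x numeric vector, `length(x) >= 2^levels`.
#' @param wavelet_name see [wavelet_filters()].
#' @param levels decomposition depth (default 6).
#' @return object of class `ecg_dwt`: list with `details` (list `d1..d<L>`),
#'   `approx`, `wavelet_name`, `levels` and the per-level input lengths.
#' @export
dwt_multilevel <- function(x, wavelet_name = "db6", levels = 6) {
  if (length(x) < 2^levels)
    stop("input too short for ", levels, "-level DWT: need at least ",
         2^levels, " samples, got ", length(x))
  filt <- wavelet_filters(wavelet_name)
  details <- vector("list", levels)
  lengths <- integer(levels)
  a <- x
  for (lev in seq_len(levels)) {
    st <- .dwt_step(a, filt)
    details[[lev]] <- st$d
    lengths[lev] <- st$input_length
    a <- st$a
  }
  names(details) <- paste0("d", seq_len(levels))
  structure(list(details = details, approx = a, wavelet_name = wavelet_name,
                 levels = levels, input_lengths = lengths),
            class = "ecg_dwt")
}

#' Inverse multilevel periodized DWT
#'
#' @param decomp an `ecg_dwt` object (coefficients possibly modified, e.g.
#'   by thresholding).
#' @return reconstructed numeric vector of the original length.
#' @export
idwt_multilevel <- function(decomp) {
  filt <- wavelet_filters(decomp$wavelet_name)
  a <- decomp$approx
  for (lev in rev(seq_len(decomp$levels)))
    a <- .idwt_step(a, decomp$details[[lev]], decomp$input_lengths[lev], filt)
  a
}

#' Denoising parameters
#'
#' @param wavelet_name orthogonal wavelet (default `"db6"`).
#' @param levels decomposition depth (default 6).
#' @param threshold_rule only `"universal"`: sigma * sqrt(2 log N) with the
#'   noise scale sigma estimated as median(|d1|)/0.6745.
#' @param threshold_mode `"soft"` (default) or `"hard"`.
#' @return object of class `denoise_params`.
#' @export
denoise_params <- function(wavelet_name = "db6", levels = 6,
                           threshold_rule = "universal",
                           threshold_mode = c("soft", "hard")) {
  if (levels < 1) stop("levels must be >= 1")
  threshold_rule <- match.arg(threshold_rule, "universal")
  threshold_mode <- match.arg(threshold_mode)
  wavelet_filters(wavelet_name)  # validates the name
  structure(list(wavelet_name = wavelet_name, levels = levels,
                 threshold_rule = threshold_rule,
                 threshold_mode = threshold_mode),
            class = "denoise_params")
}

.threshold <- function(d, thr, mode) {
  if (mode == "soft") sign(d) * pmax(abs(d) - thr, 0)
  else d * (abs(d) > thr)
}

#' Wavelet denoising of an ECG record
#'
#' Multilevel db6 decomposition, universal thresholding of every detail
#' band, inverse transform.  Length, label and metadata are preserved.
#'
#' @param record an `ecg_record` (or plain numeric vector).
#' @param params a [denoise_params()].
#' @param threshold override the universal threshold with a fixed value
#'   (`0` disables thresholding, recovering the input exactly).
#' @return denoised record of the same type as the input.
#' @export
denoise <- function(record, params = denoise_params(), threshold = NULL) {
  x <- if (inherits(record, "ecg_record")) record$samples else record
  if (length(x) < 2^params$levels)
    stop("record too short to denoise at ", params$levels,
         " levels: minimum length is ", 2^params$levels)
  dec <- dwt_multilevel(x, params$wavelet_name, params$levels)
  if (is.null(threshold)) {
    sigma <- median(abs(dec$details$d1)) / 0.6745
    threshold <- sigma * sqrt(2 * log(length(x)))
  }
  dec$details <- lapply(dec$details, .threshold, thr = threshold,
                        mode = params$threshold_mode)
  y <- idwt_multilevel(dec)
  if (inherits(record, "ecg_record")) { record$samples <- y; record }
  else y
}
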