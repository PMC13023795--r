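# Empirical mode decomposition by standard sifting: local extrema ->
# cubic-spline upper/lower envelopes (mirror-extended at the boundaries) ->
# subtract the mean envelope, iterated until the candidate satisfies the IMF
# conditions (zero-crossing/extrema counts differing by at most one,
# Cauchy-type SD below threshold) or the iteration cap is hit.  The sift
# loop is compiled (src/emd.cpp); the R helpers below are used by tests to
# audit extrema and zero-crossing counts.

#' EMD sifting parameters
#'
#' @param max_imfs number of intrinsic mode functions to extract (default 5,
#'   the number retained for feature extraction).
#' @param sift_stop_sd Cauchy stopping threshold for one sift:
#'   sum(m^2)/sum(h^2) of the removed mean envelope `m` relative to the
#'   current candidate `h` (default 0.2).
#' @param max_sift_iters hard cap on sift iterations per IMF (default 300;
#'   on noisy 10,000-sample ECG segments the first mode typically needs
#'   100-200 sifts before its zero-crossing and extrema counts agree).
#' @return object of class `emd_params`.
#' @export
emd_params <- function(max_imfs = 5, sift_stop_sd = 0.2,
                       max_sift_iters = 300) {
  if (max_imfs < 1) stop("max_imfs must be >= 1")
  if (sift_stop_sd <= 0) stop("sift_stop_sd must be > 0")
  structure(list(max_imfs = max_imfs, sift_stop_sd = sift_stop_sd,
                 max_sift_iters = max_sift_iters),
            class = "emd_params")
}

# Indices of strict local maxima and minima.
.local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  up <- d > 0
  dn <- d < 0
  list(max = which(up[-(n - 1)] & dn[-1]) + 1L,
       min = which(dn[-(n - 1)] & up[-1]) + 1L)
}

.zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' Empirical mode decomposition
#'
#' Decomposes a segment into up to `max_imfs` intrinsic mode functions plus
#' a residue; the decomposition is exactly additive by construction
#' (`Reduce("+", imfs) + residue == x`).  Monotone or extremum-poor input
#' yields zero IMFs with the input as residue (flagged, not an error).
#'
#' @param segment an `ecg_segment` or numeric vector.
#' @param params an [emd_params()].
#' @return list with `imfs` (list of numeric vectors, possibly empty),
#'   `residue`, and `n_imfs`.
#' @export
emd_decompose <- function(segment, params = emd_params()) {
  x <- if (inherits(segment, "ecg_segment")) segment$samples else segment
  emd_decompose_cpp(as.numeric(x), as.integer(params$max_imfs),
                    params$sift_stop_sd, as.integer(params$max_sift_iters))
}
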