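# Per-segment component set: the 13 signal groups on which features are
# computed -- the original segment, the six DWT detail bands plus the
# level-6 approximation (coefficient sequences, not reconstructed signals),
# and the first five EMD intrinsic mode functions.

#' Canonical component names
#'
#' @param levels DWT depth, `n_imfs` retained IMF count.
#' @return character vector `orj, d1..d6, a6, imf1..imf5` (defaults).
#' @export
component_names <- function(levels = 6, n_imfs = 5) {
  c("orj", paste0("d", seq_len(levels)), paste0("a", levels),
    paste0("imf", seq_len(n_imfs)))
}

#' DWT part of a component set
#'
#' @param segment `ecg_segment` or numeric vector.
#' @param wavelet_name,levels see [dwt_multilevel()].
#' @return named list `d1..d<levels>`, `a<levels>` of coefficient vectors.
#' @export
dwt_components <- function(segment, wavelet_name = "db6", levels = 6) {
  x <- if (inherits(segment, "ecg_segment")) segment$samples else segment
  dec <- dwt_multilevel(x, wavelet_name, levels)
  out <- dec$details
  out[[paste0("a", levels)]] <- dec$approx
  out
}

#' Build the full 13-component set for one segment
#'
#' Components for IMFs beyond those the sifting produced are marked absent
#' (`NULL` entries listed in the `absent` attribute); downstream feature
#' extraction emits missing values for them.
#'
#' @param segment an `ecg_segment` (or numeric vector).
#' @param wavelet_name,levels DWT settings.
#' @param emd an [emd_params()].
#' @return object of class `component_set`: named list of numeric vectors in
#'   canonical order with attributes `absent` (character vector) and
#'   `segment` (label/record/segment-index metadata).
#' @export
build_component_set <- function(segment, wavelet_name = "db6", levels = 6,
                                emd = emd_params()) {
  x <- if (inherits(segment, "ecg_segment")) segment$samples else segment
  comps <- c(list(orj = x), dwt_components(x, wavelet_name, levels))
  ed <- emd_decompose(x, emd)
  absent <- character(0)
  for (k in seq_len(emd$max_imfs)) {
    nm <- paste0("imf", k)
    if (k <= ed$n_imfs) comps[[nm]] <- ed$imfs[[k]]
    else { comps[nm] <- list(NULL); absent <- c(absent, nm) }
  }
  meta <- if (inherits(segment, "ecg_segment"))
    segment[c("label", "record_id", "segment_index")]
  else list(label = NA_character_, record_id = "segment", segment_index = 0L)
  structure(comps, absent = absent, segment = meta, class = "component_set")
}
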