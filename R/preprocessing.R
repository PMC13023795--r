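# Record preprocessing: denoise -> min-max normalize -> fixed-length
# segmentation (record-level normalization is the default ordering; a
# per-segment normalization scope is also supported).

#' Number of fixed-length segments obtainable from a record
#'
#' @param total_length record length in samples.
#' @param segment_length window length (default 10000).
#' @return `floor(total_length / segment_length)`; the trailing remainder is
#'   dropped.
#' @export
n_segments <- function(total_length, segment_length = 10000) {
  if (segment_length < 1) stop("segment_length must be >= 1")
  floor(total_length / segment_length)
}

#' Min-max normalization
#'
#' Maps `x` to `(x - min) / (max - min)`, so the output spans exactly
#' \[0, 1\].  Constant input is rejected: the mapping is undefined there and a
#' constant segment always indicates an upstream bug, so it fails loudly.
#'
#' @param x numeric vector or `ecg_segment`.
#' @return normalized object of the same type.
#' @export
normalize_minmax <- function(x) {
  if (inherits(x, "ecg_segment")) {
    x$samples <- normalize_minmax(x$samples)
    return(x)
  }
  rng <- range(x)
  if (!all(is.finite(rng))) stop("cannot normalize: non-finite values")
  if (rng[1] == rng[2])
    stop("cannot min-max normalize a constant segment (max == min)")
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Cut a record into fixed-length non-overlapping segments
#'
#' @param record an `ecg_record` (or numeric vector).
#' @param segment_length samples per segment (default 10000, i.e. 10 s at
#'   1000 Hz).
#' @return list of `ecg_segment` objects (`samples`, `label`, `record_id`,
#'   0-based `segment_index`); empty list if the record is shorter than one
#'   segment.
#' @export
segment_record <- function(record, segment_length = 10000) {
  x <- if (inherits(record, "ecg_record")) record$samples else record
  label <- if (inherits(record, "ecg_record")) record$label else NA_character_
  rid <- if (inherits(record, "ecg_record")) record$record_id else "record"
  k <- n_segments(length(x), segment_length)
  lapply(seq_len(k), function(i) {
    structure(list(samples = x[((i - 1) * segment_length + 1):(i * segment_length)],
                   label = label, record_id = rid, segment_index = i - 1L),
              class = "ecg_segment")
  })
}

#' Preprocess records into normalized segments
#'
#' Pipeline order: wavelet denoising of the whole record, min-max
#' normalization, then segmentation.  With `norm_scope = "record"` (default)
#' normalization is applied once per record, so segment values lie within
#' \[0, 1\] but an individual segment need not attain both bounds; with
#' `"segment"` each segment is normalized separately and attains 0 and 1
#' exactly.
#'
#' @param records list of `ecg_record` objects.
#' @param segment_length samples per segment.
#' @param norm_scope `"record"` or `"segment"`.
#' @param params [denoise_params()].
#' @param denoise_records set `FALSE` to skip denoising (already-clean
#'   input).
#' @return flat list of `ecg_segment` objects.
#' @export
preprocess <- function(records, segment_length = 10000,
                       norm_scope = c("record", "segment"),
                       params = denoise_params(), denoise_records = TRUE) {
  norm_scope <- match.arg(norm_scope)
  out <- lapply(records, function(rec) {
    if (denoise_records) rec <- denoise(rec, params)
    if (norm_scope == "record") {
      rec$samples <- normalize_minmax(rec$samples)
      segment_record(rec, segment_length)
    } else {
      lapply(segment_record(rec, segment_length), normalize_minmax)
    }
  })
  unlist(out, recursive = FALSE)
}
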