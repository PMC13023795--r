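# Minimal WFDB (.hea/.dat) adapter for single-lead ingestion, supporting
# signal format 16 (16-bit little-endian two's complement, interleaved
# channels) -- the format used by the 1000 Hz PTB diagnostic recordings.
# The adapter is optional: the rest of the package never requires it.

#' Read one lead of a WFDB record
#'
#' Parses the `.hea` header, memory-maps nothing (reads the full `.dat`),
#' extracts the requested lead and converts ADC units to physical units via
#' `(adc - baseline) / gain`.
#'
#' @param path record path prefix (with or without `.hea`).
#' @param lead lead name to extract (default `"II"`, case-insensitive).
#' @param label class label to attach (from the caller's manifest; the
#'   header has no diagnosis field this adapter interprets).
#' @return an `ecg_record`.
#' @export
read_wfdb_record <- function(path, lead = "II", label = NA_character_) {
  hea <- sub("\\.hea$", "", path)
  hea_file <- paste0(hea, ".hea")
  if (!file.exists(hea_file)) stop("WFDB header not found: ", hea_file)
  lines <- readLines(hea_file)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_name <- top[1]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lines[1 + seq_len(nsig)]
  fields <- lapply(strsplit(trimws(sig), "\\s+"), identity)
  leads <- vapply(fields, function(f) f[length(f)], character(1))
  idx <- which(tolower(leads) == tolower(lead))
  if (!length(idx))
    stop("lead `", lead, "` not found; header has: ",
         paste(leads, collapse = ", "))
  f <- fields[[idx]]
  if (f[2] != "16")
    stop("only WFDB signal format 16 is supported (got ", f[2], ")")
  gain_field <- f[3]
  gain <- as.numeric(sub("^([-0-9.]+).*", "\\1", gain_field))
  baseline <- if (grepl("\\(", gain_field))
    as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
  else if (length(f) >= 5) as.numeric(f[5]) else 0
  if (!is.finite(gain) || gain == 0) gain <- 200
  dat_file <- file.path(dirname(hea_file), f[1])
  if (!file.exists(dat_file)) stop("WFDB signal file not found: ", dat_file)
  raw <- readBin(dat_file, "integer", n = file.info(dat_file)$size / 2,
                 size = 2, signed = TRUE, endian = "little")
  total <- floor(length(raw) / nsig) * nsig
  mat <- matrix(raw[seq_len(total)], nrow = nsig)
  samples <- (mat[idx, ] - baseline) / gain
  if (is.finite(nsamp) && nsamp > 0 && nsamp <= length(samples))
    samples <- samples[seq_len(nsamp)]
  structure(list(samples = samples, sampling_rate = fs, label = label,
                 record_id = record_name, lead = leads[idx]),
            class = "ecg_record")
}

#' Write an ECG record in WFDB format 16
#'
#' Single-channel writer used for round-trip testing of the adapter.
#' Amplitudes are quantized as `round(samples * gain)`.
#'
#' @param record an `ecg_record`.
#' @param path output path prefix (writes `<path>.hea` and `<path>.dat`).
#' @param gain ADC units per mV (default 1000).
#' @return `path`, invisibly.
#' @export
write_wfdb_record <- function(record, path, gain = 1000) {
  name <- basename(path)
  adc <- as.integer(round(record$samples * gain))
  if (any(abs(adc) > 32767)) stop("samples exceed 16-bit range at this gain")
  writeLines(c(sprintf("%s 1 %g %d", name, record$sampling_rate,
                       length(adc)),
               sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s", name, gain,
                       adc[1], record$lead)),
             paste0(path, ".hea"))
  writeBin(adc, paste0(path, ".dat"), size = 2, endian = "little")
  invisible(path)
}
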