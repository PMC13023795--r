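#' @useDynLib ecgmi, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median sd rnorm runif rbinom var fft spline splinefun
#'   quantile approx wilcox.test predict
#' @importFrom utils head write.csv read.csv
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library functions never perturb
# user-level reproducibility.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  code
}

#' Configuration for the synthetic Lead-II ECG generator
#'
#' Builds a validated configuration describing one synthetic single-lead ECG
#' record.  The generator emulates the statistical shape of 1000 Hz Lead-II
#' clinical recordings: a quasi-periodic P-QRS-T beat train placed by a
#' jittered RR process, with class-dependent ST-segment offset, T-wave
#' polarity and irregularity, plus baseline wander, powerline interference
#' and white measurement noise.
#'
#' Class defaults: healthy records use `rr_jitter_sd = 25` ms, `st_offset = 0`
#' and upright T waves; MI records use `rr_jitter_sd = 60` ms, an ST
#' elevation of `+0.15` mV, T-wave inversion with probability 1/2, and a
#' white-noise SD raised by 50% so that complexity (entropy) features -- not
#' only amplitude features -- carry class signal.
#'
#' @param class_label `"healthy"` or `"MI"`.
#' @param duration record duration in seconds.
#' @param sampling_rate samples per second (default 1000).
#' @param mean_rr mean RR interval in ms (default 850).
#' @param rr_jitter_sd SD of the RR interval in ms; class default if `NULL`.
#' @param st_offset ST-segment offset in mV; class default if `NULL`.
#' @param t_polarity +1 or -1; if `NULL`, healthy is +1 and MI draws -1 with
#'   probability 1/2 at generation time.
#' @param noise_levels list with elements `baseline_wander_amp` (mV),
#'   `baseline_wander_freq` (Hz), `powerline_amp` (mV), `powerline_freq`
#'   (Hz, default 50) and `white_sd` (mV).
#' @param seed integer seed; generation is fully deterministic given the
#'   configuration.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(class_label = c("healthy", "MI"),
                         duration = 30,
                         sampling_rate = 1000,
                         mean_rr = 850,
                         rr_jitter_sd = NULL,
                         st_offset = NULL,
                         t_polarity = NULL,
                         noise_levels = list(),
                         seed = 1L) {
  class_label <- match.arg(class_label)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("invalid synth_config field `sampling_rate`: must be > 0")
  if (!is.numeric(duration) || length(duration) != 1 ||
      duration * sampling_rate < 1)
    stop("invalid synth_config field `duration`: duration * sampling_rate must be >= 1")
  if (!is.numeric(mean_rr) || mean_rr <= 200)
    stop("invalid synth_config field `mean_rr`: must be > 200 ms")
  if (is.null(rr_jitter_sd))
    rr_jitter_sd <- if (class_label == "MI") 60 else 25
  if (!is.numeric(rr_jitter_sd) || rr_jitter_sd < 0)
    stop("invalid synth_config field `rr_jitter_sd`: must be >= 0")
  if (is.null(st_offset))
    st_offset <- if (class_label == "MI") 0.15 else 0
  if (!is.numeric(st_offset))
    stop("invalid synth_config field `st_offset`: must be numeric")
  if (!is.null(t_polarity) && !(t_polarity %in% c(-1, 1)))
    stop("invalid synth_config field `t_polarity`: must be +1 or -1")
  defaults <- list(baseline_wander_amp = 0.05, baseline_wander_freq = 0.33,
                   powerline_amp = 0.02, powerline_freq = 50,
                   white_sd = 0.02)
  unknown <- setdiff(names(noise_levels), names(defaults))
  if (length(unknown))
    stop("invalid synth_config field `noise_levels`: unknown entries ",
         paste(unknown, collapse = ", "))
  defaults[names(noise_levels)] <- noise_levels
  bad <- vapply(defaults, function(v) !is.numeric(v) || v < 0, logical(1))
  if (any(bad))
    stop("invalid synth_config field `noise_levels`: ",
         paste(names(defaults)[bad], collapse = ", "), " must be >= 0")
  if (class_label == "MI" && !("white_sd" %in% names(noise_levels)))
    defaults$white_sd <- defaults$white_sd * 1.5
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("invalid synth_config field `seed`: must be a finite integer")
  structure(list(class_label = class_label, duration = duration,
                 sampling_rate = sampling_rate, mean_rr = mean_rr,
                 rr_jitter_sd = rr_jitter_sd, st_offset = st_offset,
                 t_polarity = t_polarity, noise_levels = defaults,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Beat template landmarks (ms relative to the R peak) and Gaussian bump
# parameters (amplitude mV, centre ms, width ms).
.beat_waves <- function(t_polarity) {
  list(P = c(amp = 0.12, mu = -180, sd = 22),
       Q = c(amp = -0.12, mu = -22, sd = 8),
       R = c(amp = 1.00, mu = 0, sd = 11),
       S = c(amp = -0.18, mu = 30, sd = 9),
       T = c(amp = 0.30 * t_polarity, mu = 300, sd = 55))
}

# ST plateau window (ms relative to R) over which the class offset is
# applied, with 20 ms cosine ramps at both edges.
.st_window_ms <- c(60, 220)

#' Generate one synthetic ECG record
#'
#' Deterministically (given the seed in `config`) synthesizes a Lead-II-like
#' record as a sum of per-beat Gaussian-bump P, Q, R, S and T waves placed by
#' a jittered RR process, a smooth class-dependent ST-segment offset between
#' QRS end and T onset, and additive baseline-wander, powerline and white
#' noise.
#'
#' @param config a [synth_config()].
#' @return object of class `ecg_record`: list with `samples` (mV),
#'   `sampling_rate`, `label`, `record_id`, `lead = "II"` and annotations
#'   `r_peaks` (sample indices) and `st_windows` (two-column matrix of ST
#'   window start/end indices), which tests use to audit class separation.
#' @export
generate_record <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  with_seed(config$seed, {
    tpol <- config$t_polarity
    if (is.null(tpol))
      tpol <- if (config$class_label == "MI" && runif(1) < 0.5) -1 else 1
    waves <- .beat_waves(tpol)
    # RR process (ms); truncated below so beats never overlap pathologically
    n_beats <- ceiling(config$duration * 1000 / config$mean_rr) + 3
    rr <- rnorm(n_beats, config$mean_rr, config$rr_jitter_sd)
    rr <- pmax(rr, 400)
    if (config$rr_jitter_sd == 0) rr[] <- config$mean_rr
    r_ms <- cumsum(c(400, rr))  # first R peak at 400 ms
    r_ms <- r_ms[r_ms < config$duration * 1000 + 400]
    t_ms <- (seq_len(n) - 1) / fs * 1000
    x <- numeric(n)
    st_windows <- NULL
    for (rm in r_ms) {
      lo <- max(1L, floor((rm - 400) / 1000 * fs) + 1L)
      hi <- min(n, ceiling((rm + 550) / 1000 * fs) + 1L)
      if (lo > hi) next
      tt <- t_ms[lo:hi] - rm
      seg <- numeric(hi - lo + 1L)
      for (w in waves)
        seg <- seg + w["amp"] * exp(-0.5 * ((tt - w["mu"]) / w["sd"])^2)
      if (config$st_offset != 0) {
        ramp <- 20
        w0 <- .st_window_ms[1]; w1 <- .st_window_ms[2]
        plateau <- ifelse(tt <= w0 - ramp | tt >= w1 + ramp, 0,
                   ifelse(tt >= w0 & tt <= w1, 1,
                   ifelse(tt < w0, 0.5 * (1 + cos(pi * (w0 - tt) / ramp)),
                                   0.5 * (1 + cos(pi * (tt - w1) / ramp)))))
        seg <- seg + config$st_offset * plateau
      }
      x[lo:hi] <- x[lo:hi] + seg
      w_idx <- round((rm + .st_window_ms) / 1000 * fs) + 1L
      if (w_idx[1] >= 1 && w_idx[2] <= n)
        st_windows <- rbind(st_windows, w_idx)
    }
    nl <- config$noise_levels
    tsec <- (seq_len(n) - 1) / fs
    if (nl$baseline_wander_amp > 0)
      x <- x + nl$baseline_wander_amp *
        sin(2 * pi * nl$baseline_wander_freq * tsec + runif(1, 0, 2 * pi))
    if (nl$powerline_amp > 0)
      x <- x + nl$powerline_amp *
        sin(2 * pi * nl$powerline_freq * tsec + runif(1, 0, 2 * pi))
    if (nl$white_sd > 0) x <- x + rnorm(n, 0, nl$white_sd)
    r_peaks <- round(r_ms / 1000 * fs) + 1L
    r_peaks <- r_peaks[r_peaks >= 1 & r_peaks <= n]
    structure(list(samples = x, sampling_rate = fs,
                   label = config$class_label,
                   record_id = sprintf("synth_%s_%d", config$class_label,
                                       config$seed),
                   lead = "II", r_peaks = r_peaks, st_windows = st_windows,
                   t_polarity = tpol),
              class = "ecg_record")
  })
}

#' Generate a labelled two-class synthetic dataset
#'
#' Per-record seeds are `seed + record index` (index over the concatenated
#' MI-then-healthy ordering), so any record can be regenerated independently.
#'
#' @param n_mi,n_healthy record counts (>= 0).
#' @param record_duration seconds per record.
#' @param seed master integer seed.
#' @param ... further arguments passed to [synth_config()] (applied to both
#'   classes).
#' @return list of `ecg_record` objects, MI records first.
#' @export
generate_dataset <- function(n_mi, n_healthy, record_duration, seed = 1L, ...) {
  if (n_mi < 0 || n_healthy < 0) stop("record counts must be >= 0")
  labels <- c(rep("MI", n_mi), rep("healthy", n_healthy))
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    cfg <- synth_config(class_label = labels[i], duration = record_duration,
                        seed = seed + i, ...)
    rec <- generate_record(cfg)
    rec$record_id <- sprintf("rec%03d_%s", i, labels[i])
    out[[i]] <- rec
  }
  out
}

#' Detect R peaks by thresholded local-maximum search
#'
#' Finds local maxima exceeding half the maximum amplitude, with a refractory
#' window of 200 ms.  Used by tests to audit the RR statistics of generated
#' records; the classification pipeline itself never uses beat annotations.
#'
#' @param record an `ecg_record` (or numeric vector, with `fs` given).
#' @param fs sampling rate, taken from the record if absent.
#' @return integer vector of peak sample indices.
#' @export
detect_rpeaks <- function(record, fs = NULL) {
  x <- if (inherits(record, "ecg_record")) record$samples else record
  if (is.null(fs)) fs <- record$sampling_rate
  n <- length(x)
  thr <- max(x) / 2
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  if (!length(cand)) return(integer(0))
  refr <- round(0.2 * fs)
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last > refr) { peaks <- c(peaks, i); last <- i }
    else if (x[i] > x[peaks[length(peaks)]]) { peaks[length(peaks)] <- i; last <- i }
  }
  peaks
}
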