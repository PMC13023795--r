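# The 23-measure entropy/complexity registry.  Each measure maps a numeric
# series to one scalar; multiscale families collapse to the mean over scales
# so every component contributes exactly one value per measure.  All
# hyperparameters live in entropy_params(); every measure runs on a
# length-capped prefix of the series (see `max_len`).

#' Hyperparameters for the entropy measures
#'
#' One configuration block for all 23 measures.  Defaults follow the
#' dominant conventions of the entropy literature: embedding dimension
#' `m = 2`, tolerance 0.2 * SD, lag `tau = 1`, 16 amplitude bins,
#' permutation order 3, 5 scales for the multiscale families, and
#' `alpha = q = 2` for the Renyi/Tsallis orders.
#'
#' @param m embedding dimension for template-matching measures.
#' @param r_frac tolerance as a fraction of the series SD.
#' @param tau embedding lag.
#' @param bins amplitude-histogram bins (Shannon/Renyi/Tsallis).
#' @param perm_order ordinal pattern order for permutation entropy.
#' @param scales number of scales for multiscale/enhanced/hierarchical
#'   entropies.
#' @param alpha Renyi order; `q` Tsallis order.
#' @param q Tsallis order.
#' @param cond_bins quantization levels for conditional and
#'   symbolic-dynamics entropies.
#' @param phase_sectors angular sectors for phase entropy.
#' @param dist_bins distance-histogram bins for distribution entropy.
#' @param grid_n grid resolution per axis for grid-distribution entropy.
#' @param incr_levels magnitude quantization levels for increment entropy.
#' @param eoe_window,eoe_bins window length and amplitude slices for
#'   entropy-of-entropy.
#' @param cse_r angular-distance threshold for cosine-similarity entropy.
#' @param max_len the costlier measures (sample, fuzzy, Kolmogorov-Sinai,
#'   the three multiscale families, cosine-similarity, distribution, hurst,
#'   permutation, entropy-of-entropy) are evaluated on the first `max_len`
#'   samples of the series; the remaining measures use the full series.
#'   ECG segments are stationary enough at this scale that the prefix is
#'   representative.
#' @return object of class `entropy_params`.
#' @export
entropy_params <- function(m = 2, r_frac = 0.2, tau = 1, bins = 16,
                           perm_order = 3, scales = 5, alpha = 2, q = 2,
                           cond_bins = 6, phase_sectors = 8, dist_bins = 512,
                           grid_n = 3, incr_levels = 4, eoe_window = 10,
                           eoe_bins = 10, cse_r = 0.1, max_len = 800) {
  stopifnot(m >= 1, r_frac > 0, tau >= 1, bins >= 2, perm_order >= 2,
            scales >= 1, alpha > 0, cond_bins >= 2, phase_sectors >= 2,
            dist_bins >= 2, grid_n >= 2, incr_levels >= 1, eoe_window >= 2,
            eoe_bins >= 2, cse_r > 0, max_len >= 16)
  structure(as.list(environment()), class = "entropy_params")
}

.shannon_of_p <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

.hist_probs <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("cannot bin a constant series (degenerate amplitude range)")
  b <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L, bins)
  tabulate(b, bins) / length(x)
}

.capped <- function(x, params) {
  if (length(x) > params$max_len) x[seq_len(params$max_len)] else x
}

#' Sample entropy (SampEn)
#'
#' `-ln(A/B)` where `B` (`A`) counts pairs of m- ((m+1)-)templates within
#' Chebyshev distance `r` (d <= r, self-matches excluded, both counted over
#' the first n-m template start points).
#'
#' @param x numeric series, length > m + 1.
#' @param m embedding dimension.
#' @param r tolerance; defaults to `0.2 * sd(x)`.
#' @return SampEn in nats; `NA` when no m-template pairs match (B = 0) or
#'   A = 0.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (length(x) <= m + 1) stop("series too short for sample entropy")
  cnt <- sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  if (cnt[["B"]] == 0 || cnt[["A"]] == 0) return(NA_real_)
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Permutation entropy
#'
#' Shannon entropy of ordinal-pattern frequencies in delay-embedded windows;
#' ties are broken by index order (stable argsort).  Normalized by
#' `log(order!)` so the value lies in \[0, 1\].
#'
#' @param x numeric series, length > order.
#' @param order pattern order (default 3).
#' @param tau embedding lag.
#' @param normalized divide by `log(order!)`.
#' @return permutation entropy.
#' @export
permutation_entropy <- function(x, order = 3, tau = 1, normalized = TRUE) {
  n <- length(x)
  if (n <= order) stop("series too short for permutation entropy")
  n_win <- n - (order - 1) * tau
  emb <- vapply(seq_len(order), function(k) x[(k - 1) * tau + seq_len(n_win)],
                numeric(n_win))
  # pattern id via pairwise comparisons with stable (index-order) ties
  pat <- integer(n_win)
  for (col in seq_len(order)) {
    rank_col <- rowSums(vapply(seq_len(order), function(other) {
      if (other == col) return(rep(FALSE, n_win))
      emb[, other] < emb[, col] | (emb[, other] == emb[, col] & other < col)
    }, logical(n_win)))
    pat <- pat * order + rank_col
  }
  p <- table(pat) / n_win
  h <- .shannon_of_p(as.numeric(p))
  if (normalized) h / log(factorial(order)) else h
}

#' Renyi entropy of the amplitude histogram
#'
#' `log(sum(p^alpha)) / (1 - alpha)` over an equal-width histogram of the
#' amplitudes; `alpha = 1` routes to the Shannon entropy of the same
#' histogram.
#'
#' @param x numeric series, length >= bins.
#' @param alpha Renyi order (> 0).
#' @param bins histogram bins.
#' @return Renyi entropy in nats.
#' @export
renyi_entropy <- function(x, alpha = 2, bins = 16) {
  if (length(x) < bins) stop("series shorter than the number of bins")
  if (alpha <= 0) stop("alpha must be > 0")
  p <- .hist_probs(x, bins)
  p <- p[p > 0]
  if (alpha == 1) return(.shannon_of_p(p))
  log(sum(p^alpha)) / (1 - alpha)
}

#' Tsallis entropy of the amplitude histogram
#'
#' `(1 - sum(p^q)) / (q - 1)`; `q = 1` routes to Shannon.
#'
#' @inheritParams renyi_entropy
#' @param q Tsallis order.
#' @return Tsallis entropy.
#' @export
tsallis_entropy <- function(x, q = 2, bins = 16) {
  if (length(x) < bins) stop("series shorter than the number of bins")
  p <- .hist_probs(x, bins)
  p <- p[p > 0]
  if (q == 1) return(.shannon_of_p(p))
  (1 - sum(p^q)) / (q - 1)
}

#' Fuzzy entropy
#'
#' Like SampEn but with baseline-removed templates and a smooth exponential
#' membership `exp(-d^2 / (2 r^2))` in place of the hard match indicator:
#' `FuzzyEn = ln(phi_m / phi_{m+1})`.
#'
#' @inheritParams sample_entropy
#' @return fuzzy entropy in nats.
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (length(x) <= m + 1) stop("series too short for fuzzy entropy")
  phi <- fuzzy_phi_cpp(as.numeric(x), as.integer(m), r)
  if (phi[["phi_m"]] <= 0 || phi[["phi_m1"]] <= 0) return(NA_real_)
  log(phi[["phi_m"]] / phi[["phi_m1"]])
}

# ---- remaining registry measures (internal workers) ----

.spectral_entropy <- function(x, params) {
  n <- length(x)
  nper <- min(1024L, n)
  step <- max(1L, floor(nper / 2))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  nf <- floor(nper / 2)
  psd <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(fft(seg))^2
    psd <- psd + sp[2:(nf + 1)]
  }
  tot <- sum(psd)
  if (tot <= 0) return(0)
  .shannon_of_p(psd / tot) / log(nf)
}

.wavelet_entropy <- function(x, params) {
  levels <- min(6L, floor(log2(length(x))) - 1L)
  if (levels < 1) return(NA_real_)
  dec <- dwt_multilevel(x, "db6", levels)
  e <- c(vapply(dec$details, function(d) sum(d^2), numeric(1)),
         sum(dec$approx^2))
  tot <- sum(e)
  if (tot <= 0) return(0)
  .shannon_of_p(e / tot)
}

.phase_entropy <- function(x, params) {
  # analytic signal via the FFT Hilbert construction
  n <- length(x)
  X <- fft(x - mean(x))
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  z <- fft(X * h, inverse = TRUE) / n
  ang <- Arg(z)
  sec <- pmin(floor((ang + pi) / (2 * pi) * params$phase_sectors) + 1L,
              params$phase_sectors)
  .shannon_of_p(tabulate(sec, params$phase_sectors) / n)
}

.hurst_rs <- function(x, params) {
  n <- length(x)
  if (n < 32) return(NA_real_)
  sizes <- unique(round(exp(seq(log(8), log(floor(n / 2)), length.out = 8))))
  sizes <- sizes[sizes >= 8]
  rs <- vapply(sizes, function(w) {
    k <- floor(n / w)
    vals <- vapply(seq_len(k), function(b) {
      seg <- x[((b - 1) * w + 1):(b * w)]
      z <- cumsum(seg - mean(seg))
      s <- sd(seg)
      if (s == 0) return(NA_real_)
      (max(z) - min(z)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2) return(NA_real_)
  unname(stats::lm.fit(cbind(1, log(sizes[ok])), log(rs[ok]))$coefficients[2])
}

.attention_entropy <- function(x, params) {
  ext <- .local_extrema(x)
  if (length(ext$max) < 2 || length(ext$min) < 2) return(NA_real_)
  key <- sort(c(ext$max, ext$min))
  is_max <- key %in% ext$max
  h_of <- function(iv) {
    if (!length(iv)) return(NA_real_)
    .shannon_of_p(as.numeric(table(iv)) / length(iv))
  }
  trans <- is_max[-length(is_max)] * 2 + is_max[-1]  # 0 min>min .. 3 max>max
  gaps <- diff(key)
  mean(c(h_of(diff(ext$max)), h_of(diff(ext$min)),
         h_of(gaps[trans == 2]), h_of(gaps[trans == 1])), na.rm = TRUE)
}

# Word codes and Shannon entropy over integer symbol sequences
# (symbols in 1..K); words of length `len` are base-K integer codes.
.word_codes <- function(sym, len, K) {
  n_words <- length(sym) - len + 1
  if (n_words < 1) return(integer(0))
  w <- sym[seq_len(n_words)] - 1L
  for (k in seq_len(len - 1)) w <- w * K + (sym[k + seq_len(n_words)] - 1L)
  w + 1L
}

.word_entropy <- function(sym, len, K = max(sym)) {
  w <- .word_codes(sym, len, K)
  if (!length(w)) return(NA_real_)
  .shannon_of_p(tabulate(w, K^len) / length(w))
}

.conditional_entropy <- function(x, params) {
  # Porta-style corrected conditional entropy at word length m+1
  rng <- range(x)
  if (rng[1] == rng[2]) return(NA_real_)
  sym <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * params$cond_bins) + 1L,
              params$cond_bins)
  K <- params$cond_bins
  L <- params$m + 1
  e_L <- .word_entropy(sym, L, K)
  e_Lm1 <- .word_entropy(sym, L - 1, K)
  e_1 <- .word_entropy(sym, 1, K)
  w <- .word_codes(sym, L, K)
  perc <- sum(tabulate(w, K^L) == 1) / length(w)
  e_L - e_Lm1 + perc * e_1
}

.symbolic_entropy <- function(x, params) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(NA_real_)
  sym <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * params$cond_bins) + 1L,
              params$cond_bins)
  .word_entropy(sym, 3, params$cond_bins)
}

.increment_entropy <- function(x, params) {
  d <- diff(x)
  if (!length(d)) return(NA_real_)
  s <- sign(d)
  sdd <- sd(d)
  R <- params$incr_levels
  q <- if (sdd == 0) rep(0L, length(d))
       else pmin(R, floor(abs(d) / sdd * R))
  sym <- as.integer((s + 1) * (R + 1) + q + 1)  # (sign, magnitude) pairs
  m <- 2
  .word_entropy(sym, m, 3L * (R + 1L)) / (m - 1)
}

.slope_entropy <- function(x, params) {
  d <- diff(x)
  if (!length(d)) return(NA_real_)
  gam <- sd(d)
  if (gam == 0) return(0)
  del <- 1e-3 * gam
  sym <- ifelse(d > gam, 2L, ifelse(d > del, 1L,
          ifelse(d >= -del, 0L, ifelse(d >= -gam, -1L, -2L)))) + 3L
  .word_entropy(sym, 2, 5L)
}

.grid_entropy <- function(x, params) {
  n <- length(x)
  tau <- params$tau
  a <- x[seq_len(n - tau)]; b <- x[seq_len(n - tau) + tau]
  rng <- range(x)
  if (rng[1] == rng[2]) return(NA_real_)
  g <- params$grid_n
  ia <- pmin(floor((a - rng[1]) / (rng[2] - rng[1]) * g) + 1L, g)
  ib <- pmin(floor((b - rng[1]) / (rng[2] - rng[1]) * g) + 1L, g)
  .shannon_of_p(tabulate((ia - 1L) * g + ib, g * g) / length(a))
}

.entropy_of_entropy <- function(x, params) {
  w <- params$eoe_window
  k <- floor(length(x) / w)
  if (k < 2) return(NA_real_)
  rng <- range(x)
  if (rng[1] == rng[2]) return(NA_real_)
  bins <- params$eoe_bins
  slice <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L, bins)
  ent <- vapply(seq_len(k), function(b) {
    .shannon_of_p(tabulate(slice[((b - 1) * w + 1):(b * w)], bins) / w)
  }, numeric(1))
  .shannon_of_p(as.numeric(table(round(ent, 10))) / k)
}

.distribution_entropy <- function(x, params) {
  p <- cheb_dist_probs_cpp(as.numeric(x), as.integer(params$m),
                           as.integer(params$dist_bins))
  .shannon_of_p(p) / log(params$dist_bins)
}

.cosine_similarity_entropy <- function(x, params) {
  x <- x - median(x)
  p <- cosine_match_p_cpp(as.numeric(x), as.integer(params$m),
                          as.integer(params$tau), params$cse_r)
  if (p <= 0 || p >= 1) return(0)
  -(p * log2(p) + (1 - p) * log2(1 - p))
}

.k2_entropy <- function(x, params, r) {
  cs <- corr_sums_cpp(as.numeric(x), as.integer(params$m), r)
  if (cs[["C_m"]] <= 0 || cs[["C_m1"]] <= 0) return(NA_real_)
  log(cs[["C_m"]] / cs[["C_m1"]])
}

# Coarse-grained (non-overlapping mean), moving-average, and hierarchical
# (pairwise-average chain) rescalings used by the multiscale families.
.coarse_grain <- function(x, s) {
  k <- floor(length(x) / s)
  if (k < 1) return(numeric(0))
  colMeans(matrix(x[seq_len(k * s)], nrow = s))
}
.moving_average <- function(x, s) {
  if (s == 1) return(x)
  as.numeric(stats::filter(x, rep(1 / s, s), sides = 1))[-seq_len(s - 1)]
}
.hier_chain <- function(x, s) {
  for (i in seq_len(s - 1)) {
    n2 <- floor(length(x) / 2) * 2
    x <- (x[seq(1, n2, by = 2)] + x[seq(2, n2, by = 2)]) / 2
  }
  x
}

.multiscale_family <- function(x, params, rescale) {
  r <- params$r_frac * sd(x)
  vals <- vapply(seq_len(params$scales), function(s) {
    y <- rescale(x, s)
    if (length(y) <= params$m + 1) return(NA_real_)
    cnt <- sampen_counts_cpp(as.numeric(y), as.integer(params$m), r)
    if (cnt[["B"]] == 0 || cnt[["A"]] == 0) return(NA_real_)
    -log(cnt[["A"]] / cnt[["B"]])
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' The entropy measure registry
#'
#' The ordered collection of the 23 entropy/complexity measures computed for
#' every signal component.  Names double as feature-name suffixes (e.g.
#' `imf2_renyi`, `d2_hurst`).  `shannon` (16-bin amplitude-histogram Shannon
#' entropy) is the 23rd measure completing the 7 + 23 = 30 features per
#' component; the registry is order-stable so an alternative can be swapped
#' in via configuration.
#'
#' @return character vector of the 23 measure names, in registry order.
#' @export
entropy_registry <- function() {
  reg <- c("attention", "conditional", "cosine_similarity", "distribution",
           "entropy_of_entropy", "grid_distribution", "increment", "phase",
           "slope", "spectral", "symbolic_dynamics", "tsallis", "renyi",
           "wavelet", "hurst", "fuzzy", "hierarchical_multiscale",
           "kolmogorov_sinai", "multiscale", "permutation",
           "enhanced_multiscale", "sample", "shannon")
  if (anyDuplicated(reg)) stop("entropy registry contains duplicate names")
  reg
}

#' Compute one registry measure
#'
#' Single dispatch for all 23 measures.  Quadratic-cost measures are
#' evaluated on the first `params$max_len` samples.
#'
#' @param name a name from [entropy_registry()].
#' @param x numeric series.
#' @param params an [entropy_params()].
#' @return scalar measure value (`NA` on measure-specific degeneracy).
#' @export
compute_measure <- function(name, x, params = entropy_params()) {
  x <- as.numeric(x)
  xc <- .capped(x, params)
  r <- params$r_frac * sd(xc)
  switch(name,
    attention = .attention_entropy(x, params),
    conditional = .conditional_entropy(x, params),
    cosine_similarity = .cosine_similarity_entropy(xc, params),
    distribution = .distribution_entropy(xc, params),
    entropy_of_entropy = .entropy_of_entropy(xc, params),
    grid_distribution = .grid_entropy(x, params),
    increment = .increment_entropy(x, params),
    phase = .phase_entropy(x, params),
    slope = .slope_entropy(x, params),
    spectral = .spectral_entropy(x, params),
    symbolic_dynamics = .symbolic_entropy(x, params),
    tsallis = tsallis_entropy(x, q = params$q, bins = params$bins),
    renyi = renyi_entropy(x, alpha = params$alpha, bins = params$bins),
    wavelet = .wavelet_entropy(x, params),
    hurst = .hurst_rs(xc, params),
    fuzzy = fuzzy_entropy(xc, m = params$m, r = r),
    hierarchical_multiscale = .multiscale_family(xc, params, .hier_chain),
    kolmogorov_sinai = .k2_entropy(xc, params, r),
    multiscale = .multiscale_family(xc, params, .coarse_grain),
    permutation = permutation_entropy(xc, order = params$perm_order,
                                      tau = params$tau),
    enhanced_multiscale = .multiscale_family(xc, params, .moving_average),
    sample = sample_entropy(xc, m = params$m, r = r),
    shannon = .shannon_of_p(.hist_probs(x, params$bins)),
    stop("unknown entropy measure `", name, "`"))
}
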