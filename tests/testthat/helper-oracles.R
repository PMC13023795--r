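# Brute-force reference implementations used as independent oracles for the
# entropy measures, plus small fixture builders.  The oracles are written as
# literal double loops over the definitions and share nothing with the
# package's vectorized/compiled code paths.

sampen_counts_bf <- function(x, m, r) {
  n <- length(x)
  N <- n - m
  A <- 0; B <- 0
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  c(B = B, A = A)
}

sampen_bf <- function(x, m, r) {
  cnt <- sampen_counts_bf(x, m, r)
  # same missing-value convention as the package: undefined when either
  # count is zero
  if (cnt[["B"]] == 0 || cnt[["A"]] == 0) return(NA_real_)
  -log(cnt[["A"]] / cnt[["B"]])
}

fuzzyen_bf <- function(x, m, r) {
  n <- length(x)
  N <- n - m
  phi <- function(mm) {
    tot <- 0; cnt <- 0
    for (i in 1:(N - 1)) {
      for (j in (i + 1):N) {
        ti <- x[i:(i + mm - 1)]; tj <- x[j:(j + mm - 1)]
        d <- max(abs((ti - mean(ti)) - (tj - mean(tj))))
        tot <- tot + exp(-d^2 / (2 * r^2))
        cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  log(phi(m) / phi(m + 1))
}

perment_bf <- function(x, order = 3, tau = 1, normalized = TRUE) {
  n_win <- length(x) - (order - 1) * tau
  pats <- character(n_win)
  for (w in seq_len(n_win)) {
    v <- x[w + (seq_len(order) - 1) * tau]
    ranks <- integer(order)
    for (col in seq_len(order)) {
      ranks[col] <- sum(v < v[col]) +
        sum(v[seq_len(order) < col] == v[col])
    }
    pats[w] <- paste(ranks, collapse = "-")
  }
  p <- as.numeric(table(pats)) / n_win
  h <- -sum(p * log(p))
  if (normalized) h / log(factorial(order)) else h
}

hist_probs_bf <- function(x, bins) {
  rng <- range(x)
  counts <- integer(bins)
  for (v in x) {
    b <- min(floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1, bins)
    counts[b] <- counts[b] + 1
  }
  counts / length(x)
}

renyi_bf <- function(x, alpha, bins) {
  p <- hist_probs_bf(x, bins)
  p <- p[p > 0]
  log(sum(p^alpha)) / (1 - alpha)
}

tsallis_bf <- function(x, q, bins) {
  p <- hist_probs_bf(x, bins)
  p <- p[p > 0]
  (1 - sum(p^q)) / (q - 1)
}

disten_bf <- function(x, m, bins) {
  N <- length(x) - m + 1
  d <- c()
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      d <- c(d, max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])))
    }
  }
  dmax <- max(d)
  counts <- integer(bins)
  for (v in d) {
    b <- min(floor(v / dmax * bins) + 1, bins)
    counts[b] <- counts[b] + 1
  }
  p <- counts / length(d)
  p <- p[p > 0]
  -sum(p * log(p)) / log(bins)
}

incren_bf <- function(x, R = 4) {
  d <- diff(x)
  s <- sign(d)
  sdd <- sd(d)
  q <- pmin(R, floor(abs(d) / sdd * R))
  sym <- paste(s, q, sep = ":")
  words <- paste(sym[-length(sym)], sym[-1], sep = "|")
  p <- as.numeric(table(words)) / length(words)
  -sum(p * log(p))
}

# quiet ECG-like fixture: one preprocessed 10,000-sample segment
ecg_fixture_segment <- function(label = "MI", seed = 3) {
  rec <- generate_record(synth_config(label, duration = 10, seed = seed))
  preprocess(list(rec))[[1]]
}

dominant_freq <- function(x, fs = 1000) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  (which.max(sp[2:floor(n / 2)])) * fs / n
}
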