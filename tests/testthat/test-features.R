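# Time-domain statistics, the 23-measure registry, oracle equivalence and
# the feature-vector assembly arithmetic.

test_that("time-domain statistics match their definitions", {
  expect_equal(time_domain_features(rep(2, 5)),
               c(min = 2, max = 2, mean = 2, variance = 0, rms = 2,
                 skewness = 0, kurtosis = 0))
  f <- time_domain_features(c(1, 2, 3, 4))
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["variance"]], 5 / 3)
  expect_equal(f[["rms"]], sqrt(30 / 4))
  expect_equal(f[["min"]], 1)
  expect_equal(f[["max"]], 4)
  # symmetric series: odd central moment vanishes
  x <- c(-3, -1, 0, 1, 3)
  expect_lt(abs(time_domain_features(x)[["skewness"]]), 1e-12)
  # normal kurtosis is non-excess (about 3)
  set.seed(2)
  expect_lt(abs(time_domain_features(rnorm(2e4))[["kurtosis"]] - 3), 0.15)
  expect_error(time_domain_features(1), "at least 2")
})

test_that("the registry holds 23 uniquely named measures, all finite on ECG", {
  reg <- entropy_registry()
  expect_length(reg, 23)
  expect_false(anyDuplicated(reg) > 0)
  expect_true(all(grepl("^[a-z][a-z_]*$", reg)))
  seg <- ecg_fixture_segment(seed = 31)
  vals <- vapply(reg, compute_measure, numeric(1), x = seg$samples)
  expect_true(all(is.finite(vals)))
  expect_error(compute_measure("not_a_measure", seg$samples), "unknown")
})

test_that("sample entropy matches the brute-force template count oracle", {
  set.seed(41)
  for (n in c(50, 120)) {
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    cnt <- ecgmi:::sampen_counts_cpp(x, 2L, r)
    bf <- sampen_counts_bf(x, 2, r)
    expect_identical(unname(cnt), unname(as.numeric(bf)))
    expect_equal(sample_entropy(x, 2, r), sampen_bf(x, 2, r), tolerance = 1e-12)
  }
  # irregular noise scores above a regular tone
  set.seed(42)
  noise <- runif(1000)
  tone <- sin(2 * pi * 10 * seq_len(1000) / 1000)
  expect_gt(sample_entropy(noise), sample_entropy(tone))
  # constant series: every template matches, SampEn is 0
  expect_equal(sample_entropy(rep(1, 50)), 0)
})

test_that("permutation entropy matches the ordinal-pattern census oracle", {
  expect_equal(permutation_entropy(1:50), 0)
  set.seed(43)
  for (i in 1:5) {
    x <- rnorm(20)
    expect_equal(permutation_entropy(x), perment_bf(x), tolerance = 1e-12)
  }
  # a sequence whose 18 windows realize all 3! patterns equally often
  # (verified against the census oracle) -> normalized entropy exactly 1
  u <- c(32, 7, 3, 22, 22, 7, 13, 26, 13, 50, 46, 48, 45, 33, 48, 49, 7,
         43, 10, 7)
  expect_equal(perment_bf(u), 1, tolerance = 1e-12)
  expect_equal(permutation_entropy(u), 1, tolerance = 1e-12)
})

test_that("Renyi and Tsallis match direct summation and closed forms", {
  set.seed(44)
  x <- rnorm(300)
  expect_equal(renyi_entropy(x, 2, 16), renyi_bf(x, 2, 16), tolerance = 1e-12)
  expect_equal(tsallis_entropy(x, 2, 16), tsallis_bf(x, 2, 16),
               tolerance = 1e-12)
  # exactly uniform occupancy over 16 bins
  u <- rep(seq(0.5, 15.5), times = 4) / 16
  expect_equal(renyi_entropy(u, 2, 16), log(16), tolerance = 1e-12)
  expect_equal(tsallis_entropy(u, 2, 16), 1 - 1 / 16, tolerance = 1e-12)
  # alpha -> 1 recovers Shannon
  sh <- renyi_entropy(x, 1, 16)
  expect_equal(renyi_entropy(x, 1 + 1e-4, 16), sh, tolerance = 1e-3)
  expect_equal(renyi_entropy(x, 1 - 1e-4, 16), sh, tolerance = 1e-3)
  expect_error(renyi_entropy(x[1:10], 2, 16), "bins")
  expect_error(renyi_entropy(rep(1, 50), 2, 16), "constant")
})

test_that("fuzzy, distribution and increment entropies match their oracles", {
  set.seed(45)
  x <- rnorm(40)
  r <- 0.2 * sd(x)
  expect_equal(fuzzy_entropy(x, 2, r), fuzzyen_bf(x, 2, r), tolerance = 1e-12)
  y <- rnorm(60)
  p <- entropy_params()
  expect_equal(compute_measure("distribution", y, p),
               disten_bf(y, p$m, p$dist_bins), tolerance = 1e-12)
  expect_equal(compute_measure("increment", y, p),
               incren_bf(y, p$incr_levels), tolerance = 1e-12)
})

test_that("spectral entropy separates tones from broadband noise", {
  fs <- 1000
  tone <- sin(2 * pi * 10 * seq(0, 4, by = 1 / fs))
  set.seed(46)
  noise <- rnorm(4001)
  expect_lte(compute_measure("spectral", tone), 0.2)
  expect_gte(compute_measure("spectral", noise), 0.9)
  expect_gt(compute_measure("spectral", noise),
            compute_measure("spectral", tone))
})

test_that("the Hurst exponent of a linear trend approaches 1", {
  h <- compute_measure("hurst", seq(0, 1, length.out = 600))
  expect_lt(abs(h - 1), 0.1)
})

test_that("amplitude-scale behaviour of the statistics and entropies", {
  set.seed(47)
  x <- rnorm(300)
  a <- 3.7; b <- -1.2
  y <- a * x + b
  fx <- time_domain_features(x); fy <- time_domain_features(y)
  expect_equal(fy[["mean"]], a * fx[["mean"]] + b, tolerance = 1e-9)
  expect_equal(fy[["variance"]], a^2 * fx[["variance"]], tolerance = 1e-9)
  expect_equal(fy[["skewness"]], fx[["skewness"]], tolerance = 1e-9)
  expect_equal(fy[["kurtosis"]], fx[["kurtosis"]], tolerance = 1e-9)
  expect_equal(permutation_entropy(y), permutation_entropy(x),
               tolerance = 1e-9)
  expect_equal(sample_entropy(y, 2, 0.2 * sd(y)),
               sample_entropy(x, 2, 0.2 * sd(x)), tolerance = 1e-9)
  expect_equal(fuzzy_entropy(y, 2, 0.2 * sd(y)),
               fuzzy_entropy(x, 2, 0.2 * sd(x)), tolerance = 1e-9)
})

test_that("feature vectors count 30 per component and name deterministically", {
  seg <- ecg_fixture_segment(seed = 51)
  cs <- build_component_set(seg)
  fv <- extract_features(cs)
  expect_length(fv, 390)
  expect_identical(names(fv), feature_names())
  expect_equal(attr(fv, "n_missing"), 0)
  expect_length(feature_names("orj"), 30)
  expect_length(feature_names(c(paste0("d", 1:6), "a6")), 210)
  expect_length(feature_names(paste0("imf", 1:5)), 150)
  expect_true(all(c("imf2_renyi", "d2_hurst", "orj_permutation",
                    "d1_rms", "imf1_kurtosis") %in% names(fv)))
  # subsets of the component set yield the matching feature counts
  fv_dwt <- extract_features(cs[c(paste0("d", 1:6), "a6")])
  expect_length(fv_dwt, 210)
  fv_imf <- extract_features(cs[paste0("imf", 1:5)])
  expect_length(fv_imf, 150)
  expect_error(extract_features(list()), "empty")
})

test_that("absent components yield missing features, never short vectors", {
  t <- seq(0, 9.999, by = 1e-3)
  cs <- build_component_set(0.5 + 0.4 * sin(2 * pi * 10 * t))
  fv <- extract_features(cs)
  expect_length(fv, 390)
  ab <- attr(cs, "absent")
  expect_equal(attr(fv, "n_missing"), 30 * length(ab))
  expect_true(all(is.na(fv[grepl(paste0("^", ab[1], "_"), names(fv))])))
})

test_that("sample entropy of the raw segment separates the classes", {
  vals <- list()
  for (label in c("MI", "healthy")) {
    recs <- generate_dataset(if (label == "MI") 10 else 0,
                             if (label == "MI") 0 else 10,
                             100, seed = if (label == "MI") 500 else 900)
    segs <- preprocess(recs)
    vals[[label]] <- vapply(segs, function(s) {
      compute_measure("sample", s$samples)
    }, numeric(1))
  }
  expect_length(vals$MI, 100)
  pv <- wilcox.test(vals$MI, vals$healthy)$p.value
  expect_lt(pv, 0.01)
})
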