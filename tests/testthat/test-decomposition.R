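# DWT band structure, orthonormality and invertibility; EMD sifting
# behaviour; assembly of the 13-component set.

test_that("DWT yields the seven named coefficient bands", {
  seg <- ecg_fixture_segment()
  comps <- dwt_components(seg)
  expect_named(comps, c(paste0("d", 1:6), "a6"))
  z <- dwt_components(numeric(10000))
  expect_true(all(vapply(z, function(v) all(v == 0), logical(1))))
  expect_error(dwt_multilevel(rnorm(32), levels = 6), "too short")
})

test_that("periodized DWT conserves energy and inverts exactly", {
  set.seed(21)
  x <- rnorm(6400)  # divisible by 2^6: transform is orthonormal
  dec <- dwt_multilevel(x)
  energy <- sum(vapply(dec$details, function(d) sum(d^2), numeric(1))) +
    sum(dec$approx^2)
  expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-9)
  expect_lt(max(abs(idwt_multilevel(dec) - x)) / max(abs(x)), 1e-8)
  # odd lengths appear at deeper levels of a 10,000-sample segment:
  # invertibility must still be exact
  y <- rnorm(10000)
  dy <- dwt_multilevel(y)
  expect_lt(max(abs(idwt_multilevel(dy) - y)) / max(abs(y)), 1e-8)
  expect_equal(vapply(dy$details, length, integer(1)),
               c(d1 = 5000L, d2 = 2500L, d3 = 1250L, d4 = 625L, d5 = 313L,
                 d6 = 157L))
})

test_that("EMD handles monotone input and isolates a clean tone", {
  ramp <- as.numeric(1:100)
  ed <- emd_decompose(ramp)
  expect_equal(ed$n_imfs, 0)
  expect_identical(ed$residue, ramp)

  t <- seq(0, 2, by = 1e-3)
  s <- sin(2 * pi * 10 * t)
  es <- emd_decompose(s)
  expect_gte(es$n_imfs, 1)
  expect_gt(cor(es$imfs[[1]], s), 0.99)
  total <- Reduce(`+`, es$imfs) + es$residue
  expect_lt(max(abs(total - s)), 1e-9 * max(abs(s)))
})

test_that("EMD is additive and accepted IMFs satisfy the count condition", {
  seg <- ecg_fixture_segment(seed = 13)
  ed <- emd_decompose(seg)
  expect_equal(ed$n_imfs, 5)
  total <- Reduce(`+`, ed$imfs) + ed$residue
  expect_lt(max(abs(total - seg$samples)), 1e-9 * max(abs(seg$samples)))
  for (imf in ed$imfs) {
    ext <- ecgmi:::.local_extrema(imf)
    n_ext <- length(ext$max) + length(ext$min)
    zc <- ecgmi:::.zero_crossings(imf)
    expect_lte(abs(zc - n_ext), 1)
  }
})

test_that("IMF dominant frequencies are non-increasing for a multi-tone input", {
  t <- seq(0, 4, by = 1e-3)
  x <- sin(2 * pi * 200 * t) + sin(2 * pi * 40 * t) + sin(2 * pi * 8 * t)
  ed <- emd_decompose(x)
  expect_gte(ed$n_imfs, 3)
  freqs <- vapply(ed$imfs, dominant_freq, numeric(1))
  expect_true(all(diff(freqs) <= 0))
})

test_that("the component set has 13 canonically named members", {
  seg <- ecg_fixture_segment(seed = 23)
  cs <- build_component_set(seg)
  expect_length(cs, 13)
  expect_identical(sort(names(cs)),
                   c("a6", paste0("d", 1:6), paste0("imf", 1:5), "orj"))
  expect_identical(names(cs), component_names())
  expect_identical(cs$orj, seg$samples)
  expect_length(attr(cs, "absent"), 0)
  expect_equal(attr(cs, "segment")$label, "MI")
})

test_that("components for unproduced IMFs are flagged absent", {
  t <- seq(0, 9.999, by = 1e-3)
  tone <- 0.5 + 0.4 * sin(2 * pi * 10 * t)  # clean tone: few IMFs
  cs <- build_component_set(tone)
  ab <- attr(cs, "absent")
  expect_gt(length(ab), 0)
  expect_true(all(grepl("^imf", ab)))
  expect_true(all(vapply(cs[ab], is.null, logical(1))))
  expect_length(cs, 13)
})
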