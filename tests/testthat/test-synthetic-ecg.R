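test_that("generation is deterministic given the seed", {
  cfg <- synth_config("MI", duration = 12, seed = 101)
  r1 <- generate_record(cfg)
  r2 <- generate_record(cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$t_polarity, r2$t_polarity)
  r3 <- generate_record(synth_config("MI", duration = 12, seed = 102))
  expect_false(identical(r1$samples, r3$samples))
})

test_that("noise-free jitter-free records are exactly periodic", {
  cfg <- synth_config("healthy", duration = 20, seed = 1, rr_jitter_sd = 0,
                      st_offset = 0,
                      noise_levels = list(baseline_wander_amp = 0,
                                          powerline_amp = 0, white_sd = 0))
  rec <- generate_record(cfg)
  peaks <- detect_rpeaks(rec)
  expect_gt(length(peaks), 10)
  expect_true(all(diff(peaks) == round(850 * 1000 / 1000)))
})

test_that("detected RR intervals track the configured mean", {
  rec <- generate_record(synth_config("healthy", duration = 60, seed = 7))
  peaks <- detect_rpeaks(rec)
  mean_rr <- mean(diff(peaks))  # samples == ms at 1000 Hz
  expect_lt(abs(mean_rr - 850) / 850, 0.02)
})

test_that("dataset generation honours counts, labels and per-record seeds", {
  expect_length(generate_dataset(0, 0, 10, seed = 1), 0)
  ds <- generate_dataset(5, 3, 10, seed = 1)
  expect_length(ds, 8)
  expect_equal(sum(vapply(ds, function(r) r$label, character(1)) == "MI"), 5)
  expect_length(unique(vapply(ds, function(r) r$record_id, character(1))), 8)
  # record i is reproducible in isolation from seed + i
  again <- generate_record(synth_config("MI", duration = 10, seed = 1 + 2))
  expect_identical(ds[[2]]$samples, again$samples)
})

test_that("ST-window means separate the classes by the configured offset", {
  # fixed T polarity isolates the ST offset; averaging over records washes
  # out the random baseline-wander phase
  st_mean <- function(label) {
    mean(vapply(1:10, function(s) {
      rec <- generate_record(synth_config(label, duration = 60, seed = s,
                                          t_polarity = 1))
      mean(vapply(seq_len(nrow(rec$st_windows)), function(i) {
        mean(rec$samples[rec$st_windows[i, 1]:rec$st_windows[i, 2]])
      }, numeric(1)))
    }, numeric(1)))
  }
  gap <- st_mean("MI") - st_mean("healthy")
  expect_lt(abs(gap - 0.15), 0.015)  # within 10% of st_offset
})

test_that("amplitudes stay within the template + noise bound", {
  for (label in c("healthy", "MI")) {
    cfg <- synth_config(label, duration = 30, seed = 17)
    rec <- generate_record(cfg)
    nl <- cfg$noise_levels
    bound <- 1.72 + abs(cfg$st_offset) + 6 * nl$white_sd +
      nl$baseline_wander_amp + nl$powerline_amp
    expect_lte(max(abs(rec$samples)), bound)
  }
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(synth_config("healthy", duration = 0), "duration")
  expect_error(synth_config("healthy", sampling_rate = -1), "sampling_rate")
  expect_error(synth_config("healthy", mean_rr = 100), "mean_rr")
  expect_error(synth_config("healthy", rr_jitter_sd = -2), "rr_jitter_sd")
  expect_error(synth_config("healthy", noise_levels = list(bogus = 1)),
               "noise_levels")
  expect_error(synth_config("healthy", noise_levels = list(white_sd = -1)),
               "white_sd")
})

test_that("MI defaults raise jitter, ST offset and white-noise SD", {
  h <- synth_config("healthy")
  m <- synth_config("MI")
  expect_equal(h$rr_jitter_sd, 25)
  expect_equal(m$rr_jitter_sd, 60)
  expect_equal(h$st_offset, 0)
  expect_equal(m$st_offset, 0.15)
  expect_equal(m$noise_levels$white_sd, 1.5 * h$noise_levels$white_sd)
  expect_equal(m$noise_levels$powerline_freq, 50)
})
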