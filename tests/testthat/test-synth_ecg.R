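test_that("noise-free generation returns the clean template train", {
  rec <- generate_record(quiet_config())
  expect_identical(rec$samples, rec$clean_samples)
  expect_length(rec$beat_labels, length(rec$r_peaks))
  expect_true(all(diff(rec$r_peaks) > 0))
  expect_true(all(rec$r_peaks >= 0 & rec$r_peaks < length(rec$samples)))
})

test_that("generation is seed-deterministic", {
  cfg <- bench_config(seed = 7)
  expect_identical(generate_record(cfg), generate_record(cfg))
  cfg2 <- bench_config(seed = 8)
  expect_false(identical(generate_record(cfg), generate_record(cfg2)))
})

test_that("60 bpm with zero jitter gives exactly one-second beat spacing", {
  cfg <- synth_config(heart_rate_bpm = 60, hr_jitter = 0, n_beats = 10,
                      sampling_rate = 360, seed = 1)
  rec <- generate_record(cfg)
  expect_true(all(diff(rec$r_peaks) == 360L))
})

test_that("stored R-peaks coincide with the dominant deflection", {
  rec <- generate_record(bench_config(seed = 21))
  tol <- round(0.05 * rec$sampling_rate)
  hits <- vapply(rec$r_peaks, function(p) {
    win <- max(1, p + 1 - tol):min(length(rec$samples), p + 1 + tol)
    peak_at <- win[which.max(abs(rec$clean_samples[win]))] - 1L
    abs(peak_at - p) <= 2
  }, logical(1))
  expect_true(mean(hits) > 0.95)
})

test_that("injected noise power matches the configuration", {
  cfg <- synth_config(n_beats = 120, baseline_amp = 0.15, powerline_amp = 0.05,
                      broadband_sigma = 0.05, seed = 9)
  rec <- generate_record(cfg)
  noise <- rec$samples - rec$clean_samples
  expected <- cfg$baseline_amp^2 / 2 + cfg$powerline_amp^2 / 2 +
    cfg$broadband_sigma^2
  expect_lt(abs(mean(noise^2) - expected) / expected, 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(sampling_rate = 0), "positive")
  expect_error(synth_config(n_beats = 0), "n_beats")
  expect_error(synth_config(hr_jitter = 0.6), "jitter")
  expect_error(synth_config(broadband_sigma = -1), "non-negative")
  expect_error(generate_dataset(bench_config(), 0), "n_records")
})

test_that("dataset records are distinct but reproducible, with the requested class mix", {
  cfg <- synth_config(n_beats = 2000, seed = 5,
                      class_probs = c(0.85, 0.03, 0.07, 0.01, 0.04))
  ds <- generate_dataset(cfg, 5)
  expect_length(ds, 5)
  expect_false(identical(ds[[1]]$samples, ds[[2]]$samples))
  expect_identical(generate_dataset(cfg, 5)[[3]], ds[[3]])
  labs <- unlist(lapply(ds, `[[`, "beat_labels"))
  expect_length(labs, 10000L)
  prop <- as.numeric(table(factor(labs, cfg$class_labels))) / length(labs)
  expect_true(all(abs(prop - cfg$class_probs) <= 0.01))
})

test_that("class morphologies are separable by a nearest-centroid rule", {
  rec <- generate_record(synth_config(n_beats = 150, seed = 13))
  # condition the lead the way the pipeline does before classification
  rec$samples <- remove_baseline(wavelet_denoise(rec$samples),
                                 rec$sampling_rate)
  samples <- build_samples(rec, "fixed")
  beats <- t(vapply(samples, `[[`, numeric(288), "single_cycle"))
  labs <- vapply(samples, `[[`, character(1), "label")
  centroids <- vapply(sort(unique(labs)),
                      function(cl) colMeans(beats[labs == cl, , drop = FALSE]),
                      numeric(288))
  pred <- colnames(centroids)[apply(beats, 1, function(b) {
    which.min(colSums((centroids - b)^2))
  })]
  expect_gt(mean(pred == labs), 0.9)
})
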