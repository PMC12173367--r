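# Shared fixtures: small seeded synthetic configurations used across the
# suite. The benchmark configuration mirrors the generator defaults
# (360 Hz, five beat classes, moderate noise).

bench_config <- function(n_beats = 40, seed = 7, ...) {
  synth_config(n_beats = n_beats, seed = seed, ...)
}

quiet_config <- function(n_beats = 20, seed = 3) {
  synth_config(n_beats = n_beats, baseline_amp = 0, powerline_amp = 0,
               broadband_sigma = 0, seed = seed)
}

# Dual-scale samples + spectrogram arrays for a small balanced dataset.
make_spec_data <- function(n_records = 3, n_beats = 25, seed = 1,
                           test_fraction = 0.2) {
  recs <- generate_dataset(synth_config(n_beats = n_beats, seed = seed),
                           n_records)
  samples <- list()
  for (r in recs) samples <- c(samples, build_samples(r, "fixed"))
  classes <- c("F", "N", "Q", "S", "V")
  sp <- stratified_split(samples, test_fraction, seed = seed + 1)
  list(train = samples_to_spectrograms(sp$train, 360, classes),
       test = samples_to_spectrograms(sp$test, 360, classes),
       classes = classes)
}

# tiny architecture for gradient and shape checks
tiny_meta <- function(branches = "both", use_se = TRUE) {
  ecgbeatnet:::micnn_meta(dim_a = c(6, 8), dim_b = c(6, 12), n_classes = 3,
                          filters = c(2, 4, 8, 16), kernel_sizes = c(3, 5),
                          se_reduction = 2, fc_hidden = 5,
                          branches = branches, use_se = use_se)
}
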