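test_that("WFDB round-trip preserves samples, peaks and labels", {
  dir <- withr::local_tempdir()
  rec <- generate_record(bench_config(n_beats = 15, seed = 2))
  for (fmt in c(212, 16)) {
    id <- paste0("rt", fmt)
    write_wfdb(rec, dir, id, fmt = fmt, gain = 200)
    spec <- dataset_spec(dir, "wfdb", lead_name = "MLII")
    got <- load_record(spec, id)
    # samples agree to ADC precision (half a quantization step)
    expect_lt(max(abs(got$samples - rec$samples)), 0.5 / 200 + 1e-12)
    expect_identical(got$r_peaks, rec$r_peaks)
    expect_identical(got$beat_labels, rec$beat_labels)
  }
})

test_that("annotation SKIP intervals survive long inter-beat gaps", {
  dir <- withr::local_tempdir()
  rec <- ecg_record(rnorm(20000), 360,
                    r_peaks = c(5L, 2000L, 15000L, 19000L),
                    beat_labels = c("N", "V", "/", "F"))
  write_wfdb(rec, dir, "gap")
  spec <- dataset_spec(dir, "wfdb")
  got <- load_record(spec, "gap")
  expect_identical(got$r_peaks, rec$r_peaks)
  expect_identical(got$beat_labels, c("N", "V", "Q", "F"))  # "/" maps to Q
})

test_that("unmapped annotation symbols are dropped and counted", {
  symbols <- c(rep("N", 5), "~", rep("V", 4))
  mapped <- map_labels(symbols, aami_label_map())
  expect_equal(sum(mapped$keep), 9)
  expect_equal(mapped$n_dropped, 1)
  expect_false(any(is.na(mapped$classes[mapped$keep])))
})

test_that("AAMI and SPH maps are total over their documented symbol sets", {
  am <- aami_label_map()
  expect_setequal(unique(unname(am$raw_to_class)), c("N", "S", "V", "F", "Q"))
  expect_true(all(am$raw_to_class %in% am$classes))
  sm <- sph_label_map()
  expect_setequal(unique(unname(sm$raw_to_class)), sm$classes)
  expect_error(label_map("bad", c(X = "Z"), c("A", "B")), "classes")
})

test_that("dataset iteration is sorted, deterministic, and honors exclusions", {
  dir <- withr::local_tempdir()
  ids <- c("r104", "r100", "r102", "r101", "r103")
  for (id in ids) {
    write_wfdb(generate_record(bench_config(n_beats = 5, seed = match(id, ids))),
               dir, id)
  }
  spec <- dataset_spec(dir, "wfdb", excluded_record_ids = c("r102", "r104"))
  got <- iter_dataset(spec)
  expect_identical(vapply(got, `[[`, character(1), "record_id"),
                   c("r100", "r101", "r103"))
  expect_identical(vapply(iter_dataset(spec), `[[`, character(1), "record_id"),
                   vapply(got, `[[`, character(1), "record_id"))
  empty <- dataset_spec(withr::local_tempdir(), "wfdb")
  expect_warning(out <- iter_dataset(empty), "no records")
  expect_length(out, 0)
})

test_that("missing leads and malformed records raise informative errors", {
  dir <- withr::local_tempdir()
  write_wfdb(generate_record(bench_config(n_beats = 5)), dir, "x",
             lead_name = "V5")
  spec <- dataset_spec(dir, "wfdb", lead_name = "MLII")
  expect_error(load_record(spec, "x"), "lead 'MLII' not found")
  expect_error(load_record(spec, "nothere"), "not found")
})

test_that("CSV layout reads the named lead and the record rhythm label", {
  dir <- withr::local_tempdir()
  rec <- generate_record(synth_config(sampling_rate = 500, n_beats = 10, seed = 4))
  write.csv(data.frame(I = rev(rec$samples), II = rec$samples),
            file.path(dir, "p001.csv"), row.names = FALSE)
  write.csv(data.frame(record_id = "p001", label = "AFIB"),
            file.path(dir, "labels.csv"), row.names = FALSE)
  spec <- dataset_spec(dir, "csv", lead_name = "II", sampling_rate = 500,
                       label_map = sph_label_map(),
                       labels_file = file.path(dir, "labels.csv"))
  got <- load_record(spec, "p001")
  expect_equal(got$samples, rec$samples)
  expect_identical(attr(got, "rhythm"), "AFIB")
})
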