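#' Label maps from raw annotation symbols to beat classes
#'
#' A label map ties a dataset's raw annotation symbols (or rhythm codes) to
#' the ordered class list used by the classifier. Symbols outside the map
#' are dropped (and counted) rather than silently inventing classes.
#'
#' @param scheme_name Short name of the scheme.
#' @param raw_to_class Named character vector: names are raw symbols, values
#'   are class identifiers.
#' @param classes Ordered, duplicate-free class list; every mapped value
#'   must appear here.
#' @return An object of class `label_map`.
#' @export
label_map <- function(scheme_name, raw_to_class, classes) {
  if (length(classes) == 0 || anyDuplicated(classes)) {
    stop("`classes` must be non-empty and duplicate-free")
  }
  if (!all(raw_to_class %in% classes)) {
    stop("every mapped value must appear in `classes`")
  }
  structure(list(scheme_name = scheme_name, raw_to_class = raw_to_class,
                 classes = classes),
            class = "label_map")
}

#' @describeIn label_map The AAMI EC57 five-class beat grouping
#'   (N/S/V/F/Q) over the standard MIT-BIH beat symbols. Shipped as an
#'   editable default rather than asserted: N gathers {N,L,R,e,j}, S gathers
#'   {A,a,J,S}, V gathers {V,E}, F is {F}, Q gathers {/,f,Q}.
#' @export
aami_label_map <- function() {
  label_map("aami5",
            c(N = "N", L = "N", R = "N", e = "N", j = "N",
              A = "S", a = "S", J = "S", S = "S",
              V = "V", E = "V",
              F = "F",
              "/" = "Q", f = "Q", Q = "Q"),
            c("N", "S", "V", "F", "Q"))
}

#' @describeIn label_map The 11-to-4 rhythm merge used with the SPH
#'   database: SB; SR gathers {SR,SI}; AFIB gathers {AFIB,AF}; GSVT gathers
#'   {SVT,AT,SAAWR,ST,AVNRT,AVRT}. Editable default.
#' @export
sph_label_map <- function() {
  label_map("sph4",
            c(SB = "SB", SR = "SR", SI = "SR", AFIB = "AFIB", AF = "AFIB",
              SVT = "GSVT", AT = "GSVT", SAAWR = "GSVT", ST = "GSVT",
              AVNRT = "GSVT", AVRT = "GSVT"),
            c("AFIB", "GSVT", "SB", "SR"))
}

#' Map raw annotation symbols through a label map
#'
#' @param symbols Character vector of raw symbols.
#' @param map A [label_map()].
#' @return List with `classes` (mapped values, unmapped entries `NA`),
#'   `keep` (logical), and `n_dropped`.
#' @export
map_labels <- function(symbols, map) {
  stopifnot(inherits(map, "label_map"))
  cls <- unname(map$raw_to_class[symbols])
  list(classes = cls, keep = !is.na(cls), n_dropped = sum(is.na(cls)))
}

#' Describe an on-disk ECG dataset
#'
#' @param source_path Directory holding the records.
#' @param layout `"wfdb"` (header/signal/annotation triplets) or `"csv"`
#'   (one lead per column, header row, optional per-record rhythm labels).
#' @param lead_name Name of the analysis lead (e.g. `"MLII"`).
#' @param sampling_rate Expected sampling rate in Hz.
#' @param label_map A [label_map()] for annotation symbols or rhythm codes.
#' @param excluded_record_ids Record ids to skip during iteration.
#' @param labels_file For CSV layouts: path to a two-column CSV
#'   (`record_id,label`) of per-record rhythm codes.
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(source_path, layout = c("wfdb", "csv"),
                         lead_name = "MLII", sampling_rate = 360,
                         label_map = aami_label_map(),
                         excluded_record_ids = character(),
                         labels_file = NULL) {
  layout <- match.arg(layout)
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  structure(list(source_path = source_path, layout = layout,
                 lead_name = lead_name, sampling_rate = sampling_rate,
                 label_map = label_map,
                 excluded_record_ids = as.character(excluded_record_ids),
                 labels_file = labels_file),
            class = "dataset_spec")
}

# WFDB beat annotation type codes for the symbols used by the AAMI map
# (public WFDB code table).
wfdb_ann_codes <- c(N = 1L, L = 2L, R = 3L, a = 4L, V = 5L, F = 6L, J = 7L,
                    A = 8L, S = 9L, E = 10L, j = 11L, "/" = 12L, Q = 13L,
                    "~" = 14L, "|" = 16L, e = 34L, f = 38L)

#' Write an ECG record as WFDB header/signal/annotation files
#'
#' Writes `<id>.hea`, `<id>.dat` (format 212 by default, the MIT-BIH
#' packing, or format 16) and, when R-peaks are present, `<id>.atr` in MIT
#' annotation format. Voltages are digitised at the given ADC gain.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if missing).
#' @param record_id Record name (file stem).
#' @param fmt Signal format, 212 or 16.
#' @param gain ADC units per millivolt.
#' @param lead_name Signal description written to the header.
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(record, dir, record_id, fmt = 212, gain = 200,
                       lead_name = "MLII") {
  stopifnot(inherits(record, "ecg_record"), fmt %in% c(212, 16))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(record$samples)
  adu <- as.integer(round(record$samples * gain))
  lim <- if (fmt == 212) 2047L else 32767L
  adu <- pmax(pmin(adu, lim), -lim - 1L)
  hea <- file.path(dir, paste0(record_id, ".hea"))
  writeLines(c(sprintf("%s 1 %g %d", record_id, record$sampling_rate, n),
               sprintf("%s.dat %d %g(0)/mV %d 0 %d 0 0 %s",
                       record_id, fmt, gain, if (fmt == 212) 12L else 16L,
                       adu[1], lead_name)),
             hea)
  dat <- file.path(dir, paste0(record_id, ".dat"))
  if (fmt == 16) {
    writeBin(adu, dat, size = 2, endian = "little")
  } else {
    if (n %% 2 == 1) adu <- c(adu, 0L)
    a <- adu[seq(1, length(adu), 2)]
    b <- adu[seq(2, length(adu), 2)]
    a12 <- bitwAnd(a, 0xFFFL)
    b12 <- bitwAnd(b, 0xFFFL)
    bytes <- as.raw(rbind(bitwAnd(a12, 0xFFL),
                          bitwOr(bitwShiftL(bitwShiftR(b12, 8), 4),
                                 bitwShiftR(a12, 8)),
                          bitwAnd(b12, 0xFFL)))
    writeBin(bytes, dat)
  }
  if (!is.null(record$r_peaks)) {
    syms <- record$beat_labels
    if (is.null(syms)) syms <- rep("N", length(record$r_peaks))
    write_wfdb_annotations(file.path(dir, paste0(record_id, ".atr")),
                           record$r_peaks, syms)
  }
  invisible(hea)
}

write_wfdb_annotations <- function(path, times, symbols) {
  codes <- wfdb_ann_codes[symbols]
  if (anyNA(codes)) stop("annotation symbol without a WFDB code: ",
                         paste(unique(symbols[is.na(codes)]), collapse = " "))
  con <- file(path, "wb")
  on.exit(close(con))
  prev <- 0L
  words <- integer(0)
  for (i in seq_along(times)) {
    incr <- times[i] - prev
    if (incr > 1023L) {
      # SKIP pseudo-annotation: interval stored as high word then low word
      words <- c(words, bitwShiftL(59L, 10),
                 incr %/% 65536L, incr %% 65536L,
                 bitwShiftL(codes[[i]], 10))
    } else {
      words <- c(words, bitwOr(bitwShiftL(codes[[i]], 10), incr))
    }
    prev <- times[i]
  }
  words <- c(words, 0L)
  words <- ifelse(words > 32767L, words - 65536L, words)  # two's complement
  writeBin(as.integer(words), con, size = 2, endian = "little")
  invisible(path)
}

read_wfdb_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  lo <- as.integer(raw[seq(1, length(raw), 2)])
  hi <- as.integer(raw[seq(2, length(raw), 2)])
  words <- lo + 256L * hi
  times <- integer(0)
  codes <- integer(0)
  t <- 0L
  i <- 1L
  while (i <= length(words)) {
    w <- words[i]
    code <- w %/% 1024L
    incr <- w %% 1024L
    if (w == 0L) break
    if (code == 59L && incr == 0L) {           # SKIP: 4-byte interval follows
      t <- t + words[i + 1L] * 65536L + words[i + 2L]
      i <- i + 3L
      next
    } else if (code %in% c(60L, 61L, 62L)) {   # NUM / SUB / CHN: ignore
      i <- i + 1L
      next
    } else if (code == 63L) {                  # AUX: skip payload
      i <- i + 1L + (incr + incr %% 2L) %/% 2L
      next
    }
    t <- t + incr
    times <- c(times, t)
    codes <- c(codes, code)
    i <- i + 1L
  }
  sym_tab <- names(wfdb_ann_codes)
  symbols <- vapply(codes, function(cd) {
    hit <- sym_tab[match(cd, wfdb_ann_codes)]
    if (is.na(hit)) "?" else hit
  }, character(1))
  list(times = times, symbols = symbols)
}

read_wfdb_signals <- function(header_path) {
  lines <- readLines(header_path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  head_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_id <- head_fields[1]
  nsig <- as.integer(head_fields[2])
  fs <- as.numeric(sub("/.*", "", head_fields[3]))
  sig <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gain_field <- f[3]
    gain <- as.numeric(sub("[(/].*", "", gain_field))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    } else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], fmt = as.integer(f[2]), gain = gain,
         baseline = baseline, description = desc)
  })
  fmt <- sig[[1]]$fmt
  dat_path <- file.path(dirname(header_path), sig[[1]]$file)
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path)
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  if (fmt == 16) {
    lo <- as.integer(raw[seq(1, length(raw), 2)])
    hi <- as.integer(raw[seq(2, length(raw), 2)])
    adu <- lo + 256L * hi
    adu <- ifelse(adu > 32767L, adu - 65536L, adu)
  } else if (fmt == 212) {
    b1 <- as.integer(raw[seq(1, length(raw), 3)])
    b2 <- as.integer(raw[seq(2, length(raw), 3)])
    b3 <- as.integer(raw[seq(3, length(raw), 3)])
    a <- b1 + 256L * bitwAnd(b2, 0x0FL)
    b <- b3 + 256L * bitwShiftR(b2, 4)
    a <- ifelse(a > 2047L, a - 4096L, a)
    b <- ifelse(b > 2047L, b - 4096L, b)
    adu <- as.vector(rbind(a, b))
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
  # signals are sample-interleaved across channels
  mat <- matrix(adu[seq_len((length(adu) %/% nsig) * nsig)], nrow = nsig)
  signals <- lapply(seq_len(nsig), function(i) {
    (mat[i, ] - sig[[i]]$baseline) / sig[[i]]$gain
  })
  list(record_id = record_id, fs = fs,
       descriptions = vapply(sig, `[[`, "", "description"),
       signals = signals)
}

#' Load one record from a dataset
#'
#' Reads the named analysis lead and, when annotations are present, maps
#' raw symbols through the dataset's label map; beats with unmapped symbols
#' are dropped and counted in the `n_dropped` attribute. CSV-layout records
#' carry a record-level rhythm class in the `rhythm` attribute instead of
#' per-beat labels.
#'
#' @param spec A [dataset_spec()].
#' @param record_id Record identifier (file stem).
#' @return An [ecg_record()].
#' @export
load_record <- function(spec, record_id) {
  stopifnot(inherits(spec, "dataset_spec"))
  if (spec$layout == "wfdb") {
    hea <- file.path(spec$source_path, paste0(record_id, ".hea"))
    if (!file.exists(hea)) stop("record not found: ", record_id)
    parsed <- tryCatch(read_wfdb_signals(hea),
                       error = function(e) stop("malformed WFDB record ",
                                                record_id, ": ",
                                                conditionMessage(e)))
    lead <- match(spec$lead_name, parsed$descriptions)
    if (is.na(lead)) {
      stop("lead '", spec$lead_name, "' not found in record ", record_id)
    }
    samples <- parsed$signals[[lead]]
    atr <- file.path(spec$source_path, paste0(record_id, ".atr"))
    r_peaks <- NULL
    labels <- NULL
    n_dropped <- 0L
    if (file.exists(atr)) {
      ann <- read_wfdb_annotations(atr)
      mapped <- map_labels(ann$symbols, spec$label_map)
      r_peaks <- ann$times[mapped$keep]
      labels <- mapped$classes[mapped$keep]
      n_dropped <- mapped$n_dropped
    }
    rec <- ecg_record(samples, parsed$fs, r_peaks = r_peaks,
                      beat_labels = labels, record_id = record_id)
    attr(rec, "n_dropped") <- n_dropped
    rec
  } else {
    csv <- file.path(spec$source_path, paste0(record_id, ".csv"))
    if (!file.exists(csv)) stop("record not found: ", record_id)
    tab <- read.csv(csv, check.names = FALSE)
    if (!spec$lead_name %in% names(tab)) {
      stop("lead '", spec$lead_name, "' not found in record ", record_id)
    }
    rec <- ecg_record(tab[[spec$lead_name]], spec$sampling_rate,
                      record_id = record_id)
    if (!is.null(spec$labels_file) && file.exists(spec$labels_file)) {
      lab <- read.csv(spec$labels_file, colClasses = "character")
      raw <- lab$label[match(record_id, lab$record_id)]
      if (!is.na(raw)) {
        mapped <- map_labels(raw, spec$label_map)
        attr(rec, "rhythm") <- if (mapped$keep) mapped$classes else NA_character_
      }
    }
    rec
  }
}

#' Iterate over a dataset in deterministic order
#'
#' Lists record files under the source path, sorts ids, drops the excluded
#' ones, and loads the rest.
#'
#' @param spec A [dataset_spec()].
#' @return List of [ecg_record()] objects, sorted by record id.
#' @export
iter_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  ext <- if (spec$layout == "wfdb") "\\.hea$" else "\\.csv$"
  ids <- sort(sub(ext, "", list.files(spec$source_path, pattern = ext)))
  ids <- setdiff(ids, spec$excluded_record_ids)
  if (length(ids) == 0) {
    warning("no records found under ", spec$source_path)
    return(list())
  }
  lapply(ids, function(id) load_record(spec, id))
}
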