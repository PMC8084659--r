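#' ECG record container
#'
#' A light container for a sampled single-lead signal. All sample indices
#' exposed by this package (annotations, R indices, beat provenance) are
#' 0-based; intervals are half-open. Values are millivolts.
#'
#' @param samples Numeric vector of mV values (non-empty, finite).
#' @param fs Sampling rate in Hz (this study uses 360).
#' @param record_id Identifier string.
#' @param annotations Optional data.frame with columns `r_index` (0-based)
#'   and `label` (one of NORMAL, RBBB, AF, OTHER).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs = 360, record_id = "record",
                       annotations = NULL) {
  stopifnot(is.numeric(samples), length(samples) > 0, all(is.finite(samples)),
            fs > 0)
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations),
              all(c("r_index", "label") %in% names(annotations)))
    if (is.unsorted(annotations$r_index, strictly = TRUE)) {
      annotations <- annotations[order(annotations$r_index), , drop = FALSE]
    }
  }
  structure(list(record_id = record_id, fs = fs,
                 samples = as.numeric(samples), annotations = annotations),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s': %d samples @ %g Hz (%.1f s), %s annotations>\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$annotations)) "no" else nrow(x$annotations)))
  invisible(x)
}

# full-precision number formatting so CSV round-trips are bit exact
fmt_mv <- function(x) formatC(x, digits = 17, format = "g")

write_packet_csv <- function(path, samples, start_sample, record_id) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# fs=%d start_sample=%d record=%s",
                     ECG_FS, as.integer(start_sample), record_id), con)
  writeLines("value_mv", con)
  writeLines(fmt_mv(samples), con)
}

parse_packet_header <- function(line) {
  if (!startsWith(line, "#")) stop("missing packet header line", call. = FALSE)
  get <- function(key) {
    m <- regmatches(line, regexpr(paste0(key, "=[^ ]+"), line))
    if (length(m) == 0) return(NA_character_)
    sub(paste0(key, "="), "", m)
  }
  list(fs = as.numeric(get("fs")),
       start_sample = as.numeric(get("start_sample")),
       record = get("record"))
}

read_packet_csv <- function(path) {
  lines <- readLines(path)
  hdr <- parse_packet_header(lines[1])
  stopifnot(identical(lines[2], "value_mv"))
  samples <- suppressWarnings(as.numeric(lines[-(1:2)]))
  if (anyNA(samples)) stop("unparseable packet values in ", path, call. = FALSE)
  list(samples = samples, fs = hdr$fs,
       start_sample = if (is.na(hdr$start_sample)) 0 else hdr$start_sample,
       record = hdr$record)
}

#' Write an ECG record in the CSV dialect
#'
#' One header comment line (`# fs=<fs> start_sample=0 record=<id>`), a
#' `value_mv` column header, then one sample per line at full precision.
#' Annotations, if any, go to a sibling `<path>.annotations.csv` with
#' 0-based `r_index,label` columns.
#'
#' @param record An [ecg_record].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  write_packet_csv(path, record$samples, 0L, record$record_id)
  if (!is.null(record$annotations)) {
    write.csv(record$annotations[, c("r_index", "label")],
              paste0(path, ".annotations.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read an ECG record (WFDB or CSV dialect)
#'
#' For `dialect = "csv"` reads the packet-style CSV written by
#' [write_record_csv] (annotations are picked up from
#' `<path>.annotations.csv` when present). For `dialect = "wfdb"` reads a
#' MIT/BIH-style header/signal pair (`.hea` + format-212 `.dat`) and, when a
#' `.atr` annotation file is present, maps beat annotations to package
#' labels: symbol `N` (code 1) to NORMAL, symbol `R` (code 3) to RBBB, beats
#' inside an atrial-fibrillation rhythm span (`+` with aux `(AFIB`) to AF,
#' anything else to OTHER.
#'
#' @param path File path; for wfdb, the record path with or without `.hea`.
#' @param dialect `"csv"` or `"wfdb"`.
#' @param channel For wfdb records with several signals, which channel to
#'   keep (default first).
#' @param allow_fs If `FALSE` (default) a sampling rate other than 360 Hz is
#'   refused with an error (no silent resampling).
#' @return An [ecg_record].
#' @export
read_record <- function(path, dialect = c("csv", "wfdb"), channel = 1L,
                        allow_fs = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    pk <- read_packet_csv(path)
    ann <- NULL
    ann_path <- paste0(path, ".annotations.csv")
    if (file.exists(ann_path)) {
      ann <- read.csv(ann_path, stringsAsFactors = FALSE)
    }
    fs <- pk$fs
    rec_id <- if (is.na(pk$record)) basename(path) else pk$record
  } else {
    hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
    if (!file.exists(hea)) stop("no such file: ", hea, call. = FALSE)
    w <- read_wfdb(sub("\\.hea$", "", hea), channel = channel)
    pk <- list(samples = w$samples)
    ann <- w$annotations
    fs <- w$fs
    rec_id <- w$record_id
  }
  if (fs != 360 && !allow_fs) {
    warning(sprintf("record sampled at %g Hz, not 360 Hz", fs))
    stop("refusing non-360 Hz record; pass allow_fs = TRUE to override",
         call. = FALSE)
  }
  ecg_record(pk$samples, fs = fs, record_id = rec_id, annotations = ann)
}

#' Open a packet directory as an ordered stream source
#'
#' Packets are ordered by the `manifest.yaml` listing when present (manifest
#' order wins over filename order), otherwise lexicographically. Packet
#' indices are assigned contiguously from 0; a gap in filename-derived
#' indices without a manifest is a stream-integrity error.
#'
#' @param source_dir Directory of packet CSV files.
#' @return An object of class `ecg_stream` with `$files` in stream order and
#'   `$n_packets`; read individual packets with [read_stream_packet].
#' @export
open_stream <- function(source_dir) {
  if (!dir.exists(source_dir)) {
    stop("no such directory: ", source_dir, call. = FALSE)
  }
  manifest_path <- file.path(source_dir, "manifest.yaml")
  if (file.exists(manifest_path)) {
    manifest <- yaml::read_yaml(manifest_path)
    files <- unlist(manifest$packets)
  } else {
    files <- sort(list.files(source_dir, pattern = "^packet_.*\\.csv$"))
    if (length(files) > 0) {
      idx <- suppressWarnings(as.integer(sub("^packet_0*([0-9]+)\\.csv$", "\\1",
                                             files)))
      if (!anyNA(idx) && !identical(idx, seq_along(idx) - 1L)) {
        stop("stream-integrity error: gap in packet indices", call. = FALSE)
      }
    }
  }
  missing <- !file.exists(file.path(source_dir, files))
  if (any(missing)) {
    stop("stream-integrity error: missing packet file(s): ",
         paste(files[missing], collapse = ", "), call. = FALSE)
  }
  structure(list(dir = source_dir, files = files,
                 n_packets = length(files)),
            class = "ecg_stream")
}

#' Read one packet from an open stream
#'
#' @param stream An `ecg_stream` from [open_stream].
#' @param packet_index 0-based packet index.
#' @return A list with `packet_index`, `start_sample`, `samples`, `record`.
#' @export
read_stream_packet <- function(stream, packet_index) {
  stopifnot(inherits(stream, "ecg_stream"),
            packet_index >= 0, packet_index < stream$n_packets)
  pk <- read_packet_csv(file.path(stream$dir, stream$files[packet_index + 1L]))
  list(packet_index = as.integer(packet_index),
       start_sample = pk$start_sample, samples = pk$samples,
       record = pk$record)
}

# ---------------------------------------------------------------------------
# WFDB dialect (MIT/BIH): .hea header, format-212 .dat, MIT .atr annotations.
# Only what the MIT/BIH arrhythmia records need is supported.

ATR_CODE_NORMAL <- 1L   # symbol N
ATR_CODE_RBBB   <- 3L   # symbol R
ATR_CODE_RHYTHM <- 28L  # symbol +
# non-beat annotation codes (rhythm/signal quality/etc.) that carry no beat
ATR_NONBEAT <- c(14L, 15L, 16L, 18L, 19L, 20L, 21L, 22L, 23L, 24L, 25L,
                 26L, 27L, 28L, 29L, 36L, 37L, 39L, 40L)

map_beat_code <- function(code, in_af) {
  ifelse(in_af, "AF",
         ifelse(code == ATR_CODE_NORMAL, "NORMAL",
                ifelse(code == ATR_CODE_RBBB, "RBBB", "OTHER")))
}

read_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  record_id <- sub("/.*", "", top[1])
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lapply(lines[1 + seq_len(nsig)], function(l) {
    f <- strsplit(trimws(l), "[ \t]+")[[1]]
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain_num <- sub("\\(.*", "", sub("/.*", "", gain_field))
    gain <- as.numeric(gain_num)
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- NA_real_
    if (grepl("\\(", gain_field)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    }
    adc_zero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    if (is.na(baseline)) baseline <- adc_zero
    list(file = f[1], format = as.integer(sub("x.*|:.*|\\+.*", "", f[2])),
         gain = gain, baseline = baseline)
  })
  list(record_id = record_id, nsig = nsig, fs = fs, nsamp = nsamp,
       signals = sig)
}

decode_212 <- function(raw_bytes, n_values) {
  b <- as.integer(raw_bytes)
  n_triplets <- length(b) %/% 3L
  b0 <- b[seq(1, by = 3, length.out = n_triplets)]
  b1 <- b[seq(2, by = 3, length.out = n_triplets)]
  b2 <- b[seq(3, by = 3, length.out = n_triplets)]
  s0 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8L)
  s1 <- b2 + bitwShiftL(bitwAnd(b1, 0xF0L), 4L)
  s0 <- ifelse(s0 > 2047L, s0 - 4096L, s0)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  out <- numeric(2L * n_triplets)
  out[c(TRUE, FALSE)] <- s0
  out[c(FALSE, TRUE)] <- s1
  out[seq_len(n_values)]
}

encode_212 <- function(adc) {
  if (length(adc) %% 2L == 1L) adc <- c(adc, 0L)
  adc <- as.integer(adc)
  adc <- ifelse(adc < 0L, adc + 4096L, adc)  # 12-bit two's complement
  s0 <- adc[c(TRUE, FALSE)]
  s1 <- adc[c(FALSE, TRUE)]
  b0 <- bitwAnd(s0, 0xFFL)
  b1 <- bitwOr(bitwShiftR(s0, 8L), bitwShiftL(bitwShiftR(s1, 8L), 4L))
  b2 <- bitwAnd(s1, 0xFFL)
  out <- integer(3L * length(s0))
  out[seq(1, by = 3, length.out = length(s0))] <- b0
  out[seq(2, by = 3, length.out = length(s0))] <- b1
  out[seq(3, by = 3, length.out = length(s0))] <- b2
  as.raw(out)
}

read_atr <- function(atr_path) {
  raw_bytes <- readBin(atr_path, what = "raw", n = file.info(atr_path)$size)
  b <- as.integer(raw_bytes)
  i <- 1L
  t_cur <- 0L
  idx <- integer(0); code <- integer(0); aux <- character(0)
  cur_aux <- NA_character_
  while (i + 1L <= length(b)) {
    word <- b[i] + bitwShiftL(b[i + 1L], 8L)
    i <- i + 2L
    a_code <- bitwShiftR(word, 10L)
    a_time <- bitwAnd(word, 1023L)
    if (a_code == 0L && a_time == 0L) break
    if (a_code == 59L) {              # SKIP: 4-byte interval follows
      hi <- b[i] + bitwShiftL(b[i + 1L], 8L)
      lo <- b[i + 2L] + bitwShiftL(b[i + 3L], 8L)
      i <- i + 4L
      t_cur <- t_cur + hi * 65536L + lo
    } else if (a_code == 63L) {       # AUX: a_time bytes of text, even-padded
      nb <- a_time
      aux_raw <- raw_bytes[i:(i + nb - 1L)]
      cur_aux <- rawToChar(aux_raw[aux_raw != as.raw(0L)])
      i <- i + nb + (nb %% 2L)
      if (length(code) > 0) aux[length(code)] <- cur_aux
    } else if (a_code %in% c(60L, 61L, 62L)) {
      # NUM/SUB/CHN modifiers: ignored
    } else {
      t_cur <- t_cur + a_time
      idx <- c(idx, t_cur)
      code <- c(code, a_code)
      aux <- c(aux, NA_character_)
    }
  }
  data.frame(sample = idx, code = code, aux = aux, stringsAsFactors = FALSE)
}

atr_to_annotations <- function(atr) {
  if (nrow(atr) == 0) return(NULL)
  in_af <- logical(nrow(atr))
  state <- FALSE
  for (j in seq_len(nrow(atr))) {
    if (atr$code[j] == ATR_CODE_RHYTHM && !is.na(atr$aux[j])) {
      state <- grepl("^\\(AFIB", atr$aux[j])
    }
    in_af[j] <- state
  }
  beat <- !(atr$code %in% ATR_NONBEAT)
  if (!any(beat)) return(NULL)
  data.frame(r_index = atr$sample[beat],
             label = map_beat_code(atr$code[beat], in_af[beat]),
             stringsAsFactors = FALSE)
}

#' Read a WFDB (MIT/BIH dialect) record
#'
#' Parses the `.hea` header, decodes the format-212 `.dat` signal into mV
#' using the header gain/baseline, and (if a `.atr` file exists) converts
#' MIT annotations to 0-based beat labels (see [read_record] for the symbol
#' table).
#'
#' @param record_path Record path without extension.
#' @param channel 1-based signal channel to keep.
#' @return A list with `samples` (mV), `fs`, `record_id`, `annotations`.
#' @export
read_wfdb <- function(record_path, channel = 1L) {
  hdr <- read_wfdb_header(paste0(record_path, ".hea"))
  if (channel > hdr$nsig) stop("record has only ", hdr$nsig, " channel(s)",
                               call. = FALSE)
  sig <- hdr$signals[[channel]]
  if (sig$format != 212L) {
    stop("only WFDB format 212 is supported (got ", sig$format, ")",
         call. = FALSE)
  }
  dat_path <- file.path(dirname(record_path), sig$file)
  raw_bytes <- readBin(dat_path, what = "raw", n = file.info(dat_path)$size)
  total <- if (is.na(hdr$nsamp)) {
    (length(raw_bytes) %/% 3L) * 2L
  } else hdr$nsamp * hdr$nsig
  vals <- decode_212(raw_bytes, total)
  # channels are interleaved sample-by-sample
  adc <- vals[seq(channel, length(vals), by = hdr$nsig)]
  samples <- (adc - sig$baseline) / sig$gain
  ann <- NULL
  atr_path <- paste0(record_path, ".atr")
  if (file.exists(atr_path)) ann <- atr_to_annotations(read_atr(atr_path))
  list(samples = samples, fs = hdr$fs, record_id = hdr$record_id,
       annotations = ann)
}

#' Write a record in the WFDB (MIT/BIH) dialect
#'
#' Quantizes mV samples with a fixed gain of 200 adu/mV (baseline 0) into a
#' format-212 `.dat`, writes a matching `.hea`, and encodes annotations
#' (NORMAL as code 1, RBBB as code 3; AF beats are wrapped in an `(AFIB`
#' rhythm span) into a `.atr`. Mainly used to build synthetic fixtures and
#' for dialect conversion.
#'
#' @param record An [ecg_record].
#' @param record_path Output path without extension.
#' @param gain ADC units per mV.
#' @return `record_path`, invisibly.
#' @export
write_wfdb <- function(record, record_path, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  adc <- as.integer(pmax(pmin(round(record$samples * gain), 2047L), -2048L))
  base <- basename(record_path)
  writeBin(encode_212(adc), paste0(record_path, ".dat"))
  hea <- c(sprintf("%s 1 %g %d", base, record$fs, length(adc)),
           sprintf("%s.dat 212 %g(0)/mV 12 0 %d 0 0 ECG", base, gain, adc[1]))
  writeLines(hea, paste0(record_path, ".hea"))
  if (!is.null(record$annotations)) {
    write_atr(record$annotations, paste0(record_path, ".atr"))
  }
  invisible(record_path)
}

atr_word <- function(code, time) {
  word <- bitwOr(bitwShiftL(as.integer(code), 10L), as.integer(time))
  as.raw(c(bitwAnd(word, 0xFFL), bitwShiftR(word, 8L)))
}

write_atr <- function(annotations, atr_path) {
  ann <- annotations[order(annotations$r_index), , drop = FALSE]
  chunks <- list()
  add <- function(x) chunks[[length(chunks) + 1L]] <<- x
  aux_chunk <- function(label) {
    nb <- nchar(label)
    c(atr_word(63L, nb), charToRaw(label),
      if (nb %% 2L == 1L) as.raw(0L) else raw(0))
  }
  # emits interval words so the next annotation word carries delta <= 1023
  shrink_delta <- function(delta) {
    while (delta > 1023L) {
      step <- min(delta, 2147000000)
      hi <- step %/% 65536L; lo <- step %% 65536L
      add(c(atr_word(59L, 0L),
            as.raw(c(hi %% 256L, hi %/% 256L)),
            as.raw(c(lo %% 256L, lo %/% 256L))))
      delta <- delta - step
    }
    delta
  }
  t_prev <- 0L
  in_af <- FALSE
  for (j in seq_len(nrow(ann))) {
    want_af <- ann$label[j] == "AF"
    delta <- as.integer(ann$r_index[j]) - t_prev
    if (want_af != in_af) {
      delta <- shrink_delta(delta)
      add(atr_word(ATR_CODE_RHYTHM, delta))
      add(aux_chunk(if (want_af) "(AFIB" else "(N"))
      in_af <- want_af
      delta <- 0L
    }
    delta <- shrink_delta(delta)
    code <- switch(ann$label[j],
                   NORMAL = ATR_CODE_NORMAL,
                   RBBB = ATR_CODE_RBBB,
                   AF = ATR_CODE_NORMAL,  # AF is a rhythm; beats carry N
                   38L)                   # 'Q'/unclassifiable for OTHER
    add(atr_word(code, delta))
    t_prev <- as.integer(ann$r_index[j])
  }
  add(atr_word(0L, 0L))
  writeBin(do.call(c, chunks), atr_path)
}
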