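#' @importFrom stats rnorm runif convolve predict
#' @importFrom utils read.csv write.csv write.table head tail
NULL

ECG_FS <- 360L
CLASS_LEVELS <- c("NORMAL", "RBBB", "AF")

#' Beat morphology template
#'
#' Describes one of the three beat morphologies the pipeline classifies as a
#' sum of Gaussian bumps for the P, Q, R, S and T waves. RBBB beats carry a
#' widened, notched QRS (a secondary R' bump); AF beats have no P wave and
#' are intended to be paired with an irregular rhythm ([rhythm_spec] with
#' `rr_jitter >= 0.15`).
#'
#' @param class_label One of `"NORMAL"`, `"RBBB"`, `"AF"`.
#' @param qrs_width QRS duration in seconds (> 0). Defaults: 0.08 s for
#'   NORMAL/AF, 0.14 s for RBBB (widened complex).
#' @param qrs_amplitude R-wave amplitude in mV.
#' @param p_wave_present Logical; forced to `FALSE` for AF.
#' @param t_wave_amplitude T-wave amplitude in mV.
#' @return An object of class `beat_template`.
#' @examples
#' beat_template("RBBB")
#' @export
beat_template <- function(class_label = c("NORMAL", "RBBB", "AF"),
                          qrs_width = NULL,
                          qrs_amplitude = 1.2,
                          p_wave_present = NULL,
                          t_wave_amplitude = 0.3) {
  class_label <- match.arg(class_label)
  if (is.null(qrs_width)) {
    qrs_width <- if (class_label == "RBBB") 0.14 else 0.08
  }
  if (is.null(p_wave_present)) {
    p_wave_present <- class_label != "AF"
  }
  if (class_label == "AF" && p_wave_present) {
    stop("AF templates must have p_wave_present = FALSE", call. = FALSE)
  }
  stopifnot(qrs_width > 0, is.finite(qrs_amplitude), is.finite(t_wave_amplitude))
  structure(
    list(class_label = class_label, qrs_width = qrs_width,
         qrs_amplitude = qrs_amplitude, p_wave_present = p_wave_present,
         t_wave_amplitude = t_wave_amplitude,
         notched = class_label == "RBBB"),
    class = "beat_template")
}

#' Rhythm specification for the synthetic generator
#'
#' @param mean_rr Mean RR interval in seconds (> 0).
#' @param rr_jitter Coefficient of variation of the RR interval
#'   (dimensionless, >= 0). AF rhythms should use >= 0.15 to emulate the
#'   irregular RR intervals characteristic of atrial fibrillation.
#' @param duration Record duration in seconds (>= 2).
#' @param noise_sd Additive white noise standard deviation in mV.
#' @param baseline_wander_amp Amplitude (mV) of a 0.25 Hz sinusoidal
#'   baseline wander component.
#' @param seed Integer seed; identical seeds give bit-identical records.
#' @return An object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(mean_rr = 0.8, rr_jitter = 0.05, duration = 10,
                        noise_sd = 0.02, baseline_wander_amp = 0.05,
                        seed = 1L) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  if (!is.numeric(mean_rr) || mean_rr <= 0) {
    stop("mean_rr must be positive", call. = FALSE)
  }
  stopifnot(rr_jitter >= 0, noise_sd >= 0, baseline_wander_amp >= 0)
  structure(
    list(mean_rr = mean_rr, rr_jitter = rr_jitter, duration = duration,
         noise_sd = noise_sd, baseline_wander_amp = baseline_wander_amp,
         seed = as.integer(seed)),
    class = "rhythm_spec")
}

#' Record-disjoint synthetic train/test benchmark
#'
#' Builds labeled train and test feature sets mirroring the study design:
#' one record per class, per-class raw sample budgets of 400000 (NORMAL),
#' 400200 (RBBB) and 311600 (AF) samples for training and 104400, 129600
#' and 124200 samples for testing, all at 360 Hz, with a mean RR of 200
#' samples so the beat count per class tracks the sample count divided by
#' the 200-sample beat width (about 5559 training beats at `scale = 1`).
#' Train and test records use disjoint generator seeds derived from `seed`.
#' Beats are cut at the ground-truth R indices, so the benchmark isolates
#' the feature/classifier stages from detector error.
#'
#' @param seed Integer master seed.
#' @param noise_sd White-noise level in mV (default 0.05).
#' @param scale Fraction of the full sample budget (e.g. 0.1 for quick
#'   tests).
#' @param wavelet Wavelet used for features.
#' @return List with `train` and `test` [labeled_dataset]s.
#' @export
synthetic_benchmark <- function(seed = 1L, noise_sd = 0.05, scale = 1,
                                wavelet = "db4") {
  train_samples <- c(NORMAL = 400000, RBBB = 400200, AF = 311600) * scale
  test_samples <- c(NORMAL = 104400, RBBB = 129600, AF = 124200) * scale
  spec <- filter_spec()
  build <- function(budgets, seed_base) {
    X <- NULL
    y <- character(0)
    for (cl in names(budgets)) {
      jit <- if (cl == "AF") 0.2 else 0.05
      rh <- rhythm_spec(mean_rr = 200 / ECG_FS, rr_jitter = jit,
                        duration = budgets[[cl]] / ECG_FS,
                        noise_sd = noise_sd,
                        seed = seed_base + match(cl, CLASS_LEVELS))
      out <- generate_record(rh, beat_template(cl))
      filt <- bandpass_fir(out$record$samples, spec)
      tr <- out$truth[!out$truth$boundary, ]
      beats <- segment_beats(filt, tr$r_index, labels = tr$label)
      fm <- extract_feature_matrix(beats, wavelet = wavelet)
      X <- rbind(X, fm$X)
      y <- c(y, fm$label)
    }
    labeled_dataset(X, y)
  }
  list(train = build(train_samples, seed_base = seed * 1000L),
       test = build(test_samples, seed_base = seed * 1000L + 500L))
}

# Gaussian bump helper: amplitude `a`, centre `mu` (s), width `sigma` (s),
# evaluated at times t (s).
gauss_bump <- function(t, a, mu, sigma) a * exp(-((t - mu)^2) / (2 * sigma^2))

# One beat waveform evaluated at times `t` (seconds) relative to the R peak.
beat_waveform <- function(t, template) {
  w <- template$qrs_width
  y <- gauss_bump(t, template$qrs_amplitude, 0, w / 5)         # R
  y <- y + gauss_bump(t, -0.12, -w / 2.2, w / 7)               # Q
  y <- y + gauss_bump(t, -0.18, w / 2.0, w / 6)                # S
  if (template$notched) {                                      # RBBB R'
    y <- y + gauss_bump(t, 0.55 * template$qrs_amplitude, 0.55 * w, w / 5)
  }
  if (template$p_wave_present) {
    y <- y + gauss_bump(t, 0.15, -0.17, 0.025)                 # P
  }
  y + gauss_bump(t, template$t_wave_amplitude, 0.28, 0.06)     # T
}

#' Generate a synthetic single-lead ECG record with ground truth
#'
#' Produces a 360 Hz record of `rhythm$duration` seconds built from the
#' given beat template, with per-beat RR intervals drawn around `mean_rr`
#' (coefficient of variation `rr_jitter`), additive white noise and 0.25 Hz
#' baseline wander. R-peak sample positions land exactly on the sample grid
#' so that, in the noise-free case, the signal argmax within the QRS window
#' equals the recorded R index.
#'
#' @param rhythm A [rhythm_spec].
#' @param template A [beat_template].
#' @param record_id Identifier stored on the returned record.
#' @return A list with components `record` (an `ecg_record`, see
#'   [ecg_record]) and `truth` (a data.frame with 0-based `r_index`, `label`
#'   and a logical `boundary` flag marking beats lacking the full
#'   69-before/130-after sample context).
#' @examples
#' out <- generate_record(rhythm_spec(duration = 5, seed = 7), beat_template("NORMAL"))
#' length(out$record$samples)  # 1800 samples = 5 s at 360 Hz
#' @export
generate_record <- function(rhythm, template, record_id = "synthetic") {
  stopifnot(inherits(rhythm, "rhythm_spec"), inherits(template, "beat_template"))
  if (rhythm$duration < 2) stop("duration must be >= 2 s", call. = FALSE)
  fs <- ECG_FS
  n <- round(rhythm$duration * fs)
  withr::with_seed(rhythm$seed, {
    # R-peak times: start half an interval in, step by jittered RR.
    t_r <- numeric(0)
    t_cur <- 0.5 * rhythm$mean_rr
    end_t <- rhythm$duration
    while (t_cur < end_t) {
      t_r <- c(t_r, t_cur)
      rr <- rhythm$mean_rr * (1 + rhythm$rr_jitter * rnorm(1))
      rr <- max(rr, 0.25 * rhythm$mean_rr)  # keep physiological
      t_cur <- t_cur + rr
    }
    r_idx <- round(t_r * fs)                     # 0-based sample indices
    r_idx <- r_idx[r_idx >= 0 & r_idx <= n - 1]
    r_idx <- unique(r_idx)
    t_grid <- (seq_len(n) - 1) / fs
    sig <- numeric(n)
    # each beat's waveform has negligible support beyond +/- 0.65 s of its R
    half <- as.integer(ceiling(0.65 * fs))
    for (r in r_idx) {
      lo <- max(0L, r - half)
      hi <- min(n - 1L, r + half)
      win <- (lo + 1L):(hi + 1L)
      sig[win] <- sig[win] + beat_waveform(t_grid[win] - r / fs, template)
    }
    if (rhythm$baseline_wander_amp > 0) {
      phase <- runif(1, 0, 2 * pi)
      sig <- sig + rhythm$baseline_wander_amp * sin(2 * pi * 0.25 * t_grid + phase)
    }
    if (rhythm$noise_sd > 0) {
      sig <- sig + rnorm(n, sd = rhythm$noise_sd)
    }
  })
  boundary <- !(r_idx >= 69 & r_idx + 130 <= n - 1)
  truth <- data.frame(r_index = r_idx,
                      label = rep(template$class_label, length(r_idx)),
                      boundary = boundary,
                      stringsAsFactors = FALSE)
  rec <- ecg_record(samples = sig, fs = fs, record_id = record_id,
                    annotations = truth[, c("r_index", "label")])
  list(record = rec, truth = truth)
}

#' Write a multi-record synthetic stream as a directory of 5-second packets
#'
#' Concatenates one generated record per `(rhythm, template)` pair into a
#' single stream signal, cuts it into consecutive non-overlapping packets of
#' `packet_seconds` (the last packet may be short and is flagged in the
#' manifest), and writes: one CSV packet file per epoch, a YAML manifest
#' listing the packets in stream order, and a ground-truth CSV with global
#' 0-based `r_index` and per-beat `label`.
#'
#' @param specs A list of `list(rhythm = , template = )` pairs.
#' @param dir Output directory (created if needed).
#' @param packet_seconds Packet duration in seconds (default 5).
#' @param record_id Stream identifier written into packet headers.
#' @return Invisibly, a list with `signal`, `truth`, `manifest_path`,
#'   `truth_path` and `packet_paths`.
#' @export
generate_dataset <- function(specs, dir, packet_seconds = 5,
                             record_id = "stream") {
  if (length(specs) == 0) stop("specs must be a non-empty list", call. = FALSE)
  if (!is.numeric(packet_seconds) || packet_seconds <= 0) {
    stop("packet_seconds must be positive", call. = FALSE)
  }
  sig <- numeric(0)
  truth <- NULL
  for (sp in specs) {
    out <- generate_record(sp$rhythm, sp$template, record_id = record_id)
    off <- length(sig)
    tr <- out$truth
    tr$r_index <- tr$r_index + off
    sig <- c(sig, out$record$samples)
    truth <- rbind(truth, tr)
  }
  # boundary flags are relative to the concatenated stream
  n <- length(sig)
  truth$boundary <- !(truth$r_index >= 69 & truth$r_index + 130 <= n - 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plen <- round(packet_seconds * ECG_FS)
  n_packets <- ceiling(n / plen)
  packet_files <- character(n_packets)
  for (k in seq_len(n_packets) - 1L) {
    lo <- k * plen + 1L
    hi <- min((k + 1L) * plen, n)
    fname <- sprintf("packet_%05d.csv", k)
    write_packet_csv(file.path(dir, fname), sig[lo:hi],
                     start_sample = k * plen, record_id = record_id)
    packet_files[k + 1L] <- fname
  }
  manifest <- list(record = record_id, fs = ECG_FS,
                   packet_seconds = packet_seconds,
                   packets = as.list(packet_files),
                   last_packet_short = (n %% plen) != 0)
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  truth_path <- file.path(dir, "truth.csv")
  write.csv(truth[, c("r_index", "label")], truth_path, row.names = FALSE)
  invisible(list(signal = sig, truth = truth, manifest_path = manifest_path,
                 truth_path = truth_path,
                 packet_paths = file.path(dir, packet_files)))
}
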