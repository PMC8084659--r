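#' FIR band-pass filter specification
#'
#' Linear-phase (symmetric, odd-length) FIR band-pass design used for ECG
#' denoising. The defaults — 0.5 to 40 Hz, 101 taps, Hamming window —
#' retain QRS energy while removing baseline wander and powerline/white
#' noise; all are configurable. After the windowed design the coefficients
#' are mean-centred so the response has an exact null at DC (a 101-tap
#' window alone leaves a wide transition band at the 0.5 Hz edge).
#'
#' @param low_cut Lower passband edge, Hz.
#' @param high_cut Upper passband edge, Hz.
#' @param num_taps Number of taps; must be odd (type-I linear phase).
#' @param fs Sampling rate, Hz.
#' @return An object of class `filter_spec` carrying the designed
#'   coefficients in `$h`.
#' @export
filter_spec <- function(low_cut = 0.5, high_cut = 40, num_taps = 101,
                        fs = 360) {
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < fs / 2)) {
    stop("require 0 < low_cut < high_cut < fs/2", call. = FALSE)
  }
  if (num_taps %% 2 != 1) stop("num_taps must be odd", call. = FALSE)
  h <- signal::fir1(num_taps - 1, c(low_cut, high_cut) / (fs / 2),
                    type = "pass", window = signal::hamming(num_taps))
  h <- as.numeric(h)
  h <- h - mean(h)  # exact DC null
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 num_taps = as.integer(num_taps), fs = fs, h = h),
            class = "filter_spec")
}

#' Apply the band-pass FIR with group-delay compensation
#'
#' The filter is applied as a zero-padded convolution and the output is
#' re-aligned by the (num_taps-1)/2 group delay of the symmetric design, so
#' R-peaks are not shifted and the output has the same length as the input.
#' FFT convolution is used for speed on long records.
#'
#' @param x Numeric signal.
#' @param spec A [filter_spec].
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_fir <- function(x, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  if (n <= spec$num_taps) {
    stop("signal must be longer than the filter (", spec$num_taps, " taps)",
         call. = FALSE)
  }
  h <- spec$h
  m <- length(h)
  # full linear convolution via FFT (convolve with type "open" reverses its
  # second argument, so pass rev(h))
  full <- convolve(x, rev(h), type = "open")  # length n + m - 1
  delay <- (m - 1L) %/% 2L
  full[(delay + 1L):(delay + n)]
}

# magnitude of the designed frequency response at frequency f (Hz)
filter_gain <- function(spec, f) {
  k <- seq_along(spec$h) - 1
  vapply(f, function(fi) {
    Mod(sum(spec$h * exp(-2i * pi * fi * k / spec$fs)))
  }, numeric(1))
}

#' Online R-peak detection (Pan-Tompkins style)
#'
#' Implements the canonical online QRS detection chain on an already
#' band-pass filtered signal: five-point derivative, squaring, moving-window
#' integration (150 ms), then adaptive dual thresholds on integrated-signal
#' peaks with a search-back pass at half threshold when no QRS is found
#' within 1.66 times the running average RR. Accepted candidates are snapped
#' to the maximum of the filtered signal within +/- `snap` samples, since
#' the R-peak is the highest point of the QRS complex. A refractory period
#' (default 0.2 s) enforces a minimum separation.
#'
#' @param x Filtered signal (see [bandpass_fir]).
#' @param fs Sampling rate, Hz.
#' @param refractory_s Refractory period in seconds.
#' @param snap Half-width (samples) of the window used to locate the R-peak
#'   on the filtered signal around each accepted candidate.
#' @return Integer vector of strictly increasing 0-based R indices (empty
#'   when nothing is detected).
#' @export
detect_r_peaks <- function(x, fs = 360, refractory_s = 0.2, snap = 25L) {
  n <- length(x)
  if (n < 10 || all(x == 0)) return(integer(0))
  refractory <- as.integer(round(refractory_s * fs))

  # derivative -> squaring -> moving-window integration (150 ms)
  d <- c(0, 0, 0, 0, (2 * x[5:n] + x[4:(n - 1)] - x[2:(n - 3)] -
                        2 * x[1:(n - 4)]) / 8)
  sq <- d * d
  wlen <- as.integer(round(0.15 * fs))
  cs <- cumsum(sq)
  mwi <- (cs - c(rep(0, wlen), head(cs, n - wlen))) / wlen

  # candidate peaks of the integrated signal (local maxima)
  is_peak <- c(FALSE, mwi[2:(n - 1)] > mwi[1:(n - 2)] &
                 mwi[2:(n - 1)] >= mwi[3:n], FALSE)
  cand <- which(is_peak)
  if (length(cand) == 0) return(integer(0))

  spki <- 0; npki <- 0
  # seed thresholds from the first two seconds (or whole signal if shorter)
  init_span <- min(n, as.integer(2 * fs))
  spki <- max(mwi[seq_len(init_span)]) / 3
  npki <- mean(mwi[seq_len(init_span)]) / 2
  thr1 <- npki + 0.25 * (spki - npki)

  peaks <- integer(0)       # 1-based accepted positions (on mwi)
  rr_avg <- as.integer(round(0.8 * fs))
  last_qrs <- -Inf
  unreviewed <- integer(0)  # candidates below thr1 since last QRS

  for (p in cand) {
    if (p - last_qrs < refractory) next
    if (mwi[p] >= thr1) {
      peaks <- c(peaks, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (length(peaks) >= 2) {
        rr <- diff(tail(peaks, min(8, length(peaks))))
        rr_avg <- as.integer(round(mean(rr)))
      }
      last_qrs <- p
      unreviewed <- integer(0)
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      unreviewed <- c(unreviewed, p)
      # search-back when expected QRS is overdue
      if (is.finite(last_qrs) && (p - last_qrs) > 1.66 * rr_avg &&
          length(unreviewed) > 0) {
        ok <- unreviewed[mwi[unreviewed] >= thr1 / 2 &
                           unreviewed - last_qrs >= refractory]
        if (length(ok) > 0) {
          b <- ok[which.max(mwi[ok])]
          peaks <- sort(c(peaks, b))
          spki <- 0.25 * mwi[b] + 0.75 * spki
          last_qrs <- max(peaks)
          unreviewed <- unreviewed[unreviewed > b]
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (length(peaks) == 0) return(integer(0))

  # snap each accepted candidate to the filtered-signal maximum nearby;
  # MWI peaks trail the R wave by up to the integration window
  r <- vapply(peaks, function(p) {
    lo <- max(1L, p - wlen - snap)
    hi <- min(n, p + snap)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  r <- sort(unique(r))
  # enforce refractory after snapping: keep the larger peak of close pairs
  if (length(r) >= 2) {
    keep <- rep(TRUE, length(r))
    j <- 1L
    for (k in 2:length(r)) {
      if (r[k] - r[j] < refractory) {
        if (x[r[k]] > x[r[j]]) { keep[j] <- FALSE; j <- k } else keep[k] <- FALSE
      } else j <- k
    }
    r <- r[keep]
  }
  as.integer(r - 1L)  # 0-based
}

#' Cut fixed-width beats around detected R-peaks
#'
#' Each beat is exactly `pre + 1 + post` samples (default 69 before the
#' R-peak, the R-peak sample itself, and 130 after, i.e. 200 samples) with
#' the R-peak at offset `pre`. R indices lacking the full context are
#' dropped, not padded, and counted in `dropped_boundary`.
#'
#' @param x Signal (typically filtered).
#' @param r_indices 0-based R-peak sample indices.
#' @param pre,post Samples kept before/after the R-peak.
#' @param labels Optional per-peak labels aligned with `r_indices`.
#' @return An object of class `beat_set`: list with `X` (n_beats x 200
#'   matrix), `r_index` (0-based, per row), `label` (or NA) and
#'   `dropped_boundary`.
#' @export
segment_beats <- function(x, r_indices, pre = 69L, post = 130L,
                          labels = NULL) {
  n <- length(x)
  r_indices <- as.integer(r_indices)
  if (!is.null(labels)) stopifnot(length(labels) == length(r_indices))
  ok <- r_indices - pre >= 0L & r_indices + post <= n - 1L
  kept <- r_indices[ok]
  width <- pre + 1L + post
  X <- matrix(0, nrow = length(kept), ncol = width)
  for (j in seq_along(kept)) {
    X[j, ] <- x[(kept[j] - pre + 1L):(kept[j] + post + 1L)]
  }
  structure(list(X = X, r_index = kept,
                 label = if (is.null(labels)) rep(NA_character_, length(kept))
                         else as.character(labels[ok]),
                 pre = as.integer(pre), post = as.integer(post),
                 dropped_boundary = sum(!ok)),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set: %d beats x %d samples (R at offset %d), %d dropped at boundaries>\n",
              nrow(x$X), ncol(x$X), x$pre, x$dropped_boundary))
  invisible(x)
}
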