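# Orthonormal decomposition filter banks (standard published coefficients).
# dec_lo is the low-pass (scaling) filter; dec_hi the quadrature mirror
# high-pass, h[j] = (-1)^(j+1) * dec_lo[len-1-j] (0-based j).
WAVELET_BANK <- local({
  db4_lo <- c(-0.010597401785069032, 0.0328830116668852,
              0.030841381835560764, -0.18703481171909309,
              -0.027983769416859854, 0.6308807679298589,
              0.7148465705529157, 0.2303778133088965)
  haar_lo <- c(1, 1) / sqrt(2)
  qmf <- function(lo) rev(lo) * (-1)^seq_along(lo)
  list(
    haar = list(dec_lo = haar_lo, dec_hi = qmf(haar_lo)),
    db4 = list(dec_lo = db4_lo, dec_hi = qmf(db4_lo))
  )
})

#' Decomposition filters for a named wavelet
#'
#' @param wavelet `"haar"` or `"db4"`.
#' @return List with `dec_lo` and `dec_hi` coefficient vectors.
#' @export
wavelet_filters <- function(wavelet = c("db4", "haar")) {
  wavelet <- match.arg(wavelet)
  WAVELET_BANK[[wavelet]]
}

#' One dyadic subband decomposition step
#'
#' Splits an even-length signal into half-length approximation (low-pass)
#' and detail (high-pass) branches:
#' `Y_low[k] = sum_n S[n] * L[2k - n]` and
#' `Y_high[k] = sum_n S[n] * H[2k - n]`,
#' evaluated under periodic extension with the downsampling phase fixed at
#' `flen/2` so results coincide with the common periodized DWT convention.
#' Half the samples are removed at each step (Nyquist), so both outputs
#' have length `length(x)/2`.
#'
#' @param x Even-length numeric signal.
#' @param low_pass,high_pass Filter taps; defaults are the db4 bank.
#' @return List with `approx` and `detail`, each of length `length(x)/2`.
#' @export
subband_step <- function(x,
                         low_pass = wavelet_filters("db4")$dec_lo,
                         high_pass = wavelet_filters("db4")$dec_hi) {
  n <- length(x)
  if (n %% 2L != 0L) {
    stop("internal error: subband_step requires an even-length signal",
         call. = FALSE)
  }
  apply_branch <- function(h) {
    m <- length(h)
    half <- n %/% 2L
    out <- numeric(half)
    # y[k] = sum_j h[j] * x[(2k + m/2 - j) mod n], k = 0..n/2-1 (0-based)
    for (j in seq_len(m) - 1L) {
      idx <- (2L * (seq_len(half) - 1L) + m %/% 2L - j) %% n
      out <- out + h[j + 1L] * x[idx + 1L]
    }
    out
  }
  list(approx = apply_branch(low_pass), detail = apply_branch(high_pass))
}

#' Reduce a 200-sample beat to its 25-coefficient wavelet feature vector
#'
#' Applies [subband_step] repeatedly, feeding the approximation (low-pass)
#' branch forward, until the approximation length equals `target_len`. For
#' the pipeline's 200-sample beats this is the exact halving chain
#' 200 -> 100 -> 50 -> 25; the final approximation branch is the feature
#' vector. `target_len` must be reachable from the beat length by repeated
#' halving.
#'
#' @param beat Numeric vector of beat samples (length 200 in this
#'   pipeline), or a single-row of a `beat_set$X`.
#' @param wavelet Wavelet name (see [wavelet_filters]).
#' @param target_len Feature vector length (default 25).
#' @return Numeric vector of `target_len` approximation coefficients.
#' @export
extract_features <- function(beat, wavelet = "db4", target_len = 25L) {
  x <- as.numeric(beat)
  flt <- wavelet_filters(wavelet)
  if (length(x) < target_len) {
    stop("beat shorter than target_len", call. = FALSE)
  }
  len <- length(x)
  chain <- len
  while (chain > target_len) {
    if (chain %% 2L != 0L) {
      stop(sprintf("target_len %d is not reachable from %d by halving",
                   target_len, len), call. = FALSE)
    }
    chain <- chain %/% 2L
  }
  if (chain != target_len) {
    stop(sprintf("target_len %d is not reachable from %d by halving",
                 target_len, len), call. = FALSE)
  }
  while (length(x) > target_len) {
    x <- subband_step(x, flt$dec_lo, flt$dec_hi)$approx
  }
  x
}

#' Feature matrix for a set of beats
#'
#' @param beats A `beat_set` from [segment_beats].
#' @param wavelet Wavelet name.
#' @param target_len Feature length (default 25).
#' @return A list with `X` (n_beats x target_len matrix, columns
#'   `f1..f<target_len>`), `label`, `r_index`.
#' @export
extract_feature_matrix <- function(beats, wavelet = "db4", target_len = 25L) {
  stopifnot(inherits(beats, "beat_set"))
  n <- nrow(beats$X)
  F <- matrix(0, nrow = n, ncol = target_len,
              dimnames = list(NULL, paste0("f", seq_len(target_len))))
  for (j in seq_len(n)) {
    F[j, ] <- extract_features(beats$X[j, ], wavelet, target_len)
  }
  list(X = F, label = beats$label, r_index = beats$r_index)
}

#' Write a feature matrix as CSV
#'
#' Columns `f1..f25,label,record,r_index` (0-based r_index).
#'
#' @param features Result of [extract_feature_matrix].
#' @param path Output path.
#' @param record Record id stored per row.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path, record = "record") {
  df <- as.data.frame(features$X)
  df$label <- features$label
  df$record <- record
  df$r_index <- features$r_index
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
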