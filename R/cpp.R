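#' Framing configuration
#'
#' Frames of 1,024 samples with a hop of 128 samples (87.5% overlap) and a
#' Hamming analysis window — at 16 kHz each frame spans 64 ms and consecutive
#' frames are 8 ms apart.
#'
#' @param frame_len frame length in samples.
#' @param hop hop (frame advance) in samples; `0 < hop <= frame_len`.
#' @param window_kind `"hamming"` (default) or `"hanning"`.
#' @return An object of class `framing_config`.
#' @export
framing_config <- function(frame_len = 1024, hop = 128, window_kind = "hamming") {
  if (!is_count(frame_len) || frame_len < 2) stop_input("frame_len must be an integer >= 2")
  if (!is_count(hop) || hop < 1 || hop > frame_len) {
    stop_input("hop must satisfy 0 < hop <= frame_len")
  }
  window_kind <- match.arg(window_kind, c("hamming", "hanning"))
  structure(list(frame_len = as.integer(frame_len), hop = as.integer(hop),
                 window_kind = window_kind),
            class = "framing_config")
}

#' Cepstral analysis configuration
#'
#' Parameters of the smoothed cepstral-peak-prominence measure: the quefrency
#' search band `[tmin, tmax]` (in samples; 22–400 at 16 kHz corresponds to
#' fundamental frequencies of roughly 727 Hz down to 40 Hz, covering child
#' voices), the lengths of the two unit-sum Hamming-shaped FIR smoothers
#' (cepstral direction `smooth_len_cepstral`, temporal direction
#' `smooth_len_temporal`; 7 taps at the default hop give a 56 ms temporal
#' window), and a positive floor applied to spectral magnitudes before the
#' logarithm so silent frames stay finite.
#'
#' @param smooth_len_cepstral taps of the quefrency-direction smoother.
#' @param tmin,tmax quefrency band bounds in samples, `3 <= tmin < tmax`.
#' @param smooth_len_temporal taps of the frame-direction smoother.
#' @param log_floor positive floor for log-magnitude.
#' @return An object of class `cepstral_config`.
#' @export
cepstral_config <- function(smooth_len_cepstral = 7, tmin = 22, tmax = 400,
                            smooth_len_temporal = 7, log_floor = 1e-10) {
  if (!is_count(smooth_len_cepstral) || smooth_len_cepstral < 1) {
    stop_input("smooth_len_cepstral must be an integer >= 1")
  }
  if (!is_count(smooth_len_temporal) || smooth_len_temporal < 1) {
    stop_input("smooth_len_temporal must be an integer >= 1")
  }
  if (!is_count(tmin) || !is_count(tmax) || tmin < 3 || tmin >= tmax) {
    stop_input("quefrency band must satisfy 3 <= tmin < tmax")
  }
  if (!is.numeric(log_floor) || log_floor <= 0) stop_input("log_floor must be > 0")
  structure(list(smooth_len_cepstral = as.integer(smooth_len_cepstral),
                 tmin = as.integer(tmin), tmax = as.integer(tmax),
                 smooth_len_temporal = as.integer(smooth_len_temporal),
                 log_floor = log_floor),
            class = "cepstral_config")
}

analysis_window <- function(cfg) {
  switch(cfg$window_kind,
         hamming = signal::hamming(cfg$frame_len),
         hanning = signal::hanning(cfg$frame_len))
}

#' Segment a signal into overlapping frames
#'
#' Frame `i` (0-based) covers sample indices `[i * hop, i * hop + frame_len)`;
#' trailing samples that do not fill a complete frame are discarded and no
#' padding is applied.
#'
#' @param signal an [audio_signal()].
#' @param cfg a [framing_config()].
#' @return Numeric matrix, one frame per row (`n_frames x frame_len`).
#' @export
frame_signal <- function(signal, cfg = framing_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  n <- length(x)
  if (n < cfg$frame_len) {
    stop_input("signal too short to frame: %d samples, minimum is frame_len = %d",
               n, cfg$frame_len)
  }
  n_frames <- (n - cfg$frame_len) %/% cfg$hop + 1L
  starts <- (seq_len(n_frames) - 1L) * cfg$hop
  idx <- outer(seq_len(cfg$frame_len), starts, `+`)  # frame_len x n_frames
  t(matrix(x[idx], nrow = cfg$frame_len))
}

#' Real cepstrum of one frame
#'
#' The frame is multiplied sample-by-sample by the analysis window; the
#' cepstrum is the real part of the inverse FFT of the natural log of the
#' magnitude spectrum, with magnitudes floored at `log_floor` so all-silence
#' frames do not produce `-Inf`.
#'
#' @param frame numeric vector of length `cfg$frame_len`.
#' @param cfg a [framing_config()].
#' @param ccfg a [cepstral_config()].
#' @return Numeric vector of cepstral coefficients indexed by quefrency
#'   (element 1 = quefrency 0 samples); same length as the frame.
#' @export
compute_cepstrum <- function(frame, cfg = framing_config(),
                             ccfg = cepstral_config()) {
  if (length(frame) != cfg$frame_len) {
    stop_input("frame length %d does not match frame_len %d",
               length(frame), cfg$frame_len)
  }
  if (!all(is.finite(frame))) stop_input("frame contains non-finite values")
  w <- analysis_window(cfg)
  spec <- stats::fft(frame * w)
  logmag <- log(pmax(Mod(spec), ccfg$log_floor))
  Re(stats::fft(logmag, inverse = TRUE)) / length(logmag)
}

# Unit-sum Hamming-shaped FIR coefficients.
hamming_fir <- function(l) {
  if (l == 1L) return(1)
  a <- signal::hamming(l)
  a / sum(a)
}

# Causal FIR along a vector: y[n] = sum_{i=0}^{l-1} a_i x[n-i]. At the leading
# edge (n < l) only the available taps are used, renormalized to unit sum so
# constants are preserved everywhere.
causal_fir <- function(x, l) {
  n <- length(x)
  if (n == 0L) return(x)
  a <- hamming_fir(l)
  y <- as.numeric(stats::filter(x, a, method = "convolution", sides = 1))
  for (k in seq_len(min(l - 1L, n))) {
    ak <- a[seq_len(k)]
    y[k] <- sum(ak * x[k:1]) / sum(ak)
  }
  y
}

#' Smooth a cepstrum frame along the quefrency axis
#'
#' Causal unit-sum Hamming-shaped FIR of `smooth_len_cepstral` taps, applied
#' to suppress spurious cepstral values while preserving true peaks.
#'
#' @param cep numeric cepstrum vector.
#' @param ccfg a [cepstral_config()].
#' @return Smoothed cepstrum, same length.
#' @export
smooth_cepstrum <- function(cep, ccfg = cepstral_config()) {
  if (!all(is.finite(cep))) stop_input("cepstrum contains non-finite values")
  causal_fir(cep, ccfg$smooth_len_cepstral)
}

#' Cepstral peak prominence of one smoothed cepstrum frame
#'
#' The cepstrum is restricted to quefrencies `[tmin, tmax]` (inclusive, in
#' samples); CPP is the band maximum minus the mean of the remaining
#' `tmax - tmin` band values after removing that single maximum.
#'
#' @param cf smoothed cepstrum vector (quefrency 0 at element 1).
#' @param ccfg a [cepstral_config()].
#' @return A single non-negative number.
#' @export
cpp_of_frame <- function(cf, ccfg = cepstral_config()) {
  if (ccfg$tmax + 1L > length(cf)) {
    stop_input("quefrency band [%d, %d] exceeds cepstrum length %d",
               ccfg$tmin, ccfg$tmax, length(cf))
  }
  band <- cf[(ccfg$tmin:ccfg$tmax) + 1L]
  peak <- max(band)
  peak - (sum(band) - peak) / (ccfg$tmax - ccfg$tmin)
}

#' Band-limited cepstral argmax
#'
#' Location of the dominant cepstral peak within the `[tmin, tmax]` band, in
#' quefrency samples; for a periodic voice this estimates the fundamental
#' period (`rate / f0` samples).
#'
#' @param cf cepstrum vector (quefrency 0 at element 1).
#' @param ccfg a [cepstral_config()].
#' @return Quefrency of the band maximum, in samples.
#' @export
band_argmax <- function(cf, ccfg = cepstral_config()) {
  band <- cf[(ccfg$tmin:ccfg$tmax) + 1L]
  ccfg$tmin + which.max(band) - 1L
}

#' Smooth a per-frame CPP series along the frame axis
#'
#' Causal unit-sum Hamming-shaped FIR of `smooth_len_temporal` taps (56 ms at
#' the default hop/rate), reducing frame-to-frame noise while preserving the
#' large CPP variations characteristic of dysphonic voices.
#'
#' @param raw numeric vector of per-frame CPP values (may be empty).
#' @param ccfg a [cepstral_config()].
#' @return Smoothed series, same length.
#' @export
smooth_cpp_series <- function(raw, ccfg = cepstral_config()) {
  causal_fir(raw, ccfg$smooth_len_temporal)
}

#' Extract the smoothed CPP series of a recording
#'
#' Full chain: framing, windowed FFT log-magnitude cepstrum, quefrency-
#' direction smoothing, band-limited peak prominence, temporal smoothing.
#'
#' @param signal an [audio_signal()].
#' @param cfg a [framing_config()].
#' @param ccfg a [cepstral_config()].
#' @return An object of class `cpp_series`: list with `raw`, `smoothed`
#'   (equal-length numeric vectors, one value per frame) and `hop_seconds`.
#' @export
extract_cpp <- function(signal, cfg = framing_config(),
                        ccfg = cepstral_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  if (signal$rate != 16000) {
    warning(sprintf(paste0("sampling rate %g Hz differs from the 16 kHz the default ",
                           "quefrency band [%d, %d] was calibrated for (f0 range ",
                           "%.0f-%.0f Hz at this rate)"),
                    signal$rate, ccfg$tmin, ccfg$tmax,
                    signal$rate / ccfg$tmax, signal$rate / ccfg$tmin),
            call. = FALSE)
  }
  frames <- frame_signal(signal, cfg)
  raw <- vapply(seq_len(nrow(frames)), function(i) {
    cep <- compute_cepstrum(frames[i, ], cfg, ccfg)
    cpp_of_frame(smooth_cepstrum(cep, ccfg), ccfg)
  }, numeric(1))
  structure(list(raw = raw,
                 smoothed = smooth_cpp_series(raw, ccfg),
                 hop_seconds = cfg$hop / signal$rate),
            class = "cpp_series")
}

#' @export
print.cpp_series <- function(x, ...) {
  cat(sprintf("<cpp_series: %d frames, hop %.4f s, mean smoothed CPP %.4f>\n",
              length(x$raw), x$hop_seconds,
              if (length(x$smoothed)) mean(x$smoothed) else NA_real_))
  invisible(x)
}

#' @export
as.data.frame.cpp_series <- function(x, ...) {
  n <- length(x$raw)
  data.frame(frame_index = seq_len(n),
             time_s = (seq_len(n) - 1) * x$hop_seconds,
             cpp_raw = x$raw,
             cpp_smoothed = x$smoothed)
}

#' Write a CPP series as CSV
#'
#' Columns: `frame_index`, `time_s`, `cpp_raw`, `cpp_smoothed`.
#'
#' @param series a `cpp_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpp_csv <- function(series, path) {
  stopifnot(inherits(series, "cpp_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
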