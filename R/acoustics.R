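# Acoustic measurement of advertisement calls: band filtering, short-time
# spectra under the study's settings (512-sample Hann window, 50% overlap),
# call duration / peak frequency, and envelope-based note detection used
# with synthetic audio. WAV (RIFF PCM 16-bit) read/write is implemented
# directly with readBin/writeBin.

#' Construct an audio clip
#'
#' @param samples Numeric amplitude vector, nominally in `[-1, 1]`.
#' @param sample_rate_hz Sampling rate in Hz (default 48000, the rate the
#'   source recordings are converted to).
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate_hz = 48000) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    rlang::abort("`samples` must be finite numeric amplitudes")
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    rlang::abort("`sample_rate_hz` must be positive")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate_hz = sample_rate_hz),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf(
    "<audio_clip> %.3f s at %g Hz (%d samples)\n",
    length(x$samples) / x$sample_rate_hz, x$sample_rate_hz, length(x$samples)
  ))
  invisible(x)
}

clip_duration_s <- function(clip) length(clip$samples) / clip$sample_rate_hz

#' Read a mono 16-bit PCM WAV file
#'
#' Reads RIFF PCM WAV. Stereo input is downmixed to mono by channel mean,
#' with a warning. Samples are scaled to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) rlang::abort("not a RIFF file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) rlang::abort("not a WAVE file")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little"),
        n_channels = readBin(con, "integer", 1, size = 2, endian = "little"),
        sample_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits = readBin(con, "integer", 1, size = 2, endian = "little")
      )
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) rlang::abort("WAV file missing fmt or data chunk")
  if (fmt$audio_format != 1 || fmt$bits != 16) {
    rlang::abort("only 16-bit PCM WAV is supported")
  }
  x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
               signed = TRUE, endian = "little") / 32768
  if (fmt$n_channels > 1) {
    rlang::warn(sprintf("downmixing %d channels to mono by channel mean", fmt$n_channels))
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  audio_clip(x, fmt$sample_rate)
}

#' Write an audio clip as mono 16-bit PCM WAV
#'
#' @param clip An [audio_clip()]; samples are clipped to `[-1, 1]`.
#' @param path Output path.
#' @return `clip`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmin(1, pmax(-1, clip$samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(clip$sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(clip$sample_rate_hz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(clip)
}

#' Band-pass filter a clip
#'
#' Zero-phase band-pass (4th-order Butterworth applied forward and
#' backward with `signal::filtfilt`), used to reduce out-of-band
#' background noise before measurement. Zero-phase filtering preserves
#' note boundaries. Output length and rate equal the input's.
#'
#' @param clip An [audio_clip()].
#' @param low_hz,high_hz Passband edges, `0 <= low_hz < high_hz <=`
#'   Nyquist.
#' @return The filtered [audio_clip()].
#' @export
band_filter <- function(clip, low_hz, high_hz) {
  stopifnot(inherits(clip, "audio_clip"))
  nyq <- clip$sample_rate_hz / 2
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      low_hz < 0 || low_hz >= high_hz || high_hz > nyq) {
    rlang::abort("need 0 <= low_hz < high_hz <= Nyquist")
  }
  bf <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  audio_clip(signal::filtfilt(bf, clip$samples), clip$sample_rate_hz)
}

#' Short-time power spectrogram
#'
#' Hann-windowed magnitude-squared short-time Fourier transform at the
#' study's measurement settings: window size 512 samples with 50% overlap,
#' giving a bin width of `sample_rate / window_size` (93.75 Hz at 48 kHz).
#'
#' @param clip An [audio_clip()] at least one window long.
#' @param window_size Window length in samples (default 512).
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.5).
#' @return An object of class `spectrogram_grid`: list with `times` (frame
#'   centres, s), `freqs` (bin centres, Hz), and `power` (frames x bins,
#'   non-negative).
#' @export
spectrogram <- function(clip, window_size = 512, overlap = 0.5) {
  stopifnot(inherits(clip, "audio_clip"))
  n <- length(clip$samples)
  if (n < window_size) {
    rlang::abort(sprintf("clip (%d samples) shorter than one window (%d)", n, window_size))
  }
  hop <- round(window_size * (1 - overlap))
  sg <- signal::specgram(
    clip$samples, n = window_size, Fs = clip$sample_rate_hz,
    window = signal::hanning(window_size), overlap = window_size - hop
  )
  structure(
    list(
      times = as.numeric(sg$t) + window_size / (2 * clip$sample_rate_hz),
      freqs = as.numeric(sg$f),
      power = t(abs(sg$S)^2),
      window_size = window_size,
      hop = hop,
      sample_rate_hz = clip$sample_rate_hz
    ),
    class = "spectrogram_grid"
  )
}

#' @export
print.spectrogram_grid <- function(x, ...) {
  cat(sprintf(
    "<spectrogram_grid> %d frames x %d bins, bin width %.4g Hz\n",
    nrow(x$power), ncol(x$power), x$freqs[2] - x$freqs[1]
  ))
  invisible(x)
}

#' Measure duration and peak frequency of one call
#'
#' Duration is the selection length (`end_s - start_s`). Peak frequency is
#' the frequency of the maximum of the selection's mean power spectrum
#' within the given band: power spectra are averaged over all frames in
#' the selection before taking the argmax, which is robust to single-frame
#' noise. The measurement is invariant to uniform gain scaling.
#'
#' @param clip An [audio_clip()].
#' @param start_s,end_s Selection bounds in seconds, within the clip.
#' @param band Length-2 numeric, the frequency band (Hz) searched for the
#'   peak.
#' @param window_size,overlap Spectrogram settings (defaults 512 and 0.5).
#' @return One-row tibble: `duration_s`, `peak_freq_hz`.
#' @export
measure_call <- function(clip, start_s, end_s, band,
                         window_size = 512, overlap = 0.5) {
  stopifnot(inherits(clip, "audio_clip"))
  len <- clip_duration_s(clip)
  if (!is.numeric(start_s) || !is.numeric(end_s) ||
      start_s < 0 || end_s <= start_s || end_s > len + 1e-9) {
    rlang::abort("selection must satisfy 0 <= start_s < end_s <= clip length")
  }
  fs <- clip$sample_rate_hz
  i0 <- max(1L, floor(start_s * fs) + 1L)
  i1 <- min(length(clip$samples), ceiling(end_s * fs))
  seg <- clip$samples[i0:i1]
  if (length(seg) < window_size) {
    # pad the tail so short selections still yield one full window
    seg <- c(seg, numeric(window_size - length(seg)))
  }
  sg <- spectrogram(audio_clip(seg, fs), window_size, overlap)
  mean_spec <- colMeans(sg$power)
  in_band <- sg$freqs >= band[1] & sg$freqs <= band[2]
  if (!any(in_band)) rlang::abort("band contains no spectrogram bins")
  spec <- mean_spec[in_band]
  if (max(spec) <= 0) {
    rlang::abort("selection is silent; peak frequency undefined",
                 class = "callvar_silent_selection")
  }
  tibble::tibble(
    duration_s = end_s - start_s,
    peak_freq_hz = sg$freqs[in_band][which.max(spec)]
  )
}

#' Measure several selections of a clip
#'
#' @param clip An [audio_clip()].
#' @param selections Tibble with columns `start_s`, `end_s`.
#' @param band Frequency band (Hz) searched for the peak.
#' @param ... Passed to [measure_call()].
#' @return Tibble with one row per selection: `start_s`, `end_s`,
#'   `duration_s`, `peak_freq_hz`.
#' @export
measure_calls <- function(clip, selections, band, ...) {
  measured <- purrr::pmap(
    list(selections$start_s, selections$end_s),
    function(s, e) measure_call(clip, s, e, band, ...)
  ) |>
    purrr::list_rbind()
  dplyr::bind_cols(selections[c("start_s", "end_s")], measured)
}

#' Detect notes by envelope thresholding
#'
#' Replaces the study's manual call selection for synthetic audio: the
#' absolute amplitude is smoothed with a moving average (default 10 ms),
#' and maximal runs where the smoothed envelope exceeds the clip's peak
#' envelope offset by `threshold_db` are returned as selections. Runs
#' separated by less than `min_gap_s` are merged.
#'
#' @param clip An [audio_clip()].
#' @param threshold_db Threshold relative to the peak envelope, in dB
#'   (default -20).
#' @param min_gap_s Gaps shorter than this are merged (default 0.05 s).
#' @param smooth_s Envelope smoothing width in seconds (default 0.010).
#' @return Tibble of selections (`start_s`, `end_s`) in time order; empty
#'   for a silent clip.
#' @export
detect_notes <- function(clip, threshold_db = -20, min_gap_s = 0.05, smooth_s = 0.010) {
  stopifnot(inherits(clip, "audio_clip"))
  fs <- clip$sample_rate_hz
  w <- max(1L, round(smooth_s * fs))
  env <- as.numeric(stats::filter(abs(clip$samples), rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  peak <- max(env)
  empty <- tibble::tibble(start_s = numeric(), end_s = numeric())
  if (peak <= 0) return(empty)
  above <- env >= peak * 10^(threshold_db / 20)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble::tibble(
    start_s = (starts[r$values] - 1) / fs,
    end_s = ends[r$values] / fs
  )
  if (nrow(runs) == 0) return(empty)
  # merge runs separated by < min_gap_s
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs$start_s[i] - last$end_s < min_gap_s) {
        merged[[length(merged)]]$end_s <- runs$end_s[i]
      } else {
        merged[[length(merged) + 1]] <- runs[i, ]
      }
    }
  }
  purrr::list_rbind(merged)
}
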