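#' Construct a call recording
#'
#' A `call_recording` is the package's light-weight audio container: a mono
#' sample vector in `[-1, 1]`, its sampling rate, and optional caller
#' metadata (individual id, age, sex, call type) plus, for bellows, a
#' segment table labelling inhalation and exhalation phases.
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param metadata Named list of caller metadata (`individual`, `age`,
#'   `sex`, `call_type`, ...).
#' @param segments Optional tibble with columns `start`, `end` (seconds) and
#'   `label` (`"inhalation"` / `"exhalation"`) for bellows.
#' @return A `call_recording` object.
#' @export
call_recording <- function(samples, sample_rate = 44100, metadata = list(),
                           segments = NULL) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  structure(
    list(
      samples = as.numeric(samples),
      sample_rate = sample_rate,
      metadata = metadata,
      segments = segments
    ),
    class = "call_recording"
  )
}

#' @export
print.call_recording <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate
  cat(sprintf(
    "<call_recording> %.3f s @ %d Hz (%d samples), peak %.3f\n",
    dur, as.integer(x$sample_rate), length(x$samples),
    max(abs(x$samples))
  ))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata),
      vapply(x$metadata, function(v) paste(format(v), collapse = ","), ""),
      sep = "=", collapse = "; "
    ), "\n")
  }
  if (!is.null(x$segments)) {
    cat("  segments:", nrow(x$segments), "labelled\n")
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `call_recording`.
#' @return Length of the sample vector divided by the sampling rate.
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$sample_rate

#' Read a PCM WAV file
#'
#' Reads 16-bit (or 8/32-bit integer) PCM WAV. Samples are rescaled to
#' `[-1, 1]`; stereo files are averaged to mono; the sampling rate is
#' preserved.
#'
#' @param path Path to a WAV file.
#' @param metadata Optional metadata list attached to the result.
#' @return A [call_recording()].
#' @export
read_wav <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAV file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
          signed = FALSE, endian = "little"
        ),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, 2,
          signed = FALSE, endian = "little"
        ),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4,
          endian = "little"
        ),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2,
          signed = FALSE, endian = "little"
        )
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size) stop("truncated WAV data chunk: ", path)
    } else {
      skip <- readBin(con, "raw", size)
      if (length(skip) < size) break
    }
    if (size %% 2 == 1) readBin(con, "raw", 1) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing chunk): ", path)
  if (fmt$audio_format != 1L) stop("unsupported WAV encoding (not PCM): ", path)

  bytes_per <- fmt$bits / 8
  n <- length(data_raw) %/% bytes_per
  x <- switch(as.character(fmt$bits),
    "8" = (readBin(data_raw, "integer", n, 1, signed = FALSE) - 128) / 128,
    "16" = readBin(data_raw, "integer", n, 2, signed = TRUE, endian = "little") / 32768,
    "32" = readBin(data_raw, "integer", n, 4, signed = TRUE, endian = "little") / 2147483648,
    stop("unsupported PCM bit depth: ", fmt$bits)
  )
  if (fmt$n_channels > 1) {
    x <- matrix(x, nrow = fmt$n_channels)
    x <- colMeans(x)
  }
  call_recording(x, fmt$sample_rate, metadata = metadata)
}

#' Write a recording as 16-bit PCM WAV
#'
#' @param rec A [call_recording()]; samples are clipped to `[-1, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  x <- pmin(1, pmax(-1, rec$samples))
  pcm <- pmin(32767L, as.integer(round(x * 32768)))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # PCM
  writeBin(1L, con, size = 2, endian = "little") # mono
  sr <- as.integer(rec$sample_rate)
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little") # block align
  writeBin(16L, con, size = 2, endian = "little") # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Peak-normalize a recording
#'
#' Rescales so that the maximum absolute sample equals 1 (pure gain; the
#' waveform shape is preserved).
#'
#' @param rec A [call_recording()].
#' @return The normalized recording.
#' @export
normalize_peak <- function(rec) {
  peak <- max(abs(rec$samples))
  if (peak == 0) stop("cannot normalize silence (all-zero samples)")
  rec$samples <- rec$samples / peak
  rec
}

# Resample audio to a new rate in the frequency domain (brick-wall
# anti-aliasing, no interpolation noise floor -- formant analysis needs the
# full dynamic range of the band to survive the rate change).
resample_audio <- function(x, fs_in, fs_out) {
  if (fs_out == fs_in) return(x)
  n <- length(x)
  # pad to a multiple of the rate denominator times a power of two, so both
  # FFT lengths factor into small primes and the output length is exact
  g <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  d <- g(fs_in, fs_out)
  p <- fs_out / d
  q <- fs_in / d
  m <- stats::nextn(ceiling(n / q), 2)
  n_pad <- q * m
  n_out_pad <- p * m
  X <- stats::fft(c(x, rep(0, n_pad - n)))
  keep <- floor(min(n_pad, n_out_pad) / 2)
  Y <- complex(length.out = n_out_pad)
  Y[seq_len(keep + 1)] <- X[seq_len(keep + 1)]
  if (keep > 1) {
    Y[(n_out_pad - keep + 2):n_out_pad] <- X[(n_pad - keep + 2):n_pad]
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n_pad
  y[seq_len(max(2L, round(n * fs_out / fs_in)))]
}

# Extract the concatenated samples for one bellow segment label.
segment_samples <- function(rec, label) {
  if (is.null(rec$segments)) return(rec$samples)
  seg <- rec$segments[rec$segments$label == label, , drop = FALSE]
  if (nrow(seg) == 0) return(numeric(0))
  idx <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    i0 <- max(1L, floor(seg$start[i] * rec$sample_rate) + 1L)
    i1 <- min(length(rec$samples), ceiling(seg$end[i] * rec$sample_rate))
    seq.int(i0, i1)
  }))
  rec$samples[idx]
}
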