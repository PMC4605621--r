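#' Per-call-type analysis presets
#'
#' Measurement settings per call type: bellows use an F0 search range of
#' 10-100 Hz and formant analysis up to 3000 Hz (6 formants); tonal
#' rejection calls use an F0 range of 180-2500 Hz and no formant analysis
#' (their high F0 undersamples the spectral envelope); snarls have no F0
#' analysis and formants up to 7000 Hz.
#'
#' @param call_type `"bellow"`, `"snarl"`, or `"tonal_rejection"`.
#' @return A list of preset values.
#' @export
call_type_preset <- function(call_type) {
  switch(call_type,
    bellow = list(
      f0_range = c(10, 100), octave_cost = 0.02, voicing_threshold = 0.30,
      max_formant = 3000, n_formants = 6,
      chaos_range = c(10, 100), nlp = "chaos"
    ),
    tonal_rejection = list(
      f0_range = c(180, 2500), octave_cost = 0.12, voicing_threshold = 0.45,
      max_formant = NA, n_formants = 0,
      chaos_range = c(180, 2500), nlp = c("chaos", "subharmonics", "biphonation")
    ),
    snarl = list(
      f0_range = NULL, octave_cost = NA,
      max_formant = 7000, n_formants = 6,
      chaos_range = c(50, 400), nlp = "chaos"
    ),
    stop("unknown call type: ", call_type)
  )
}

#' Extract the full acoustic feature vector from a recording
#'
#' Dispatches the per-call-type presets ([call_type_preset()]): duration is
#' always measured from the waveform; bellows get F0 statistics (measured
#' on their inhalation segments), formants, formant spacing and chaos
#' detection; tonal rejection calls get F0 statistics and all three
#' nonlinear-phenomena detectors; snarls get formants, formant spacing and
#' chaos. Measures inapplicable to a call type are `NA` in the result.
#'
#' @param rec A [call_recording()]. For bellows, inhalation segments must
#'   be labelled (`rec$segments`), as produced by [synthesize_call()]; a
#'   recording without segment labels is treated as a single inhalation
#'   section.
#' @param call_type `"bellow"`, `"snarl"`, or `"tonal_rejection"`;
#'   defaults to the recording's metadata.
#' @return A one-row feature tibble with metadata columns (`individual`,
#'   `age`, `sex`, `call_type`) and the measure columns `duration_s` ..
#'   `delta_f_hz`.
#' @export
extract_features <- function(rec, call_type = rec$metadata$call_type) {
  if (is.null(call_type)) stop("call_type is required")
  preset <- call_type_preset(call_type)
  row <- stats::setNames(
    as.list(rep(NA_real_, length(feature_columns))), feature_columns
  )
  row$duration_s <- measure_duration(rec)

  # the recording analysed for source/filter features: inhalation sections
  # for bellows, the whole call otherwise
  ana <- rec
  if (call_type == "bellow") {
    inh <- segment_samples(rec, "inhalation")
    if (length(inh) == 0) stop("bellow has no inhalation segments")
    ana <- call_recording(inh, rec$sample_rate, metadata = rec$metadata)
  }

  contour <- NULL
  if (!is.null(preset$f0_range)) {
    oc <- preset$octave_cost
    if (call_type == "bellow" && !is.null(rec$segments)) {
      # track each inhalation segment separately (correlation frames must
      # not straddle the splice between segments) and stack the contours
      # with an unvoiced separator so sumvar never spans a splice
      segs <- rec$segments[rec$segments$label == "inhalation", , drop = FALSE]
      parts <- list()
      for (k in seq_len(nrow(segs))) {
        i0 <- max(1L, floor(segs$start[k] * rec$sample_rate) + 1L)
        i1 <- min(length(rec$samples), ceiling(segs$end[k] * rec$sample_rate))
        seg_rec <- call_recording(rec$samples[i0:i1], rec$sample_rate)
        part <- tryCatch(
          track_f0(seg_rec, preset$f0_range[1], preset$f0_range[2],
            octave_cost = oc, voicing_threshold = preset$voicing_threshold),
          error = function(e) NULL
        )
        if (is.null(part)) next
        parts[[length(parts) + 1]] <- part
        parts[[length(parts) + 1]] <-
          tibble::tibble(time = max(part$time) + 0.01, f0 = NA_real_, voiced = FALSE)
      }
      if (length(parts) == 0) stop("no inhalation segment long enough to track")
      contour <- dplyr::bind_rows(parts)
      contour$time <- seq(0, by = 0.01, length.out = nrow(contour))
      class(contour) <- c("f0_contour", class(contour))
      attr(contour, "time_step") <- 0.01
    } else {
      contour <- track_f0(ana, preset$f0_range[1], preset$f0_range[2],
        octave_cost = oc, voicing_threshold = preset$voicing_threshold)
    }
    st <- f0_statistics(contour)
    row$mean_f0_hz <- st$mean_f0
    row$min_f0_hz <- st$min_f0
    row$max_f0_hz <- st$max_f0
    row$f0_sumvar_hz <- st$f0_sumvar
  }

  if (preset$n_formants > 0) {
    trk <- measure_formants(ana, preset$max_formant, preset$n_formants)
    means <- attr(trk, "means")
    row[sprintf("f%d_hz", seq_len(preset$n_formants))] <- as.list(means)
    row$delta_f_hz <- estimate_delta_f(means)
  }

  ch <- detect_chaos(rec, preset$chaos_range[1], preset$chaos_range[2])
  row$chaos <- as.numeric(ch$chaos)
  sub_ratio <- NA_character_
  if ("subharmonics" %in% preset$nlp) {
    sh <- detect_subharmonics(rec, contour)
    row$subharmonics <- as.numeric(sh$subharmonics)
    sub_ratio <- sh$ratio
  }
  if ("biphonation" %in% preset$nlp) {
    # a detected subharmonic division also modulates the envelope; its
    # ripple frequency is excluded when locating G0
    excl <- if (!is.na(sub_ratio)) {
      c(1, 2) * row$mean_f0_hz / switch(sub_ratio, "1/2" = 2, "1/3" = 3)
    }
    bp <- detect_biphonation(rec, f0_hint = row$mean_f0_hz, exclude_hz = excl)
    row$biphonation <- as.numeric(bp$biphonation)
    row$g0_hz <- bp$g0
  }

  md <- rec$metadata
  tibble::as_tibble(c(
    list(
      individual = md$individual %||% NA_character_,
      age = md$age %||% NA_real_,
      sex = md$sex %||% NA_character_,
      call_type = call_type
    ),
    row
  ))
}

#' Short-time spectrogram
#'
#' Gaussian-windowed short-time Fourier magnitudes in dB relative to the
#' global maximum, clipped to the top `dynamic_range` dB.
#'
#' @param rec A [call_recording()].
#' @param window Window length in seconds (default 0.03).
#' @param time_step Hop in seconds (default 0.002).
#' @param freq_step Target frequency resolution in Hz (default 20; sets the
#'   FFT length).
#' @param dynamic_range Displayed dynamic range in dB (default 40).
#' @return A `koala_spectrogram`: list with `time`, `freq`, and the dB
#'   matrix `db` (frequency x time).
#' @export
spectrogram <- function(rec, window = 0.03, time_step = 0.002,
                        freq_step = 20, dynamic_range = 40) {
  fs <- rec$sample_rate
  x <- rec$samples
  win <- round(window * fs)
  if (win > length(x)) stop("window longer than signal")
  hop <- max(1L, round(time_step * fs))
  n_half <- (win - 1) / 2
  w <- exp(-0.5 * ((seq_len(win) - 1 - n_half) / (win / 6))^2)
  nfft <- stats::nextn(max(win, round(fs / freq_step)), 2)
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  mag <- vapply(starts, function(s) {
    fr <- x[s:(s + win - 1L)] * w
    Mod(stats::fft(c(fr, rep(0, nfft - win))))[seq_len(nfft %/% 2)]
  }, numeric(nfft %/% 2))
  db <- 20 * log10(mag / max(mag, 1e-300) + 1e-300)
  db <- pmax(db, -dynamic_range)
  structure(
    list(
      time = (starts - 1 + win / 2) / fs,
      freq = (seq_len(nfft %/% 2) - 1) * fs / nfft,
      db = db
    ),
    class = "koala_spectrogram"
  )
}

#' @export
print.koala_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<koala_spectrogram> %d frames x %d bins, %.3f-%.3f s, 0-%.0f Hz\n",
    ncol(x$db), nrow(x$db), min(x$time), max(x$time), max(x$freq)
  ))
  invisible(x)
}
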