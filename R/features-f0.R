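#' Measure call duration from the waveform
#'
#' Duration is the span from the first to the last analysis frame whose
#' short-term RMS exceeds a threshold relative to the call's peak RMS
#' (default -25 dB). Interior quiet gaps do not affect the span.
#'
#' @param rec A [call_recording()].
#' @param threshold_db Threshold in dB relative to the peak frame RMS.
#' @param frame_s RMS frame length in seconds (default 5 ms).
#' @return Duration in seconds, measured between the centres of the first
#'   and last frames above threshold.
#' @export
measure_duration <- function(rec, threshold_db = -25, frame_s = 0.005) {
  x <- rec$samples
  if (length(x) == 0 || all(x == 0)) stop("no call detected (silent input)")
  fs <- rec$sample_rate
  nf <- max(1L, round(frame_s * fs))
  hop <- max(1L, nf %/% 2)
  starts <- seq(1L, max(1L, length(x) - nf + 1L), by = hop)
  rms <- vapply(starts, function(s) {
    sqrt(mean(x[s:(s + nf - 1L)]^2))
  }, numeric(1))
  peak <- max(rms)
  if (peak == 0) stop("no call detected (silent input)")
  thr <- peak * 10^(threshold_db / 20)
  above <- which(rms > thr)
  if (length(above) == 0) stop("no call detected (all frames below threshold)")
  (starts[max(above)] - starts[min(above)] + hop) / fs
}

#' Track the fundamental frequency contour
#'
#' Frame-wise normalized cross-correlation peak picking within
#' `[f0_min, f0_max]`: the signal is decimated to a rate suited to the
#' search range, and each frame correlates a one-period-of-`f0_min` window
#' with its lagged continuation (so rapidly swept contours still correlate
#' period to period). Candidate lags are local maxima of the normalized
#' cross-correlation, scored with a small octave cost favouring the
#' higher-frequency interpretation so that true fundamentals are not
#' displaced by subharmonic or amplitude-modulation lags; the final track
#' is the best-scoring candidate path under an octave-jump transition cost
#' (dynamic programming). Frames whose best normalized peak falls below
#' `voicing_threshold` are marked unvoiced. Remaining voiced outliers
#' relative to the running median of neighbouring frames (ratio >= 1.8)
#' are re-snapped to the candidate closest to the median.
#'
#' @param rec A [call_recording()].
#' @param f0_min,f0_max Search range in Hz.
#' @param time_step Frame step in seconds (default 0.01).
#' @param voicing_threshold Minimum normalized autocorrelation peak for a
#'   frame to count as voiced (default 0.45).
#' @param octave_cost Score penalty per octave below `f0_max` (default
#'   0.12), discouraging subharmonic and amplitude-modulation lags whose
#'   raw autocorrelation can slightly exceed the true period's.
#' @return An `f0_contour`: a tibble with columns `time` (s), `f0` (Hz,
#'   `NA` when unvoiced) and `voiced`.
#' @export
track_f0 <- function(rec, f0_min = 180, f0_max = 2500, time_step = 0.01,
                     voicing_threshold = 0.45, octave_cost = 0.12) {
  if (f0_min <= 0 || f0_min >= f0_max) stop("need 0 < f0_min < f0_max")
  if (f0_max >= rec$sample_rate / 2) stop("f0_max must be below Nyquist")
  fs0 <- rec$sample_rate
  fs <- min(fs0, max(2000, 8 * f0_max))
  x <- resample_audio(rec$samples, fs0, fs)
  # band-limit to the fundamental's band: removes resonance ringing that
  # would otherwise offer spurious correlation lags, and broadens the
  # correlation peaks of pulse trains so swept contours stay trackable
  lp <- 1.5 * f0_max
  if (lp < 0.45 * fs) {
    x <- signal::filtfilt(signal::butter(4, lp / (fs / 2)), x)
  }

  L <- round(2 * fs / f0_min) # correlation window: two periods of the floor
  lag_min <- max(2L, floor(fs / f0_max))
  lag_max <- ceiling(fs / f0_min)
  seg_len <- L + lag_max
  if (seg_len > length(x)) stop("search range infeasible: window longer than signal")
  hop <- max(1L, round(time_step * fs))

  starts <- seq(1L, length(x) - seg_len + 1L, by = hop)
  nfft <- stats::nextn(seg_len + L, 2)
  res <- lapply(starts, function(s) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- seg - mean(seg)
    x1 <- seg[seq_len(L)]
    e1 <- sum(x1^2)
    if (e1 < 1e-12) {
      return(list(f0 = NA_real_, voiced = FALSE, cand = numeric(0)))
    }
    # normalized cross-correlation of the leading window with its lagged
    # continuation, for all lags at once via FFT
    num <- Re(stats::fft(
      Conj(stats::fft(c(x1, rep(0, nfft - L)))) *
        stats::fft(c(seg, rep(0, nfft - seg_len))),
      inverse = TRUE
    ))[seq_len(lag_max + 1L)] / nfft
    csum <- cumsum(seg^2)
    e2 <- csum[L:(L + lag_max)] - c(0, csum[seq_len(lag_max)])
    r <- num / sqrt(e1 * pmax(e2, 1e-20))
    # local maxima in the admissible lag range
    idx <- (lag_min + 1L):(lag_max + 1L) # r[k+1] is lag k
    rr <- r[idx]
    is_peak <- c(FALSE, diff(rr) > 0) & c(rev(diff(rev(rr)) > 0), FALSE)
    peaks <- which(is_peak)
    if (length(peaks) == 0) peaks <- which.max(rr)
    lags <- (idx[peaks] - 1L)
    strengths <- rr[peaks]
    # parabolic interpolation of each peak: both the lag and the peak
    # height (an integer-lag sample can sit well below the true peak when
    # the period is not a whole number of samples)
    lag_ref <- numeric(length(peaks))
    for (j in seq_along(peaks)) {
      k <- idx[peaks[j]]
      if (k <= 2 || k >= length(r)) {
        lag_ref[j] <- lags[j]
        next
      }
      denom <- r[k - 1] - 2 * r[k] + r[k + 1]
      if (abs(denom) < 1e-12) {
        lag_ref[j] <- lags[j]
        next
      }
      delta <- 0.5 * (r[k - 1] - r[k + 1]) / denom
      lag_ref[j] <- (k - 1) + delta
      strengths[j] <- r[k] - 0.25 * (r[k - 1] - r[k + 1]) * delta
    }
    freqs <- fs / lag_ref
    ok <- freqs >= f0_min & freqs <= f0_max
    if (!any(ok)) {
      return(list(f0 = NA_real_, voiced = FALSE, cand = numeric(0)))
    }
    freqs <- freqs[ok]
    strengths <- strengths[ok]
    score <- strengths - octave_cost * log2(f0_max / freqs)
    best <- which.max(score)
    keep <- order(score, decreasing = TRUE)[seq_len(min(4, length(freqs)))]
    list(
      f0 = freqs[best],
      voiced = strengths[best] >= voicing_threshold,
      strength = strengths[best],
      cand = freqs[keep],
      cand_score = score[keep]
    )
  })

  voiced <- vapply(res, function(z) isTRUE(z$voiced), logical(1))
  # candidate path choice by dynamic programming: maximize summed candidate
  # scores minus a cost per octave jumped between consecutive voiced
  # frames, so a run of subharmonic-lag candidates cannot capture the track
  f0 <- rep(NA_real_, length(res))
  vi0 <- which(voiced)
  if (length(vi0) > 0) {
    jump_cost <- 0.35
    prev <- NULL
    back <- vector("list", length(vi0))
    dp <- NULL
    for (j in seq_along(vi0)) {
      z <- res[[vi0[j]]]
      emit <- z$cand_score
      if (is.null(prev)) {
        dp <- emit
        back[[j]] <- rep(0L, length(emit))
      } else {
        trans <- outer(prev$cand, z$cand, function(a, b) abs(log2(b / a)))
        tot <- sweep(-jump_cost * trans, 1, dp, "+")
        back[[j]] <- max.col(t(tot), ties.method = "first")
        dp <- apply(tot, 2, max) + emit
      }
      prev <- z
    }
    pick <- which.max(dp)
    for (j in rev(seq_along(vi0))) {
      f0[vi0[j]] <- res[[vi0[j]]]$cand[pick]
      if (j > 1) pick <- back[[j]][pick]
    }
  }

  # octave-jump correction against the running median of voiced neighbours
  vi <- which(voiced)
  if (length(vi) >= 3) {
    f0v <- f0[vi]
    for (j in seq_along(vi)) {
      nb <- setdiff(max(1, j - 2):min(length(vi), j + 2), j)
      med <- stats::median(f0v[nb])
      ratio <- max(f0v[j] / med, med / f0v[j])
      if (is.finite(ratio) && ratio >= 1.8) {
        cand <- res[[vi[j]]]$cand
        if (length(cand) > 0) {
          f0[vi[j]] <- cand[which.min(abs(log(cand / med)))]
        }
      }
    }
  }

  # light running-median pass over voiced runs: removes single-frame
  # estimation jitter without flattening ramps or modulation
  vi <- which(voiced)
  if (length(vi) >= 3) {
    f0v <- f0[vi]
    sm <- f0v
    inner <- 2:(length(f0v) - 1)
    consec <- diff(vi) == 1L
    ok <- consec[inner - 1] & consec[inner]
    sm[inner[ok]] <- vapply(
      inner[ok],
      function(j) stats::median(f0v[(j - 1):(j + 1)]),
      numeric(1)
    )
    f0[vi] <- sm
  }

  out <- tibble::tibble(
    time = (starts - 1L + L / 2) / fs,
    f0 = f0,
    voiced = voiced
  )
  class(out) <- c("f0_contour", class(out))
  attr(out, "f0_range") <- c(f0_min, f0_max)
  attr(out, "time_step") <- time_step
  out
}

#' Summary statistics of an F0 contour
#'
#' Mean, minimum and maximum F0 over voiced frames, and `f0_sumvar`: the
#' cumulative absolute inter-frame F0 change divided by the voiced time
#' span (Hz per second of voiced signal) -- the amount of F0 modulation per
#' second.
#'
#' @param contour An `f0_contour` from [track_f0()].
#' @return A one-row tibble: `mean_f0`, `min_f0`, `max_f0`, `f0_sumvar`,
#'   `n_voiced`.
#' @export
f0_statistics <- function(contour) {
  vi <- which(contour$voiced)
  f0 <- contour$f0[vi]
  if (length(f0) < 2) stop("need at least 2 voiced frames")
  step <- if (nrow(contour) > 1) mean(diff(contour$time)) else attr(contour, "time_step")
  # sumvar runs over consecutive voiced frames only (gaps contribute
  # neither change nor time)
  consec <- which(diff(vi) == 1L)
  if (length(consec) == 0) stop("no consecutive voiced frames for sumvar")
  sum_abs <- sum(abs(f0[consec + 1L] - f0[consec]))
  span <- length(consec) * step
  tibble::tibble(
    mean_f0 = mean(f0),
    min_f0 = min(f0),
    max_f0 = max(f0),
    f0_sumvar = sum_abs / span,
    n_voiced = length(f0)
  )
}
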