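# Frame-wise harmonics-to-noise ratio: the maximum unbiased normalized
# autocorrelation r within the periodicity search range, as
# 10*log10(r / (1 - r)). Periodic frames score high; noise (including
# resonance-coloured noise, whose autocorrelation decays with the
# resonance bandwidth) scores low at the lags of plausible F0 periods.
frame_hnr <- function(x, fs, f0_min, f0_max, window_s = NULL, hop_s = 0.01) {
  win <- round((window_s %||% (3 / f0_min)) * fs)
  hop <- max(1L, round(hop_s * fs))
  if (win > length(x)) win <- length(x)
  lag_min <- max(2L, floor(fs / f0_max))
  lag_max <- min(win - 2L, ceiling(fs / f0_min))
  starts <- seq(1L, max(1L, length(x) - win + 1L), by = hop)
  nfft <- stats::nextn(2L * win, 2)
  vapply(starts, function(s) {
    fr <- x[s:(min(length(x), s + win - 1L))]
    fr <- fr - mean(fr)
    if (sum(fr^2) < 1e-12) return(NA_real_)
    sp <- stats::fft(c(fr, rep(0, nfft - length(fr))))
    ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE))[seq_len(lag_max + 1L)]
    ac <- ac / (length(fr) - (seq_len(lag_max + 1L) - 1L))
    r <- ac[(lag_min + 1L):(lag_max + 1L)] / ac[1]
    rmax <- min(max(r), 1 - 1e-6)
    if (rmax <= 0) return(-60)
    10 * log10(rmax / (1 - rmax))
  }, numeric(1))
}

#' Detect deterministic chaos
#'
#' A call is flagged as containing deterministic chaos when the fraction of
#' analysis frames with a harmonics-to-noise ratio (HNR) below
#' `hnr_threshold_db` reaches `min_fraction`. The HNR is the maximum
#' normalized autocorrelation of the LPC-whitened frame within the
#' periodicity search range, expressed in dB.
#'
#' @param rec A [call_recording()].
#' @param f0_min,f0_max Periodicity search range in Hz.
#' @param hnr_threshold_db Frames below this HNR count as aperiodic
#'   (default 4 dB).
#' @param min_fraction Minimum fraction of aperiodic frames (default 0.2).
#' @return A list: `chaos` (flag), `fraction_aperiodic`, `n_frames`.
#' @export
detect_chaos <- function(rec, f0_min = 50, f0_max = 2500,
                         hnr_threshold_db = 4, min_fraction = 0.2) {
  fs <- min(rec$sample_rate, max(2000, 8 * f0_max))
  x <- resample_audio(rec$samples, rec$sample_rate, fs)
  hnr <- frame_hnr(x, fs, f0_min, f0_max)
  hnr <- hnr[!is.na(hnr)]
  if (length(hnr) == 0) stop("audio too short for chaos analysis")
  frac <- mean(hnr < hnr_threshold_db)
  list(
    chaos = frac >= min_fraction,
    fraction_aperiodic = frac,
    n_frames = length(hnr)
  )
}

#' Detect subharmonics and their ratio
#'
#' Looks for spectral components at integer fractional values of the
#' tracked F0 (F0/2, F0/3): in each voiced frame the magnitude spectrum is
#' probed at the expected inter-harmonic positions and compared against the
#' local spectral floor sampled between those positions. Subharmonics are
#' present when the excess reaches `threshold_db` in at least
#' `min_consecutive` consecutive voiced frames; the ratio reported is the
#' deepest division detected (1/3 before 1/2).
#'
#' @param rec A [call_recording()].
#' @param contour An `f0_contour` from [track_f0()]; tracked at the call's
#'   F0 preset.
#' @param threshold_db Required excess of inter-harmonic peaks over the
#'   local floor (default 10 dB).
#' @param min_consecutive Consecutive qualifying frames required (default 3).
#' @param window Spectral analysis window in seconds (default 0.05; long
#'   enough to separate inter-harmonic components from window leakage).
#' @param max_below_harmonic_db A qualifying inter-harmonic peak must also
#'   come within this many dB of its neighbouring harmonics (default 30),
#'   so spectral leakage over a near-silent floor cannot trigger detection.
#' @return A list: `subharmonics` (flag), `ratio` (`"1/2"`, `"1/3"` or
#'   `NA`), per-frame detail in `frames`.
#' @export
detect_subharmonics <- function(rec, contour, threshold_db = 10,
                                min_consecutive = 3, window = 0.05,
                                max_below_harmonic_db = 30) {
  fs <- rec$sample_rate
  x <- rec$samples
  win <- round(window * fs)
  if (win > length(x)) stop("audio shorter than the analysis window")
  n_half <- (win - 1) / 2
  w <- exp(-0.5 * ((seq_len(win) - 1 - n_half) / (win / 6))^2)
  nfft <- stats::nextn(4L * win, 2)
  freqs <- (seq_len(nfft %/% 2) - 1) * fs / nfft

  probe <- function(mag, f_target) {
    if (f_target <= 0 || f_target >= fs / 2) return(NA_real_)
    half <- max(2 * fs / nfft, 0.015 * f_target)
    sel <- which(freqs >= f_target - half & freqs <= f_target + half)
    if (length(sel) == 0) return(NA_real_)
    max(mag[sel])
  }

  voiced <- which(contour$voiced)
  if (length(voiced) == 0) {
    return(list(subharmonics = FALSE, ratio = NA_character_, frames = NULL))
  }
  # drop frames whose F0 estimate is an octave-type outlier relative to the
  # call: probing at multiples of a wrong F0 would land on true harmonics
  med_f0 <- stats::median(contour$f0[voiced])
  voiced <- voiced[abs(log2(contour$f0[voiced] / med_f0)) <= 0.3]
  if (length(voiced) == 0) {
    return(list(subharmonics = FALSE, ratio = NA_character_, frames = NULL))
  }
  hits <- matrix(FALSE, nrow = length(voiced), ncol = 2,
                 dimnames = list(NULL, c("1/2", "1/3")))
  for (j in seq_along(voiced)) {
    tc <- contour$time[voiced[j]]
    f0 <- contour$f0[voiced[j]]
    s <- round(tc * fs - win / 2)
    if (s < 1 || s + win - 1 > length(x)) next
    fr <- x[s:(s + win - 1L)] * w
    mag <- Mod(stats::fft(c(fr, rep(0, nfft - win))))[seq_along(freqs)]
    for (den in c(2L, 3L)) {
      base <- f0 / den
      # probe only the low-order inter-harmonic components (m <= 5): higher
      # orders are too weak to separate from broadband modulation residue
      ks <- setdiff(seq_len(5L), den * seq_len(2L))
      ks <- ks[ks * base < 0.45 * fs]
      if (length(ks) == 0) next
      peaks <- vapply(ks, function(k) probe(mag, k * base), numeric(1))
      # reference harmonics flanking each probed position
      refs <- vapply(ks, function(k) {
        max(probe(mag, floor(k / den) * f0),
            probe(mag, ceiling(k / den) * f0), na.rm = TRUE)
      }, numeric(1))
      # floor positions: between the probed component and its neighbours
      floor_pos <- if (den == 2L) {
        c((seq_len(4L) - 0.75) * f0, (seq_len(4L) - 0.25) * f0)
      } else {
        (seq_len(4L) - 0.5) * f0
      }
      floor_pos <- floor_pos[floor_pos < 0.45 * fs]
      floors <- vapply(floor_pos, function(f) probe(mag, f), numeric(1))
      flo <- stats::median(floors, na.rm = TRUE)
      if (!is.finite(flo) || flo <= 0) next
      ok <- is.finite(peaks) & is.finite(refs) & refs > 0 &
        20 * log10(peaks / flo) >= threshold_db &
        20 * log10(peaks / refs) >= -max_below_harmonic_db
      hits[j, sprintf("1/%d", den)] <- any(ok)
    }
  }

  runs_ok <- function(v) {
    if (!any(v)) return(FALSE)
    r <- rle(v)
    any(r$values & r$lengths >= min_consecutive)
  }
  has3 <- runs_ok(hits[, "1/3"])
  has2 <- runs_ok(hits[, "1/2"])
  list(
    subharmonics = has2 || has3,
    ratio = if (has3) "1/3" else if (has2) "1/2" else NA_character_,
    frames = tibble::tibble(
      time = contour$time[voiced],
      hit_half = hits[, "1/2"], hit_third = hits[, "1/3"]
    )
  )
}

#' Detect biphonation and measure G0
#'
#' Biphonation is measured from periodic amplitude modulation of the
#' waveform: the amplitude envelope (rectify + low-pass) is extracted, its
#' modulation depth computed, and G0 taken as the envelope peak rate
#' (peaks per second). The flag is raised when the depth reaches
#' `depth_threshold` and G0 falls in the plausibility band.
#'
#' @param rec A [call_recording()].
#' @param lp_hz Envelope low-pass cut-off in Hz (default 400).
#' @param depth_threshold Minimum modulation depth (default 0.25).
#' @param g0_band Plausible G0 range in Hz (default 50-300).
#' @param f0_hint The call's fundamental in Hz, if known: the envelope
#'   cut-off is then kept below it so F0-rate rectification ripple is not
#'   mistaken for amplitude modulation.
#' @param exclude_hz Modulation frequencies to ignore when locating the
#'   modulation rate (e.g. a subharmonic ripple at F0/2 or F0/3 when
#'   subharmonics co-occur with biphonation).
#' @param line_excess_db The dominant envelope-spectrum component must
#'   stand this far above the band's median level (default 10 dB), so
#'   broadband envelope fluctuation does not pass as periodic modulation.
#' @return A list: `biphonation` (flag), `g0` (Hz, `NA` when absent),
#'   `depth`, `peak_rate`.
#' @export
detect_biphonation <- function(rec, lp_hz = 400, depth_threshold = 0.25,
                               g0_band = c(50, 300), f0_hint = NULL,
                               exclude_hz = NULL, line_excess_db = 10) {
  fs <- rec$sample_rate
  if (length(rec$samples) / fs < 0.1) stop("audio shorter than 0.1 s")
  env <- abs(rec$samples)
  if (!is.null(f0_hint) && is.finite(f0_hint)) {
    lp_hz <- min(lp_hz, 0.75 * f0_hint)
  }
  bf <- signal::butter(6, lp_hz / (fs / 2))
  env <- pmax(0, signal::filtfilt(bf, env))
  # trim edge transients
  trim <- round(0.02 * length(env))
  env <- env[(trim + 1):(length(env) - trim)]
  t_span <- length(env) / fs
  q <- stats::quantile(env, c(0.05, 0.5, 0.95), names = FALSE)
  depth <- if (q[3] > 0) (q[3] - q[1]) / q[3] else 0

  # locate the dominant periodic modulation: envelope spectrum peak within
  # the plausibility band, away from any excluded ripple frequencies
  ec <- env - mean(env)
  nfft <- stats::nextn(2L * length(ec), 2)
  mag <- Mod(stats::fft(c(ec, rep(0, nfft - length(ec)))))[seq_len(nfft %/% 2)]
  freqs <- (seq_len(nfft %/% 2) - 1) * fs / nfft
  in_band <- freqs >= g0_band[1] & freqs <= g0_band[2]
  for (f_ex in exclude_hz) {
    if (is.finite(f_ex)) in_band <- in_band & abs(freqs - f_ex) > 0.12 * f_ex
  }
  if (!is.null(f0_hint) && is.finite(f0_hint)) {
    # the (possibly swept) fundamental itself is not amplitude modulation
    in_band <- in_band & freqs < 0.72 * f0_hint
  }
  periodic <- FALSE
  rate <- NA_real_
  if (any(in_band)) {
    i_peak <- which(in_band)[which.max(mag[in_band])]
    f_dom <- freqs[i_peak]
    # a periodic modulation is a sharp line; broadband envelope
    # fluctuation (e.g. a chaotic episode) is not
    line_excess <- 20 * log10(
      mag[i_peak] / stats::quantile(mag[in_band], 0.9, names = FALSE)
    )
    if (is.finite(line_excess) && line_excess >= line_excess_db) {
      # count envelope pulses per second in a narrow band around the
      # dominant component, and require consistency with that component
      bp <- signal::butter(2, pmin(0.99, c(0.75, 1.35) * f_dom / (fs / 2)),
        type = "pass")
      eb <- signal::filtfilt(bp, ec)
      up <- eb > 0
      rate <- sum(diff(up) == 1) / t_span
      periodic <- is.finite(rate) && abs(rate - f_dom) <= 0.15 * f_dom
    }
  }
  flag <- periodic && depth >= depth_threshold &&
    !is.na(rate) && rate >= g0_band[1] && rate <= g0_band[2]
  list(
    biphonation = flag,
    g0 = if (flag) rate else NA_real_,
    depth = depth,
    peak_rate = rate
  )
}
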