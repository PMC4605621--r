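#' Measure formant frequencies with Burg LPC
#'
#' The signal is resampled to twice the maximum formant value,
#' pre-emphasized (+6 dB/octave above `preemphasis_from`), and a Burg
#' autoregressive model of order `2 * n_formants` is fitted to each
#' Gaussian-windowed frame. Formant frequencies are the angles of the
#' complex pole pairs; candidates with bandwidth above `max_bandwidth` or
#' frequency below 50 Hz are discarded. Per-call means are taken over the
#' frames in which all `n_formants` formants are found.
#'
#' @param rec A [call_recording()].
#' @param max_formant Maximum formant frequency in Hz (analysis Nyquist).
#' @param n_formants Number of formants to track (default 6).
#' @param window Analysis window length in seconds (default 0.03).
#' @param time_step Frame step in seconds (default 0.01).
#' @param preemphasis_from Pre-emphasis corner frequency in Hz (default 50).
#' @param max_bandwidth Candidate bandwidth cut-off in Hz (default 700).
#' @return A `formant_track`: tibble of per-frame formants (`time`, `f1` ..
#'   `fn`), with the per-call means in `attr(, "means")`.
#' @export
measure_formants <- function(rec, max_formant = 3000, n_formants = 6,
                             window = 0.03, time_step = 0.01,
                             preemphasis_from = 50, max_bandwidth = 700) {
  fs0 <- rec$sample_rate
  fs <- 2 * max_formant
  if (fs > fs0) stop("max_formant above input Nyquist; record at a higher rate")
  x <- resample_audio(rec$samples, fs0, fs)
  win <- round(window * fs)
  if (length(x) < 2 * win) stop("audio shorter than two analysis windows")
  hop <- max(1L, round(time_step * fs))

  # +6 dB/octave above the corner frequency
  alpha <- exp(-2 * pi * preemphasis_from / fs)
  x <- c(x[1], x[-1] - alpha * x[-length(x)])

  # Gaussian window (sd = win/6, near-zero at the edges)
  n_half <- (win - 1) / 2
  w <- exp(-0.5 * ((seq_len(win) - 1 - n_half) / (win / 6))^2)

  order <- 2L * n_formants
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  frames <- lapply(starts, function(s) {
    fr <- x[s:(s + win - 1L)] * w
    if (sum(fr^2) < 1e-14) return(NULL)
    fit <- tryCatch(
      stats::ar.burg(fr, aic = FALSE, order.max = order, demean = TRUE),
      error = function(e) NULL
    )
    if (is.null(fit) || length(fit$ar) < order) return(NULL)
    # roots are in the z^-1 variable: pole angle = -Arg, modulus = 1/Mod
    roots <- polyroot(c(1, -fit$ar))
    ang <- -Arg(roots)
    keep <- ang > 0 & ang < pi
    freq <- ang[keep] * fs / (2 * pi)
    bw <- log(pmax(Mod(roots[keep]), 1 + 1e-12)) * fs / pi
    ok <- freq >= 50 & freq <= 0.99 * (fs / 2) & bw <= max_bandwidth
    cand <- sort(freq[ok])
    if (length(cand) < n_formants) return(NULL)
    cand[seq_len(n_formants)]
  })

  good <- !vapply(frames, is.null, logical(1))
  if (!any(good)) stop("formant measurement failed: no frame yields all formants")
  mat <- do.call(rbind, frames[good])
  colnames(mat) <- sprintf("f%d", seq_len(n_formants))
  out <- tibble::as_tibble(mat)
  out <- dplyr::mutate(out,
    time = (starts[good] - 1 + win / 2) / fs, .before = 1
  )
  class(out) <- c("formant_track", class(out))
  attr(out, "means") <- colMeans(mat)
  attr(out, "max_formant") <- max_formant
  out
}

#' Formant spacing by through-origin regression
#'
#' Under the uniform quarter-wave tube model, formant `i` sits at
#' `(2i - 1)/2` times the spacing. The spacing estimate is the
#' least-squares slope, through the origin, of the measured formant
#' frequencies on that predictor:
#' `delta_f = sum(x_i * F_i) / sum(x_i^2)` with `x_i = (2i - 1) / 2`.
#'
#' @param mean_formants Increasing vector of mean formant frequencies (Hz).
#' @return Formant spacing in Hz.
#' @examples
#' estimate_delta_f(c(259.9, 511.8, 743.0, 1313.7, 1874.1, 2634.9)) # ~423.5
#' @export
estimate_delta_f <- function(mean_formants) {
  f <- as.numeric(mean_formants)
  if (length(f) < 2) stop("need at least two formants")
  if (any(diff(f) <= 0) || any(f <= 0)) {
    stop("formant frequencies must be positive and strictly increasing")
  }
  x <- (2 * seq_along(f) - 1) / 2
  sum(x * f) / sum(x^2)
}
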