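# Shared fixture builders: everything is generated in code at test time.

fs_std <- 44100

tone <- function(freq, dur = 0.5, fs = fs_std, amp = 1) {
  call_recording(amp * sin(2 * pi * freq * (0:(round(dur * fs) - 1)) / fs), fs)
}

white_noise <- function(dur = 0.5, fs = fs_std, seed = 1) {
  set.seed(seed)
  call_recording(stats::rnorm(round(dur * fs)) / 4, fs)
}

# harmonic stack with optional subharmonic stack and amplitude modulation
harmonic_rec <- function(f0, dur = 0.5, fs = fs_std, n_harm = 10,
                         sub_den = NA, sub_amp = 0.06, am_g0 = NA,
                         am_depth = 0.55) {
  t <- (0:(round(dur * fs) - 1)) / fs
  x <- 0
  for (h in seq_len(n_harm)) {
    if (h * f0 < 8000) x <- x + (1 / h) * sin(2 * pi * h * f0 * t)
  }
  if (!is.na(sub_den)) {
    for (m in seq_len(n_harm * sub_den)) {
      if (m %% sub_den == 0) next
      if (m * f0 / sub_den < 8000) {
        x <- x + sub_amp * (sub_den / m) * sin(2 * pi * m * f0 / sub_den * t)
      }
    }
  }
  if (!is.na(am_g0)) {
    x <- x * ((1 - am_depth / 2) + (am_depth / 2) * cos(2 * pi * am_g0 * t))
  }
  call_recording(x / max(abs(x)), fs,
    metadata = list(call_type = "tonal_rejection")
  )
}

# a population spec with all randomness switched off (zero SDs)
zero_variance_spec <- function() {
  spec <- population_spec()
  for (ct in c("bellow", "tonal_rejection", "snarl")) {
    spec[[ct]]$sd <- 0
  }
  spec$tonal_prevalence[] <- 0
  spec
}

# construct an f0_contour tibble by hand (times in s, NA = unvoiced)
manual_contour <- function(f0, step = 0.01) {
  out <- tibble::tibble(
    time = (seq_along(f0) - 1) * step,
    f0 = f0,
    voiced = !is.na(f0)
  )
  class(out) <- c("f0_contour", class(out))
  attr(out, "time_step") <- step
  out
}
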