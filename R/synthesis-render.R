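# F0 contour path construction -------------------------------------------
#
# Builds an F0 path on [0, T] that realizes the drawn call parameters:
# a slow base sweep (dwell at the minimum, ramp, dwell at the maximum) that
# spans the F0 range and fixes the time-average at the drawn mean, plus a
# small sinusoidal vibrato that supplies the remaining modulation per
# second (sumvar). Real contours realize high cumulative modulation as
# rapid shallow movement, not repeated full-range swings; the vibrato rate
# is chosen per call type so the pitch tracker can resolve it.
f0_contour_path <- function(f0_min, f0_max, f0_mean, sumvar, duration,
                            vibrato_rate = 8) {
  m <- f0_min; M <- f0_max; mu <- f0_mean
  TT <- duration
  V <- max(0, sumvar) * TT
  if (M - m < 1e-6) {
    return(data.frame(t = c(0, TT), f0 = c(mu, mu)))
  }
  if (V < (M - m)) {
    # too little modulation to span the range: centred ramp of the right
    # total variation (extremes unreachable by construction)
    a <- mu - V / 2
    b <- a + V
    if (a < m) { a <- m; b <- m + V }
    if (b > M) { b <- M; a <- M - V }
    return(data.frame(t = c(0, TT), f0 = c(a, b)))
  }
  # vibrato amplitude from the residual modulation demand; |d/dt| of a
  # sinusoid integrates to 4 * a * rate per second. The amplitude is also
  # capped so the base sweep can still place its time-average at the mean.
  a_vib <- (V - (M - m)) / (4 * vibrato_rate * TT)
  a_vib <- min(a_vib, 0.25 * (M - m), 0.9 * (mu - m), 0.9 * (M - mu), 0.4 * m)
  a_vib <- max(a_vib, 0)

  # base sweep over [m + a, M - a]; vibrato peaks touch the extremes
  lo <- m + a_vib
  hi <- M - a_vib
  t_ramp <- 0.25 * TT
  dwell <- TT - t_ramp
  d1 <- ((lo + hi) / 2 * t_ramp + hi * dwell - mu * TT) / (hi - lo)
  d1 <- min(max(d1, 0), dwell)

  grid <- seq(0, TT, by = min(0.005, TT / 50))
  base <- stats::approx(
    x = c(0, d1, d1 + t_ramp, TT),
    y = c(lo, lo, hi, hi),
    xout = grid, ties = "ordered"
  )$y
  data.frame(t = grid, f0 = base + a_vib * sin(2 * pi * vibrato_rate * grid))
}

# Evaluate a contour path at arbitrary times.
contour_at <- function(path, t) {
  stats::approx(path$t, path$f0, xout = t, rule = 2, ties = "ordered")$y
}

# F0 statistics a 10-ms-step tracker would read off a contour path: used by
# the generator to record the realized (rather than merely requested)
# min/max/sumvar of a call.
contour_realized_stats <- function(path, duration) {
  s <- contour_at(path, seq(0, duration, by = 0.01))
  list(
    mean = mean(s), min = min(s), max = max(s),
    sumvar = sum(abs(diff(s))) / duration
  )
}

# The fixed respiratory phrasing of a bellow: alternating exhalation and
# inhalation stretches filling the call duration.
bellow_segment_plan <- function(duration) {
  exh_d <- 0.6
  inh_d <- 1.4
  if (duration < 1.0) {
    return(tibble::tibble(label = "inhalation", dur = duration))
  }
  labs <- character(0)
  durs <- numeric(0)
  lab <- "exhalation"
  remaining <- duration
  while (remaining > 1e-9) {
    d <- min(if (lab == "exhalation") exh_d else inh_d, remaining)
    labs <- c(labs, lab)
    durs <- c(durs, d)
    remaining <- remaining - d
    lab <- if (lab == "exhalation") "inhalation" else "exhalation"
  }
  tibble::tibble(label = labs, dur = durs)
}

# Sources ------------------------------------------------------------------

# Glottal/velar pulse train following an F0 contour. Generated at the
# synthesis rate; pulses are placed with sub-sample precision (each
# impulse split across the two neighbouring samples) so the period is not
# quantized to the sample grid.
pulse_train_source <- function(path, duration, fs) {
  n <- max(2L, round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  f0 <- contour_at(path, t)
  phase <- cumsum(f0) / fs
  x <- numeric(n + 1L)
  cross <- which(diff(floor(phase)) > 0) + 1L
  for (i in cross) {
    # fractional position of the integer-phase crossing within the step
    frac <- (ceiling(phase[i - 1L]) - phase[i - 1L]) / (phase[i] - phase[i - 1L])
    x[i - 1L] <- x[i - 1L] + (1 - frac)
    x[i] <- x[i] + frac
  }
  x[seq_len(n)]
}

# -6 dB/octave source colouring (leaky integrator with its corner at
# `corner_hz`). Broadband vocal sources fall off with frequency; giving the
# synthetic source the same roll-off that formant analysis pre-emphasis
# assumes keeps the rendered calls spectrally realistic.
source_rolloff <- function(x, fs, corner_hz = 50) {
  alpha <- exp(-2 * pi * corner_hz / fs)
  as.numeric(signal::filter(signal::Arma(b = 1, a = c(1, -alpha)), x))
}

# Harmonic source (sum of harmonics with 1/h amplitude fall-off) following
# an F0 contour; optional additive subharmonic stack at F0/den.
harmonic_source <- function(path, duration, fs, n_harmonics = 10,
                            subharmonic_den = NA, sub_amp = 0.06,
                            freq_cap = NULL) {
  n <- max(2L, round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  f0 <- contour_at(path, t)
  cap <- if (is.null(freq_cap)) min(8000, 0.45 * fs) else freq_cap
  phase <- 2 * pi * cumsum(f0) / fs
  x <- numeric(n)
  f0_top <- max(f0)
  for (h in seq_len(n_harmonics)) {
    if (h * f0_top > cap) break
    x <- x + (1 / h) * sin(h * phase)
  }
  if (!is.na(subharmonic_den)) {
    den <- as.integer(subharmonic_den)
    for (m in seq_len(n_harmonics * den)) {
      if (m %% den == 0) next # coincides with a harmonic
      if (m * f0_top / den > cap) break
      x <- x + sub_amp * (den / m) * sin(m * phase / den)
    }
  }
  x
}

# Cascade of two-pole resonators (unity DC gain sections) at the formant
# targets -- the classic source-filter synthesis filter.
apply_formant_cascade <- function(x, fs, freqs, bws) {
  if (any(freqs >= fs / 2)) {
    stop("formant target at or above Nyquist (", fs / 2, " Hz)")
  }
  for (i in seq_along(freqs)) {
    r <- exp(-pi * bws[i] / fs)
    theta <- 2 * pi * freqs[i] / fs
    b0 <- 1 - 2 * r * cos(theta) + r^2
    x <- signal::filter(signal::Arma(b = b0, a = c(1, -2 * r * cos(theta), r^2)), x)
  }
  as.numeric(x)
}

fade_edges <- function(x, fs, fade_s = 0.005) {
  nf <- min(length(x) %/% 2, max(1L, round(fade_s * fs)))
  if (nf > 1) {
    ramp <- seq(0, 1, length.out = nf)
    x[seq_len(nf)] <- x[seq_len(nf)] * ramp
    x[(length(x) - nf + 1):length(x)] <-
      x[(length(x) - nf + 1):length(x)] * rev(ramp)
  }
  x
}

#' Render a call as audio
#'
#' Synthesizes one call from its parameters:
#' \itemize{
#'   \item \strong{bellow} -- alternating exhalation (formant-filtered noise,
#'     i.e. deterministic chaos) and inhalation (band-limited glottal pulse
#'     train following the F0 contour) segments, all passed through a cascade
#'     of resonators at the formant targets; segments are labelled in the
#'     output.
#'   \item \strong{snarl} -- white noise through six resonators.
#'   \item \strong{tonal rejection call} -- harmonic source following the F0
#'     contour, with optional additive subharmonic stack at F0/2 or F0/3,
#'     optional amplitude modulation at G0 (biphonation), and an optional
#'     additive noise stretch (deterministic chaos).
#' }
#' Output is peak-normalized. Uses the current RNG stream for noise.
#'
#' @param params A `call_parameters` object from [realize_call_parameters()].
#' @param sample_rate Output sampling rate in Hz (default 44100).
#' @param am_depth Amplitude-modulation depth used for biphonation.
#' @param chaos_frac Fraction of a tonal call overlaid with noise when the
#'   chaos flag is set.
#' @return A [call_recording()].
#' @export
synthesize_call <- function(params, sample_rate = 44100,
                            am_depth = 0.55, chaos_frac = 0.45) {
  fs <- sample_rate
  if (params$duration <= 0) stop("duration must be positive")
  if (!is.null(params$formants) && any(params$formants >= fs / 2)) {
    stop("formant target at or above Nyquist")
  }
  meta <- list(
    individual = params$individual, age = params$age, sex = params$sex,
    call_type = params$call_type
  )
  segments <- NULL

  if (params$call_type == "snarl") {
    # synthesize at the band's modelling rate (2 x the 7 kHz analysis
    # band), then upsample: the rendered call is an exact all-pole
    # source-filter process over its band
    fs_m <- min(fs, 2 * 7000)
    n <- round(params$duration * fs_m)
    if (n < 2 * round(0.03 * fs_m)) stop("duration shorter than two analysis windows")
    if (any(params$formants >= fs_m / 2)) stop("formant target at or above Nyquist")
    x <- source_rolloff(stats::rnorm(n), fs_m)
    x <- apply_formant_cascade(x, fs_m, params$formants, params$bandwidths)
    x <- resample_audio(x, fs_m, fs)
    x <- fade_edges(x, fs, 0.01)
  } else if (params$call_type == "tonal_rejection") {
    n <- round(params$duration * fs)
    if (n < 2 * round(0.03 * fs)) stop("duration shorter than two analysis windows")
    path <- params$f0$path %||% f0_contour_path(
      params$f0$min, params$f0$max, params$f0$mean,
      params$f0$sumvar, params$duration
    )
    ratio <- params$nlp$subharmonic_ratio
    den <- if (is.null(ratio) || is.na(ratio)) {
      NA_integer_
    } else {
      switch(ratio, "1/2" = 2L, "1/3" = 3L, NA_integer_)
    }
    x <- harmonic_source(path, params$duration, fs, subharmonic_den = den)
    if (isTRUE(params$nlp$biphonation)) {
      t <- (seq_along(x) - 1) / fs
      x <- x * ((1 - am_depth / 2) + (am_depth / 2) * cos(2 * pi * params$nlp$g0 * t))
    }
    if (isTRUE(params$nlp$chaos)) {
      i0 <- max(1L, round(0.55 * length(x)))
      i1 <- min(length(x), i0 + round(chaos_frac * length(x)))
      seg <- i0:i1
      x[seg] <- x[seg] + stats::rnorm(length(seg), sd = sqrt(mean(x[seg]^2)))
    }
    x <- fade_edges(x, fs)
  } else if (params$call_type == "bellow") {
    # alternating segments: exhalation noise then inhalation pulse train
    plan <- bellow_segment_plan(params$duration)
    labs <- plan$label
    durs <- plan$dur
    t_voiced <- sum(durs[labs == "inhalation"])
    path <- params$f0$path %||% f0_contour_path(
      params$f0$min, params$f0$max, params$f0$mean,
      params$f0$sumvar, t_voiced, vibrato_rate = 0.35
    )
    # modelling rate covering the 3 kHz bellow formant band
    fs_m <- min(fs, 2 * 3000)
    if (any(params$formants >= fs_m / 2)) stop("formant target at or above Nyquist")
    pieces <- vector("list", nrow(plan))
    v_used <- 0
    for (i in seq_len(nrow(plan))) {
      if (labs[i] == "exhalation") {
        src <- stats::rnorm(round(durs[i] * fs_m))
      } else {
        sub <- data.frame(
          t = seq(0, durs[i], length.out = 200),
          f0 = contour_at(path, v_used + seq(0, durs[i], length.out = 200))
        )
        src <- pulse_train_source(sub, durs[i], fs_m)
        v_used <- v_used + durs[i]
      }
      src <- source_rolloff(src, fs_m)
      # comparable loudness across segments
      src <- src / max(1e-12, sqrt(mean(src^2)))
      pieces[[i]] <- fade_edges(src, fs_m, 0.01)
    }
    x <- unlist(pieces)
    x <- apply_formant_cascade(x, fs_m, params$formants, params$bandwidths)
    x <- resample_audio(x, fs_m, fs)
    ends <- cumsum(durs)
    segments <- tibble::tibble(
      start = c(0, ends[-length(ends)]), end = ends, label = labs
    )
  } else {
    stop("unknown call type: ", params$call_type)
  }

  peak <- max(abs(x))
  if (peak == 0) stop("synthesis produced silence")
  call_recording(0.98 * x / peak, fs, metadata = meta, segments = segments)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# Feature-table construction ----------------------------------------------

feature_columns <- c(
  "duration_s", "mean_f0_hz", "max_f0_hz", "min_f0_hz", "f0_sumvar_hz",
  "chaos", "subharmonics", "biphonation", "g0_hz",
  "f1_hz", "f2_hz", "f3_hz", "f4_hz", "f5_hz", "f6_hz", "delta_f_hz"
)

# One feature row straight from call parameters (the generative model's own
# values; no rendering/measurement noise).
params_to_feature_row <- function(params) {
  row <- stats::setNames(
    as.list(rep(NA_real_, length(feature_columns))), feature_columns
  )
  row$duration_s <- params$duration
  if (!is.null(params$f0)) {
    row$mean_f0_hz <- params$f0$mean
    row$max_f0_hz <- params$f0$max
    row$min_f0_hz <- params$f0$min
    row$f0_sumvar_hz <- params$f0$sumvar
  }
  row$chaos <- as.numeric(params$nlp$chaos)
  if (params$call_type == "tonal_rejection") {
    row$subharmonics <- as.numeric(!is.na(params$nlp$subharmonic_ratio))
    row$biphonation <- as.numeric(params$nlp$biphonation)
    if (isTRUE(params$nlp$biphonation)) row$g0_hz <- params$nlp$g0
  }
  if (!is.null(params$formants)) {
    row[sprintf("f%d_hz", 1:6)] <- as.list(params$formants)
    row$delta_f_hz <- estimate_delta_f(params$formants)
  }
  tibble::as_tibble(c(
    list(
      individual = params$individual, age = params$age, sex = params$sex,
      call_type = params$call_type
    ),
    row
  ))
}

#' Default study design for the synthetic cohort
#'
#' Callers and calls per call type matching the analysed study population:
#' 12 females with 8 bellows each, 14 with 8 tonal rejection calls, 6 with
#' 5 snarls.
#'
#' @return A tibble with columns `call_type`, `n_individuals`,
#'   `calls_per_individual`.
#' @export
default_study_design <- function() {
  tibble::tribble(
    ~call_type, ~n_individuals, ~calls_per_individual,
    "bellow", 12L, 8L,
    "tonal_rejection", 14L, 8L,
    "snarl", 6L, 5L
  )
}

#' Build a synthetic feature table without rendering audio
#'
#' Draws a caller population and realizes call parameters per caller and
#' call type, summarizing each call directly as a feature-vector row (the
#' generative values; no measurement noise). This is the fast path for
#' exercising the statistics stage.
#'
#' @param spec A [population_spec()].
#' @param n_individuals Number of callers (used when `design` is `NULL`).
#' @param calls_per_individual Calls per caller and call type (when
#'   `design` is `NULL`).
#' @param seed Integer seed fixing all randomness.
#' @param call_types Call types to generate (when `design` is `NULL`).
#' @param design Optional design tibble as from [default_study_design()];
#'   each call type then uses its own leading subset of the population.
#' @param sex Sex passed to [generate_population()].
#' @return A feature-table tibble: metadata columns `individual`, `age`,
#'   `sex`, `call_type`, then the measure columns (`duration_s`,
#'   `mean_f0_hz`, ..., `delta_f_hz`). Inapplicable measures are `NA`.
#' @export
build_feature_table <- function(spec = population_spec(), n_individuals = 12,
                                calls_per_individual = 8, seed = 1,
                                call_types = c("bellow", "tonal_rejection", "snarl"),
                                design = NULL, sex = "female") {
  if (is.null(design)) {
    design <- tibble::tibble(
      call_type = call_types,
      n_individuals = as.integer(n_individuals),
      calls_per_individual = as.integer(calls_per_individual)
    )
  }
  if (any(design$n_individuals < 1) || any(design$calls_per_individual < 1)) {
    stop("counts must be >= 1")
  }
  pop <- generate_population(spec, max(design$n_individuals), seed, sex = sex)
  with_seed(seed + 1L, {
    rows <- purrr::pmap(design, function(call_type, n_individuals, calls_per_individual) {
      purrr::map(seq_len(n_individuals), function(i) {
        purrr::map(seq_len(calls_per_individual), function(j) {
          params_to_feature_row(
            realize_call_parameters(pop[i, ], call_type, spec)
          )
        })
      })
    })
    dplyr::bind_rows(purrr::flatten(purrr::flatten(rows)))
  })
}

#' Render a batch of calls for a population
#'
#' Realizes and synthesizes `calls_per_individual` calls of each requested
#' type for each caller, returning recordings plus the generating
#' parameters.
#'
#' @inheritParams build_feature_table
#' @param sample_rate Audio sampling rate.
#' @return A tibble with columns `individual`, `call_type`, `index`,
#'   `params` (list of `call_parameters`), `recording` (list of
#'   [call_recording()]).
#' @export
synthesize_population_calls <- function(spec = population_spec(),
                                        n_individuals = 3,
                                        calls_per_individual = 2, seed = 1,
                                        call_types = c("bellow", "tonal_rejection", "snarl"),
                                        sample_rate = 44100) {
  pop <- generate_population(spec, n_individuals, seed)
  with_seed(seed + 1L, {
    grid <- tidyr::expand_grid(
      i = seq_len(n_individuals), call_type = call_types,
      index = seq_len(calls_per_individual)
    )
    out <- purrr::pmap(grid, function(i, call_type, index) {
      params <- realize_call_parameters(pop[i, ], call_type, spec)
      list(
        individual = pop$id[i], call_type = call_type, index = index,
        params = params, recording = synthesize_call(params, sample_rate)
      )
    })
    tibble::tibble(
      individual = vapply(out, `[[`, "", "individual"),
      call_type = vapply(out, `[[`, "", "call_type"),
      index = vapply(out, function(z) z$index, integer(1)),
      params = lapply(out, `[[`, "params"),
      recording = lapply(out, `[[`, "recording")
    )
  })
}

#' Write / read a feature table as CSV
#'
#' The on-disk dialect: comma separator, UTF-8, one header row, metadata
#' columns `individual,age,sex,call_type` then the measure columns;
#' inapplicable measures are written as empty fields (not 0), so absence is
#' not conflated with a measured zero.
#'
#' @param table A feature-table tibble.
#' @param path Output/input CSV path.
#' @return `write_feature_table()`: `path` invisibly;
#'   `read_feature_table()`: the tibble.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      individual = readr::col_character(),
      sex = readr::col_character(),
      call_type = readr::col_character(),
      .default = readr::col_double()
    )
  )
}
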