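test_that("pure tone is tracked within 1 Hz and fully voiced", {
  ct <- track_f0(tone(440), 180, 2500)
  expect_gt(mean(ct$voiced), 0.95)
  expect_equal(mean(ct$f0[ct$voiced]), 440, tolerance = 1 / 440)
})

test_that("white noise is essentially unvoiced", {
  ct <- track_f0(white_noise(), 180, 2500)
  expect_lt(mean(ct$voiced), 0.10)
})

test_that("a 31.3 Hz pulse train through bellow resonators tracks within 2%", {
  spec <- population_spec()
  pop <- generate_population(spec, 1, seed = 4)
  set.seed(4)
  p <- realize_call_parameters(pop[1, ], "bellow", spec)
  p$duration <- 3
  p$f0 <- list(mean = 31.3, min = 31.3, max = 31.3, sumvar = 0)
  rec <- synthesize_call(p)
  inh <- call_recording(
    koalacall:::segment_samples(rec, "inhalation"), rec$sample_rate
  )
  ct <- track_f0(inh, 10, 100, octave_cost = 0.02)
  expect_equal(mean(ct$f0[ct$voiced]), 31.3, tolerance = 0.02)
})

test_that("voiced estimates never leave the search range", {
  set.seed(21)
  for (i in 1:4) {
    x <- sin(2 * pi * runif(1, 200, 900) * (0:44099) / fs_std) +
      0.3 * stats::rnorm(44100)
    ct <- track_f0(call_recording(x, fs_std), 180, 2500)
    v <- ct$f0[ct$voiced]
    expect_true(all(v >= 180 & v <= 2500))
  }
  expect_error(track_f0(tone(440), 2500, 180), "f0_min < f0_max")
})

test_that("F0 statistics follow their definitions exactly", {
  # constant contour
  st <- f0_statistics(manual_contour(rep(100, 50)))
  expect_equal(unlist(st[1:4]), c(mean_f0 = 100, min_f0 = 100, max_f0 = 100, f0_sumvar = 0))
  # linear ramp 100 -> 200 over exactly 1 s of voiced frames: 100 Hz/s
  ramp <- manual_contour(seq(100, 200, length.out = 101))
  expect_equal(f0_statistics(ramp)$f0_sumvar, 100)
  # hand evaluation: 100, 110, 105 at 10 ms steps -> (10 + 5) / 0.02
  st3 <- f0_statistics(manual_contour(c(100, 110, 105)))
  expect_equal(st3$f0_sumvar, 750)
  expect_equal(st3$mean_f0, 105)
  expect_equal(st3$min_f0, 100)
  expect_equal(st3$max_f0, 110)
  # sumvar is non-negative, zero iff constant
  set.seed(2)
  for (i in 1:10) {
    f <- 300 + cumsum(stats::rnorm(30))
    expect_gte(f0_statistics(manual_contour(f))$f0_sumvar, 0)
  }
  expect_error(f0_statistics(manual_contour(c(100, NA, NA))), "2 voiced")
})

test_that("unvoiced gaps contribute neither modulation nor time to sumvar", {
  # two constant stretches at different levels separated by a gap: no
  # consecutive pair straddles the gap, so sumvar stays 0
  f <- c(rep(100, 10), NA, rep(150, 10))
  expect_equal(f0_statistics(manual_contour(f))$f0_sumvar, 0)
})

test_that("duration is measured from the waveform at -25 dB re peak", {
  fs <- fs_std
  x <- c(
    rep(0, round(0.25 * fs)),
    sin(2 * pi * 440 * (0:(round(0.5 * fs) - 1)) / fs),
    rep(0, round(0.25 * fs))
  )
  expect_equal(measure_duration(call_recording(x, fs)), 0.5, tolerance = 0.02)
  expect_error(measure_duration(call_recording(rep(0, fs), fs)), "silent")
})

test_that("spectrogram has a single ridge for a pure tone and clips range", {
  sg <- spectrogram(tone(1000, dur = 0.2))
  ridge <- sg$freq[apply(sg$db, 2, which.max)]
  expect_true(all(abs(ridge - 1000) < 40))
  expect_equal(min(sg$db), -40)
  expect_equal(max(sg$db), 0)
  expect_error(spectrogram(tone(1000, dur = 0.01), window = 0.1), "longer")
})
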