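test_that("zero between-individual variance gives identical profiles", {
  spec <- population_spec()
  spec$bellow$between_frac <- 0
  spec$tonal_rejection$between_frac <- 0
  spec$snarl$between_frac <- 0
  pop <- generate_population(spec, 5, seed = 1)
  for (ct in c("bellow", "tonal_rejection", "snarl")) {
    base1 <- pop$base[[1]][[ct]]
    for (i in 2:5) expect_equal(pop$base[[i]][[ct]], base1)
  }
})

test_that("the same seed reproduces the same population and audio", {
  p1 <- generate_population(population_spec(), 6, seed = 99)
  p2 <- generate_population(population_spec(), 6, seed = 99)
  expect_equal(p1, p2)
  spec <- population_spec()
  set.seed(5)
  cp <- realize_call_parameters(p1[1, ], "snarl", spec)
  set.seed(31)
  r1 <- synthesize_call(cp)
  set.seed(31)
  r2 <- synthesize_call(cp)
  expect_identical(r1$samples, r2$samples)
  expect_error(generate_population(population_spec(), 0, seed = 1), ">= 1")
})

test_that("between-individual spread matches the configured SD over replicates", {
  spec <- population_spec()
  b_sd <- with(spec$bellow, between_frac[param == "f1_hz"] * sd[param == "f1_hz"])
  sds <- vapply(1:100, function(s) {
    pop <- generate_population(spec, 12, seed = s)
    sd(vapply(pop$base, function(b) b$bellow[["f1_hz"]], numeric(1)))
  }, numeric(1))
  # expected sample SD of 12 normal draws, with its Monte-Carlo error
  expected <- b_sd * sqrt(2 / 11) * gamma(6) / gamma(5.5)
  mc_err <- sd(sds) / sqrt(length(sds))
  expect_lt(abs(mean(sds) - expected), 3 * mc_err)
})

test_that("age slopes shift tonal F0 by the configured Hz per year", {
  spec <- zero_variance_spec()
  pop <- generate_population(spec, 2, seed = 1)
  pop$age <- c(6, 7)
  pa <- realize_call_parameters(pop[1, ], "tonal_rejection", spec)
  pb <- realize_call_parameters(pop[2, ], "tonal_rejection", spec)
  expect_equal(pa$f0$mean - pb$f0$mean, 37.23, tolerance = 1e-9)
})

test_that("bellow formant targets differ by sex as configured", {
  spec <- zero_variance_spec()
  fem <- generate_population(spec, 1, seed = 1, sex = "female")
  mal <- generate_population(spec, 1, seed = 1, sex = "male")
  fem$age <- 6
  mal$age <- 6
  pf <- realize_call_parameters(fem[1, ], "bellow", spec)
  pm <- realize_call_parameters(mal[1, ], "bellow", spec)
  expect_equal(round(estimate_delta_f(pf$formants), 1), 424.6)
  expect_equal(round(estimate_delta_f(pm$formants), 1), 355.8)
  expect_error(realize_call_parameters(mal[1, ], "snarl", spec), "male")
  expect_error(realize_call_parameters(fem[1, ], "yodel", spec), "unknown")
})

test_that("zero slopes and zero variance reproduce the base parameters", {
  spec <- zero_variance_spec()
  spec$age_slopes[] <- 0
  pop <- generate_population(spec, 1, seed = 1)
  p <- realize_call_parameters(pop[1, ], "snarl", spec)
  expect_equal(unname(p$formants), unname(sort(pop$base[[1]]$snarl[sprintf("f%d_hz", 1:6)])))
  expect_equal(p$duration, unname(pop$base[[1]]$snarl["duration_s"]))
})

test_that("call parameters respect their structural invariants", {
  spec <- population_spec()
  pop <- generate_population(spec, 4, seed = 13)
  set.seed(13)
  for (i in 1:4) {
    pb <- realize_call_parameters(pop[i, ], "bellow", spec)
    expect_true(all(diff(pb$formants) > 0))
    expect_lte(pb$f0$min, pb$f0$mean)
    expect_lte(pb$f0$mean, pb$f0$max)
    pt <- realize_call_parameters(pop[i, ], "tonal_rejection", spec)
    expect_null(pt$formants) # F0 too high to sample formants
    ps <- realize_call_parameters(pop[i, ], "snarl", spec)
    expect_null(ps$f0) # no fundamental in broadband snarls
    expect_true(is.na(ps$nlp$subharmonic_ratio))
  }
})

test_that("feature tables are reproducible and carry the null pattern", {
  tab1 <- build_feature_table(n_individuals = 3, calls_per_individual = 2, seed = 5)
  tab2 <- build_feature_table(n_individuals = 3, calls_per_individual = 2, seed = 5)
  expect_identical(tab1, tab2)
  # CSV round trip is byte-identical on re-write
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_feature_table(tab1, f1)
  write_feature_table(tab2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_feature_table(f1)
  expect_equal(as.data.frame(back), as.data.frame(tab1), tolerance = 1e-12)

  # exactly the measures inapplicable to a call type are missing
  bell <- tab1[tab1$call_type == "bellow", ]
  expect_true(all(is.na(bell$subharmonics)) && all(is.na(bell$biphonation)) &&
    all(is.na(bell$g0_hz)))
  expect_true(all(!is.na(bell$mean_f0_hz)) && all(!is.na(bell$f1_hz)))
  ton <- tab1[tab1$call_type == "tonal_rejection", ]
  expect_true(all(is.na(ton$f1_hz)) && all(is.na(ton$delta_f_hz)))
  expect_true(all(!is.na(ton$mean_f0_hz)))
  sn <- tab1[tab1$call_type == "snarl", ]
  expect_true(all(is.na(sn$mean_f0_hz)) && all(!is.na(sn$delta_f_hz)))
})

test_that("zero-variance tables have identical rows per call type", {
  spec <- zero_variance_spec()
  spec$age_slopes[] <- 0 # ages still differ across callers
  tab <- build_feature_table(
    spec = spec, n_individuals = 3, calls_per_individual = 1, seed = 2
  )
  for (ct in unique(tab$call_type)) {
    rows <- dplyr::select(
      dplyr::filter(tab, call_type == ct), -individual, -age
    )
    expect_true(all(vapply(
      seq_len(nrow(rows)),
      function(i) isTRUE(all.equal(rows[i, ], rows[1, ], check.attributes = FALSE)),
      logical(1)
    )))
  }
})

test_that("feature-table column means match the generating distributions", {
  tab <- build_feature_table(seed = 31, design = default_study_design())
  spec <- population_spec()
  # columns whose generative law is the plain truncated normal (no
  # realization constraints): compare to the analytic truncated mean
  cases <- list(
    list("bellow", "f1_hz"), list("bellow", "mean_f0_hz"),
    list("snarl", "f4_hz"), list("tonal_rejection", "duration_s")
  )
  for (cs in cases) {
    ct <- cs[[1]]
    parm <- cs[[2]]
    rowi <- spec[[ct]][spec[[ct]]$param == parm, ]
    expected <- koalacall:::trunc_norm_mean(
      rowi$mean, rowi$sd, rowi$lower, rowi$upper
    )
    vals <- tab[[parm]][tab$call_type == ct]
    se <- rowi$sd / sqrt(length(vals))
    expect_lt(abs(mean(vals) - expected), 3.5 * se)
  }
  # delta_f is the through-origin regression of the formant targets
  bell <- tab[tab$call_type == "bellow", ]
  for (i in seq_len(nrow(bell))) {
    expect_equal(
      bell$delta_f_hz[i],
      estimate_delta_f(unlist(bell[i, sprintf("f%d_hz", 1:6)]))
    )
  }
})

test_that("rendered calls stay in range and carry segment labels", {
  spec <- population_spec()
  pop <- generate_population(spec, 1, seed = 3)
  set.seed(3)
  p <- realize_call_parameters(pop[1, ], "bellow", spec)
  p$duration <- 3
  r <- synthesize_call(p)
  expect_lte(max(abs(r$samples)), 1)
  expect_true(all(c("inhalation", "exhalation") %in% r$segments$label))
  expect_equal(max(r$segments$end), p$duration, tolerance = 1e-6)
  # formant above Nyquist is rejected
  p$formants[6] <- 23000
  expect_error(synthesize_call(p), "Nyquist")
})

test_that("a biphonic render shows the configured envelope pulse rate", {
  spec <- population_spec()
  pop <- generate_population(spec, 1, seed = 17)
  set.seed(17)
  p <- realize_call_parameters(pop[1, ], "tonal_rejection", spec)
  p$duration <- 1
  p$f0 <- list(mean = 800, min = 780, max = 820, sumvar = 80, path = NULL)
  p$nlp <- list(
    chaos = FALSE, subharmonic_ratio = NA_character_,
    biphonation = TRUE, g0 = 186
  )
  r <- synthesize_call(p)
  bp <- detect_biphonation(r, f0_hint = 800)
  expect_equal(bp$peak_rate, 186, tolerance = 0.05)
})
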