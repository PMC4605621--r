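#' Default population specification for synthetic koala calls
#'
#' Defines the generative model for the three female call archetypes
#' (bellows, snarls, tonal rejection calls) and the male bellow contrast:
#' per-parameter means and standard deviations, the fraction of each SD
#' attributed to stable between-individual differences, nonlinear-phenomena
#' (NLP) prevalences, age slopes for tonal-call F0 features, and per-sex
#' bellow parameter means.
#'
#' Defaults reproduce the descriptive statistics of the study population:
#' bellows with F0 near 31 Hz and six formants between ~260 and ~2635 Hz
#' (spacing ~423.5 Hz), snarls as broadband noise with six resonances
#' between ~824 and ~6243 Hz (spacing ~1205 Hz), and tonal rejection calls
#' with F0 near 790 Hz plus optional subharmonics, biphonation
#' (amplitude-modulation rate G0) and deterministic chaos.
#'
#' F0 extrema are generated relative to the call's mean F0 through offsets
#' (`gap_down = mean - min`, `gap_up = max - mean`), which guarantees
#' `min <= mean <= max` while preserving the configured marginal means.
#'
#' @param between_frac_default Fraction of each parameter SD attributed to
#'   between-individual variation (bellow source features use a smaller
#'   value: bellow F0 is not strongly individual).
#' @param age_range Age range (years) of the synthetic cohort; ages are
#'   drawn uniformly over it.
#' @param reference_age Age (years) at which tonal F0 parameters equal the
#'   population means; age slopes act on `(age - reference_age)`. Default is
#'   the midpoint of `age_range` so call-type parameter means are unchanged
#'   marginally.
#' @return A `population_spec` object (a list of parameter tibbles and
#'   scalar settings).
#' @export
population_spec <- function(between_frac_default = 0.85,
                            age_range = c(2, 14),
                            reference_age = mean(age_range)) {
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2])
  bf <- between_frac_default
  bellow <- tibble::tribble(
    ~param, ~mean, ~male_mean, ~sd, ~between_frac, ~lower, ~upper,
    "duration_s", 18.97, 38.50, 9.9, bf, 1.0, Inf,
    "mean_f0_hz", 31.97, 27.07, 12.7, 0.3, 12.0, 95,
    "gap_down_hz", 21.49, 17.27, 4.3, 0.3, 1.0, Inf,
    "gap_up_hz", 38.41, 34.38, 22.1, 0.3, 1.0, Inf,
    "f0_sumvar_hz", 58.5, 58.5, 26.8, 0.3, 0.0, Inf,
    "f1_hz", 259.51, 216.94, 23.5, bf, 50, Inf,
    "f2_hz", 511.06, 416.68, 29.7, bf, 50, Inf,
    "f3_hz", 745.83, 660.79, 42.1, bf, 50, Inf,
    "f4_hz", 1322.82, 1155.96, 69.9, bf, 50, Inf,
    "f5_hz", 1886.32, 1618.40, 71.0, bf, 50, Inf,
    "f6_hz", 2633.09, 2131.99, 91.4, bf, 50, 2940
  )
  tonal <- tibble::tribble(
    ~param, ~mean, ~sd, ~between_frac, ~lower, ~upper,
    "duration_s", 0.5, 0.5, bf, 0.1, Inf,
    "mean_f0_hz", 792.1, 193.6, bf, 260, 1190,
    "gap_down_hz", 50.8, 12.4, 0, 2.0, Inf,
    "gap_up_hz", 50.0, 38.0, 0, 2.0, Inf,
    "f0_sumvar_hz", 604.9, 475.0, 0.5, 6.0, Inf,
    "g0_hz", 186.3, 45.0, 0.5, 60, Inf
  )
  snarl <- tibble::tribble(
    ~param, ~mean, ~sd, ~between_frac, ~lower, ~upper,
    "duration_s", 0.9, 0.3, bf, 0.2, Inf,
    "f1_hz", 824.2, 212.6, bf, 200, Inf,
    "f2_hz", 2130.8, 249.6, bf, 200, Inf,
    "f3_hz", 3273.7, 264.2, bf, 200, Inf,
    "f4_hz", 4413.5, 266.7, bf, 200, Inf,
    "f5_hz", 5463.4, 242.7, bf, 200, Inf,
    "f6_hz", 6243.1, 168.4, bf, 200, 6860
  )
  structure(
    list(
      bellow = bellow,
      tonal_rejection = tonal,
      snarl = snarl,
      # NLP prevalences among tonal rejection calls; bellows and snarls
      # always contain deterministic chaos and no other NLP.
      tonal_prevalence = c(chaos = 0.075, subharmonics = 0.335, biphonation = 0.462),
      # observed ratio split: 51 calls at F0/2, 18 at F0/3
      subharmonic_ratio_probs = c("1/2" = 51 / 69, "1/3" = 18 / 69),
      # Hz per year, applied to tonal-call F0 features around reference_age;
      # extrema slopes are honoured through the gap parameterization.
      age_slopes = c(
        mean_f0_hz = -37.23, max_f0_hz = -34.11,
        min_f0_hz = -41.10, f0_sumvar_hz = 28.72
      ),
      g0_band = c(60, 290),
      formant_bandwidth_frac = 0.08,
      age_range = age_range,
      reference_age = reference_age
    ),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>\n")
  cat(sprintf(
    "  ages uniform on [%g, %g] yr (slopes centred at %g yr)\n",
    x$age_range[1], x$age_range[2], x$reference_age
  ))
  for (ct in c("bellow", "tonal_rejection", "snarl")) {
    cat(sprintf("  %s: %d parameters\n", ct, nrow(x[[ct]])))
  }
  cat(
    "  tonal NLP prevalence:",
    paste(names(x$tonal_prevalence), round(x$tonal_prevalence, 3),
      sep = "=", collapse = " "
    ), "\n"
  )
  invisible(x)
}

# Truncated-normal draw via inverse CDF so truncation stays deterministic
# under the RNG stream (no rejection loops).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) stop("sd must be >= 0")
  if (all(sd == 0)) {
    return(pmin(pmax(rep(mean, length.out = n), lower), upper))
  }
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, p_lo, p_hi)
  stats::qnorm(u, mean, sd)
}

# Analytic mean of the truncated normal used by the generator; exposed for
# calibration checks.
trunc_norm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic caller population
#'
#' Draws `n_individuals` caller profiles: an age (uniform over the spec's
#' age range), a sex, and per-call-type base parameters
#' (population mean + between-individual deviation).
#'
#' @param spec A [population_spec()].
#' @param n_individuals Number of callers (>= 1).
#' @param seed Integer seed fixing all randomness.
#' @param sex Sex of the callers: `"female"` (default), `"male"`, or a
#'   vector of length `n_individuals`. Males produce only bellows.
#' @param id_prefix Prefix for individual labels.
#' @return A tibble with columns `id`, `age`, `sex` and a list-column
#'   `base` of per-call-type named base-parameter vectors.
#' @export
generate_population <- function(spec, n_individuals, seed,
                                sex = "female", id_prefix = "F") {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (any(vapply(
    c("bellow", "tonal_rejection", "snarl"),
    function(ct) any(spec[[ct]]$between_frac < 0), logical(1)
  ))) {
    stop("between-individual SD fractions must be >= 0")
  }
  sex <- rep(sex, length.out = n_individuals)
  with_seed(seed, {
    ages <- stats::runif(n_individuals, spec$age_range[1], spec$age_range[2])
    base <- lapply(seq_len(n_individuals), function(i) {
      types <- if (sex[i] == "male") "bellow" else c("bellow", "tonal_rejection", "snarl")
      prof <- lapply(types, function(ct) {
        tab <- spec[[ct]]
        mu <- if (ct == "bellow" && sex[i] == "male") tab$male_mean else tab$mean
        b_sd <- tab$between_frac * tab$sd
        stats::setNames(
          rnorm_trunc(nrow(tab), mu, b_sd, lower = tab$lower, upper = tab$upper),
          tab$param
        )
      })
      stats::setNames(prof, types)
    })
    tibble::tibble(
      id = sprintf(
        "%s%02d", ifelse(sex == "male", "M", id_prefix),
        seq_len(n_individuals)
      ),
      age = ages,
      sex = sex,
      base = base
    )
  })
}

#' Realize the parameters of one call
#'
#' Draws one call's parameters around a caller's base parameters:
#' within-individual scatter per parameter, age-slope shifts for tonal-call
#' F0 features, and NLP flags from the configured prevalences. Uses the
#' current RNG stream (seed it, e.g. via `set.seed()`, for reproducibility).
#'
#' @param profile One row of [generate_population()] output (tibble row or
#'   list with `id`, `age`, `sex`, `base`).
#' @param call_type `"bellow"`, `"snarl"`, or `"tonal_rejection"`.
#' @param spec The [population_spec()] the population was generated from.
#' @return A `call_parameters` object: `call_type`, `duration`, `f0`
#'   (mean/min/max/sumvar, absent for snarls), `formants` and `bandwidths`
#'   (absent for tonal calls), and `nlp` (chaos, subharmonic ratio,
#'   biphonation, G0).
#' @export
realize_call_parameters <- function(profile, call_type, spec = population_spec()) {
  if (!call_type %in% c("bellow", "snarl", "tonal_rejection")) {
    stop("unknown call type: ", call_type)
  }
  base_all <- if (is.data.frame(profile)) profile$base[[1]] else profile$base
  sex <- if (is.data.frame(profile)) profile$sex[[1]] else profile$sex
  age <- if (is.data.frame(profile)) profile$age[[1]] else profile$age
  if (call_type != "bellow" && identical(sex, "male")) {
    stop("male profiles produce bellows only")
  }
  base <- base_all[[call_type]]
  if (is.null(base)) stop("profile has no base parameters for ", call_type)
  tab <- spec[[call_type]]
  w_sd <- sqrt(pmax(0, 1 - tab$between_frac^2)) * tab$sd
  val <- stats::setNames(
    rnorm_trunc(nrow(tab), base[tab$param], w_sd,
      lower = tab$lower, upper = tab$upper),
    tab$param
  )

  if (call_type == "tonal_rejection") {
    da <- age - spec$reference_age
    sl <- spec$age_slopes
    val["mean_f0_hz"] <- max(tab$lower[tab$param == "mean_f0_hz"],
      val["mean_f0_hz"] + sl["mean_f0_hz"] * da)
    # extrema slopes act on the gaps so min <= mean <= max is preserved
    val["gap_down_hz"] <- max(0.5, val["gap_down_hz"] +
      (sl["mean_f0_hz"] - sl["min_f0_hz"]) * da)
    val["gap_up_hz"] <- max(0.5, val["gap_up_hz"] +
      (sl["max_f0_hz"] - sl["mean_f0_hz"]) * da)
    val["f0_sumvar_hz"] <- max(0, val["f0_sumvar_hz"] + sl["f0_sumvar_hz"] * da)
  }

  f0 <- NULL
  if (call_type %in% c("bellow", "tonal_rejection")) {
    # the floor keeps the realized minimum F0 inside the call type's
    # measurable search range
    f0_floor <- if (call_type == "bellow") 12 else 200
    f0_ceiling <- if (call_type == "bellow") 95 else 2400
    f0 <- list(
      mean = unname(val["mean_f0_hz"]),
      min = unname(pmax(f0_floor, val["mean_f0_hz"] - val["gap_down_hz"])),
      max = unname(pmin(f0_ceiling,
        pmax(val["mean_f0_hz"], val["mean_f0_hz"] + val["gap_up_hz"]))),
      sumvar = unname(val["f0_sumvar_hz"])
    )
    # construct the F0 contour now and record what it actually realizes:
    # the drawn extrema/modulation are demands, and physics (vibrato
    # amplitude and rate limits over the drawn range and duration) can
    # bind, so the recorded parameters must match the rendered call
    f_v <- if (call_type == "bellow") 0.35 else 8
    t_voiced <- if (call_type == "bellow") {
      sum(bellow_segment_plan(val["duration_s"])$dur[
        bellow_segment_plan(val["duration_s"])$label == "inhalation"
      ])
    } else {
      unname(val["duration_s"])
    }
    path <- f0_contour_path(f0$min, f0$max, f0$mean, f0$sumvar,
      t_voiced, vibrato_rate = f_v)
    realized <- contour_realized_stats(path, t_voiced)
    f0$min <- realized$min
    f0$max <- realized$max
    f0$sumvar <- realized$sumvar
    f0$path <- path
  }
  formants <- NULL
  if (call_type %in% c("bellow", "snarl")) {
    formants <- sort(unname(val[sprintf("f%d_hz", 1:6)]))
  }

  nlp <- list(chaos = FALSE, subharmonic_ratio = NA_character_,
              biphonation = FALSE, g0 = NA_real_)
  if (call_type %in% c("bellow", "snarl")) {
    nlp$chaos <- TRUE
  } else {
    prev <- spec$tonal_prevalence
    u <- stats::runif(3)
    nlp$chaos <- u[1] < prev["chaos"]
    if (u[2] < prev["subharmonics"]) {
      pr <- spec$subharmonic_ratio_probs
      nlp$subharmonic_ratio <- sample(names(pr), 1, prob = pr)
    }
    # biphonation only in higher-F0 calls (squawks/screams): below ~550 Hz
    # the modulation sidebands are not spectrally separable from the
    # subharmonic grid, and observed biphonic calls average ~847 Hz mean F0
    if (u[3] < prev["biphonation"] && val["mean_f0_hz"] >= 550) {
      nlp$biphonation <- TRUE
      g0 <- unname(val["g0_hz"])
      # keep G0 away from integer fractions of F0: amplitude modulation at
      # F0/k is period-k subharmonics, not an independent second frequency
      g0 <- min(spec$g0_band[2], max(spec$g0_band[1], g0))
      # modulation sidebands at h*F0 +/- G0 must stay clear of the
      # subharmonic grids (F0/2, F0/3) and their spectral reference
      # positions, so G0 near these fractions of F0 is excluded
      mult <- c(1, 3 / 4, 2 / 3, 1 / 2, 1 / 3, 1 / 4)
      fks <- unname(val["mean_f0_hz"]) * mult
      allowed <- function(g) {
        g >= spec$g0_band[1] && g <= spec$g0_band[2] &&
          all(g <= 0.8 * fks | g >= 1.25 * fks)
      }
      if (!allowed(g0)) {
        # snap to a point comfortably outside the zone edges
        cand <- c(0.72 * fks, 1.33 * fks, spec$g0_band)
        cand <- cand[vapply(cand, allowed, logical(1))]
        if (length(cand) > 0) g0 <- cand[which.min(abs(cand - g0))]
      }
      nlp$g0 <- g0
    }
  }

  structure(
    list(
      call_type = call_type,
      individual = if (is.data.frame(profile)) profile$id[[1]] else profile$id,
      age = age,
      sex = sex,
      duration = unname(val["duration_s"]),
      f0 = f0,
      formants = formants,
      bandwidths = if (!is.null(formants)) spec$formant_bandwidth_frac * formants,
      nlp = nlp
    ),
    class = "call_parameters"
  )
}

#' @export
print.call_parameters <- function(x, ...) {
  cat(sprintf("<call_parameters> %s, %.2f s", x$call_type, x$duration))
  if (!is.null(x$f0)) {
    cat(sprintf(
      ", F0 %.1f (%.1f-%.1f) Hz, sumvar %.1f Hz/s",
      x$f0$mean, x$f0$min, x$f0$max, x$f0$sumvar
    ))
  }
  if (!is.null(x$formants)) {
    cat("\n  formants:", paste(round(x$formants, 1), collapse = ", "), "Hz")
  }
  cat(sprintf(
    "\n  NLP: chaos=%s subharmonics=%s biphonation=%s",
    x$nlp$chaos, x$nlp$subharmonic_ratio, x$nlp$biphonation
  ))
  if (isTRUE(x$nlp$biphonation)) cat(sprintf(" (G0 %.1f Hz)", x$nlp$g0))
  cat("\n")
  invisible(x)
}
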