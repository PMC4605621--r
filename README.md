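# koalacall

Source-filter acoustic analysis of koala (*Phascolarctos cinereus*)
vocalisations in R.

Female koalas produce three acoustically distinct call classes: **bellows**
(long calls with a very low fundamental frequency, near 31 Hz, and six
formants between roughly 260 and 2600 Hz), **snarls** (short broadband
noise with six spectral peaks up to ~6.5 kHz and no fundamental), and
**tonal rejection calls** (short high-pitched calls, F0 near 790 Hz, that
often carry nonlinear phenomena: subharmonics at F0/2 or F0/3, biphonation
visible as amplitude modulation at a second frequency G0, and episodes of
deterministic chaos). Under the source-filter theory of vocal production,
the source features (F0 and its statistics) and filter features (formants
F1–F6 and their spacing ΔF) of these calls can carry information about the
caller's identity, age and sex.

`koalacall` implements the full analysis chain for this problem, end to
end, on synthetic data — no field recordings are required:

* **Synthesis** — a generative model of a caller population
  (`population_spec()`, `generate_population()`,
  `realize_call_parameters()`, `synthesize_call()`,
  `build_feature_table()`) whose defaults reproduce the descriptive
  statistics of the study population, including per-individual parameter
  offsets, age slopes on tonal-call F0, and male/female bellow differences.
* **Feature extraction** — `extract_features()` measures duration, the F0
  contour (normalized cross-correlation tracking, `track_f0()`), formants
  (Burg LPC, `measure_formants()`), formant spacing
  (`estimate_delta_f()`), and the three nonlinear phenomena
  (`detect_chaos()`, `detect_subharmonics()`, `detect_biphonation()`) with
  per-call-type presets, plus `spectrogram()` for display.
* **Biomechanics** — the vocal-fold string model `F0 = (1/2L)·sqrt(σ/ρ)`
  (`string_f0()`, `string_stress()`), estimated vocal tract length
  `eVTL = c/(2ΔF)` (`estimate_vtl()`), and uniform-tube formant
  prediction `F_i = (2i−1)·ΔF/2` (`tube_formants()`).
* **Statistics** — mixed-variable two-step clustering with log-likelihood
  merge distance and silhouette model selection (`two_step_cluster()`),
  canonical discriminant analysis with exact leave-one-out classification
  and Wilks' Λ (`discriminant_analysis()`), exact binomial tests against
  chance (`binomial_vs_chance()`), univariate group tests
  (`group_means_tests()`), and MANOVAs of per-subject means on age or sex
  (`manova_features()`).
* **Pipeline** — `run_pipeline()` chains synthesis → extraction →
  filtering → clustering → per-cluster DFA → MANOVAs and writes CSV/JSON
  results with a reproducibility manifest.

Results are tibbles (or small S3 objects with `tidy()` / `glance()` /
`autoplot()` methods) so everything composes with the tidyverse.

## Worked example

```r
library(koalacall)

# a synthetic cohort matching the study design:
# 12 callers x 8 bellows, 14 x 8 tonal rejection calls, 6 x 5 snarls
tab <- build_feature_table(seed = 1, design = default_study_design())

# call-type structure: two-step clustering over k = 2..6
cl <- two_step_cluster(tab)
cl$silhouette
#> # A tibble: 5 × 2
#>       k silhouette
#>   <int>      <dbl>
#> 1     2      0.647
#> 2     3      0.725
#> 3     4      0.605
#> 4     5      0.585
#> 5     6      0.610
cl$chosen_k
#> [1] 3

# caller identity in bellows: DFA with leave-one-out cross-validation
bellows <- dplyr::filter(tab, call_type == "bellow")
d <- discriminant_analysis(bellows, "individual")
glance(d)[, c("wilks_lambda", "resubstitution_pct", "loo_pct", "binomial_p")]
#> # A tibble: 1 × 4
#>   wilks_lambda resubstitution_pct loo_pct binomial_p
#>          <dbl>              <dbl>   <dbl>      <dbl>
#> 1     0.000266               95.8    77.1   5.58e-60

# biomechanics: tract length implied by the bellow formant spacing
estimate_vtl(423.5) * 100   # cm
#> [1] 41.32231
```

The silhouette table says the three-cluster solution (bellows, snarls,
tonal rejection calls) fits best; the DFA says bellows are strongly
individually distinctive (leave-one-out classification far above the 1/12
chance rate, exact binomial p << 0.001); and the 41 cm estimated vocal
tract length — far longer than a koala's head — reproduces the anomaly
that motivates non-uniform vocal tract models for bellows.

Synthesis and measurement round-trip directly:

```r
spec <- population_spec()
pop <- generate_population(spec, n_individuals = 3, seed = 2)
set.seed(2)
params <- realize_call_parameters(pop[1, ], "snarl", spec)
rec <- synthesize_call(params)          # a call_recording
feats <- extract_features(rec, "snarl") # measures it back
write_wav(rec, "snarl.wav")
```

## Documentation

The methods vignette (`vignettes/koala-call-analysis.Rmd`) describes the
generative model, the measurement algorithms and their parameters, the
statistical procedures, and the package's design decisions and known
limitations.
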