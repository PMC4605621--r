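#' Pipeline run configuration
#'
#' Bundles the settings for a full analysis run: synthesis design (or an
#' input directory of WAV files), statistics options and the seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for all randomness.
#' @param design Synthesis design tibble ([default_study_design()]); used
#'   when `audio_dir` is `NULL`.
#' @param spec A [population_spec()].
#' @param audio_dir Optional directory of WAV files named
#'   `<individual>_<calltype>_<index>.wav`; when given, features are
#'   extracted from audio instead of synthesized directly.
#' @param k_range Candidate cluster-count range, length 2 (default 2-6).
#' @param min_calls Minimum calls per individual and call type (default 4).
#' @param priors DFA priors, `"proportional"` or `"uniform"`.
#' @param include_sex_contrast Also synthesize a male bellow cohort and run
#'   the sex MANOVA (default `TRUE`; ignored with `audio_dir`).
#' @param n_males,calls_per_male Male cohort size for the sex contrast.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, design = default_study_design(),
                       spec = population_spec(), audio_dir = NULL,
                       k_range = c(2, 6), min_calls = 4,
                       priors = "proportional", include_sex_contrast = TRUE,
                       n_males = 20, calls_per_male = 14) {
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), design = design,
      spec = spec, audio_dir = audio_dir, k_range = k_range,
      min_calls = min_calls, priors = priors,
      include_sex_contrast = include_sex_contrast,
      n_males = n_males, calls_per_male = calls_per_male
    ),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Chains the stages of the analysis on one configuration: feature input
#' (synthesis or extraction from WAV files), the minimum-calls filter,
#' two-step clustering over the candidate k range, a per-cluster
#' discriminant analysis with leave-one-out classification (each cluster
#' labelled by its majority call type), and the age and sex MANOVAs on
#' per-subject means. All result tables are written to `out_dir` together
#' with a JSON run manifest (package version, configuration snapshot,
#' output checksums, row counts per stage, seed, wall time).
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly; results are attached as
#'   `attr(, "results")`.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  # --- stage: features -----------------------------------------------------
  if (!is.null(config$audio_dir)) {
    wavs <- list.files(config$audio_dir, pattern = "\\.wav$", full.names = TRUE)
    if (length(wavs) == 0) stop("no input: no WAV files in ", config$audio_dir)
    features <- purrr::map_dfr(wavs, function(w) {
      parts <- strsplit(sub("\\.wav$", "", basename(w)), "_")[[1]]
      if (length(parts) < 3) stop("cannot parse file name: ", basename(w))
      ct <- paste(parts[2:(length(parts) - 1)], collapse = "_")
      rec <- read_wav(w, metadata = list(individual = parts[1], call_type = ct))
      extract_features(rec, ct)
    })
  } else {
    features <- build_feature_table(
      spec = config$spec, seed = config$seed, design = config$design
    )
  }
  counts$features <- nrow(features)

  # --- stage: filter -------------------------------------------------------
  filtered <- filter_min_calls(features, config$min_calls)
  counts$filtered <- nrow(filtered)

  # --- stage: clustering ---------------------------------------------------
  clus <- two_step_cluster(filtered,
    k_min = config$k_range[1], k_max = config$k_range[2], seed = config$seed
  )

  # --- stage: per-cluster DFA ----------------------------------------------
  filtered$cluster <- clus$assignment
  dfas <- list()
  for (cl in sort(unique(clus$assignment))) {
    rows <- filtered[filtered$cluster == cl, ]
    label <- names(sort(table(rows$call_type), decreasing = TRUE))[1]
    enough <- names(which(table(rows$individual) >= 2))
    rows <- rows[rows$individual %in% enough, ]
    if (length(unique(rows$individual)) < 2) next
    dfas[[paste0("cluster", cl, "_", label)]] <-
      discriminant_analysis(rows, "individual", priors = config$priors)
  }

  # --- stage: MANOVAs ------------------------------------------------------
  manovas <- list()
  tonal_means <- subject_means(filtered, "tonal_rejection")
  if (nrow(tonal_means) >= 3) {
    manovas$age_tonal <- manova_features(
      tonal_means,
      predictor = "age",
      vars = intersect(
        c("mean_f0_hz", "max_f0_hz", "min_f0_hz", "f0_sumvar_hz"),
        names(tonal_means)
      )
    )
  }
  if (isTRUE(config$include_sex_contrast) && is.null(config$audio_dir)) {
    males <- build_feature_table(
      spec = config$spec, seed = config$seed + 1000L,
      design = tibble::tibble(
        call_type = "bellow",
        n_individuals = config$n_males,
        calls_per_individual = config$calls_per_male
      ),
      sex = "male"
    )
    bellows <- dplyr::bind_rows(
      dplyr::filter(filtered, .data$call_type == "bellow")[names(males)],
      males
    )
    sex_means <- subject_means(bellows, "bellow")
    manovas$sex_bellow <- manova_features(
      sex_means,
      predictor = "sex",
      vars = intersect(
        c(
          "duration_s", "mean_f0_hz", "max_f0_hz", "min_f0_hz",
          sprintf("f%d_hz", 1:6)
        ),
        names(sex_means)
      )
    )
  }

  # --- outputs -------------------------------------------------------------
  paths <- list(features = file.path(config$out_dir, "features.csv"))
  write_feature_table(features, paths$features)
  paths$silhouette <- file.path(config$out_dir, "cluster_silhouette.csv")
  readr::write_csv(clus$silhouette, paths$silhouette)
  paths$assignment <- file.path(config$out_dir, "cluster_assignment.csv")
  readr::write_csv(
    tibble::tibble(
      individual = filtered$individual, call_type = filtered$call_type,
      cluster = filtered$cluster
    ),
    paths$assignment
  )
  for (nm in names(dfas)) {
    p <- file.path(config$out_dir, paste0("dfa_", nm, "_structure.csv"))
    readr::write_csv(
      tibble::as_tibble(dfas[[nm]]$structure_matrix, rownames = "variable"), p
    )
    paths[[paste0("dfa_", nm)]] <- p
  }
  summary_list <- list(
    chosen_k = clus$chosen_k,
    silhouette = stats::setNames(
      as.list(clus$silhouette$silhouette), clus$silhouette$k
    ),
    dfa = lapply(dfas, function(d) {
      list(
        n = d$n, groups = d$k, wilks_lambda = d$wilks_lambda,
        chi_sq = d$chi_sq, df = d$chi_df, p_value = d$p_value,
        resubstitution_pct = d$resubstitution_pct, loo_pct = d$loo_pct,
        chance_uniform = d$chance_uniform,
        binomial_p_uniform = d$binomial_p$uniform,
        binomial_p_proportional = d$binomial_p$proportional
      )
    }),
    manova = lapply(manovas, function(m) {
      list(
        predictor = m$predictor, n = m$n,
        multivariate = if (!is.null(m$multivariate)) as.list(m$multivariate),
        univariate = m$univariate
      )
    })
  )
  paths$summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary_list, paths$summary,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("koalacall")),
    seed = config$seed,
    config = list(
      k_range = config$k_range, min_calls = config$min_calls,
      priors = config$priors,
      design = as.data.frame(config$design),
      audio_dir = config$audio_dir %||% NA
    ),
    row_counts = counts,
    checksums = as.list(tools::md5sum(unlist(paths))),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  attr(manifest, "results") <- list(
    features = features, filtered = filtered, cluster = clus,
    dfa = dfas, manova = manovas
  )
  invisible(manifest)
}
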