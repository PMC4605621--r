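#' Per-subject mean feature table
#'
#' Averages the measure columns over each caller's calls of one call type
#' (one row per subject), the input expected by [manova_features()].
#'
#' @param data A feature table.
#' @param call_type Optional call type to filter to first.
#' @return A tibble with one row per individual.
#' @export
subject_means <- function(data, call_type = NULL) {
  if (!is.null(call_type)) {
    data <- dplyr::filter(data, .data$call_type == .env$call_type)
  }
  meas <- intersect(feature_columns, names(data))
  data |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(
      age = dplyr::first(.data$age),
      sex = dplyr::first(.data$sex),
      n_calls = dplyr::n(),
      dplyr::across(dplyr::all_of(meas), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' MANOVA of acoustic features on age or sex
#'
#' Multivariate general linear model with one predictor (the caller's age,
#' a continuous covariate, or sex, a two-level factor) and the per-subject
#' mean acoustic measures as dependent variables. Reports the multivariate
#' Wilks' lambda with its F approximation, and per-variable univariate F
#' tests with the effect direction (regression slope for age; group mean
#' difference for sex). When the subject count is too small for the
#' multivariate test (`n <= p + 1`) that test is skipped with a warning and
#' the univariate tests are still returned.
#'
#' @param data Per-subject means, e.g. from [subject_means()].
#' @param predictor `"age"` or `"sex"`.
#' @param vars Dependent variable columns; default: all measure columns
#'   present that are complete and non-constant.
#' @return A `koala_manova` object; see [tidy.koala_manova()] and
#'   [glance.koala_manova()].
#' @export
manova_features <- function(data, predictor = c("age", "sex"), vars = NULL) {
  predictor <- match.arg(predictor)
  if (is.null(vars)) {
    vars <- intersect(feature_columns, names(data))
    keep <- vapply(vars, function(v) {
      col <- data[[v]]
      !anyNA(col) && stats::sd(col) > 0
    }, logical(1))
    vars <- vars[keep]
  }
  if (length(vars) == 0) stop("no usable dependent variables")
  Y <- as.matrix(data[vars])
  if (anyNA(Y)) stop("missing values in dependent variables")
  x <- if (predictor == "sex") droplevels(factor(data$sex)) else data$age
  if (predictor == "sex" && nlevels(x) != 2) stop("sex must have two levels")
  n <- nrow(Y)
  p <- ncol(Y)

  multivariate <- NULL
  if (n > p + 1 && p >= 2) {
    fit <- stats::manova(Y ~ x)
    sm <- summary(fit, test = "Wilks")$stats
    multivariate <- tibble::tibble(
      wilks_lambda = sm["x", "Wilks"],
      statistic = sm["x", "approx F"],
      df1 = sm["x", "num Df"],
      df2 = sm["x", "den Df"],
      p_value = sm["x", "Pr(>F)"]
    )
  } else if (n > p + 1 && p == 1) {
    # a single dependent variable: the multivariate test reduces exactly
    # to the univariate F test, with Wilks' lambda = RSS / TSS
    lf <- stats::lm(Y[, 1] ~ x)
    an <- stats::anova(lf)
    multivariate <- tibble::tibble(
      wilks_lambda = an$`Sum Sq`[2] / sum(an$`Sum Sq`),
      statistic = an$`F value`[1],
      df1 = an$Df[1],
      df2 = an$Df[2],
      p_value = an$`Pr(>F)`[1]
    )
  } else {
    warning("n <= p + 1: multivariate test skipped; univariate tests reported")
  }

  univariate <- purrr::map_dfr(vars, function(v) {
    lf <- stats::lm(data[[v]] ~ x)
    an <- stats::anova(lf)
    eff <- if (predictor == "sex") {
      # difference of group means, second level minus first
      diff(tapply(data[[v]], x, mean))
    } else {
      stats::coef(lf)[2]
    }
    tibble::tibble(
      variable = v,
      effect = unname(eff),
      direction = sign(unname(eff)),
      statistic = an$`F value`[1],
      df1 = an$Df[1],
      df2 = an$Df[2],
      p_value = an$`Pr(>F)`[1]
    )
  })

  structure(
    list(
      predictor = predictor, vars = vars, n = n, p = p,
      multivariate = multivariate, univariate = univariate
    ),
    class = "koala_manova"
  )
}

#' @export
print.koala_manova <- function(x, ...) {
  cat(sprintf(
    "<koala_manova> predictor = %s; %d subjects, %d dependent variables\n",
    x$predictor, x$n, x$p
  ))
  if (!is.null(x$multivariate)) {
    with(x$multivariate, cat(sprintf(
      "  Wilks' lambda = %.3f, F(%g, %g) = %.3f, p = %.3g\n",
      wilks_lambda, df1, df2, statistic, p_value
    )))
  } else {
    cat("  multivariate test skipped (n <= p + 1)\n")
  }
  print(x$univariate)
  invisible(x)
}

#' Univariate tests of equality of group means
#'
#' One-way ANOVA of each measure across groups, with the univariate Wilks'
#' lambda (`SSW / SST`). Constant variables are reported as not computable
#' rather than tested.
#'
#' @param data A feature table.
#' @param group Grouping column name (default `"individual"`).
#' @param vars Measure columns; default: all measure columns present
#'   without missing values.
#' @return A tibble: `variable`, `wilks_lambda`, `statistic` (F), `df1`,
#'   `df2`, `p_value`, `computable`.
#' @export
group_means_tests <- function(data, group = "individual", vars = NULL) {
  g <- droplevels(factor(data[[group]]))
  if (nlevels(g) < 2) stop("need at least two groups")
  if (is.null(vars)) {
    vars <- intersect(feature_columns, names(data))
    vars <- vars[vapply(vars, function(v) !anyNA(data[[v]]), logical(1))]
  }
  purrr::map_dfr(vars, function(v) {
    y <- data[[v]]
    if (stats::sd(y) == 0) {
      return(tibble::tibble(
        variable = v, wilks_lambda = NA_real_, statistic = NA_real_,
        df1 = NA_integer_, df2 = NA_integer_, p_value = NA_real_,
        computable = FALSE
      ))
    }
    an <- stats::anova(stats::lm(y ~ g))
    ssb <- an$`Sum Sq`[1]
    ssw <- an$`Sum Sq`[2]
    tibble::tibble(
      variable = v,
      wilks_lambda = ssw / (ssb + ssw),
      statistic = an$`F value`[1],
      df1 = an$Df[1],
      df2 = an$Df[2],
      p_value = an$`Pr(>F)`[1],
      computable = TRUE
    )
  })
}

#' Keep only individuals with enough calls
#'
#' Drops, within each call type, the individuals contributing fewer than
#' `min_calls` calls. The retained per-individual counts are attached as
#' `attr(, "retained")`.
#'
#' @param data A feature table.
#' @param min_calls Minimum calls per individual and call type (default 4).
#' @return The filtered table.
#' @export
filter_min_calls <- function(data, min_calls = 4) {
  if (min_calls < 1) stop("min_calls must be >= 1")
  out <- data |>
    dplyr::group_by(.data$call_type, .data$individual) |>
    dplyr::filter(dplyr::n() >= min_calls) |>
    dplyr::ungroup()
  if (nrow(out) == 0) stop("no individuals retain >= ", min_calls, " calls")
  attr(out, "retained") <- out |>
    dplyr::count(.data$call_type, .data$individual, name = "n_calls")
  out
}
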