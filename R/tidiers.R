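#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a discriminant analysis
#'
#' One row per canonical function: eigenvalue, percentage of variance and
#' cumulative percentage.
#'
#' @param x A `koala_dfa` from [discriminant_analysis()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.koala_dfa <- function(x, ...) {
  tibble::tibble(
    "function" = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    pct_variance = x$pct_variance,
    cumulative_pct = cumsum(x$pct_variance)
  )
}

#' Glance at a discriminant analysis
#'
#' @param x A `koala_dfa`.
#' @param ... Unused.
#' @return A one-row tibble: group count, Wilks' lambda, chi-square test,
#'   classification rates and the binomial test against 1/g chance.
#' @export
glance.koala_dfa <- function(x, ...) {
  tibble::tibble(
    n = x$n, groups = x$k, n_vars = x$p,
    wilks_lambda = x$wilks_lambda,
    chi_sq = x$chi_sq, df = x$chi_df, p_value = x$p_value,
    resubstitution_pct = x$resubstitution_pct,
    loo_pct = x$loo_pct,
    chance_pct = 100 * x$chance_uniform,
    binomial_p = if (!is.null(x$binomial_p)) x$binomial_p$uniform else NA_real_
  )
}

#' Tidy a MANOVA result
#'
#' The univariate follow-up tests, one row per dependent variable.
#'
#' @param x A `koala_manova` from [manova_features()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.koala_manova <- function(x, ...) x$univariate

#' Glance at a MANOVA result
#'
#' @param x A `koala_manova`.
#' @param ... Unused.
#' @return A one-row tibble with the multivariate Wilks test (all `NA` when
#'   it was skipped).
#' @export
glance.koala_manova <- function(x, ...) {
  if (is.null(x$multivariate)) {
    return(tibble::tibble(
      predictor = x$predictor, n = x$n, n_vars = x$p,
      wilks_lambda = NA_real_, statistic = NA_real_,
      df1 = NA_real_, df2 = NA_real_, p_value = NA_real_
    ))
  }
  dplyr::bind_cols(
    tibble::tibble(predictor = x$predictor, n = x$n, n_vars = x$p),
    x$multivariate
  )
}

#' Tidy a clustering solution
#'
#' @param x A `two_step_cluster` from [two_step_cluster()].
#' @param ... Unused.
#' @return A tibble of candidate k vs silhouette, flagging the chosen k.
#' @export
tidy.two_step_cluster <- function(x, ...) {
  dplyr::mutate(x$silhouette, chosen = .data$k == x$chosen_k)
}

#' Glance at a clustering solution
#'
#' @param x A `two_step_cluster`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `chosen_k`, `best_silhouette`.
#' @export
glance.two_step_cluster <- function(x, ...) {
  tibble::tibble(
    n = x$n, chosen_k = x$chosen_k,
    best_silhouette = max(x$silhouette$silhouette)
  )
}
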