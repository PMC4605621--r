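# Core canonical discriminant fit on a numeric matrix. Returns what both
# the user-facing wrapper and the leave-one-out refits need.
dfa_fit <- function(X, g, priors, ridge_tol = 1e-10, warn = TRUE) {
  g <- droplevels(g)
  n <- nrow(X)
  p <- ncol(X)
  lev <- levels(g)
  ng <- table(g)
  if (any(ng < 2)) stop("every group needs at least two rows")
  k <- length(lev)
  means <- do.call(rbind, lapply(lev, function(l) colMeans(X[g == l, , drop = FALSE])))
  rownames(means) <- lev
  grand <- colMeans(X)

  Xc <- X - means[as.integer(g), , drop = FALSE] # within-group centred
  W <- crossprod(Xc)
  B <- crossprod(sweep(means, 2, grand) * sqrt(as.numeric(ng)))

  Sw <- W / (n - k)
  ridged <- FALSE
  if (rcond(Sw) < ridge_tol) {
    lambda <- 1e-6 * sum(diag(Sw)) / p
    Sw <- Sw + diag(lambda, p)
    W <- Sw * (n - k)
    ridged <- TRUE
    if (warn) warning("singular pooled covariance: ridge inflation applied")
  }

  ev <- eigen(solve(W, B))
  ord <- order(Re(ev$values), decreasing = TRUE)
  s <- min(p, k - 1)
  lambda_can <- pmax(0, Re(ev$values[ord][seq_len(s)]))
  A <- Re(ev$vectors[, ord[seq_len(s)], drop = FALSE])
  # scale so canonical variates have unit pooled within-group variance
  scl <- sqrt(diag(t(A) %*% Sw %*% A))
  A <- sweep(A, 2, scl, "/")
  rownames(A) <- colnames(X)

  wilks <- prod(1 / (1 + lambda_can))
  chi_sq <- -(n - 1 - (p + k) / 2) * log(wilks)
  chi_df <- p * (k - 1)

  prior <- switch(priors,
    proportional = as.numeric(ng) / n,
    uniform = rep(1 / k, k),
    stop("priors must be 'proportional' or 'uniform'")
  )
  names(prior) <- lev

  Sinv <- solve(Sw)
  list(
    levels = lev, means = means, Sw = Sw, Sinv = Sinv, W = W, B = B,
    coef = A, eigenvalues = lambda_can, wilks = wilks,
    chi_sq = chi_sq, chi_df = chi_df, prior = prior,
    n = n, p = p, k = k, ridged = ridged, Xc = Xc
  )
}

dfa_classify <- function(fit, X) {
  sc <- vapply(seq_along(fit$levels), function(j) {
    mu <- fit$means[j, ]
    drop(X %*% (fit$Sinv %*% mu)) - 0.5 * drop(mu %*% fit$Sinv %*% mu) +
      log(fit$prior[j])
  }, numeric(nrow(X)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1)
  fit$levels[max.col(sc, ties.method = "first")]
}

#' Discriminant function analysis with leave-one-out classification
#'
#' Canonical linear discriminant analysis of a feature table: canonical
#' functions are the eigenvectors of `W^-1 B` (pooled within-group and
#' between-group SSCP), Wilks' lambda is tested with the chi-square
#' approximation `-(n - 1 - (p + g)/2) * ln(lambda)` on `p (g - 1)` df, and
#' the structure matrix holds pooled within-group correlations between each
#' variable and each canonical function. Calls are classified by linear
#' discriminant scores with log-prior offsets; classification accuracy is
#' reported both by resubstitution and by exact leave-one-out
#' cross-validation (the model is refitted without each held-out row). The
#' leave-one-out rate is compared to chance with an exact binomial test
#' ([binomial_vs_chance()]), both against `1/g` and against the
#' proportional-chance criterion `sum(prior^2)`.
#'
#' @param data A feature table (one row per call).
#' @param group Name of the grouping column (e.g. `"individual"`).
#' @param vars Discriminating variable columns; default: all measure
#'   columns present that are complete and non-constant.
#' @param priors `"proportional"` (computed from group sizes; default) or
#'   `"uniform"`.
#' @param loo Run leave-one-out cross-validation (default `TRUE`).
#' @return A `koala_dfa` object; see [tidy.koala_dfa()] and
#'   [glance.koala_dfa()].
#' @export
discriminant_analysis <- function(data, group = "individual", vars = NULL,
                                  priors = c("proportional", "uniform"),
                                  loo = TRUE) {
  priors <- match.arg(priors)
  g <- droplevels(factor(data[[group]]))
  if (nlevels(g) < 2) stop("need at least two groups")
  if (is.null(vars)) {
    vars <- intersect(feature_columns, names(data))
    keep <- vapply(vars, function(v) {
      col <- data[[v]]
      !anyNA(col) && stats::sd(col) > 0
    }, logical(1))
    vars <- vars[keep]
  }
  if (length(vars) == 0) stop("no usable discriminating variables")
  X <- as.matrix(data[vars])
  if (anyNA(X)) stop("missing values in discriminating variables")
  # classification, Wilks' lambda and the structure matrix are invariant
  # to per-variable rescaling; standardizing keeps the pooled covariance
  # well conditioned when variables live on very different scales
  X <- scale(X)

  fit <- dfa_fit(X, g, priors)

  # structure matrix: pooled within-group correlations between variables
  # and canonical scores
  scores <- fit$Xc %*% fit$coef
  sd_x <- sqrt(colSums(fit$Xc^2))
  sd_s <- sqrt(colSums(scores^2))
  structure_matrix <- crossprod(fit$Xc, scores) / outer(sd_x, sd_s)
  colnames(structure_matrix) <- paste0("df", seq_len(ncol(structure_matrix)))

  pred <- dfa_classify(fit, X)
  resub <- mean(pred == as.character(g))

  loo_pred <- NULL
  loo_rate <- NA_real_
  if (loo) {
    loo_pred <- vapply(seq_len(nrow(X)), function(i) {
      f <- dfa_fit(X[-i, , drop = FALSE], g[-i], priors, warn = FALSE)
      dfa_classify(f, X[i, , drop = FALSE])
    }, character(1))
    loo_rate <- mean(loo_pred == as.character(g))
  }

  k <- fit$k
  n <- fit$n
  chance_uniform <- 1 / k
  chance_proportional <- sum((as.numeric(table(g)) / n)^2)
  binom <- if (loo) {
    list(
      uniform = binomial_vs_chance(round(loo_rate * n), n, chance_uniform),
      proportional = binomial_vs_chance(round(loo_rate * n), n, chance_proportional)
    )
  } else {
    NULL
  }

  pct_var <- if (sum(fit$eigenvalues) > 0) {
    100 * fit$eigenvalues / sum(fit$eigenvalues)
  } else {
    rep(0, length(fit$eigenvalues))
  }

  structure(
    list(
      group = group, vars = vars, priors = priors,
      levels = fit$levels, n = n, p = fit$p, k = k,
      eigenvalues = fit$eigenvalues, pct_variance = pct_var,
      wilks_lambda = fit$wilks, chi_sq = fit$chi_sq, chi_df = fit$chi_df,
      p_value = stats::pchisq(fit$chi_sq, fit$chi_df, lower.tail = FALSE),
      coefficients = fit$coef,
      structure_matrix = structure_matrix,
      prior = fit$prior,
      predicted = pred, resubstitution_pct = 100 * resub,
      loo_predicted = loo_pred, loo_pct = 100 * loo_rate,
      chance_uniform = chance_uniform,
      chance_proportional = chance_proportional,
      binomial_p = binom,
      observed = as.character(g),
      ridged = fit$ridged
    ),
    class = "koala_dfa"
  )
}

#' @export
print.koala_dfa <- function(x, ...) {
  cat(sprintf(
    "<koala_dfa> %d calls, %d groups (%s), %d variables\n",
    x$n, x$k, x$group, x$p
  ))
  cat(sprintf(
    "  Wilks' lambda = %.4g, chi-sq(%d) = %.2f, p = %.3g\n",
    x$wilks_lambda, x$chi_df, x$chi_sq, x$p_value
  ))
  cat(sprintf("  resubstitution: %.1f%% correct\n", x$resubstitution_pct))
  if (!is.na(x$loo_pct)) {
    cat(sprintf(
      "  leave-one-out:  %.1f%% correct (chance 1/g = %.1f%%, binomial p = %.3g)\n",
      x$loo_pct, 100 * x$chance_uniform, x$binomial_p$uniform
    ))
  }
  invisible(x)
}

#' Exact binomial test against a chance rate
#'
#' Two-tailed exact binomial test of `n_correct` successes in `n_total`
#' trials against success probability `chance_p`, using the
#' point-probability method (outcomes with probability no larger than the
#' observed one are summed), capped at 1.
#'
#' @param n_correct Number of correct classifications.
#' @param n_total Number of trials.
#' @param chance_p Chance success probability, in (0, 1).
#' @return The two-tailed p-value.
#' @export
binomial_vs_chance <- function(n_correct, n_total, chance_p) {
  if (n_total < 1 || n_correct < 0 || n_correct > n_total) {
    stop("need 0 <= n_correct <= n_total, n_total >= 1")
  }
  if (chance_p <= 0 || chance_p >= 1) stop("chance_p must be in (0, 1)")
  min(1, stats::binom.test(n_correct, n_total, chance_p)$p.value)
}
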