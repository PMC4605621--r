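toy_groups <- function(sep = 4, n_per = 4, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    individual = rep(c("a", "b", "c"), each = n_per),
    duration_s = rnorm(3 * n_per, rep(c(0, sep, 2 * sep), each = n_per)),
    mean_f0_hz = rnorm(3 * n_per, rep(c(0, sep, 0), each = n_per))
  )
}

test_that("classification agrees row-for-row with a brute-force Gaussian classifier", {
  tab <- toy_groups(sep = 2.5)
  d <- discriminant_analysis(tab, "individual",
    vars = c("duration_s", "mean_f0_hz"), loo = FALSE
  )

  # independent oracle: maximize prior x Gaussian density under the pooled
  # covariance, computed from scratch on the raw data
  X <- scale(as.matrix(tab[, c("duration_s", "mean_f0_hz")]))
  g <- factor(tab$individual)
  mns <- t(sapply(levels(g), function(l) colMeans(X[g == l, , drop = FALSE])))
  S <- Reduce(`+`, lapply(levels(g), function(l) {
    xc <- sweep(X[g == l, , drop = FALSE], 2, mns[l, ])
    crossprod(xc)
  })) / (nrow(X) - nlevels(g))
  prior <- table(g) / length(g)
  pred_ref <- apply(X, 1, function(x) {
    dens <- sapply(levels(g), function(l) {
      v <- x - mns[l, ]
      as.numeric(prior[l]) * exp(-0.5 * drop(v %*% solve(S) %*% v))
    })
    names(which.max(dens))
  })
  expect_identical(d$predicted, unname(pred_ref))
})

test_that("far-separated groups are perfectly classified with tiny lambda", {
  tab <- toy_groups(sep = 15)
  d <- discriminant_analysis(tab, "individual",
    vars = c("duration_s", "mean_f0_hz")
  )
  expect_equal(d$resubstitution_pct, 100)
  expect_equal(d$loo_pct, 100)
  expect_lt(d$wilks_lambda, 0.01)
  expect_lt(d$p_value, 1e-6)
  expect_equal(sum(d$pct_variance), 100)
})

test_that("a simulated null shows lambda near 1 and chance-level accuracy", {
  set.seed(33)
  loos <- replicate(10, {
    tab <- tibble::tibble(
      individual = rep(c("a", "b"), each = 8),
      duration_s = rnorm(16),
      mean_f0_hz = rnorm(16)
    )
    d <- discriminant_analysis(tab, "individual",
      vars = c("duration_s", "mean_f0_hz")
    )
    c(d$wilks_lambda, d$loo_pct)
  })
  expect_gt(mean(loos[1, ]), 0.6) # lambda near 1 on average
  expect_lt(abs(mean(loos[2, ]) - 50), 20) # LOO about chance
})

test_that("classification is invariant to affine rescaling of variables", {
  tab <- toy_groups(sep = 2, seed = 5)
  d1 <- discriminant_analysis(tab, "individual",
    vars = c("duration_s", "mean_f0_hz")
  )
  tab2 <- tab
  tab2$duration_s <- 1000 * tab2$duration_s - 7
  tab2$mean_f0_hz <- 0.001 * tab2$mean_f0_hz + 3
  d2 <- discriminant_analysis(tab2, "individual",
    vars = c("duration_s", "mean_f0_hz")
  )
  expect_identical(d1$predicted, d2$predicted)
  expect_identical(d1$loo_predicted, d2$loo_predicted)
  expect_equal(d1$wilks_lambda, d2$wilks_lambda, tolerance = 1e-9)
})

test_that("the canonical decomposition matches an independent reference", {
  # MASS::lda as an independent cross-check on assignments and scalings
  tab <- build_feature_table(seed = 3, design = default_study_design())
  bell <- dplyr::filter(tab, call_type == "bellow")
  d <- suppressWarnings(discriminant_analysis(bell, "individual", loo = FALSE))
  ld <- suppressWarnings(
    MASS::lda(scale(as.matrix(bell[d$vars])), grouping = factor(bell$individual))
  )
  pr <- predict(ld)$class
  expect_gt(mean(as.character(pr) == d$predicted), 0.97)
})

test_that("structure matrix holds pooled within-group correlations in [-1, 1]", {
  tab <- toy_groups(sep = 3, seed = 9)
  d <- discriminant_analysis(tab, "individual",
    vars = c("duration_s", "mean_f0_hz"), loo = FALSE
  )
  expect_true(all(abs(d$structure_matrix) <= 1 + 1e-12))
  expect_equal(dim(d$structure_matrix), c(2, 2))
})

test_that("binomial test against chance matches pmf enumeration", {
  # direct summation oracle: point-probability two-tailed method
  enum_p <- function(k, n, p) {
    probs <- dbinom(0:n, n, p)
    min(1, sum(probs[probs <= dbinom(k, n, p) * (1 + 1e-7)]))
  }
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95)
    expect_equal(binomial_vs_chance(k, n, p), enum_p(k, n, p),
      tolerance = 1e-12
    )
  }
  # observing exactly the expected count gives p = 1
  expect_equal(binomial_vs_chance(10, 20, 0.5), 1)
  # strongly above-chance classification is highly significant
  expect_lt(binomial_vs_chance(73, 115, 1 / 12), 0.001)
  expect_error(binomial_vs_chance(5, 4, 0.5), "n_correct")
  expect_error(binomial_vs_chance(2, 4, 1.5), "chance_p")
})

test_that("binomial p-values shrink monotonically away from the expectation", {
  n <- 40
  p <- 0.25
  mode_k <- round(n * p)
  pv <- vapply(mode_k:n, binomial_vs_chance, numeric(1), n_total = n, chance_p = p)
  expect_true(all(diff(pv) < 1e-12))
  expect_true(all(pv > 0 & pv <= 1))
})

test_that("dfa tidiers expose eigenvalues and the test summary", {
  tab <- toy_groups(sep = 4)
  d <- discriminant_analysis(tab, "individual",
    vars = c("duration_s", "mean_f0_hz")
  )
  td <- tidy(d)
  expect_equal(nrow(td), 2)
  expect_equal(td$cumulative_pct[2], 100)
  gl <- glance(d)
  expect_true(all(c("wilks_lambda", "loo_pct", "binomial_p") %in% names(gl)))
})
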