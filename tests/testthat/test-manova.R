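test_that("one-variable two-group design reduces to the univariate F test", {
  set.seed(2)
  tab <- tibble::tibble(
    individual = sprintf("i%02d", 1:16),
    sex = rep(c("female", "male"), each = 8),
    age = runif(16, 2, 14),
    duration_s = rnorm(16, rep(c(10, 14), each = 8), 2)
  )
  mv <- manova_features(tab, "sex", vars = "duration_s")
  expect_equal(mv$multivariate$statistic, mv$univariate$statistic[1],
    tolerance = 1e-9
  )
  expect_equal(mv$multivariate$p_value, mv$univariate$p_value[1],
    tolerance = 1e-9
  )
  # effect direction is the group-mean difference
  expect_gt(mv$univariate$effect[1], 0)
})

test_that("an unrelated predictor behaves like a null", {
  set.seed(5)
  lambdas <- replicate(20, {
    tab <- tibble::tibble(
      individual = sprintf("i%02d", 1:15),
      age = runif(15, 2, 14),
      sex = "female",
      mean_f0_hz = rnorm(15, 800, 50),
      duration_s = rnorm(15, 1, 0.2)
    )
    mv <- manova_features(tab, "age", vars = c("mean_f0_hz", "duration_s"))
    c(mv$multivariate$wilks_lambda, mv$univariate$p_value)
  })
  expect_gt(mean(lambdas[1, ]), 0.7)
  # univariate p-values roughly uniform: around half above 0.5
  expect_gt(mean(lambdas[2:3, ] > 0.3), 0.4)
})

test_that("the multivariate test is skipped when subjects are too few", {
  set.seed(6)
  tab <- tibble::tibble(
    individual = sprintf("i%d", 1:5),
    age = runif(5, 2, 14), sex = "female",
    mean_f0_hz = rnorm(5), max_f0_hz = rnorm(5),
    min_f0_hz = rnorm(5), f0_sumvar_hz = rnorm(5), duration_s = rnorm(5)
  )
  expect_warning(
    mv <- manova_features(tab, "age",
      vars = c("mean_f0_hz", "max_f0_hz", "min_f0_hz", "f0_sumvar_hz", "duration_s")
    ),
    "skipped"
  )
  expect_null(mv$multivariate)
  expect_equal(nrow(mv$univariate), 5)
  expect_true(all(is.na(glance(mv)$wilks_lambda)))
})

test_that("age slopes are recovered from synthetic tonal subject means", {
  negs <- vapply(1:15, function(s) {
    tab <- build_feature_table(
      seed = s,
      design = tibble::tibble(
        call_type = "tonal_rejection", n_individuals = 14L,
        calls_per_individual = 8L
      )
    )
    mv <- manova_features(subject_means(tab), "age",
      vars = c("mean_f0_hz", "max_f0_hz", "min_f0_hz", "f0_sumvar_hz")
    )
    mv$univariate$effect[mv$univariate$variable == "mean_f0_hz"]
  }, numeric(1))
  expect_true(all(negs < 0)) # mean F0 falls with age in every replicate
  expect_equal(mean(negs), -37.23, tolerance = 0.35)
})

test_that("group-mean equality tests match a hand-computed one-way ANOVA", {
  # printed toy data, worked by hand: 3 groups x 3 values
  tab <- tibble::tibble(
    individual = rep(c("a", "b", "c"), each = 3),
    duration_s = c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  )
  # group means 2, 5, 8; grand mean 5; SSB = 3*(9 + 0 + 9) = 54; SSW = 6
  # F = (54/2) / (6/6) = 27; lambda = 6/60 = 0.1
  out <- group_means_tests(tab, "individual", vars = "duration_s")
  expect_equal(out$statistic, 27)
  expect_equal(out$wilks_lambda, 0.1)
  expect_equal(out$df1, 2)
  expect_equal(out$df2, 6)
  expect_equal(out$p_value, pf(27, 2, 6, lower.tail = FALSE))
})

test_that("constant variables are reported as not computable", {
  tab <- tibble::tibble(
    individual = rep(c("a", "b"), each = 4),
    chaos = rep(1, 8),
    duration_s = c(1, 2, 1, 2, 5, 6, 5, 6)
  )
  out <- group_means_tests(tab, "individual", vars = c("chaos", "duration_s"))
  expect_false(out$computable[out$variable == "chaos"])
  expect_true(is.na(out$statistic[out$variable == "chaos"]))
  expect_true(out$computable[out$variable == "duration_s"])
  # identical distributions across groups: lambda 1, F 0
  tab2 <- tibble::tibble(
    individual = rep(c("a", "b"), each = 3),
    duration_s = rep(c(1, 2, 3), 2)
  )
  out2 <- group_means_tests(tab2, "individual", vars = "duration_s")
  expect_equal(out2$wilks_lambda, 1)
  expect_equal(out2$statistic, 0)
})

test_that("the minimum-calls filter keeps exactly the well-sampled individuals", {
  tab <- tibble::tibble(
    individual = rep(c("a", "b", "c"), times = c(3, 4, 5)),
    call_type = "snarl",
    duration_s = 1
  )
  out <- filter_min_calls(tab, 4)
  expect_setequal(unique(out$individual), c("b", "c"))
  expect_equal(nrow(out), 9)
  expect_equal(nrow(attr(out, "retained")), 2)
  # identity at min_calls = 1; error when nothing survives
  expect_equal(nrow(filter_min_calls(tab, 1)), nrow(tab))
  expect_error(filter_min_calls(tab, 10), "retain")
})
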