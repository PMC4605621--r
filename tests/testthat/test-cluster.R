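# Direct, independent evaluation of the cluster log-likelihood criterion,
# written from the formula (not the package's incremental statistics).
xi_direct <- function(rows_cont, rows_bin, var_k) {
  n <- nrow(rows_cont)
  term <- 0
  for (k in seq_len(ncol(rows_cont))) {
    s2 <- mean(rows_cont[, k]^2) - mean(rows_cont[, k])^2
    term <- term + 0.5 * log(var_k[k] + s2)
  }
  for (k in seq_len(ncol(rows_bin))) {
    p <- mean(rows_bin[, k])
    e <- 0
    if (p > 0) e <- e - p * log(p)
    if (p < 1) e <- e - (1 - p) * log(1 - p)
    term <- term + e
  }
  -n * term
}

toy_table <- function() {
  tibble::tibble(
    duration_s = c(1.0, 1.2, 0.9, 5.1, 5.3, 5.0),
    mean_f0_hz = c(100, 110, 95, 480, 500, 470),
    chaos = c(0, 0, 0, 1, 1, 1),
    biphonation = c(1, 0, 1, 0, 0, 0)
  )
}

test_that("log-likelihood distance matches a direct evaluation on a toy table", {
  tab <- toy_table()
  st <- cluster_table_stats(tab)
  a <- 1:3
  b <- 4:6
  d_pkg <- loglik_distance(a, b, st)
  xc <- st$X_cont
  xb <- st$X_bin
  d_ref <- xi_direct(xc[a, , drop = FALSE], xb[a, , drop = FALSE], st$var_k) +
    xi_direct(xc[b, , drop = FALSE], xb[b, , drop = FALSE], st$var_k) -
    xi_direct(xc[c(a, b), , drop = FALSE], xb[c(a, b), , drop = FALSE], st$var_k)
  expect_equal(d_pkg, unname(d_ref), tolerance = 1e-12)
})

test_that("merge distance is symmetric and zero for identical binary singletons", {
  tab <- toy_table()
  st <- cluster_table_stats(tab)
  set.seed(1)
  for (i in 1:5) {
    a <- sample(1:6, 2)
    b <- setdiff(1:6, a)[1:2]
    expect_equal(loglik_distance(a, b, st), loglik_distance(b, a, st))
    expect_gte(loglik_distance(a, b, st), -1e-10)
  }
  # all-binary table: merging two identical singleton rows costs nothing
  tb <- tibble::tibble(chaos = c(1, 1, 0), subharmonics = c(0, 0, 1))
  stb <- cluster_table_stats(tb)
  expect_equal(loglik_distance(1, 2, stb), 0, tolerance = 1e-12)

  # zero-variance table column is signalled
  bad <- tibble::tibble(duration_s = rep(2, 4), mean_f0_hz = 1:4)
  expect_error(cluster_table_stats(bad), "zero-variance")
})

test_that("mixed silhouette equals a brute-force double-loop computation", {
  set.seed(4)
  tab <- tibble::tibble(
    duration_s = c(rnorm(5, 0), rnorm(5, 4)),
    mean_f0_hz = c(rnorm(5, 0), rnorm(5, 4)),
    chaos = rep(c(0, 1), each = 5)
  )
  cl <- rep(1:2, each = 5)
  s_pkg <- as.numeric(silhouette_mixed(tab, cl))

  # independent double loop over rows on the same mixed distance
  z <- scale(as.matrix(tab[, 1:2]))
  b <- tab$chaos
  dfun <- function(i, j) sqrt(sum((z[i, ] - z[j, ])^2)) + as.numeric(b[i] != b[j])
  widths <- vapply(1:10, function(i) {
    a_own <- mean(vapply(setdiff(which(cl == cl[i]), i), dfun, numeric(1), i = i))
    b_other <- mean(vapply(which(cl != cl[i]), dfun, numeric(1), i = i))
    (b_other - a_own) / max(a_own, b_other)
  }, numeric(1))
  expect_equal(s_pkg, mean(widths), tolerance = 1e-9)

  # singleton clusters take width 0 by convention
  tab2 <- tibble::tibble(duration_s = c(0, 10, 0.1), mean_f0_hz = c(0, 10, 0.1))
  s2 <- silhouette_mixed(tab2, c(1, 2, 1))
  expect_equal(unname(attr(s2, "widths")[2]), 0)
})

test_that("two far-separated blobs select k = 2 with a high silhouette", {
  set.seed(9)
  tab <- tibble::tibble(
    duration_s = c(rnorm(12, 0, 0.05), rnorm(12, 8, 0.05)),
    mean_f0_hz = c(rnorm(12, 0, 0.05), rnorm(12, 8, 0.05))
  )
  cl <- two_step_cluster(tab, k_min = 2, k_max = 4)
  expect_equal(cl$chosen_k, 2)
  expect_gt(max(cl$silhouette$silhouette), 0.9)
  truth <- rep(1:2, each = 12)
  expect_equal(length(unique(paste(truth, cl$assignment))), 2)
})

test_that("a single Gaussian blob shows no strong cluster structure", {
  set.seed(10)
  tab <- tibble::tibble(
    duration_s = rnorm(40), mean_f0_hz = rnorm(40), f1_hz = rnorm(40)
  )
  cl <- two_step_cluster(tab, k_min = 2, k_max = 6)
  expect_true(all(cl$silhouette$silhouette < 0.5))
})

test_that("agglomeration orders merges like a brute-force implementation", {
  # small continuous-only instance: replay the merge sequence with an
  # independent quadratic-time implementation of the same criterion
  set.seed(12)
  tab <- tibble::tibble(
    duration_s = rnorm(9, rep(c(0, 3, 7), each = 3), 0.5),
    mean_f0_hz = rnorm(9, rep(c(5, 0, 2), each = 3), 0.5)
  )
  st <- cluster_table_stats(tab)
  xc <- st$X_cont

  clusters <- as.list(1:9)
  merges_ref <- list()
  while (length(clusters) > 2) {
    best <- NULL
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- xi_direct(xc[clusters[[i]], , drop = FALSE], st$X_bin[clusters[[i]], , drop = FALSE], st$var_k) +
          xi_direct(xc[clusters[[j]], , drop = FALSE], st$X_bin[clusters[[j]], , drop = FALSE], st$var_k) -
          xi_direct(
            xc[c(clusters[[i]], clusters[[j]]), , drop = FALSE],
            st$X_bin[c(clusters[[i]], clusters[[j]]), , drop = FALSE], st$var_k
          )
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  ref_assign <- integer(9)
  for (i in seq_along(clusters)) ref_assign[clusters[[i]]] <- i

  cl <- two_step_cluster(tab, k_min = 2, k_max = 3)
  # same partition at k = 2 (labels may be permuted)
  expect_equal(
    length(unique(paste(ref_assign, cl$assignments[["2"]]))), 2
  )
})

test_that("tidy and glance summarize a clustering solution", {
  set.seed(2)
  tab <- tibble::tibble(
    duration_s = c(rnorm(8, 0, 0.1), rnorm(8, 5, 0.1)),
    mean_f0_hz = c(rnorm(8, 0, 0.1), rnorm(8, 5, 0.1))
  )
  cl <- two_step_cluster(tab, 2, 4)
  td <- tidy(cl)
  expect_true(all(c("k", "silhouette", "chosen") %in% names(td)))
  expect_equal(sum(td$chosen), 1L)
  gl <- glance(cl)
  expect_equal(gl$chosen_k, cl$chosen_k)
  expect_equal(gl$n, 16)
})
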