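# Identify measure columns and split them into continuous and binary sets.
# Binary columns are those whose observed values lie in {0, 1}.
split_measure_columns <- function(data, vars = NULL) {
  if (is.null(vars)) vars <- intersect(feature_columns, names(data))
  if (length(vars) == 0) stop("no measure columns found")
  is_bin <- vapply(vars, function(v) {
    u <- unique(stats::na.omit(data[[v]]))
    length(u) > 0 && all(u %in% c(0, 1))
  }, logical(1))
  list(continuous = vars[!is_bin], binary = vars[is_bin])
}

#' Precompute table-level statistics for log-likelihood clustering
#'
#' Splits the measure columns into continuous and binary sets, optionally
#' replaces missing values with 0 (the convention that a measure absent
#' from a call type is zero), and precomputes the whole-table variance of
#' each continuous column, which regularizes the within-cluster variance in
#' the log-likelihood distance.
#'
#' @param data A feature table (calls x measures).
#' @param vars Measure columns to use. The default is every recognised
#'   measure column present except `g0_hz`: G0 exists only when
#'   biphonation is present, so entering it (zero-filled) alongside the
#'   biphonation flag would double-weight a single phenomenon in the
#'   distances.
#' @param na_as_zero Replace `NA` measures by 0 (default `TRUE`).
#' @return A `cluster_table_stats` list: matrices `X_cont`, `X_bin` and the
#'   per-column variances `var_k`.
#' @export
cluster_table_stats <- function(data, vars = NULL, na_as_zero = TRUE) {
  if (is.null(vars)) {
    vars <- setdiff(intersect(feature_columns, names(data)), "g0_hz")
  }
  sp <- split_measure_columns(data, vars)
  as_mat <- function(cols) {
    if (length(cols) == 0) {
      return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
    }
    m <- as.matrix(data[cols])
    if (na_as_zero) m[is.na(m)] <- 0
    if (anyNA(m)) stop("missing values present; use na_as_zero = TRUE or complete the table")
    m
  }
  X_cont <- as_mat(sp$continuous)
  X_bin <- as_mat(sp$binary)
  n <- nrow(X_cont)
  var_k <- if (ncol(X_cont)) colSums(sweep(X_cont, 2, colMeans(X_cont))^2) / n else numeric(0)
  if (any(var_k == 0)) {
    stop(
      "zero-variance table column(s): ",
      paste(sp$continuous[var_k == 0], collapse = ", ")
    )
  }
  structure(
    list(X_cont = X_cont, X_bin = X_bin, var_k = var_k,
         continuous = sp$continuous, binary = sp$binary),
    class = "cluster_table_stats"
  )
}

# xi for clusters given sufficient statistics. `n` is a vector of cluster
# sizes, `s`/`ss` row-per-cluster matrices of sums and sums of squares of
# the continuous columns, `c1` counts of ones in the binary columns.
# xi_v = -N_v * [ sum_cont 0.5*log(var_k + s2_vk) + sum_bin entropy_vk ]
xi_from_stats <- function(n, s, ss, c1, var_k) {
  term <- numeric(length(n))
  if (length(var_k)) {
    mu <- s / n
    s2 <- ss / n - mu^2
    s2[s2 < 0] <- 0 # guard tiny negative rounding
    term <- term + rowSums(0.5 * log(sweep(s2, 2, var_k, "+")))
  }
  if (!is.null(c1) && ncol(c1)) {
    p <- c1 / n
    ent <- -(ifelse(p > 0, p * log(p), 0) + ifelse(p < 1, (1 - p) * log(1 - p), 0))
    term <- term + rowSums(ent)
  }
  -n * term
}

#' Log-likelihood merge distance between two clusters
#'
#' The two-step clustering distance for mixed continuous/binary data:
#' `d(a, b) = xi_a + xi_b - xi_{a union b}`, where for a cluster `v`,
#' `xi_v = -N_v * [ sum_k 0.5*log(sigma_hat_k^2 + sigma_vk^2) + sum_binary E_vk ]`,
#' `sigma_hat_k^2` is the whole-table variance of continuous column `k`
#' (a regularizer), `sigma_vk^2` the within-cluster variance, and `E_vk`
#' the category-proportion entropy of binary column `k`.
#'
#' @param idx_a,idx_b Row indices of the two clusters (non-empty, disjoint).
#' @param table_stats A [cluster_table_stats()].
#' @return The non-negative merge cost.
#' @export
loglik_distance <- function(idx_a, idx_b, table_stats) {
  if (length(idx_a) == 0 || length(idx_b) == 0) stop("clusters must be non-empty")
  st <- table_stats
  stat_of <- function(idx) {
    Xc <- st$X_cont[idx, , drop = FALSE]
    Xb <- st$X_bin[idx, , drop = FALSE]
    list(
      n = length(idx),
      s = matrix(colSums(Xc), 1), ss = matrix(colSums(Xc^2), 1),
      c1 = matrix(colSums(Xb), 1)
    )
  }
  a <- stat_of(idx_a)
  b <- stat_of(idx_b)
  xi <- function(z) xi_from_stats(z$n, z$s, z$ss, z$c1, st$var_k)
  m <- list(n = a$n + b$n, s = a$s + b$s, ss = a$ss + b$ss, c1 = a$c1 + b$c1)
  unname(xi(a) + xi(b) - xi(m))
}

#' Mixed-data silhouette score
#'
#' Silhouette of a partition under the package's mixed distance: Euclidean
#' distance on z-scored continuous columns plus one unit per binary
#' mismatch. Rows in singleton clusters take silhouette width 0.
#'
#' @param data A feature table.
#' @param assignment Cluster labels, one per row (>= 2 non-empty clusters).
#' @param vars,na_as_zero Passed to [cluster_table_stats()].
#' @return The mean silhouette width, with per-row widths in
#'   `attr(, "widths")`.
#' @export
silhouette_mixed <- function(data, assignment, vars = NULL, na_as_zero = TRUE) {
  st <- cluster_table_stats(data, vars, na_as_zero)
  D <- mixed_distance_matrix(st)
  cl <- as.integer(factor(assignment))
  if (length(unique(cl)) < 2) stop("need at least two clusters")
  sil <- cluster::silhouette(cl, dmatrix = D)
  widths <- sil[, "sil_width"]
  out <- mean(widths)
  attr(out, "widths") <- widths
  out
}

mixed_distance_matrix <- function(st) {
  n <- nrow(st$X_cont)
  D <- matrix(0, n, n)
  if (ncol(st$X_cont)) {
    D <- as.matrix(stats::dist(scale(st$X_cont)))
  }
  if (ncol(st$X_bin)) {
    B <- st$X_bin
    D <- D + B %*% t(1 - B) + (1 - B) %*% t(B)
  }
  D
}

#' Two-step clustering with silhouette model selection
#'
#' Mixed-variable clustering: agglomerative merging under the
#' log-likelihood distance ([loglik_distance()]) down to each candidate
#' number of clusters, silhouette scoring of each candidate partition, and
#' selection of the number of clusters with the highest silhouette (ties
#' resolved towards fewer clusters). The agglomeration is exact (no
#' pre-clustering pass); it is deterministic, so `seed` only documents the
#' run.
#'
#' @param data A feature table.
#' @param k_min,k_max Candidate range for the number of clusters
#'   (default 2-6).
#' @param vars,na_as_zero Passed to [cluster_table_stats()].
#' @param seed Optional integer recorded in the result.
#' @return A `two_step_cluster` object: `silhouette` (tibble of k vs
#'   score), `chosen_k`, `assignment` (labels for the chosen k), and
#'   `assignments` (list of labels per candidate k).
#' @export
two_step_cluster <- function(data, k_min = 2, k_max = 6, vars = NULL,
                             na_as_zero = TRUE, seed = NULL) {
  st <- cluster_table_stats(data, vars, na_as_zero)
  n <- nrow(st$X_cont)
  if (k_max > n) stop("k_max exceeds the number of rows")
  if (k_min < 2 || k_min > k_max) stop("need 2 <= k_min <= k_max")

  # sufficient statistics per active cluster
  sz <- rep(1, n)
  S <- st$X_cont
  SS <- st$X_cont^2
  C1 <- st$X_bin
  active <- rep(TRUE, n)
  labels <- seq_len(n)
  xi <- xi_from_stats(sz, S, SS, C1, st$var_k)

  # full pairwise merge-cost matrix, vectorized per variable
  pair_xi <- function() {
    N <- outer(sz, sz, "+")
    term <- matrix(0, n, n)
    for (k in seq_len(ncol(S))) {
      SUM <- outer(S[, k], S[, k], "+")
      SSQ <- outer(SS[, k], SS[, k], "+")
      s2 <- pmax(0, SSQ / N - (SUM / N)^2)
      term <- term + 0.5 * log(s2 + st$var_k[k])
    }
    for (k in seq_len(ncol(C1))) {
      P <- outer(C1[, k], C1[, k], "+") / N
      term <- term + -(ifelse(P > 0, P * log(P), 0) +
        ifelse(P < 1, (1 - P) * log(1 - P), 0))
    }
    -N * term
  }
  D <- outer(xi, xi, "+") - pair_xi()
  diag(D) <- Inf

  # merge cost of cluster i against all active clusters, vectorized
  costs_vs <- function(i, act) {
    nn <- sz[act] + sz[i]
    s <- sweep(S[act, , drop = FALSE], 2, S[i, ], "+")
    ss <- sweep(SS[act, , drop = FALSE], 2, SS[i, ], "+")
    c1 <- if (ncol(C1)) sweep(C1[act, , drop = FALSE], 2, C1[i, ], "+") else C1[act, , drop = FALSE]
    xi[act] + xi[i] - xi_from_stats(nn, s, ss, c1, st$var_k)
  }

  snapshots <- list()
  m <- n
  while (m > k_min) {
    idx <- which.min(D) # first minimum: deterministic tie-break
    j <- ((idx - 1) %/% n) + 1
    i <- ((idx - 1) %% n) + 1
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    # merge j into i
    sz[i] <- sz[i] + sz[j]
    S[i, ] <- S[i, ] + S[j, ]
    SS[i, ] <- SS[i, ] + SS[j, ]
    if (ncol(C1)) C1[i, ] <- C1[i, ] + C1[j, ]
    active[j] <- FALSE
    labels[labels == labels[j]] <- labels[i]
    xi[i] <- xi_from_stats(sz[i], S[i, , drop = FALSE], SS[i, , drop = FALSE],
      C1[i, , drop = FALSE], st$var_k)
    D[j, ] <- Inf
    D[, j] <- Inf
    oth <- which(active & seq_len(n) != i)
    if (length(oth)) {
      cst <- costs_vs(i, oth)
      D[i, oth] <- cst
      D[oth, i] <- cst
    }
    m <- m - 1
    if (m <= k_max && m >= k_min) {
      snapshots[[as.character(m)]] <- as.integer(factor(labels))
    }
  }

  ks <- k_min:k_max
  ks <- ks[as.character(ks) %in% names(snapshots)]
  Dm <- mixed_distance_matrix(st)
  sil <- vapply(ks, function(k) {
    cl <- snapshots[[as.character(k)]]
    mean(cluster::silhouette(cl, dmatrix = Dm)[, "sil_width"])
  }, numeric(1))
  best <- ks[which.max(sil)] # which.max breaks ties towards smaller k
  structure(
    list(
      silhouette = tibble::tibble(k = ks, silhouette = sil),
      chosen_k = best,
      assignment = snapshots[[as.character(best)]],
      assignments = snapshots,
      n = n,
      seed = seed
    ),
    class = "two_step_cluster"
  )
}

#' @export
print.two_step_cluster <- function(x, ...) {
  cat(sprintf(
    "<two_step_cluster> n = %d; chosen k = %d (silhouette %.3f)\n",
    x$n, x$chosen_k, x$silhouette$silhouette[x$silhouette$k == x$chosen_k]
  ))
  print(x$silhouette)
  invisible(x)
}
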