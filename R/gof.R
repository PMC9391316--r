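# Goodness of fit of an embedding population against a null fingerprint:
# Rosenblatt transform under the Gaussian-mixture null (closed form),
# one-sample Kolmogorov-Smirnov test against the uniform, and the subset
# rejection-rate procedure.

#' Rosenblatt transform under a fingerprint null
#'
#' Maps points to the unit square via `(u1, u2) = (F1(x1), F2|1(x2 | x1))`
#' where F1 is the CDF of the mixture's first marginal (a 1D Gaussian mixture
#' with means `point_i1` and variance `H11`) and F2|1 the conditional CDF:
#' responsibilities `w_i(x1)` proportional to `N(x1; point_i1, H11)`,
#' conditional means `point_i2 + (H21/H11)(x1 - point_i1)` and conditional
#' standard deviation `sqrt(H22 - H21^2 / H11)`. All closed form. Under the
#' null (points drawn from the fingerprint's own mixture) the output
#' coordinates are independent uniforms. The factorization order is fixed to
#' the embedding axis order (x1 then x2).
#'
#' @param null_fp A `fingerprint` (the null density).
#' @param points M x 2 matrix of test points.
#' @return M x 2 matrix with entries in `[0, 1]`.
#' @export
rosenblatt <- function(null_fp, points) {
  check_spd(null_fp$H)
  q <- if (is.null(dim(points))) matrix(points, 1) else as.matrix(points)
  H <- null_fp$H
  s1 <- sqrt(H[1, 1])
  slope <- H[2, 1] / H[1, 1]
  s_c <- sqrt(H[2, 2] - H[2, 1]^2 / H[1, 1])
  p1 <- null_fp$points[, 1]; p2 <- null_fp$points[, 2]
  M <- nrow(q)
  U <- matrix(0, M, 2)
  chunk <- max(16L, floor(4e6 / null_fp$n))
  i0 <- 1L
  while (i0 <= M) {
    i1 <- min(i0 + chunk - 1L, M)
    T1 <- outer(q[i0:i1, 1], p1, "-")                 # x1 - mu_i1
    U[i0:i1, 1] <- rowMeans(stats::pnorm(T1 / s1))
    # responsibilities w_i(x1), computed stably in log space
    L <- -T1^2 / (2 * H[1, 1])
    L <- L - apply(L, 1, max)
    Wgt <- exp(L)
    Wgt <- Wgt / rowSums(Wgt)
    MU2 <- outer(q[i0:i1, 1] * slope, slope * p1, "-") +
      matrix(p2, i1 - i0 + 1L, null_fp$n, byrow = TRUE)
    U[i0:i1, 2] <- rowSums(Wgt * stats::pnorm((q[i0:i1, 2] - MU2) / s_c))
    i0 <- i1 + 1L
  }
  clamp01(U)  # guard against <= 1 ulp spill from the weighted sums
}

# Asymptotic Kolmogorov survival function Q(lambda) = 2 sum (-1)^{k-1} e^{-2 k^2 lambda^2}
kolmogorov_sf <- function(lambda) {
  if (lambda < 0.1) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' One-sample Kolmogorov-Smirnov test against the uniform
#'
#' Exact sup-distance between the empirical CDF and U(0,1), taking the
#' maximum of the left and right gaps at every jump, with the standard
#' asymptotic p-value including the small-sample correction
#' `(sqrt(n) + 0.12 + 0.11/sqrt(n)) * D`.
#'
#' @param u Numeric sample with values in `[0, 1]`.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_uniform <- function(u) {
  n <- length(u)
  if (n == 0) stop("ks_uniform: empty sample")
  if (any(u < 0 | u > 1)) stop("ks_uniform: values outside [0, 1]")
  us <- sort(u)
  i <- seq_len(n)
  D <- max(i / n - us, us - (i - 1) / n)
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  list(statistic = D, p_value = kolmogorov_sf(lambda))
}

#' Subset rejection-rate goodness-of-fit procedure
#'
#' The test population is shuffled without replacement (seeded) and split
#' into `floor(M / N_test)` disjoint subsets of size `N_test` (remainder
#' dropped). Each subset is Rosenblatt-transformed under the null fingerprint
#' and its `2 * N_test` pooled coordinates (independent uniforms under the
#' null) are KS-tested against U(0,1); a subset is rejected when
#' `p < alpha`. The fraction of rejected subsets quantifies how inconsistent
#' the population is with the null: near `alpha` for a matching population,
#' near 1 for a grossly different one. `pool = FALSE` instead tests each
#' coordinate separately at level `alpha / 2` (Bonferroni).
#'
#' @param null_fp A `fingerprint`.
#' @param test_points M x 2 matrix (M >= N_test).
#' @param N_test Subset size (default 100).
#' @param alpha Significance level (default 0.05).
#' @param seed Shuffle seed.
#' @param pool Pool the two transformed coordinates into one KS sample
#'   (default) or Bonferroni-combine per-coordinate tests.
#' @return A `gof_result`: list with `rejection_fraction`, `subset_count`,
#'   per-subset `table` (subset, D, p, reject), and the settings.
#' @export
subset_rejection_rate <- function(null_fp, test_points, N_test = 100L,
                                  alpha = 0.05, seed = 1L, pool = TRUE) {
  pts <- as.matrix(test_points)
  M <- nrow(pts)
  if (M < N_test)
    stop("subset_rejection_rate: fewer test points (", M,
         ") than the subset size ", N_test)
  n_sub <- as.integer(M %/% N_test)
  perm <- with_seed(seed, sample.int(M))
  U <- rosenblatt(null_fp, pts)
  Dv <- numeric(n_sub); pv <- numeric(n_sub)
  for (b in seq_len(n_sub)) {
    idx <- perm[((b - 1) * N_test + 1):(b * N_test)]
    if (pool) {
      ks <- ks_uniform(c(U[idx, 1], U[idx, 2]))
      Dv[b] <- ks$statistic; pv[b] <- ks$p_value
    } else {
      k1 <- ks_uniform(U[idx, 1]); k2 <- ks_uniform(U[idx, 2])
      Dv[b] <- max(k1$statistic, k2$statistic)
      pv[b] <- min(1, 2 * min(k1$p_value, k2$p_value))
    }
  }
  reject <- pv < alpha
  structure(list(null_label = null_fp$label,
                 N_test = as.integer(N_test), alpha = alpha,
                 subset_count = n_sub,
                 rejection_fraction = mean(reject),
                 table = data.frame(subset = seq_len(n_sub), D = Dv, p = pv,
                                    reject = reject),
                 pooled_coordinates = pool,
                 coordinate_order = "x1_then_x2",
                 seed = as.integer(seed)),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof_result vs '%s': %d subsets of %d, alpha %.3g, rejected %.1f%%>\n",
              x$null_label, x$subset_count, x$N_test, x$alpha,
              100 * x$rejection_fraction))
  invisible(x)
}

#' Serialize a goodness-of-fit result
#'
#' Writes the scalar summary as JSON and (optionally) the per-subset table
#' as CSV next to it.
#'
#' @param res A `gof_result`.
#' @param path JSON output path.
#' @param table_path Optional CSV path for the per-subset table.
#' @return `path`, invisibly.
#' @export
write_gof_result <- function(res, path, table_path = NULL) {
  out <- res[c("null_label", "N_test", "alpha", "subset_count",
               "rejection_fraction", "pooled_coordinates",
               "coordinate_order", "seed")]
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  if (!is.null(table_path))
    utils::write.csv(res$table, table_path, row.names = FALSE)
  invisible(path)
}
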