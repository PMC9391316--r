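test_that("the Rosenblatt transform has the right closed-form structure", {
  # single component: the mean maps to (0.5, 0.5)
  fp1 <- fit_fingerprint(matrix(c(2, -1), 1, 2),
                         H = matrix(c(0.5, 0.2, 0.2, 0.4), 2, 2))
  expect_equal(rosenblatt(fp1, c(2, -1))[1, ], c(0.5, 0.5), tolerance = 1e-12)
  # monotone in each argument with the other held fixed
  fp <- fit_fingerprint(with_seed(71, matrix(rnorm(100), 50, 2)),
                        label = "null")
  xs <- seq(-2, 2, length.out = 25)
  u1 <- rosenblatt(fp, cbind(xs, 0))[, 1]
  u2 <- rosenblatt(fp, cbind(0.3, xs))[, 2]
  expect_true(all(diff(u1) > 0))
  expect_true(all(diff(u2) > 0))
  expect_true(all(rosenblatt(fp, with_seed(72, matrix(rnorm(400, sd = 4),
                                                      200, 2))) >= 0))
})

test_that("the conditional CDF agrees with numerical integration", {
  pts <- with_seed(73, matrix(rnorm(60), 30, 2) %*%
                     matrix(c(1, 0.5, 0, 0.9), 2, 2))
  fp <- fit_fingerprint(pts, label = "corr")
  probes <- with_seed(74, matrix(rnorm(200, sd = 1.2), 100, 2))
  U <- rosenblatt(fp, probes)
  # oracle: F(x2 | x1) = int_-inf^x2 f(x1, y) dy / int f(x1, y) dy, trapezoid
  trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  for (i in seq_len(20)) {
    ys_num <- seq(-15, probes[i, 2], length.out = 40001)
    ys_den <- seq(-15, 15, length.out = 80001)
    num <- trapz(ys_num, kde_pdf(fp, cbind(probes[i, 1], ys_num)))
    den <- trapz(ys_den, kde_pdf(fp, cbind(probes[i, 1], ys_den)))
    expect_equal(U[i, 2], num / den, tolerance = 1e-6)
  }
  # first coordinate against the marginal mixture CDF
  for (i in seq_len(10)) {
    oracle <- mean(pnorm(probes[i, 1], mean = fp$points[, 1],
                         sd = sqrt(fp$H[1, 1])))
    expect_equal(U[i, 1], oracle, tolerance = 1e-12)
  }
})

test_that("points drawn from the null itself transform to uniforms", {
  fp <- null_fingerprint(n_support = 200, seed = 75)
  pass <- 0L
  for (rep in 1:60) {
    x <- sample_fingerprint(fp, 1000, seed = 7000 + rep)
    u <- rosenblatt(fp, x)
    if (ks_uniform(as.numeric(u))$p_value >= 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 56)  # >= 93% of seeded repetitions accept at alpha = 0.01
})

test_that("the KS statistic matches closed forms and a brute-force ECDF", {
  n <- 20
  u <- (seq_len(n) - 0.5) / n
  expect_equal(ks_uniform(u)$statistic, 1 / (2 * n), tolerance = 1e-12)
  expect_equal(ks_uniform(rep(0.5, 7))$statistic, 0.5, tolerance = 1e-12)
  brute_D <- function(u) {
    us <- sort(u); n <- length(u)
    max(vapply(seq_len(n), function(i)
      max(i / n - us[i], us[i] - (i - 1) / n), numeric(1)))
  }
  for (s in 1:200) {
    u <- with_seed(8000 + s, runif(sample(5:80, 1)))
    mine <- ks_uniform(u)
    expect_equal(mine$statistic, brute_D(u), tolerance = 1e-12)
    # the statistic agrees with the reference implementation
    expect_equal(mine$statistic,
                 unname(suppressWarnings(stats::ks.test(u, "punif")$statistic)),
                 tolerance = 1e-12)
  }
  expect_error(ks_uniform(c(0.2, 1.4)), "outside")
  expect_error(ks_uniform(numeric(0)), "empty")
})

test_that("subset partitioning follows the floor(M / N_test) arithmetic", {
  fp <- null_fingerprint(n_support = 200, seed = 75)
  x <- sample_fingerprint(fp, 250, seed = 76)
  r <- subset_rejection_rate(fp, x, N_test = 100, alpha = 0.05, seed = 77)
  expect_equal(r$subset_count, 2L)            # remainder of 50 dropped
  expect_equal(nrow(r$table), 2L)
  expect_equal(r$rejection_fraction, mean(r$table$p < 0.05))
  expect_error(subset_rejection_rate(fp, x[1:50, ], N_test = 100), "fewer")
  # bit-reproducible under a fixed shuffle seed
  r2 <- subset_rejection_rate(fp, x, N_test = 100, alpha = 0.05, seed = 77)
  expect_identical(r$table, r2$table)
})

test_that("rejection power increases monotonically with the shift", {
  fp <- null_fingerprint(n_support = 200, seed = 75)
  sd_null <- sqrt(mean(diag(stats::cov(fp$points))))
  rates <- vapply(c(0, 1.5, 10), function(shift) {
    mean(vapply(1:10, function(s) {
      x <- sweep(sample_fingerprint(fp, 1000, seed = 9000 + 37 * s), 2,
                 shift * sd_null, "+")
      subset_rejection_rate(fp, x, N_test = 100, alpha = 0.05,
                            seed = 9100 + s)$rejection_fraction
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.2)
  expect_equal(rates[3], 1.0)
})

test_that("the Bonferroni per-coordinate variant is also calibrated", {
  fp <- null_fingerprint(n_support = 200, seed = 75)
  x <- sample_fingerprint(fp, 10000, seed = 78)
  r <- subset_rejection_rate(fp, x, N_test = 100, alpha = 0.05, seed = 79,
                             pool = FALSE)
  expect_equal(r$subset_count, 100L)
  expect_lte(r$rejection_fraction, 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
  expect_false(r$pooled_coordinates)
})

test_that("GOF results serialize with their per-subset table", {
  fp <- null_fingerprint(n_support = 200, seed = 75)
  x <- sample_fingerprint(fp, 300, seed = 80)
  r <- subset_rejection_rate(fp, x, N_test = 100, seed = 81)
  fj <- tempfile(fileext = ".json"); fc <- tempfile(fileext = ".csv")
  write_gof_result(r, fj, fc)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$rejection_fraction, r$rejection_fraction)
  expect_equal(back$subset_count, r$subset_count)
  tab <- utils::read.csv(fc)
  expect_equal(tab$p, r$table$p, tolerance = 1e-12)
  unlink(c(fj, fc))
})
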