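test_that("plug-in bandwidth is scale and rotation equivariant", {
  X <- with_seed(61, matrix(rnorm(1000), 500, 2) %*%
                   matrix(c(1, 0.4, 0, 0.8), 2, 2))
  H <- plugin_bandwidth(X)
  check_spd <- particleprint:::check_spd
  expect_true(check_spd(H))
  # scaling by 2 scales H by 4 exactly
  expect_equal(plugin_bandwidth(2 * X), 4 * H, tolerance = 1e-12)
  # rotation conjugates H
  th <- 0.53
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_lt(max(abs(plugin_bandwidth(X %*% t(R)) - R %*% H %*% t(R))), 1e-8)
  # degenerate clouds are refused
  expect_error(plugin_bandwidth(cbind(1:100, 2 * (1:100))), "collinear")
  expect_error(plugin_bandwidth(matrix(rnorm(10), 5, 2)), "at least 8")
})

test_that("bandwidth shrinks with sample size and matches the normal oracle", {
  hs <- vapply(c(200, 2000, 20000), function(n) {
    Z <- with_seed(1000 + n, matrix(rnorm(2 * n), n, 2))
    mean(diag(plugin_bandwidth(Z)))
  }, numeric(1))
  expect_true(all(diff(hs) < 0))
  # at n = 20000 the diagonal sits within 20% of the AMISE optimum n^(-1/3)
  expect_lt(abs(hs[3] - 20000^(-1 / 3)) / 20000^(-1 / 3), 0.2)
})

test_that("the KDE is an exact Gaussian mixture with unit mass", {
  fp1 <- fit_fingerprint(matrix(0, 1, 2), H = diag(2), label = "one")
  expect_equal(kde_pdf(fp1, c(0, 0)), 1 / (2 * pi), tolerance = 1e-12)
  # random fingerprint: quadrature mass within 1e-3, symmetry exact
  pts <- with_seed(62, matrix(rnorm(60), 30, 2))
  fp <- fit_fingerprint(pts, label = "rand")
  g <- seq(-8, 8, length.out = 321)
  grid <- cbind(rep(g, times = 321), rep(g, each = 321))
  mass <- sum(kde_pdf(fp, grid)) * (g[2] - g[1])^2
  expect_lt(abs(mass - 1), 1e-3)
  fp2 <- fit_fingerprint(rbind(c(-1, 0), c(1, 0)), H = diag(2), label = "sym")
  q <- with_seed(63, matrix(rnorm(40), 20, 2))
  qr <- q; qr[, 1] <- -qr[, 1]   # mirror about the midpoint axis
  expect_equal(kde_pdf(fp2, q), kde_pdf(fp2, qr), tolerance = 1e-12)
  expect_true(all(kde_pdf(fp, grid) >= 0))
})

test_that("fingerprints use the union bandwidth and survive serialization", {
  emb <- embedding_set(with_seed(64, rbind(matrix(rnorm(60), 30, 2),
                                           matrix(rnorm(60, 2), 30, 2))),
                       labels = rep(c("a", "b"), each = 30))
  fp_union <- fit_fingerprint(emb, subset = c("a", "b"))
  expect_equal(fp_union$H, plugin_bandwidth(emb$points), tolerance = 1e-12)
  fa <- fit_fingerprint(emb, subset = "a")
  fb <- fit_fingerprint(emb, subset = "b")
  expect_gt(max(abs(fp_union$H - (fa$H + fb$H) / 2)), 1e-4)
  expect_error(fit_fingerprint(emb, subset = "zzz"), "no points")
  expect_error(fit_fingerprint(matrix(0, 1, 2)), "at least 8")
  # JSON round trip reproduces the pdf to 1e-12 at 100 probes
  f <- tempfile(fileext = ".json")
  write_fingerprint(fa, f)
  back <- read_fingerprint(f)
  probes <- with_seed(65, matrix(rnorm(200), 100, 2))
  expect_equal(kde_pdf(back, probes), kde_pdf(fa, probes), tolerance = 1e-12)
  unlink(f)
})

test_that("HDR levels match the bivariate-normal closed form", {
  fp <- fit_fingerprint(matrix(0, 1, 2), H = diag(2), label = "std")
  s <- sample_fingerprint(fp, 10000, seed = 66)
  hl <- hdr_levels(fp, c(0.2, 0.4, 0.6, 0.8), points = s)
  truth <- (1 - hl$mass) / (2 * pi)
  expect_true(all(abs(hl$level - truth) / truth < 0.05))
  expect_true(all(diff(hl$level) < 0))          # strictly decreasing in mass
  # p -> 0 approaches the max density over the evaluated points
  tiny <- hdr_levels(fp, 1e-9, points = s)
  expect_equal(tiny$level, max(kde_pdf(fp, s)), tolerance = 1e-6)
  expect_error(hdr_levels(fp, c(0.2, 1)), "inside")
})

test_that("the global mode maximizes the density", {
  # single component: the mode is the point itself
  fp1 <- fit_fingerprint(matrix(c(1.5, -2), 1, 2), H = 0.5 * diag(2))
  m1 <- global_mode(fp1)
  expect_equal(m1$point, c(1.5, -2), tolerance = 1e-6)
  expect_false(m1$tie)
  # exact two-cluster tie is flagged
  fp2 <- fit_fingerprint(rbind(c(-3, 0), c(3, 0)), H = diag(2))
  expect_true(global_mode(fp2)$tie)
  # random fingerprint: no grid point beats the reported mode
  pts <- with_seed(67, matrix(rnorm(400, sd = 1.5), 200, 2))
  fp <- fit_fingerprint(pts, label = "rand")
  md <- global_mode(fp)
  g1 <- seq(min(pts[, 1]), max(pts[, 1]), length.out = 256)
  g2 <- seq(min(pts[, 2]), max(pts[, 2]), length.out = 256)
  grid <- cbind(rep(g1, times = 256), rep(g2, each = 256))
  expect_gte(md$value + 1e-9, max(kde_pdf(fp, grid)))
  # translating the points translates the mode
  fp_t <- fit_fingerprint(sweep(pts, 2, c(5, -3), "+"), H = fp$H)
  md_t <- global_mode(fp_t)
  expect_equal(md_t$point, md$point + c(5, -3), tolerance = 1e-6)
})

test_that("nearest_to_point ranks by distance with index tie-breaking", {
  pts <- with_seed(68, matrix(rnorm(2000), 1000, 2))
  target <- c(0.3, -0.2)
  nn <- nearest_to_point(pts, target, k = 50)
  d <- sqrt(colSums((t(pts) - target)^2))
  expect_identical(nn, order(d)[1:50])
  expect_identical(nearest_to_point(pts, target, k = 1000), order(d))
  # the query sitting on a point returns that point first
  expect_equal(nearest_to_point(pts, pts[17, ], k = 1)[1], 17)
  # exact ties break toward the lower index
  tied <- rbind(c(1, 0), c(2, 0), c(1, 0))
  expect_identical(nearest_to_point(tied, c(0, 0), k = 3), c(1L, 3L, 2L))
  expect_error(nearest_to_point(pts, target, k = 1001), "exceeds")
})
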