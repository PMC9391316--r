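# Bivariate Gaussian-KDE "fingerprints" of 2D embedding scatters.
#
# The bandwidth is the unconstrained (full 2x2, off-diagonals included)
# two-stage plug-in estimate of the AMISE-optimal matrix: the data are
# pre-sphered, the sixth-order curvature functionals are taken from a normal
# reference to give a scalar pilot, the fourth-order functionals are then
# estimated from the data with that pilot, and the resulting AMISE objective
# is minimized over symmetric positive-definite matrices.

# 1D Gaussian-density derivative phi_g^(k)(u), k = 0..4, via probabilists'
# Hermite polynomials: phi_g^(k)(u) = (-1)^k He_k(u/g) dnorm(u/g) / g^(k+1).
gauss_deriv <- function(u, g, k) {
  t <- u / g
  he <- switch(as.character(k),
               "0" = 1,
               "1" = t,
               "2" = t^2 - 1,
               "3" = t^3 - 3 * t,
               "4" = t^4 - 6 * t^2 + 3)
  (-1)^k * he * stats::dnorm(t) / g^(k + 1)
}

psi4_exact <- function(Z, g) {
  n <- nrow(Z)
  chunk <- max(64L, floor(4e6 / n))
  acc <- numeric(5)  # psi40, psi31, psi22, psi13, psi04
  i0 <- 1L
  while (i0 <= n) {
    i1 <- min(i0 + chunk - 1L, n)
    DX <- outer(Z[i0:i1, 1], Z[, 1], "-")
    DY <- outer(Z[i0:i1, 2], Z[, 2], "-")
    dx <- lapply(0:4, function(k) gauss_deriv(DX, g, k))
    dy <- lapply(0:4, function(k) gauss_deriv(DY, g, k))
    acc <- acc + c(sum(dx[[5]] * dy[[1]]), sum(dx[[4]] * dy[[2]]),
                   sum(dx[[3]] * dy[[3]]), sum(dx[[2]] * dy[[4]]),
                   sum(dx[[1]] * dy[[5]]))
    i0 <- i1 + 1L
  }
  acc / n^2
}

linbin2d <- function(Z, G = 64L) {
  bin1 <- function(z) {
    r <- range(z)
    if (r[2] - r[1] <= 0) r <- r + c(-0.5, 0.5)
    gx <- seq(r[1], r[2], length.out = G)
    d <- gx[2] - gx[1]
    pos <- (z - gx[1]) / d + 1
    i0 <- pmin(pmax(floor(pos), 1), G - 1)
    list(grid = gx, lo = as.integer(i0), w_hi = pos - i0)
  }
  bx <- bin1(Z[, 1]); by <- bin1(Z[, 2])
  W <- matrix(0, G, G)
  add <- function(i, j, w) {
    idx <- i + (j - 1L) * G
    tab <- rowsum(w, idx)
    ii <- as.integer(rownames(tab))
    W[ii] <<- W[ii] + tab[, 1]
  }
  add(bx$lo,      by$lo,      (1 - bx$w_hi) * (1 - by$w_hi))
  add(bx$lo + 1L, by$lo,      bx$w_hi       * (1 - by$w_hi))
  add(bx$lo,      by$lo + 1L, (1 - bx$w_hi) * by$w_hi)
  add(bx$lo + 1L, by$lo + 1L, bx$w_hi       * by$w_hi)
  list(W = W, gx = bx$grid, gy = by$grid)
}

psi4_binned <- function(Z, g, G = 64L) {
  n <- nrow(Z)
  b <- linbin2d(Z, G)
  ddx <- outer(b$gx, b$gx, "-")
  ddy <- outer(b$gy, b$gy, "-")
  fx <- lapply(0:4, function(k) gauss_deriv(ddx, g, k))
  fy <- lapply(0:4, function(k) gauss_deriv(ddy, g, k))
  one <- function(kx, ky) {
    M <- b$W %*% fy[[ky + 1]] %*% t(b$W)
    sum(fx[[kx + 1]] * M) / n^2
  }
  c(one(4, 0), one(3, 1), one(2, 2), one(1, 3), one(0, 4))
}

# AMISE(H) = (1/4) * int (tr(H f''))^2 + (4 pi n)^{-1} |H|^{-1/2}, with
# int (tr H f'')^2 expanded in the five fourth-order functionals.
amise_obj <- function(theta, psi, n) {
  a <- exp(theta[1]); b <- theta[2]; cc <- exp(theta[3])
  h11 <- a^2; h12 <- a * b; h22 <- b^2 + cc^2
  Q <- h11^2 * psi[1] + h22^2 * psi[5] +
    (2 * h11 * h22 + 4 * h12^2) * psi[3] +
    4 * h11 * h12 * psi[2] + 4 * h12 * h22 * psi[4]
  det <- h11 * h22 - h12^2
  Q / 4 + det^(-1 / 2) / (4 * pi * n)
}

amise_grad <- function(theta, psi, n) {
  a <- exp(theta[1]); b <- theta[2]; cc <- exp(theta[3])
  h11 <- a^2; h12 <- a * b; h22 <- b^2 + cc^2
  det <- h11 * h22 - h12^2
  gQ11 <- 2 * h11 * psi[1] + 2 * h22 * psi[3] + 4 * h12 * psi[2]
  gQ22 <- 2 * h22 * psi[5] + 2 * h11 * psi[3] + 4 * h12 * psi[4]
  gQ12 <- 8 * h12 * psi[3] + 4 * h11 * psi[2] + 4 * h22 * psi[4]
  cdet <- -det^(-3 / 2) / (8 * pi * n)
  g11 <- gQ11 / 4 + cdet * h22
  g22 <- gQ22 / 4 + cdet * h11
  g12 <- gQ12 / 4 + cdet * (-2 * h12)
  # chain rule through h11 = a^2, h12 = a b, h22 = b^2 + c^2
  c(g11 * 2 * h11 + g12 * h12,          # d/d l1 (a = exp(l1))
    g22 * 2 * b + g12 * a,              # d/d b
    g22 * 2 * cc^2)                     # d/d l2 (c = exp(l2))
}

#' Plug-in bandwidth matrix for a bivariate Gaussian KDE
#'
#' Two-stage unconstrained plug-in selector: the points are pre-sphered with
#' the symmetric inverse root of their covariance; a scalar pilot bandwidth
#' `g = (16 / (3 n))^(1/8)` (the AMSE pilot under a sphered normal reference,
#' identical for the three even fourth-order functionals) smooths the
#' pairwise kernel estimates of the five fourth-order integrated density
#' derivative functionals; the asymptotic MISE objective built from those
#' functionals is then minimized over symmetric positive-definite 2x2
#' matrices (analytic-gradient BFGS plus a Newton polish) and the result is
#' transformed back to the original coordinates. Functional sums are exact
#' pairwise for `n <= n_exact` and use fine linear binning above that.
#'
#' @param points N x 2 numeric matrix, N >= 8, not collinear.
#' @param n_exact Threshold for exact pairwise functional sums (default 5000).
#' @param grid_size Linear-binning grid per axis (default 64).
#' @return A 2 x 2 symmetric positive-definite bandwidth matrix.
#' @export
plugin_bandwidth <- function(points, n_exact = 5000L, grid_size = 64L) {
  X <- as.matrix(points)
  n <- nrow(X)
  if (n < 8) stop("plugin_bandwidth: need at least 8 points")
  if (ncol(X) != 2) stop("plugin_bandwidth: points must be N x 2")
  S <- stats::cov(X)
  es <- eigen(S, symmetric = TRUE)
  if (es$values[2] <= 1e-12 * es$values[1])
    stop("plugin_bandwidth: rank-deficient point cloud (points nearly collinear)")
  Sroot <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
  Sinv <- es$vectors %*% ((1 / sqrt(es$values)) * t(es$vectors))
  Z <- X %*% Sinv

  g <- (16 / (3 * n))^(1 / 8)
  psi <- if (n <= n_exact) psi4_exact(Z, g) else psi4_binned(Z, g, grid_size)

  theta <- c(log(n^(-1 / 6)), 0, log(n^(-1 / 6)))
  opt <- stats::optim(theta, amise_obj, amise_grad, psi = psi, n = n,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  theta <- opt$par
  # Newton polish on the analytic gradient for a machine-precision stationary
  # point (keeps the selector equivariant to rotations to high accuracy)
  for (it in 1:25) {
    gr <- amise_grad(theta, psi, n)
    if (max(abs(gr)) < 1e-13) break
    J <- matrix(0, 3, 3)
    h <- 1e-6
    for (j in 1:3) {
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      J[, j] <- (amise_grad(tp, psi, n) - amise_grad(tm, psi, n)) / (2 * h)
    }
    step <- tryCatch(solve(J, gr), error = function(e) gr)
    if (max(abs(step)) > 1) step <- step / max(abs(step))
    theta_new <- theta - step
    if (amise_obj(theta_new, psi, n) <= amise_obj(theta, psi, n) ||
        max(abs(step)) < 1e-10) theta <- theta_new else break
  }
  a <- exp(theta[1]); b <- theta[2]; cc <- exp(theta[3])
  Hz <- matrix(c(a^2, a * b, a * b, b^2 + cc^2), 2, 2)
  H <- Sroot %*% Hz %*% Sroot
  H <- (H + t(H)) / 2
  eh <- eigen(H, symmetric = TRUE)
  floor_ev <- 1e-12 * sum(diag(H))
  if (any(eh$values < floor_ev)) {
    vals <- pmax(eh$values, floor_ev)
    H <- eh$vectors %*% (vals * t(eh$vectors))
    H <- (H + t(H)) / 2
  }
  H
}

#' Fit a fingerprint to an embedding population
#'
#' A fingerprint is the bivariate Gaussian-mixture KDE of a population's 2D
#' embeddings: every embedding point is a mixture center and the plug-in
#' bandwidth matrix is the common covariance. The whole filtered set is used
#' (no train/test split — particle numbers are low in this setting).
#'
#' @param embedding An `embedding_set` (or N x 2 matrix).
#' @param subset Optional label filter: keep points whose label is in `subset`.
#' @param label Name for the fingerprint (default: the subset or "all").
#' @param H Optional bandwidth matrix override (skips the plug-in selector).
#' @return A `fingerprint`: list with `points`, `H`, `label`, `n`.
#' @export
fit_fingerprint <- function(embedding, subset = NULL, label = NULL, H = NULL) {
  if (inherits(embedding, "embedding_set")) {
    pts <- embedding$points
    if (!is.null(subset)) {
      keep <- embedding$labels %in% subset
      if (!any(keep)) stop("fit_fingerprint: label filter matches no points")
      pts <- pts[keep, , drop = FALSE]
    }
  } else {
    pts <- as.matrix(embedding)
  }
  if (is.null(H)) {
    if (nrow(pts) < 8)
      stop("fit_fingerprint: need at least 8 points to select a bandwidth, got ",
           nrow(pts))
    H <- plugin_bandwidth(pts)
  }
  check_spd(H)
  structure(list(points = pts, H = H,
                 label = label %||% paste(subset %||% "all", collapse = "+"),
                 n = nrow(pts)),
            class = "fingerprint")
}

check_spd <- function(H) {
  if (!isTRUE(all.equal(H, t(H), tolerance = 1e-8)))
    stop("bandwidth matrix must be symmetric")
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("bandwidth matrix must be positive definite")
  invisible(TRUE)
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint '%s': %d mixture centers, |H| = %.3g>\n",
              x$label, x$n, det(x$H)))
  invisible(x)
}

#' Evaluate a fingerprint density
#'
#' Exact Gaussian-mixture evaluation
#' `f(x) = (1/N) sum_i N(x; point_i, H)`.
#'
#' @param fp A `fingerprint`.
#' @param queries M x 2 matrix (or length-2 vector) of evaluation points.
#' @return Length-M vector of nonnegative densities.
#' @export
kde_pdf <- function(fp, queries) {
  q <- if (is.null(dim(queries))) matrix(queries, 1) else as.matrix(queries)
  A <- solve(fp$H)
  detH <- det(fp$H)
  px <- fp$points[, 1]; py <- fp$points[, 2]
  norm_const <- 2 * pi * sqrt(detH) * fp$n
  out <- numeric(nrow(q))
  chunk <- max(16L, floor(4e6 / fp$n))
  i0 <- 1L
  while (i0 <= nrow(q)) {
    i1 <- min(i0 + chunk - 1L, nrow(q))
    DX <- outer(q[i0:i1, 1], px, "-")
    DY <- outer(q[i0:i1, 2], py, "-")
    Qd <- A[1, 1] * DX^2 + 2 * A[1, 2] * DX * DY + A[2, 2] * DY^2
    out[i0:i1] <- rowSums(exp(-Qd / 2)) / norm_const
    i0 <- i1 + 1L
  }
  out
}

#' Sample points from a fingerprint's mixture
#'
#' @param fp A `fingerprint`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return n x 2 matrix.
#' @export
sample_fingerprint <- function(fp, n, seed = 1L) {
  with_seed(seed, {
    comp <- sample.int(fp$n, n, replace = TRUE)
    R <- chol(fp$H)
    fp$points[comp, , drop = FALSE] + matrix(stats::rnorm(2 * n), n, 2) %*% R
  })
}

#' Highest-density-region levels of a fingerprint
#'
#' For each probability mass p, the density level lambda(p) whose super-level
#' set `{f >= lambda}` holds mass p, estimated as the (1 - p) quantile of the
#' density evaluated at points from the density itself (the fingerprint's own
#' support points by default) — the standard density-quantile HDR estimator.
#'
#' @param fp A `fingerprint`.
#' @param masses Probability masses in (0, 1), e.g. `c(0.2, 0.4, 0.6, 0.8)`.
#' @param points Optional M x 2 matrix of evaluation points sampled from the
#'   density; defaults to the fingerprint's own points.
#' @return An `hdr_levels` data.frame with columns `mass` and `level`
#'   (strictly decreasing in `mass`).
#' @export
hdr_levels <- function(fp, masses = c(0.2, 0.4, 0.6, 0.8), points = NULL) {
  if (any(masses <= 0 | masses >= 1))
    stop("hdr_levels: masses must lie strictly inside (0, 1)")
  pts <- points %||% fp$points
  fv <- kde_pdf(fp, pts)
  lev <- stats::quantile(fv, probs = 1 - masses, names = FALSE, type = 7)
  structure(data.frame(mass = masses, level = lev),
            class = c("hdr_levels", "data.frame"))
}

#' Global mode of a fingerprint
#'
#' Multi-start derivative-free search: from the five highest-density support
#' points, a shrinking 3x3 pattern search refines the maximizer until the
#' step falls below `tol` in embedding units. If two distinct maximizers tie
#' in density, the first encountered is returned and the tie is flagged.
#'
#' @param fp A `fingerprint`.
#' @param tol Convergence tolerance on the step size (default 1e-6).
#' @param n_starts Number of highest-density starting points (default 5).
#' @return List with `point` (length-2), `value` (density at the mode) and
#'   `tie` (logical).
#' @export
global_mode <- function(fp, tol = 1e-6, n_starts = 5L) {
  f0 <- kde_pdf(fp, fp$points)
  starts <- order(f0, decreasing = TRUE)[seq_len(min(n_starts, fp$n))]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  refine <- function(x0) {
    step <- sqrt(max(diag(fp$H)))
    x <- x0; fx <- kde_pdf(fp, x)
    while (step > tol / 2) {
      cand <- sweep(offs * step, 2, x, "+")
      fc <- kde_pdf(fp, cand)
      j <- which.max(fc)
      if (fc[j] > fx) { x <- cand[j, ]; fx <- fc[j] } else step <- step / 2
    }
    list(point = x, value = fx)
  }
  res <- lapply(starts, function(s) refine(fp$points[s, ]))
  vals <- vapply(res, `[[`, numeric(1), "value")
  best <- which.max(vals)
  tie <- FALSE
  for (j in seq_along(res)) {
    if (j == best) next
    if (abs(vals[j] - vals[best]) <= 1e-10 * max(vals[best], 1e-300) &&
        sqrt(sum((res[[j]]$point - res[[best]]$point)^2)) > 100 * tol)
      tie <- TRUE
  }
  list(point = res[[best]]$point, value = vals[best], tie = tie)
}

#' Indices of the embedding points nearest to a location
#'
#' The k smallest Euclidean distances, ascending; exact ties broken by lower
#' index. Used to curate the images nearest a fingerprint mode.
#'
#' @param embedding An `embedding_set` or N x 2 matrix.
#' @param point Length-2 location (e.g. a global mode).
#' @param k Number of neighbours (default 50).
#' @return Integer vector of k indices.
#' @export
nearest_to_point <- function(embedding, point, k = 50L) {
  pts <- if (inherits(embedding, "embedding_set")) embedding$points
         else as.matrix(embedding)
  if (k > nrow(pts)) stop("nearest_to_point: k exceeds the number of points")
  d <- sqrt((pts[, 1] - point[1])^2 + (pts[, 2] - point[2])^2)
  order(d, seq_along(d))[seq_len(k)]
}

#' Serialize / deserialize a fingerprint as JSON
#'
#' @param fp A `fingerprint`.
#' @param path File path.
#' @return `write_fingerprint` returns `path` invisibly; `read_fingerprint`
#'   the `fingerprint`.
#' @export
write_fingerprint <- function(fp, path) {
  jsonlite::write_json(list(label = fp$label, n = fp$n,
                            H = as.numeric(fp$H),
                            points = unname(as.matrix(fp$points))),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fingerprint
#' @export
read_fingerprint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(points = matrix(raw$points, ncol = 2),
                 H = matrix(raw$H, 2, 2),
                 label = raw$label, n = as.integer(raw$n)),
            class = "fingerprint")
}
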