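# Minimal convolutional network engine, vectorized base R.
#
# Layout conventions (fixed throughout):
#  * a batch is a d x n matrix, one image per column;
#  * within a column, features are ordered spatial-position-fastest,
#    column-major over (row, col), then channel: index = p + (c-1)*P;
#  * convolutions are 3x3, stride 1, valid (no padding); pooling is 2x2,
#    stride 2, odd trailing rows/columns dropped.
#
# The trunk is 2 x [3x3 conv, ReLU, 2x2 max-pool] with 16 then 32 channels,
# flatten, fully connected to a 32-unit feature layer (ReLU), and a linear
# head: K logits for the classifier, 2 coordinates for the embedder. The two
# networks differ only in that last layer.

conv_indices <- function(H, W, C, k) {
  Hout <- H - k + 1L; Wout <- W - k + 1L
  E <- k * k * C; P <- Hout * Wout
  dh <- rep(seq_len(k), times = k * C)
  dw <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  i <- rep(seq_len(Hout), times = Wout)
  j <- rep(seq_len(Wout), each = Hout)
  idx <- matrix(0L, E, P)
  for (e in seq_len(E))
    idx[e, ] <- (i + dh[e] - 1L) + (j + dw[e] - 2L) * H + (cc[e] - 1L) * H * W
  list(idx = as.vector(idx), E = E, P = P, Hout = Hout, Wout = Wout)
}

pool_indices <- function(Hin, Win, C) {
  Hout <- Hin %/% 2L; Wout <- Win %/% 2L
  io <- rep(seq_len(Hout), times = Wout)
  jo <- rep(seq_len(Wout), each = Hout)
  mk <- function(di, dj) {
    p <- (2L * io - 2L + di) + (2L * jo - 2L + dj - 1L) * Hin
    as.vector(outer(p, (seq_len(C) - 1L) * Hin * Win, "+"))
  }
  list(i = list(mk(1L, 1L), mk(2L, 1L), mk(1L, 2L), mk(2L, 2L)),
       Hout = Hout, Wout = Wout, P_in = Hin * Win, C = C)
}

#' Initialize the particle-image network
#'
#' He-initialized parameters for the fixed trunk plus a linear head with
#' `n_out` units (class logits or 2D embedding coordinates).
#'
#' @param n_out Number of output units.
#' @param seed Integer seed for the initialization draws.
#' @param input_side Input image side length (default 32).
#' @param channels Channel counts of the two convolution layers.
#' @param feat_dim Width of the penultimate feature layer (default 32).
#' @return A `particle_net` list with parameters and cached geometry.
#' @keywords internal
nn_init <- function(n_out, seed, input_side = 32L, channels = c(16L, 32L),
                    feat_dim = 32L) {
  s <- as.integer(input_side)
  g1 <- conv_indices(s, s, 1L, 3L)
  p1 <- pool_indices(g1$Hout, g1$Wout, channels[1])
  g2 <- conv_indices(p1$Hout, p1$Wout, channels[1], 3L)
  p2 <- pool_indices(g2$Hout, g2$Wout, channels[2])
  flat <- p2$Hout * p2$Wout * channels[2]
  he <- function(fan_in, nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  params <- with_seed(seed, list(
    W1 = he(g1$E, g1$E, channels[1]), b1 = numeric(channels[1]),
    W2 = he(g2$E, g2$E, channels[2]), b2 = numeric(channels[2]),
    Wf = he(flat, flat, feat_dim),    bf = numeric(feat_dim),
    Wh = he(feat_dim, feat_dim, n_out), bh = numeric(n_out)
  ))
  structure(list(params = params, input_side = s, channels = channels,
                 feat_dim = feat_dim, n_out = n_out,
                 geom = list(g1 = g1, p1 = p1, g2 = g2, p2 = p2, flat = flat)),
            class = "particle_net")
}

conv_fwd <- function(X, g, W, b) {
  n <- ncol(X); C_out <- ncol(W)
  Xp <- X[g$idx, , drop = FALSE]
  dim(Xp) <- c(g$E, g$P * n)
  Z <- crossprod(W, Xp) + b
  dim(Z) <- c(C_out, g$P, n)
  Z <- aperm(Z, c(2L, 1L, 3L))
  dim(Z) <- c(g$P * C_out, n)
  list(Z = Z, Xp = Xp)
}

conv_bwd <- function(dZ, Xp, g, W, n) {
  C_out <- ncol(W)
  dim(dZ) <- c(g$P, C_out, n)
  dZ <- aperm(dZ, c(2L, 1L, 3L))
  dim(dZ) <- c(C_out, g$P * n)
  dW <- tcrossprod(Xp, dZ)
  db <- rowSums(dZ)
  dXp <- W %*% dZ
  dim(dXp) <- c(g$E * g$P, n)
  dX <- rowsum(dXp, group = g$idx)  # every input position is in >= 1 patch
  list(dW = dW, db = db, dX = dX)
}

pool_fwd <- function(Z, pi) {
  A <- lapply(pi$i, function(ii) Z[ii, , drop = FALSE])
  M <- pmax(A[[1]], A[[2]], A[[3]], A[[4]])
  s1 <- A[[1]] == M
  s2 <- (A[[2]] == M) & !s1
  s3 <- (A[[3]] == M) & !(s1 | s2)
  s4 <- !(s1 | s2 | s3)
  list(M = M, masks = list(s1, s2, s3, s4))
}

pool_bwd <- function(dM, pi, masks, n) {
  dZ <- matrix(0, pi$P_in * pi$C, n)
  for (q in 1:4) dZ[pi$i[[q]], ] <- dM * masks[[q]]
  dZ
}

#' Forward pass through the network
#'
#' @param net A `particle_net`.
#' @param X d x n input matrix (normalized pixels, one image per column).
#' @param cache Keep intermediates for a backward pass?
#' @return List with `out` (n_out x n), `feat` (feat_dim x n) and optionally
#'   `cache`.
#' @keywords internal
nn_forward <- function(net, X, cache = FALSE) {
  p <- net$params; g <- net$geom; n <- ncol(X)
  c1 <- conv_fwd(X, g$g1, p$W1, p$b1)
  r1 <- pmax(c1$Z, 0)
  pl1 <- pool_fwd(r1, g$p1)
  c2 <- conv_fwd(pl1$M, g$g2, p$W2, p$b2)
  r2 <- pmax(c2$Z, 0)
  pl2 <- pool_fwd(r2, g$p2)
  Zf <- crossprod(p$Wf, pl2$M) + p$bf
  feat <- pmax(Zf, 0)
  out <- crossprod(p$Wh, feat) + p$bh
  res <- list(out = out, feat = feat)
  if (cache)
    res$cache <- list(X = X, c1 = c1, r1pos = c1$Z > 0, m1 = pl1$masks,
                      pool1 = pl1$M, c2 = c2, r2pos = c2$Z > 0, m2 = pl2$masks,
                      pool2 = pl2$M, fpos = Zf > 0, feat = feat, n = n)
  res
}

#' Backward pass: gradients of a scalar loss w.r.t. all parameters
#'
#' @param net A `particle_net`.
#' @param cache Cache from `nn_forward(..., cache = TRUE)`.
#' @param dOut n_out x n gradient of the loss w.r.t. the network output.
#' @return Named list of gradients matching `net$params`.
#' @keywords internal
nn_backward <- function(net, cache, dOut) {
  p <- net$params; g <- net$geom; n <- cache$n
  dWh <- tcrossprod(cache$feat, dOut)
  dbh <- rowSums(dOut)
  dfeat <- (p$Wh %*% dOut) * cache$fpos
  dWf <- tcrossprod(cache$pool2, dfeat)
  dbf <- rowSums(dfeat)
  dpool2 <- p$Wf %*% dfeat
  dr2 <- pool_bwd(dpool2, g$p2, cache$m2, n)
  dz2 <- dr2 * cache$r2pos
  b2 <- conv_bwd(dz2, cache$c2$Xp, g$g2, p$W2, n)
  dr1 <- pool_bwd(b2$dX, g$p1, cache$m1, n)
  dz1 <- dr1 * cache$r1pos
  b1 <- conv_bwd(dz1, cache$c1$Xp, g$g1, p$W1, n)
  list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db,
       Wf = dWf, bf = dbf, Wh = dWh, bh = dbh)
}

adam_init <- function(params) {
  zero <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zero, v = zero, vhat = zero, t = 0L)
}

# Adam with the AMSgrad correction (default hyperparameters otherwise):
# lr 1e-3, beta1 0.9, beta2 0.999, eps 1e-8.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    state$vhat[[nm]] <- pmax(state$vhat[[nm]], state$v[[nm]])
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$vhat[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
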