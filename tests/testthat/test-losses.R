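test_that("class weights are inverse-frequency, normalized to sum K", {
  expect_equal(class_weights(c(100, 100, 100, 100)), rep(1, 4))
  expect_equal(class_weights(c(100, 300)), c(1.5, 0.5))
  w <- with_seed(21, class_weights(sample(50:500, 7)))
  expect_equal(sum(w), 7, tolerance = 1e-12)
  expect_error(class_weights(c(10, 0)), ">= 1")
})

test_that("weighted cross entropy matches closed forms and a hand computation", {
  # uniform logits -> ln K regardless of labels/weights
  expect_equal(weighted_cross_entropy(matrix(0, 5, 3), c(1, 2, 3), rep(1, 5)),
               log(5), tolerance = 1e-12)
  # confident correct logit -> loss ~ 0
  strong <- matrix(c(50, 0, 0, 50), 2, 2)
  expect_lt(weighted_cross_entropy(strong, c(1, 2), c(1, 1)), 1e-10)
  # 3-sample 2-class hand case
  logits <- matrix(c(1, 0, 0.5, 1.5, -1, 2), 2, 3)
  labels <- c(1, 2, 2)
  w <- c(2, 0.5)
  li <- function(j, y) {
    z <- logits[, j]
    -(z[y] - log(sum(exp(z))))
  }
  hand <- (2 * li(1, 1) + 0.5 * li(2, 2) + 0.5 * li(3, 2)) / (2 + 0.5 + 0.5)
  expect_equal(weighted_cross_entropy(logits, labels, w), hand,
               tolerance = 1e-10)
  expect_error(weighted_cross_entropy(logits, c(1, 2, 3), w), "out of range")
})

test_that("duplicating a class and re-deriving weights leaves the loss unchanged", {
  with_seed(22, {
    logits <- matrix(rnorm(3 * 30), 3, 30)
    labels <- rep(1:3, times = c(5, 10, 15))
  })
  w <- class_weights(tabulate(labels, 3))
  base <- weighted_cross_entropy(logits, labels, w)
  dup_cols <- c(seq_len(30), which(labels == 1))     # class 1 duplicated
  logits2 <- logits[, dup_cols]
  labels2 <- labels[dup_cols]
  w2 <- class_weights(tabulate(labels2, 3))
  expect_equal(weighted_cross_entropy(logits2, labels2, w2), base,
               tolerance = 1e-9)
})

test_that("batch-all non-zero triplet loss matches closed forms", {
  lab6 <- rep(c("a", "b"), each = 3)
  # all embeddings identical: every term equals the margin
  expect_equal(batch_all_triplet_loss(matrix(1, 6, 2), lab6, margin = 0.7), 0.7)
  # two tight distant clusters: hinge inactive everywhere
  E <- rbind(matrix(0, 3, 2) + with_seed(23, matrix(rnorm(6, 0, 0.01), 3)),
             matrix(10, 3, 2) + with_seed(24, matrix(rnorm(6, 0, 0.01), 3)))
  expect_equal(batch_all_triplet_loss(E, lab6, margin = 1), 0)
  expect_error(batch_all_triplet_loss(E, rep("a", 6)), "single class")
})

test_that("triplet loss equals brute-force enumeration on every small batch", {
  cases <- list(
    list(B = 6, labs = rep(c("a", "b"), each = 3)),
    list(B = 9, labs = rep(c("a", "b", "c"), each = 3)),
    list(B = 12, labs = rep(c("a", "b"), times = c(4, 8))),
    list(B = 12, labs = rep(c("a", "b", "c", "d"), each = 3)),
    list(B = 5, labs = c("a", "a", "b", "b", "b"))
  )
  for (cs in cases) {
    for (s in 1:4) {
      E <- with_seed(100 * s + cs$B, matrix(rnorm(2 * cs$B), cs$B, 2))
      for (m in c(0.3, 1)) {
        expect_equal(batch_all_triplet_loss(E, cs$labs, margin = m),
                     brute_triplet(E, cs$labs, m), tolerance = 1e-12)
      }
    }
  }
})

test_that("triplet loss is invariant to rigid motions and its gradient is exact", {
  labs <- rep(c("a", "b", "c"), each = 4)
  E <- with_seed(26, matrix(rnorm(24), 12, 2))
  base <- batch_all_triplet_loss(E, labs, margin = 1)
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(batch_all_triplet_loss(E %*% R, labs, 1), base, tolerance = 1e-10)
  expect_equal(batch_all_triplet_loss(sweep(E, 2, c(3, -7), "+"), labs, 1),
               base, tolerance = 1e-10)
  tl <- batch_all_triplet_loss(E, labs, margin = 1, gradient = TRUE)
  fd <- matrix(0, 12, 2)
  for (i in 1:12) for (j in 1:2) {
    h <- 1e-6
    Ep <- E; Ep[i, j] <- Ep[i, j] + h
    Em <- E; Em[i, j] <- Em[i, j] - h
    fd[i, j] <- (batch_all_triplet_loss(Ep, labs, 1) -
                 batch_all_triplet_loss(Em, labs, 1)) / (2 * h)
  }
  expect_equal(tl$grad, fd, tolerance = 1e-6)
})

test_that("PK batches hold per_class images of every class, reproducibly", {
  labs <- rep(c("a", "b", "c"), times = c(100, 70, 40))
  b1 <- make_pk_batches(labs, per_class = 32, seed = 9)
  b2 <- make_pk_batches(labs, per_class = 32, seed = 9)
  expect_identical(b1, b2)
  expect_equal(length(b1), ceiling(100 / 32))
  for (b in b1) {
    expect_length(b, 3 * 32)
    expect_true(all(table(labs[b]) == 32))
  }
  # balanced classes: each image appears at most ceiling(n_k/per_class) times
  labs_bal <- rep(c("a", "b"), each = 100)
  bb <- make_pk_batches(labs_bal, per_class = 32, seed = 10)
  usage <- table(unlist(bb))
  expect_lte(max(usage), ceiling(100 / 32))
  # 8 classes x 32 -> batch size 256
  labs8 <- rep(letters[1:8], each = 64)
  expect_length(make_pk_batches(labs8, 32, 1)[[1]], 256)
  # undersized class falls back to replacement with a warning
  expect_warning(make_pk_batches(rep(c("a", "b"), times = c(10, 64)), 32, 2),
                 "replacement")
})
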