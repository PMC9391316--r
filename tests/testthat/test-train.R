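test_that("classifier training follows the epoch/minibatch contract", {
  ds <- generate_dataset(example_class_specs(2), 5, c(0.8, 0, 0.2), seed = 41)
  # 8 training images, minibatch 256 -> exactly one optimizer step per epoch
  m <- train_classifier(ds, train_config(epochs = 1, seed = 42))
  expect_equal(nrow(m$log), 1)
  expect_equal(m$log$steps, 1)
  # minibatch 3 over 8 images -> ceiling(8/3) = 3 steps
  m2 <- train_classifier(ds, train_config(epochs = 2, minibatch = 3, seed = 42))
  expect_equal(m2$log$steps, c(3, 3))
  expect_error(train_classifier(generate_dataset(example_class_specs(2), 4,
                                                 c(0, 0, 1), seed = 1)),
               "train")
})

test_that("training reduces the loss and is reproducible given the seed", {
  ds <- tiny_twoclass()
  cfg <- train_config(epochs = 5, seed = 43)
  m1 <- train_classifier(ds, cfg)
  expect_lte(m1$log$train_loss[5], m1$log$train_loss[1])
  m2 <- train_classifier(ds, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$net$params, m2$net$params)
  # the frozen stats come from the train split only
  expect_equal(m1$stats$mean,
               compute_normalization(ds$images[ds$split == "train"])$mean)
})

test_that("confusion matrices are row-stochastic and match a hand tally", {
  truth <- c("a", "a", "a", "b", "b", "c", "c", "c", "c")
  pred  <- c("a", "b", "a", "b", "b", "c", "a", "c", "b")
  cm <- confusion_matrix(pred, truth)
  hand <- rbind(c(2 / 3, 1 / 3, 0), c(0, 1, 0), c(1 / 4, 1 / 4, 2 / 4))
  dimnames(hand) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(unclass(cm)[, ], hand, ignore_attr = TRUE)
  expect_equal(unname(rowSums(cm)), rep(1, 3), tolerance = 1e-12)
  # perfect predictions give the identity
  cmp <- confusion_matrix(truth, truth)
  expect_equal(unclass(cmp)[, ], diag(3), ignore_attr = TRUE)
  expect_error(confusion_matrix(pred, c(truth[-1], "zzz"), labels = c("a", "b", "c")),
               "outside")
})

test_that("an out-of-sample class is force-assigned to its nearest trained class", {
  specs <- example_class_specs(3)
  ds <- generate_dataset(specs, 120, c(0.8, 0, 0.2), seed = 44)
  m <- train_classifier(ds, train_config(epochs = 8, seed = 45))
  # foreign population rendered from the same spec as a trained class
  twin <- specs[[3]]
  twin$name <- "foreign_twin"
  fds <- generate_dataset(list(twin), 60, c(0, 0, 1), seed = 46)
  row <- classify_out_of_sample(m, fds$images)
  expect_equal(sum(row), 1, tolerance = 1e-12)
  expect_identical(names(which.max(row)), specs[[3]]$name)
  expect_gte(row[[specs[[3]]$name]], 0.6)  # well above the 1/3 chance level
})

test_that("embedder early stopping selects the validation minimum", {
  ds <- generate_dataset(example_class_specs(2), 100, c(0.8, 0.2, 0), seed = 47)
  m <- train_embedder(ds, train_config(seed = 48, max_epochs = 25))
  expect_equal(m$best_val_loss, min(m$log$val_loss))
  expect_equal(m$log$val_loss[m$best_epoch], m$best_val_loss)
  # the selected snapshot improves on the first epoch's validation loss
  expect_lt(m$best_val_loss, m$log$val_loss[1])
  # patience 0: stops at the first epoch whose val loss fails to improve
  m0 <- train_embedder(ds, train_config(seed = 48, max_epochs = 25, patience = 0))
  vl <- m0$log$val_loss
  first_flat <- which(vapply(seq_along(vl), function(e)
    e > 1 && vl[e] >= min(vl[seq_len(e - 1)]), logical(1)))[1]
  expect_equal(nrow(m0$log), first_flat)
  # a class missing from the validation split is an error
  ds_bad <- ds
  ds_bad$split[ds_bad$split == "val" & ds_bad$labels == ds_bad$labels[1]] <- "train"
  expect_error(train_embedder(ds_bad, train_config(seed = 48)), "absent")
})

test_that("the trained 2D embedding separates well-separated classes", {
  fx <- threeclass_embedder()
  emb <- embed_images(fx$model, fx$dataset)
  expect_equal(nrow(emb$points), length(fx$dataset$images))
  expect_true(all(is.finite(emb$points)))
  expect_gt(silhouette_score(emb$points, emb$labels), 0.5)
})

test_that("the CNN embedding beats PCA on a brightness-confounded fixture", {
  s1 <- class_spec("smooth_disc", mean_radius_px = 11, radius_cv = 0.2,
                   boundary_roughness = 0.05, boundary_harmonics = 3,
                   interior_level = 0.5, edge_level = 0.35, edge_width_px = 2.5,
                   texture_sd = 0.05, level_jitter_sd = 0.12)
  s2 <- class_spec("rough_star", mean_radius_px = 11, radius_cv = 0.2,
                   boundary_roughness = 0.7, boundary_harmonics = 8,
                   interior_level = 0.5, edge_level = 0.35, edge_width_px = 0.5,
                   texture_sd = 0.05, level_jitter_sd = 0.12)
  ds <- generate_dataset(list(s1, s2), 200, c(0.8, 0.2, 0), seed = 81)
  sil_pca <- silhouette_score(pca_embed(ds)$points, ds$labels)
  em <- train_embedder(ds, train_config(seed = 82, max_epochs = 40))
  e <- embed_images(em, ds)
  sil_cnn <- silhouette_score(e$points, e$labels)
  expect_gt(sil_cnn, sil_pca)
  expect_gt(sil_cnn, 0.5)
})

test_that("PCA embedding is deterministic, orthonormal and matches eigen", {
  imgs <- with_seed(51, lapply(1:50, function(i)
    list(pixels = matrix(runif(32 * 32), 32), height = 32L, width = 32L,
         id = as.character(i), label = "x")))
  es <- pca_embed(imgs)
  V <- attr(es, "rotation")
  expect_equal(crossprod(V), diag(2), tolerance = 1e-10)
  # oracle: eigendecomposition of the pixel covariance
  st <- compute_normalization(imgs)
  X <- t(prepare_batch(imgs, st))
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / 1, symmetric = TRUE)
  for (j in 1:2) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(V[, j], v, tolerance = 1e-8)
  }
  # rank-1 pixel data collapses the second coordinate
  base <- matrix(runif(32 * 32), 32)
  line <- lapply(seq(0.2, 0.8, length.out = 12), function(a)
    list(pixels = a * base, height = 32L, width = 32L, id = "", label = "x"))
  es2 <- pca_embed(line)
  expect_lt(max(abs(es2$points[, 2])), 1e-6 * max(abs(es2$points[, 1])))
  expect_error(pca_embed(imgs[1:2], dims = 2), "more images")
})
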