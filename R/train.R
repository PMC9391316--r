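#' Training configuration
#'
#' Defaults follow the study conventions: the classifier trains for exactly
#' 15 epochs with shuffled minibatches of 256 under Adam with the AMSgrad
#' option (all other optimizer settings default); the embedder trains on PK
#' batches of 32 images per class with margin 1.0, early-stopping when the
#' validation triplet loss has not improved below its running minimum for
#' `patience` epochs (capped at `max_epochs`), and keeps the parameters of
#' the validation minimum.
#'
#' @param epochs Classifier epochs (default 15).
#' @param minibatch Classifier minibatch size (default 256).
#' @param lr Adam learning rate (default 1e-3).
#' @param margin Triplet margin (default 1.0).
#' @param per_class_batch Images per class per triplet batch (default 32).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param max_epochs Embedder epoch cap (default 200).
#' @param target Input side length (default 32).
#' @param seed Master seed for initialization, shuffling and batching.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 15L, minibatch = 256L, lr = 1e-3,
                         margin = 1.0, per_class_batch = 32L, patience = 5L,
                         max_epochs = 200L, target = 32L, seed = 1L) {
  stopifnot(epochs >= 1, minibatch >= 1, margin >= 0, per_class_batch >= 1,
            patience >= 0, max_epochs >= 1, target >= 8)
  structure(list(epochs = as.integer(epochs), minibatch = as.integer(minibatch),
                 lr = lr, margin = margin,
                 per_class_batch = as.integer(per_class_batch),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 target = as.integer(target), seed = as.integer(seed)),
            class = "train_config")
}

as_dataset <- function(x) {
  if (inherits(x, "particle_dataset")) return(x)
  if (is.character(x) && length(x) == 1) return(load_dataset(x))
  stop("expected a particle_dataset or a manifest path")
}

#' Train the particle-image classifier
#'
#' Computes normalization statistics on the training split, trains the
#' convolutional classifier for exactly `config$epochs` epochs with seeded
#' shuffled minibatches, weighted cross-entropy (inverse-frequency class
#' weights from the training counts), and Adam/AMSgrad. The test split never
#' touches gradients. Runs are reproducible given the seed (single-threaded
#' numerics assumed).
#'
#' @param dataset A `particle_dataset` (or manifest path) with `train` split
#'   tags; `test`-tagged images are ignored during training.
#' @param config A `train_config`.
#' @return A `particle_classifier` with the fitted network, class labels,
#'   frozen `normalization_stats`, the config, and a per-epoch training log
#'   (`epoch`, `train_loss`, `steps`).
#' @export
train_classifier <- function(dataset, config = train_config()) {
  ds <- as_dataset(dataset)
  tr <- which(ds$split == "train")
  if (length(tr) == 0) stop("train_classifier: no images tagged 'train'")
  labels_levels <- sort(unique(ds$labels[tr]))
  if (length(labels_levels) < 2) stop("train_classifier: need >= 2 classes")
  stats <- compute_normalization(ds$images[tr])
  X <- prepare_batch(ds$images[tr], stats, target = config$target)
  y <- match(ds$labels[tr], labels_levels)
  K <- length(labels_levels)
  w <- class_weights(tabulate(y, nbins = K))

  net <- nn_init(n_out = K, seed = seed_stream(config$seed, 1L),
                 input_side = config$target)
  opt <- adam_init(net$params)
  n <- ncol(X)
  log <- data.frame(epoch = integer(), train_loss = numeric(), steps = integer())
  for (epoch in seq_len(config$epochs)) {
    perm <- with_seed(seed_stream(config$seed, 100L + epoch), sample.int(n))
    starts <- seq(1L, n, by = config$minibatch)
    ep_loss <- 0; steps <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + config$minibatch - 1L, n)]
      fw <- nn_forward(net, X[, idx, drop = FALSE], cache = TRUE)
      ce <- weighted_cross_entropy(fw$out, y[idx], w, gradient = TRUE)
      grads <- nn_backward(net, fw$cache, ce$grad)
      upd <- adam_step(net$params, grads, opt, lr = config$lr)
      net$params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + ce$loss * length(idx); steps <- steps + 1L
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / n,
                                 steps = steps))
  }
  structure(list(net = net, labels = labels_levels, stats = stats,
                 weights = w, config = config, log = log),
            class = "particle_classifier")
}

#' Predict classes (or extract features) for particle images
#'
#' Images are standardized and normalized with the model's frozen training
#' statistics, then passed through the network. `type = "label"` returns the
#' argmax class, `"logits"` the K x N score matrix, `"feature"` the 32 x N
#' penultimate features.
#'
#' @param object A `particle_classifier`.
#' @param images List of `particle_image` objects (or a `particle_dataset`).
#' @param type One of `"label"`, `"logits"`, `"feature"`.
#' @param ... Unused.
#' @return Character labels, or a numeric matrix.
#' @export
predict.particle_classifier <- function(object, images,
                                        type = c("label", "logits", "feature"),
                                        ...) {
  type <- match.arg(type)
  if (inherits(images, "particle_dataset")) images <- images$images
  X <- prepare_batch(images, object$stats, target = object$config$target)
  fw <- nn_forward(object$net, X, cache = FALSE)
  switch(type,
         label = object$labels[apply(fw$out, 2, which.max)],
         logits = fw$out,
         feature = fw$feat)
}

#' Row-normalized confusion matrix
#'
#' Rows are ground truth, columns predictions; each row is divided by its
#' ground-truth count so rows sum to one. Truth labels outside `labels` are
#' an error (use [classify_out_of_sample()] for foreign classes).
#'
#' @param pred Predicted labels.
#' @param truth True labels.
#' @param labels Label ordering; default sorted union of `truth`.
#' @return A K x K `confusion_matrix` with row counts in
#'   `attr(, "row_counts")`.
#' @export
confusion_matrix <- function(pred, truth, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(as.character(truth)))
  truth <- as.character(truth); pred <- as.character(pred)
  if (!all(truth %in% labels))
    stop("confusion_matrix: truth contains label(s) outside the model classes: ",
         paste(setdiff(unique(truth), labels), collapse = ", "))
  tab <- table(factor(truth, levels = labels), factor(pred, levels = labels))
  counts <- rowSums(tab)
  if (any(counts == 0))
    stop("confusion_matrix: no test images for class(es) ",
         paste(labels[counts == 0], collapse = ", "))
  cm <- sweep(unclass(tab), 1, counts, "/")
  structure(cm, row_counts = counts, class = c("confusion_matrix", "matrix"))
}

#' Evaluate a classifier on its held-out test split
#'
#' @param model A `particle_classifier`.
#' @param dataset The dataset with `test` split tags.
#' @return A `confusion_matrix` on the test split.
#' @export
evaluate_classifier <- function(model, dataset) {
  ds <- as_dataset(dataset)
  te <- which(ds$split == "test")
  if (length(te) == 0) stop("evaluate_classifier: no images tagged 'test'")
  pred <- predict(model, ds$images[te])
  confusion_matrix(pred, ds$labels[te], labels = model$labels)
}

#' Forced assignment of an out-of-sample class
#'
#' Classifies images from a population absent from training into the trained
#' classes and returns the distribution of predicted labels (one row summing
#' to 1) — the "which trained class is the foreign population most similar
#' to" readout.
#'
#' @param model A `particle_classifier`.
#' @param images List of `particle_image` objects.
#' @return Named numeric vector over the trained classes, summing to 1.
#' @export
classify_out_of_sample <- function(model, images) {
  pred <- predict(model, images)
  tab <- table(factor(pred, levels = model$labels))
  as.numeric(tab) / length(pred) -> frac
  stats::setNames(frac, model$labels)
}

# Validation monitor: the all-triplet hinge mean. The training objective's
# non-zero averaging (mean over surviving hard triplets only) is not a
# monotone progress measure -- it can rise as easy triplets fall inactive --
# so snapshot selection uses the hinge sum over all valid triplets instead.
val_triplet_loss <- function(E, labels, margin) {
  batch_all_triplet_loss(E, labels, margin = margin, average = "all")
}

#' Train the 2D metric-embedding network
#'
#' Same trunk as the classifier, a 2-unit linear head, trained with the
#' batch-all non-zero triplet loss (squared Euclidean distances) on PK
#' batches of `per_class_batch` images per class. An 80/20 train/validation
#' split (seeded image-level shuffle, used if the dataset does not already
#' carry `val` tags) monitors the loss; training stops once the validation
#' loss has not improved below its running minimum for `patience` epochs, or
#' at `max_epochs`, and the parameters of the validation minimum are kept.
#'
#' @param dataset A `particle_dataset` or manifest path.
#' @param config A `train_config`.
#' @return A `particle_embedder` with the snapshot network, labels, frozen
#'   stats, config, per-epoch log (`epoch`, `train_loss`, `val_loss`) and
#'   `best_epoch`.
#' @export
train_embedder <- function(dataset, config = train_config()) {
  ds <- as_dataset(dataset)
  use <- which(ds$split != "test")
  if (length(use) == 0) use <- seq_along(ds$images)
  labels_all <- ds$labels[use]
  labels_levels <- sort(unique(labels_all))
  if (length(labels_levels) < 2) stop("train_embedder: need >= 2 classes")

  if (any(ds$split[use] == "val")) {
    tr <- use[ds$split[use] == "train"]
    va <- use[ds$split[use] == "val"]
  } else {
    perm <- with_seed(seed_stream(config$seed, 7L), sample(use))
    n_tr <- floor(0.8 * length(use))
    tr <- perm[seq_len(n_tr)]
    va <- perm[(n_tr + 1):length(use)]
  }
  missing_val <- setdiff(labels_levels, unique(ds$labels[va]))
  if (length(missing_val) > 0)
    stop("train_embedder: class(es) absent from the validation split: ",
         paste(missing_val, collapse = ", "))

  stats <- compute_normalization(ds$images[tr])
  Xtr <- prepare_batch(ds$images[tr], stats, target = config$target)
  Xva <- prepare_batch(ds$images[va], stats, target = config$target)
  ytr <- ds$labels[tr]; yva <- ds$labels[va]

  net <- nn_init(n_out = 2L, seed = seed_stream(config$seed, 2L),
                 input_side = config$target)
  opt <- adam_init(net$params)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best <- Inf; best_params <- net$params; best_epoch <- 0L; wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    batches <- make_pk_batches(ytr, per_class = config$per_class_batch,
                               seed = seed_stream(config$seed, 300L + epoch))
    ep_loss <- 0; nb <- 0L
    for (idx in batches) {
      fw <- nn_forward(net, Xtr[, idx, drop = FALSE], cache = TRUE)
      tl <- batch_all_triplet_loss(t(fw$out), ytr[idx],
                                   margin = config$margin, gradient = TRUE)
      if (tl$n_active > 0) {
        grads <- nn_backward(net, fw$cache, t(tl$grad))
        upd <- adam_step(net$params, grads, opt, lr = config$lr)
        net$params <- upd$params; opt <- upd$state
      }
      ep_loss <- ep_loss + tl$loss; nb <- nb + 1L
    }
    Eva <- t(nn_forward(net, Xva, cache = FALSE)$out)
    vl <- val_triplet_loss(Eva, yva, config$margin)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                 val_loss = vl))
    if (vl < best) {
      best <- vl; best_params <- net$params; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$patience) break
    }
  }
  net$params <- best_params
  structure(list(net = net, labels = labels_levels, stats = stats,
                 config = config, log = log, best_epoch = best_epoch,
                 best_val_loss = best),
            class = "particle_embedder")
}

#' Embed particle images into the 2D space
#'
#' @param model A `particle_embedder`.
#' @param images List of `particle_image` objects or a `particle_dataset`.
#' @param labels Optional labels for the embedded points (defaults to the
#'   images' own labels).
#' @return An `embedding_set`: list with `points` (N x 2), `labels`, `ids`,
#'   `source`.
#' @export
embed_images <- function(model, images, labels = NULL) {
  if (inherits(images, "particle_dataset")) {
    if (is.null(labels)) labels <- images$labels
    images <- images$images
  }
  if (is.null(labels))
    labels <- vapply(images, function(im) im$label %||% "unlabeled", "")
  X <- prepare_batch(images, model$stats, target = model$config$target)
  E <- t(nn_forward(model$net, X, cache = FALSE)$out)
  embedding_set(E, labels,
                ids = vapply(images, function(im) im$id %||% "", ""),
                source = "cnn_triplet")
}

#' Construct an embedding set
#'
#' @param points N x 2 numeric matrix.
#' @param labels Length-N labels.
#' @param ids Optional image ids.
#' @param source Identifier of the producing model.
#' @return An `embedding_set`.
#' @export
embedding_set <- function(points, labels, ids = NULL, source = "unknown") {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("embedding_set: non-finite coordinates")
  if (nrow(points) != length(labels)) stop("embedding_set: labels/points mismatch")
  structure(list(points = points, labels = as.character(labels),
                 ids = ids %||% as.character(seq_len(nrow(points))),
                 source = source),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set: %d points, %d classes, source '%s'>\n",
              nrow(x$points), length(unique(x$labels)), x$source))
  invisible(x)
}

#' @export
as.data.frame.embedding_set <- function(x, ...) {
  data.frame(x = x$points[, 1], y = x$points[, 2], label = x$labels,
             image_id = x$ids, stringsAsFactors = FALSE)
}

#' PCA baseline embedding
#'
#' Linear, unsupervised counterpart of the CNN embedding: standardized pixels
#' are flattened, centered, and projected onto the top principal axes. Sign
#' convention: within each axis the largest-magnitude loading is positive, so
#' the projection is deterministic.
#'
#' @param images List of `particle_image` objects or a `particle_dataset`.
#' @param dims Number of components (default 2).
#' @param target Side length for standardization (default 32).
#' @return An `embedding_set` with the rotation matrix in
#'   `attr(, "rotation")`.
#' @export
pca_embed <- function(images, dims = 2L, target = 32L) {
  labels <- NULL
  if (inherits(images, "particle_dataset")) {
    labels <- images$labels
    images <- images$images
  }
  if (length(images) < dims + 1)
    stop("pca_embed: need more images than requested dimensions")
  if (is.null(labels))
    labels <- vapply(images, function(im) im$label %||% "unlabeled", "")
  stats <- compute_normalization(images)
  X <- t(prepare_batch(images, stats, target = target))  # N x d
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = dims)
  V <- sv$v
  for (j in seq_len(dims)) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  es <- embedding_set(Xc %*% V, labels,
                      ids = vapply(images, function(im) im$id %||% "", ""),
                      source = "pca")
  attr(es, "rotation") <- V
  es
}
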