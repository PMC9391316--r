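#' Inverse-frequency class weights
#'
#' Weights proportional to `1 / n_k`, normalized so they sum to the number of
#' classes K (balanced data gives all-ones). Used to counter class imbalance
#' in the cross-entropy objective.
#'
#' @param counts Named or unnamed vector of per-class sample counts (>= 1).
#' @return Numeric vector of K positive weights summing to K.
#' @export
class_weights <- function(counts) {
  if (any(counts < 1)) stop("class_weights: every class count must be >= 1")
  w <- 1 / counts
  w * length(counts) / sum(w)
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Weighted cross-entropy loss
#'
#' Mean over samples of `w[y_i] * (-log softmax(logits_i)[y_i])` with the
#' weighted-mean convention: the sum is divided by `sum_i w[y_i]`, keeping the
#' loss scale comparable across imbalance levels.
#'
#' @param logits K x N matrix of class scores (one column per sample).
#' @param labels Integer vector of N true classes in `1..K`.
#' @param weights K positive class weights.
#' @param gradient Also return the gradient w.r.t. the logits?
#' @return The scalar loss, or (with `gradient = TRUE`) a list
#'   `list(loss, grad)` with `grad` a K x N matrix.
#' @export
weighted_cross_entropy <- function(logits, labels, weights, gradient = FALSE) {
  K <- nrow(logits); n <- ncol(logits)
  if (length(labels) != n) stop("weighted_cross_entropy: labels/logits mismatch")
  if (any(labels < 1 | labels > K)) stop("weighted_cross_entropy: label out of range")
  if (length(weights) != K) stop("weighted_cross_entropy: need one weight per class")
  p <- softmax_cols(logits)
  wi <- weights[labels]
  idx <- cbind(labels, seq_len(n))
  # log softmax recomputed stably
  z <- sweep(logits, 2, apply(logits, 2, max))
  logp <- z - rep(log(colSums(exp(z))), each = K)
  loss <- -sum(wi * logp[cbind(labels, seq_len(n))]) / sum(wi)
  if (!gradient) return(loss)
  onehot <- matrix(0, K, n); onehot[idx] <- 1
  grad <- sweep(p - onehot, 2, wi, "*") / sum(wi)
  list(loss = loss, grad = grad)
}

#' Batch-all non-zero triplet loss
#'
#' Over every valid (anchor, positive, negative) triplet in the batch
#' (anchor != positive with the same label; negative with a different label),
#' the hinge term is `max(0, d2(a,p) - d2(a,n) + margin)` with squared
#' Euclidean distances. The loss is the mean over *strictly positive* terms
#' (the "non-zero" convention); a batch in which every triplet is inactive
#' has loss 0 and no gradient.
#'
#' @param embeddings N x d matrix of embedding coordinates (rows = samples).
#' @param labels Length-N labels (>= 2 classes, some class with >= 2 samples).
#' @param margin Nonnegative margin (default 1).
#' @param gradient Also return the gradient w.r.t. the embeddings?
#' @param average `"nonzero"` (default): mean over strictly positive terms,
#'   the training objective; `"all"`: hinge sum divided by the number of
#'   valid triplets, a monotone progress measure used to monitor validation.
#' @return Scalar loss, or `list(loss, grad, n_active, n_triplets)`.
#' @export
batch_all_triplet_loss <- function(embeddings, labels, margin = 1,
                                   gradient = FALSE,
                                   average = c("nonzero", "all")) {
  average <- match.arg(average)
  E <- as.matrix(embeddings)
  B <- nrow(E)
  labels <- as.character(labels)
  if (length(labels) != B) stop("batch_all_triplet_loss: labels/embeddings mismatch")
  if (length(unique(labels)) < 2)
    stop("batch_all_triplet_loss: batch contains a single class - no valid triplets")
  sq <- rowSums(E^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(E)
  D[D < 0] <- 0
  same <- outer(labels, labels, "==")

  total <- 0; n_active <- 0L; n_triplets <- 0L
  grad <- if (gradient) matrix(0, B, ncol(E)) else NULL
  for (a in seq_len(B)) {
    pos <- which(same[a, ] & seq_len(B) != a)
    neg <- which(!same[a, ])
    if (length(pos) == 0 || length(neg) == 0) next
    term <- outer(D[a, pos], D[a, neg], function(dp, dn) dp - dn + margin)
    act <- term > 0
    n_triplets <- n_triplets + length(term)
    na <- sum(act)
    if (na == 0) next
    n_active <- n_active + na
    total <- total + sum(term[act])
    if (gradient) {
      cnt_p <- rowSums(act)            # per positive: # active negatives
      cnt_n <- colSums(act)            # per negative: # active positives
      # d term / d a = 2 (n - p); d/d p = -2 (a - p); d/d n = 2 (a - n)
      grad[a, ] <- grad[a, ] +
        2 * (colSums(E[neg, , drop = FALSE] * cnt_n) -
             colSums(E[pos, , drop = FALSE] * cnt_p))
      diff_p <- sweep(E[pos, , drop = FALSE], 2, E[a, ], "-")  # p - a
      diff_n <- sweep(E[neg, , drop = FALSE], 2, E[a, ], "-")  # n - a
      grad[pos, ] <- grad[pos, ] + 2 * cnt_p * diff_p
      grad[neg, ] <- grad[neg, ] - 2 * cnt_n * diff_n
    }
  }
  denom <- if (average == "nonzero") n_active else n_triplets
  loss <- if (denom > 0 && n_active > 0) total / denom else 0
  if (!gradient) return(loss)
  if (denom > 0 && n_active > 0) grad <- grad / denom
  list(loss = loss, grad = grad, n_active = n_active, n_triplets = n_triplets)
}

#' Build PK minibatches for triplet training
#'
#' Each batch holds exactly `per_class` images from every class. Per epoch,
#' each class's indices are covered by a seeded shuffle, recycled (reshuffled)
#' when a class runs out before the epoch's batch count
#' `max_k ceiling(n_k / per_class)` is reached. A class smaller than
#' `per_class` is sampled with replacement, with a warning.
#'
#' @param labels Length-N vector of class labels.
#' @param per_class Images per class per batch (default 32).
#' @param seed Integer seed.
#' @return List of integer index vectors, one per batch.
#' @export
make_pk_batches <- function(labels, per_class = 32L, seed = 1L) {
  labels <- as.character(labels)
  classes <- unique(labels)
  idx_by <- lapply(classes, function(cl) which(labels == cl))
  nk <- lengths(idx_by)
  small <- nk < per_class
  if (any(small))
    warning("make_pk_batches: class(es) ", paste(classes[small], collapse = ", "),
            " smaller than per_class; sampling with replacement")
  n_batches <- max(ceiling(nk / per_class))
  with_seed(seed, {
    streams <- lapply(seq_along(classes), function(ci) {
      need <- n_batches * per_class
      out <- integer(0)
      if (small[ci]) {
        out <- sample(idx_by[[ci]], need, replace = TRUE)
      } else {
        while (length(out) < need) out <- c(out, sample(idx_by[[ci]]))
        out <- out[seq_len(need)]
      }
      out
    })
    lapply(seq_len(n_batches), function(b) {
      unlist(lapply(streams, function(s)
        s[((b - 1) * per_class + 1):(b * per_class)]))
    })
  })
}
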