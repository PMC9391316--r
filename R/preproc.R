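#' Training-set normalization statistics
#'
#' Pools every pixel of every training image and returns the mean and the
#' population standard deviation. The statistics are computed once on the
#' training split and then frozen: validation and test images are normalized
#' with the same numbers, never with their own.
#'
#' @param training_images List of `particle_image` objects (or plain matrices).
#' @return A `normalization_stats` list with `mean` and `sd`.
#' @export
compute_normalization <- function(training_images) {
  if (length(training_images) == 0)
    stop("compute_normalization: empty training collection")
  px <- unlist(lapply(training_images, function(im)
    if (is.matrix(im)) as.numeric(im) else as.numeric(im$pixels)))
  m <- mean(px)
  s <- sqrt(mean((px - m)^2))  # population sd
  if (s <= 0)
    stop("compute_normalization: zero pixel variance (all training pixels equal ",
         format(m), ") - cannot normalize")
  structure(list(mean = m, sd = s), class = "normalization_stats")
}

#' Standardize a particle crop to a fixed square size
#'
#' Images smaller than `target` in a dimension are centered within a
#' constant-intensity border (`fill`, conventionally the training-set mean);
#' images larger than `target` are center-cropped. The two dimensions are
#' handled independently, so an image can be padded along one axis and
#' cropped along the other. No rescaling or interpolation is ever applied:
#' spatial resolution is preserved. When the centering offset is fractional,
#' the extra row/column goes on the bottom/right.
#'
#' @param image A `particle_image` or plain matrix.
#' @param target Output side length (default 32).
#' @param fill Border intensity for padding.
#' @return A `particle_image` with `target` x `target` pixels.
#' @export
standardize_size <- function(image, target = 32L, fill) {
  px <- if (is.matrix(image)) image else image$pixels
  if (target < 1) stop("standardize_size: target must be >= 1")
  if (missing(fill)) stop("standardize_size: fill intensity is required")
  h <- nrow(px); w <- ncol(px)

  place <- function(n_in, n_out) {
    # returns c(src_start, src_end, dst_start): centered, extra goes bottom/right
    if (n_in >= n_out) {
      off <- floor((n_in - n_out) / 2)       # crop: extra dropped from bottom/right
      c(off + 1L, off + n_out, 1L)
    } else {
      off <- floor((n_out - n_in) / 2)       # pad: extra border on bottom/right
      c(1L, n_in, off + 1L)
    }
  }
  pr <- place(h, target); pc <- place(w, target)
  out <- matrix(fill, target, target)
  block <- px[pr[1]:pr[2], pc[1]:pc[2], drop = FALSE]
  out[pr[3]:(pr[3] + nrow(block) - 1L), pc[3]:(pc[3] + ncol(block) - 1L)] <- block
  structure(list(pixels = out, height = target, width = target,
                 id = if (is.matrix(image)) "" else image$id,
                 label = if (is.matrix(image)) "unlabeled" else image$label),
            class = "particle_image")
}

#' Normalize a standardized image with frozen training statistics
#'
#' Maps every pixel to `(x - mean) / sd` with the training-set statistics.
#'
#' @param image A `particle_image` (already `target` x `target`) or matrix.
#' @param stats A `normalization_stats` object.
#' @param target Expected side length (default 32).
#' @return A `particle_image` with normalized pixels.
#' @export
normalize_image <- function(image, stats, target = 32L) {
  px <- if (is.matrix(image)) image else image$pixels
  if (nrow(px) != target || ncol(px) != target)
    stop(sprintf("normalize_image: expected %dx%d input, got %dx%d",
                 target, target, nrow(px), ncol(px)))
  out <- (px - stats$mean) / stats$sd
  structure(list(pixels = out, height = target, width = target,
                 id = if (is.matrix(image)) "" else image$id,
                 label = if (is.matrix(image)) "unlabeled" else image$label),
            class = "particle_image")
}

#' Invert normalization
#'
#' @param image Normalized `particle_image` or matrix.
#' @param stats The `normalization_stats` used to normalize.
#' @return Matrix of raw intensities.
#' @export
denormalize_image <- function(image, stats) {
  px <- if (is.matrix(image)) image else image$pixels
  px * stats$sd + stats$mean
}

#' Standardize and normalize a set of images into a design matrix
#'
#' Applies [standardize_size()] (fill = training mean) and [normalize_image()]
#' to each image and stacks the results as columns of a `target^2 x N` matrix
#' (pixels in column-major order), the input layout of the network engine.
#'
#' @param images List of `particle_image` objects.
#' @param stats `normalization_stats` from the training split.
#' @param target Side length (default 32).
#' @return A `target^2 x N` numeric matrix.
#' @export
prepare_batch <- function(images, stats, target = 32L) {
  n <- length(images)
  X <- matrix(0, target * target, n)
  for (i in seq_len(n)) {
    im <- standardize_size(images[[i]], target = target, fill = stats$mean)
    X[, i] <- (as.numeric(im$pixels) - stats$mean) / stats$sd
  }
  X
}
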