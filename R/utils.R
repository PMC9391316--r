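#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions do not disturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' One master seed fans out to per-stage seeds via a fixed affine counter
#' scheme, so that every stochastic stage of a run is independently
#' reproducible without reusing the same stream. Result always fits in a
#' 32-bit integer.
#'
#' @param master Integer master seed.
#' @param stage Integer stage counter (0, 1, 2, ...).
#' @return An integer seed.
#' @export
seed_stream <- function(master, stage) {
  as.integer((as.numeric(master) %% 1e6) * 2039 + 7919 * as.numeric(stage) + 1) %% 2147483646L + 1L
}

clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean silhouette coefficient of a labelled 2D point set
#'
#' Standard silhouette with Euclidean distances: for each point, a = mean
#' distance to its own cluster (excluding itself), b = minimum over other
#' clusters of the mean distance to that cluster, s = (b - a) / max(a, b).
#' Used to quantify how well an embedding separates known classes.
#'
#' @param points N x d numeric matrix.
#' @param labels Length-N vector of class labels (>= 2 distinct).
#' @return Mean silhouette coefficient in [-1, 1].
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  stopifnot(nrow(points) == length(labels))
  lev <- unique(labels)
  if (length(lev) < 2) stop("silhouette requires at least two classes")
  d <- as.matrix(stats::dist(points))
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) < 2) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(lev[lev != labels[i]],
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
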