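#' Define a synthetic particle class
#'
#' A `class_spec` describes one morphological population of synthetic
#' particle crops: dark, roughly round particles on a near-white membrane
#' background, the imaging situation of plate-based backgrounded membrane
#' imaging. Particle-to-particle size variation, boundary roughness (radial
#' Fourier perturbation), interior darkness, an edge ring, interior speckle
#' texture and global additive noise are all controllable, so classes can be
#' made grossly different (distinct shapes and sizes) or subtly different
#' (same geometry, shifted brightness).
#'
#' @param name Label string.
#' @param mean_radius_px Mean particle radius in pixels (> 0).
#' @param radius_cv Coefficient of variation of the radius across particles,
#'   in `[0, 1)`; sizes are drawn lognormally with this mean and CV.
#' @param boundary_roughness Amplitude of the radial perturbation (>= 0).
#'   Values up to about 0.8 keep the boundary radius positive.
#' @param boundary_harmonics Number of radial Fourier modes (positive integer).
#' @param interior_level Mean interior intensity in `[0, 1]` (0 = black).
#' @param edge_level Intensity of the boundary ring in `[0, 1]`.
#' @param edge_width_px Width of the boundary ring in pixels (>= 0).
#' @param texture_sd Standard deviation of interior speckle (>= 0).
#' @param background_level Background intensity in `[0, 1]`, near white.
#' @param noise_sd Standard deviation of global additive noise (>= 0).
#' @param level_jitter_sd Particle-to-particle standard deviation of a common
#'   additive shift of `interior_level` and `edge_level` (>= 0): within one
#'   population some particles image darker, some lighter, which is what
#'   makes a small between-population brightness shift genuinely subtle.
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(name,
                       mean_radius_px,
                       radius_cv = 0.3,
                       boundary_roughness = 0.3,
                       boundary_harmonics = 4L,
                       interior_level = 0.5,
                       edge_level = 0.3,
                       edge_width_px = 1.5,
                       texture_sd = 0.08,
                       background_level = 0.92,
                       noise_sd = 0.04,
                       level_jitter_sd = 0) {
  spec <- structure(list(
    name = as.character(name),
    mean_radius_px = mean_radius_px,
    radius_cv = radius_cv,
    boundary_roughness = boundary_roughness,
    boundary_harmonics = as.integer(boundary_harmonics),
    interior_level = interior_level,
    edge_level = edge_level,
    edge_width_px = edge_width_px,
    texture_sd = texture_sd,
    background_level = background_level,
    noise_sd = noise_sd,
    level_jitter_sd = level_jitter_sd
  ), class = "class_spec")
  validate_class_spec(spec)
  spec
}

validate_class_spec <- function(spec) {
  with(spec, {
    if (!nzchar(name)) stop("class_spec: name must be nonempty")
    if (!is.finite(mean_radius_px) || mean_radius_px <= 0)
      stop("class_spec: mean_radius_px must be positive")
    if (radius_cv < 0 || radius_cv >= 1)
      stop("class_spec: radius_cv must lie in [0, 1)")
    if (boundary_roughness < 0) stop("class_spec: boundary_roughness must be >= 0")
    if (boundary_harmonics < 1) stop("class_spec: boundary_harmonics must be >= 1")
    for (lv in c(interior_level, edge_level, background_level))
      if (lv < 0 || lv > 1) stop("class_spec: intensity levels must lie in [0, 1]")
    if (edge_width_px < 0) stop("class_spec: edge_width_px must be >= 0")
    if (texture_sd < 0 || noise_sd < 0 || level_jitter_sd < 0)
      stop("class_spec: texture_sd, noise_sd and level_jitter_sd must be >= 0")
  })
  invisible(spec)
}

#' @export
print.class_spec <- function(x, ...) {
  cat(sprintf("<class_spec '%s': r=%.1fpx (cv %.2f), rough %.2f/%d modes, interior %.2f, edge %.2f (w %.1f), texture %.2f, bg %.2f, noise %.2f>\n",
              x$name, x$mean_radius_px, x$radius_cv, x$boundary_roughness,
              x$boundary_harmonics, x$interior_level, x$edge_level,
              x$edge_width_px, x$texture_sd, x$background_level, x$noise_sd))
  invisible(x)
}

#' Shift the brightness of a particle class
#'
#' Returns a copy of `spec` with `interior_level` and `edge_level` shifted by
#' `brightness_shift`, all geometry untouched. A spec and its shifted copy
#' form a "subtle pair": same shapes, slightly brighter or darker interiors,
#' the situation of two mixed fatty-acid particle samples differing only in
#' total concentration.
#'
#' @param spec A `class_spec`.
#' @param brightness_shift Additive shift; resulting levels must stay in `[0, 1]`.
#' @return A new `class_spec`.
#' @export
perturb_spec <- function(spec, brightness_shift) {
  stopifnot(inherits(spec, "class_spec"))
  out <- spec
  out$interior_level <- spec$interior_level + brightness_shift
  out$edge_level <- spec$edge_level + brightness_shift
  if (out$interior_level < 0 || out$interior_level > 1 ||
      out$edge_level < 0 || out$edge_level > 1)
    stop("perturb_spec: brightness_shift pushes intensity levels outside [0, 1]")
  if (brightness_shift != 0) out$name <- paste0(spec$name, "_shift")
  validate_class_spec(out)
  out
}

#' Render one synthetic particle crop
#'
#' Draws a particle radius from the spec's lognormal size distribution, picks
#' a square crop side proportional to it (clipped to 8--64 px so both the
#' padding and the cropping branch of 32x32 standardization are exercised),
#' and renders a single connected star-shaped particle: the boundary radius at
#' polar angle theta is `r0 * (1 + roughness * sum_k a_k cos(k theta + phi_k))`
#' with seeded coefficients, the interior is filled at `interior_level` plus
#' speckle, a ring of `edge_width_px` takes `edge_level`, the rest is
#' background, and global Gaussian noise is added before clipping to `[0, 1]`.
#' Deterministic given `(spec, rng_seed)`.
#'
#' @param spec A `class_spec`.
#' @param rng_seed Integer seed.
#' @return A `particle_image`: list with `pixels` (H x W matrix in `[0, 1]`),
#'   `height`, `width`, `id`, `label`.
#' @export
render_particle <- function(spec, rng_seed) {
  validate_class_spec(spec)
  with_seed(rng_seed, {
    r0 <- if (spec$radius_cv > 0) {
      sdlog <- sqrt(log(1 + spec$radius_cv^2))
      stats::rlnorm(1, log(spec$mean_radius_px) - sdlog^2 / 2, sdlog)
    } else spec$mean_radius_px
    side <- as.integer(min(64, max(8, round(2.8 * r0))))
    K <- spec$boundary_harmonics
    a <- stats::runif(K, -1, 1) / K
    phi <- stats::runif(K, 0, 2 * pi)

    lshift <- if (spec$level_jitter_sd > 0)
      stats::rnorm(1, 0, spec$level_jitter_sd) else 0
    int_lv <- min(1, max(0, spec$interior_level + lshift))
    edg_lv <- min(1, max(0, spec$edge_level + lshift))

    cx <- (side + 1) / 2
    cy <- (side + 1) / 2
    xs <- matrix(rep(seq_len(side), each = side), side)   # column index
    ys <- matrix(rep(seq_len(side), times = side), side)  # row index
    dx <- xs - cx
    dy <- ys - cy
    dist <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)

    rb <- r0
    if (spec$boundary_roughness > 0) {
      pert <- 0
      for (k in seq_len(K)) pert <- pert + a[k] * cos(k * theta + phi[k])
      rb <- r0 * pmax(0.2, 1 + spec$boundary_roughness * pert)
    }
    img <- matrix(spec$background_level, side, side)
    inner <- dist <= (rb - spec$edge_width_px)
    ring <- dist <= rb & !inner
    img[ring] <- edg_lv
    img[inner] <- int_lv
    if (spec$texture_sd > 0 && any(inner))
      img[inner] <- img[inner] + stats::rnorm(sum(inner), 0, spec$texture_sd)
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(side * side, 0, spec$noise_sd), side)
    structure(list(pixels = clamp01(img), height = side, width = side,
                   id = sprintf("%s_seed%d", spec$name, as.integer(rng_seed)),
                   label = spec$name),
              class = "particle_image")
  })
}

split_counts <- function(n, fractions) {
  # exact per-class split sizes by largest remainder
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  base
}

#' Generate a labelled synthetic particle dataset
#'
#' Renders `n_per_class` images per class spec, assigns train/val/test split
#' tags by a seeded within-class shuffle with exact split counts, and
#' (optionally) writes 8-bit grayscale PNGs plus a `manifest.csv` with columns
#' `path,label,split`. Identical inputs reproduce the dataset byte-for-byte.
#'
#' @param specs List of `class_spec` objects (distinct names).
#' @param n_per_class Images per class (> 0).
#' @param split_fractions Length-3 nonnegative vector (train, val, test)
#'   summing to 1.
#' @param seed Integer seed.
#' @param dir Output directory for PNGs and manifest; `NULL` keeps the images
#'   in memory only.
#' @return A `particle_dataset`: list with `images` (list of `particle_image`),
#'   `labels`, `split`, `ids`, `manifest` (data.frame), `seed`, and a per-label
#'   `spec_summary`.
#' @export
generate_dataset <- function(specs, n_per_class, split_fractions = c(0.8, 0, 0.2),
                             seed = 1L, dir = NULL) {
  if (length(specs) < 1) stop("generate_dataset: need at least one class spec")
  if (inherits(specs, "class_spec")) specs <- list(specs)
  lapply(specs, validate_class_spec)
  if (n_per_class < 1) stop("generate_dataset: n_per_class must be >= 1")
  if (any(split_fractions < 0) || abs(sum(split_fractions) - 1) > 1e-9)
    stop("generate_dataset: split fractions must be nonnegative and sum to 1")
  names(split_fractions) <- c("train", "val", "test")
  labels_all <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(labels_all)) stop("generate_dataset: class names must be distinct")

  images <- list(); labels <- character(); split <- character(); ids <- character()
  for (ci in seq_along(specs)) {
    spec <- specs[[ci]]
    img_seeds <- seed_stream(seed, (ci - 1) * (n_per_class + 1)) +
      seq_len(n_per_class) - 1L
    imgs <- lapply(img_seeds, function(s) render_particle(spec, s))
    for (k in seq_len(n_per_class))
      imgs[[k]]$id <- sprintf("%s_%05d", spec$name, k)
    counts <- split_counts(n_per_class, split_fractions)
    tags <- rep(names(split_fractions), counts)
    perm <- with_seed(seed_stream(seed, 90000 + ci), sample.int(n_per_class))
    tags <- tags[order(perm)]  # seeded within-class shuffle of split tags
    images <- c(images, imgs)
    labels <- c(labels, rep(spec$name, n_per_class))
    split <- c(split, tags)
    ids <- c(ids, vapply(imgs, `[[`, "", "id"))
  }

  paths <- rep(NA_character_, length(images))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(images)) {
      paths[i] <- file.path(dir, paste0(ids[i], ".png"))
      png::writePNG(images[[i]]$pixels, paths[i])
    }
  }
  manifest <- data.frame(path = paths, label = labels, split = split,
                         stringsAsFactors = FALSE)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  structure(list(images = images, labels = labels, split = split, ids = ids,
                 manifest = manifest, seed = as.integer(seed),
                 spec_summary = stats::setNames(specs, labels_all)),
            class = "particle_dataset")
}

#' @export
print.particle_dataset <- function(x, ...) {
  cat(sprintf("<particle_dataset: %d images, %d classes (%s); splits: %s>\n",
              length(x$images), length(unique(x$labels)),
              paste(unique(x$labels), collapse = ", "),
              paste(sprintf("%s=%d", names(table(x$split)), table(x$split)),
                    collapse = ", ")))
  invisible(x)
}

#' Load a particle dataset from a manifest
#'
#' Reads `manifest.csv` (columns `path,label,split`) and the referenced
#' grayscale PNG crops back into a `particle_dataset`.
#'
#' @param manifest_path Path to a manifest CSV.
#' @return A `particle_dataset`.
#' @export
load_dataset <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("path", "label", "split") %in% names(manifest)))
    stop("load_dataset: manifest must have columns path, label, split")
  missing <- !file.exists(manifest$path)
  if (any(missing))
    stop("load_dataset: missing image files, e.g. ", manifest$path[which(missing)[1]])
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    px <- png::readPNG(manifest$path[i])
    if (length(dim(px)) == 3) px <- px[, , 1]
    structure(list(pixels = px, height = nrow(px), width = ncol(px),
                   id = sub("\\.png$", "", basename(manifest$path[i])),
                   label = manifest$label[i]),
              class = "particle_image")
  })
  structure(list(images = images, labels = manifest$label,
                 split = manifest$split,
                 ids = vapply(images, `[[`, "", "id"),
                 manifest = manifest, seed = NA_integer_,
                 spec_summary = NULL),
            class = "particle_dataset")
}

#' Built-in palettes of synthetic particle classes
#'
#' Ready-made `class_spec` collections emulating the morphological variety of
#' a BMI study: `example_class_specs(4)` gives four well-separated classes
#' (small rough protein-like particles, large bright fatty-acid-like discs, a
#' ring-dominated class, and large very rough reference-material-like
#' particles); `example_class_specs(6)` adds two intermediate fatty-acid-like
#' classes so that a six-class panel with subtler contrasts is available.
#'
#' @param k Number of classes (1..6).
#' @return List of `class_spec` objects.
#' @export
example_class_specs <- function(k = 4) {
  pal <- list(
    class_spec("protein_like", mean_radius_px = 8, radius_cv = 0.25,
               boundary_roughness = 0.55, boundary_harmonics = 5,
               interior_level = 0.35, edge_level = 0.22, edge_width_px = 1.2,
               texture_sd = 0.10),
    class_spec("fa_short_chain", mean_radius_px = 15, radius_cv = 0.35,
               boundary_roughness = 0.12, boundary_harmonics = 3,
               interior_level = 0.78, edge_level = 0.58, edge_width_px = 1.0,
               texture_sd = 0.05),
    class_spec("fa_long_chain", mean_radius_px = 11, radius_cv = 0.30,
               boundary_roughness = 0.30, boundary_harmonics = 4,
               interior_level = 0.52, edge_level = 0.30, edge_width_px = 2.6,
               texture_sd = 0.08),
    class_spec("etfe_like", mean_radius_px = 19, radius_cv = 0.40,
               boundary_roughness = 0.65, boundary_harmonics = 8,
               interior_level = 0.60, edge_level = 0.35, edge_width_px = 1.0,
               texture_sd = 0.15),
    class_spec("fa_mid_chain", mean_radius_px = 13, radius_cv = 0.32,
               boundary_roughness = 0.20, boundary_harmonics = 3,
               interior_level = 0.66, edge_level = 0.45, edge_width_px = 1.8,
               texture_sd = 0.07),
    class_spec("fa_mix", mean_radius_px = 10, radius_cv = 0.35,
               boundary_roughness = 0.40, boundary_harmonics = 6,
               interior_level = 0.45, edge_level = 0.40, edge_width_px = 1.4,
               texture_sd = 0.12)
  )
  if (!k %in% 1:6) stop("example_class_specs: k must lie in 1..6")
  pal[seq_len(k)]
}

#' A subtle brightness-only class pair
#'
#' Two classes with identical geometry whose interiors and edges differ only
#' by `shift` in intensity — the analogue of two mixed fatty-acid samples at
#' different total concentrations, one appearing slightly brighter and less
#' dense, the other slightly darker.
#'
#' @param base A `class_spec`; default is a mixed-fatty-acid-like class.
#' @param shift Brightness shift (default 0.08).
#' @return List of two `class_spec` objects.
#' @export
subtle_pair_specs <- function(base = NULL, shift = 0.08) {
  if (is.null(base))
    base <- class_spec("fa_mix_dark", mean_radius_px = 12, radius_cv = 0.32,
                       boundary_roughness = 0.35, boundary_harmonics = 5,
                       interior_level = 0.48, edge_level = 0.34,
                       edge_width_px = 1.6, texture_sd = 0.12, noise_sd = 0.06,
                       level_jitter_sd = 0.06)
  bright <- perturb_spec(base, shift)
  bright$name <- paste0(sub("_dark$", "", base$name), "_bright")
  list(base, bright)
}

#' Write / read class-spec collections as YAML
#'
#' @param specs List of `class_spec` objects.
#' @param path File path.
#' @return `write_specs` returns `path` invisibly; `read_specs` a list of
#'   `class_spec`.
#' @export
write_specs <- function(specs, path) {
  if (inherits(specs, "class_spec")) specs <- list(specs)
  yaml::write_yaml(lapply(specs, unclass), path)
  invisible(path)
}

#' @rdname write_specs
#' @export
read_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) do.call(class_spec, s))
}
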