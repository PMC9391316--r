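# Orchestration of the three study shapes over synthetic particle data:
# a classification study (confusion matrix + forced out-of-sample row), a
# fingerprint study (joint embedding, per-class fingerprints, modes, HDR
# levels, mode-nearest galleries, pairwise GOF), and a temporal study
# (training time points vs out-of-sample time points). Every run directory
# receives a config snapshot, a seed record, a structured log and an
# artifact manifest, so a run is self-describing and checkable.

run_log <- function(dir, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  cat(line, "\n", sep = "", file = file.path(dir, "run.log"), append = TRUE)
  invisible(line)
}

init_run_dir <- function(out_dir, kind, seed, config, extra = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  snap <- c(list(kind = kind, master_seed = seed,
                 train_config = unclass(config)), extra)
  jsonlite::write_json(snap, file.path(out_dir, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  writeLines(as.character(seed), file.path(out_dir, "seed.txt"))
  run_log(out_dir, paste("run started:", kind))
  invisible(out_dir)
}

finish_run_dir <- function(out_dir, artifacts) {
  artifacts <- unique(c("config.json", "seed.txt", "run.log",
                        "artifacts.json", artifacts))
  jsonlite::write_json(artifacts, file.path(out_dir, "artifacts.json"),
                       digits = NA)
  run_log(out_dir, "run finished")
  invisible(artifacts)
}

#' Check that a run directory contains every declared artifact
#'
#' @param out_dir A study output directory.
#' @return TRUE invisibly; error listing any missing artifact.
#' @export
check_run_artifacts <- function(out_dir) {
  listing <- file.path(out_dir, "artifacts.json")
  if (!file.exists(listing)) stop("no artifacts.json in ", out_dir)
  art <- unlist(jsonlite::read_json(listing, simplifyVector = TRUE))
  missing <- art[!file.exists(file.path(out_dir, art))]
  if (length(missing) > 0)
    stop("missing artifacts in ", out_dir, ": ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

write_confusion_csv <- function(cm, path) {
  df <- data.frame(truth = rownames(cm), as.data.frame.matrix(cm),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Classification study
#'
#' Generates a labelled synthetic dataset (80/20 train/test), trains the
#' weighted cross-entropy classifier, and writes the row-normalized test
#' confusion matrix. If a foreign class spec is given, its images (absent
#' from training) are force-assigned into the trained classes and the
#' resulting assignment row is written as well.
#'
#' @param specs List of `class_spec` (the training classes).
#' @param n_per_class Images per training class.
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param config A `train_config`.
#' @param foreign_spec Optional `class_spec` held out of training.
#' @param n_foreign Images for the foreign class (default `n_per_class`).
#' @return List with `model`, `confusion`, `foreign_row` (or NULL), `dataset`.
#' @export
run_classification_study <- function(specs, n_per_class = 500L, out_dir,
                                     seed = 1L, config = NULL,
                                     foreign_spec = NULL,
                                     n_foreign = n_per_class) {
  config <- config %||% train_config(seed = seed_stream(seed, 11L))
  init_run_dir(out_dir, "classify", seed, config,
               list(classes = vapply(specs, `[[`, "", "name"),
                    n_per_class = n_per_class))
  ds <- generate_dataset(specs, n_per_class, c(0.8, 0, 0.2),
                         seed = seed_stream(seed, 12L))
  run_log(out_dir, sprintf("dataset: %d images, %d classes",
                           length(ds$images), length(specs)))
  model <- train_classifier(ds, config)
  run_log(out_dir, sprintf("classifier trained: %d epochs, final loss %.4f",
                           nrow(model$log), utils::tail(model$log$train_loss, 1)))
  cm <- evaluate_classifier(model, ds)
  write_confusion_csv(cm, file.path(out_dir, "confusion_matrix.csv"))
  utils::write.csv(model$log, file.path(out_dir, "training_log.csv"),
                   row.names = FALSE)
  artifacts <- c("confusion_matrix.csv", "training_log.csv")

  foreign_row <- NULL
  if (!is.null(foreign_spec)) {
    fds <- generate_dataset(list(foreign_spec), n_foreign, c(0, 0, 1),
                            seed = seed_stream(seed, 13L))
    foreign_row <- classify_out_of_sample(model, fds$images)
    utils::write.csv(data.frame(class = names(foreign_row),
                                fraction = as.numeric(foreign_row)),
                     file.path(out_dir, "out_of_sample_row.csv"),
                     row.names = FALSE)
    artifacts <- c(artifacts, "out_of_sample_row.csv")
    run_log(out_dir, sprintf("foreign class '%s' assigned; top match '%s' (%.2f)",
                             foreign_spec$name,
                             names(which.max(foreign_row)),
                             max(foreign_row)))
  }
  finish_run_dir(out_dir, artifacts)
  list(model = model, confusion = cm, foreign_row = foreign_row, dataset = ds)
}

#' Fingerprint study
#'
#' Trains one embedding network jointly on all configured classes, embeds
#' every image, and derives per-class fingerprints with their global modes,
#' HDR contour levels and mode-nearest image galleries, plus the pairwise
#' subset-rejection GOF matrix (each class's embeddings tested against each
#' class's fingerprint).
#'
#' @param specs List of `class_spec`.
#' @param n_per_class Images per class.
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param config A `train_config`.
#' @param masses HDR masses (default 0.2, 0.4, 0.6, 0.8).
#' @param k_nearest Gallery size (default 50).
#' @param N_test GOF subset size (default 100).
#' @param alpha GOF significance level (default 0.05).
#' @return List with `model`, `embedding`, `fingerprints`, `modes`,
#'   `gof_matrix`.
#' @export
run_fingerprint_study <- function(specs, n_per_class = 500L, out_dir,
                                  seed = 1L, config = NULL,
                                  masses = c(0.2, 0.4, 0.6, 0.8),
                                  k_nearest = 50L, N_test = 100L,
                                  alpha = 0.05) {
  config <- config %||% train_config(seed = seed_stream(seed, 21L))
  init_run_dir(out_dir, "fingerprint", seed, config,
               list(classes = vapply(specs, `[[`, "", "name"),
                    n_per_class = n_per_class, masses = masses,
                    k_nearest = k_nearest, N_test = N_test, alpha = alpha))
  ds <- generate_dataset(specs, n_per_class, c(0.8, 0.2, 0),
                         seed = seed_stream(seed, 22L))
  model <- train_embedder(ds, config)
  run_log(out_dir, sprintf("embedder: best val loss %.4f at epoch %d (%d epochs run)",
                           model$best_val_loss, model$best_epoch, nrow(model$log)))
  utils::write.csv(model$log, file.path(out_dir, "training_log.csv"),
                   row.names = FALSE)
  emb <- embed_images(model, ds)
  utils::write.csv(as.data.frame(emb), file.path(out_dir, "embeddings.csv"),
                   row.names = FALSE)
  artifacts <- c("training_log.csv", "embeddings.csv")

  classes <- vapply(specs, `[[`, "", "name")
  fps <- list(); modes <- list()
  for (cl in classes) {
    fp <- fit_fingerprint(emb, subset = cl, label = cl)
    fps[[cl]] <- fp
    write_fingerprint(fp, file.path(out_dir, paste0("fingerprint_", cl, ".json")))
    md <- global_mode(fp)
    modes[[cl]] <- md
    hl <- hdr_levels(fp, masses)
    utils::write.csv(hl, file.path(out_dir, paste0("hdr_levels_", cl, ".csv")),
                     row.names = FALSE)
    keep <- which(emb$labels == cl)
    nn <- nearest_to_point(emb$points[keep, , drop = FALSE], md$point,
                           k = min(k_nearest, length(keep)))
    gal <- data.frame(rank = seq_along(nn), image_id = emb$ids[keep][nn],
                      x = emb$points[keep, 1][nn], y = emb$points[keep, 2][nn])
    utils::write.csv(gal, file.path(out_dir, paste0("mode_gallery_", cl, ".csv")),
                     row.names = FALSE)
    artifacts <- c(artifacts, paste0("fingerprint_", cl, ".json"),
                   paste0("hdr_levels_", cl, ".csv"),
                   paste0("mode_gallery_", cl, ".csv"))
    run_log(out_dir, sprintf("class '%s': mode (%.3f, %.3f), density %.4f",
                             cl, md$point[1], md$point[2], md$value))
  }

  gofm <- matrix(NA_real_, length(classes), length(classes),
                 dimnames = list(test = classes, null = classes))
  for (te in classes) {
    pts <- emb$points[emb$labels == te, , drop = FALSE]
    if (nrow(pts) < N_test) next
    for (nu in classes) {
      res <- subset_rejection_rate(fps[[nu]], pts, N_test = N_test,
                                   alpha = alpha,
                                   seed = seed_stream(seed, 40L + match(te, classes) * 8L + match(nu, classes)))
      gofm[te, nu] <- res$rejection_fraction
    }
  }
  utils::write.csv(data.frame(test = rownames(gofm), gofm, check.names = FALSE),
                   file.path(out_dir, "gof_rejection_matrix.csv"),
                   row.names = FALSE)
  artifacts <- c(artifacts, "gof_rejection_matrix.csv")
  finish_run_dir(out_dir, artifacts)
  list(model = model, embedding = emb, fingerprints = fps, modes = modes,
       gof_matrix = gofm)
}

#' Temporal fingerprint study
#'
#' One population sampled at several time points: the embedding network is
#' trained only on the in-training time points; held-out time points are
#' embedded with the frozen network. Fingerprints are fitted for all time
#' points and every held-out time point is GOF-tested against every training
#' time point's fingerprint, so morphological drift shows up as a rejection
#' profile.
#'
#' @param timepoint_specs Named list of `class_spec`, one per time point
#'   (names are the time point labels, in order).
#' @param holdout Names (or indices) of held-out time points.
#' @param n_per_timepoint Images per time point.
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param config A `train_config`.
#' @param N_test GOF subset size; `alpha` significance level.
#' @param alpha GOF significance level (default 0.05).
#' @return List with `model`, `embeddings`, `fingerprints`, `gof` (data.frame
#'   of held-out vs training rejection fractions).
#' @export
run_temporal_study <- function(timepoint_specs, holdout,
                               n_per_timepoint = 500L, out_dir, seed = 1L,
                               config = NULL, N_test = 100L, alpha = 0.05) {
  tp_names <- names(timepoint_specs)
  if (is.null(tp_names)) stop("run_temporal_study: timepoint_specs must be named")
  if (is.numeric(holdout)) holdout <- tp_names[holdout]
  train_tp <- setdiff(tp_names, holdout)
  if (length(train_tp) < 2)
    stop("run_temporal_study: need >= 2 in-training time points")
  config <- config %||% train_config(seed = seed_stream(seed, 31L))
  init_run_dir(out_dir, "temporal", seed, config,
               list(timepoints = tp_names, holdout = holdout,
                    n_per_timepoint = n_per_timepoint,
                    N_test = N_test, alpha = alpha))

  # time point label becomes the class label
  specs <- lapply(tp_names, function(tp) {
    s <- timepoint_specs[[tp]]; s$name <- tp; s
  })
  names(specs) <- tp_names
  ds_train <- generate_dataset(specs[train_tp], n_per_timepoint,
                               c(0.8, 0.2, 0), seed = seed_stream(seed, 32L))
  model <- train_embedder(ds_train, config)
  utils::write.csv(model$log, file.path(out_dir, "training_log.csv"),
                   row.names = FALSE)
  artifacts <- c("training_log.csv")

  ds_hold <- if (length(holdout) > 0)
    generate_dataset(specs[holdout], n_per_timepoint, c(0, 0, 1),
                     seed = seed_stream(seed, 33L)) else NULL
  emb_train <- embed_images(model, ds_train)
  emb_hold <- if (!is.null(ds_hold)) embed_images(model, ds_hold) else NULL

  fps <- list()
  for (tp in tp_names) {
    emb <- if (tp %in% train_tp) emb_train else emb_hold
    fp <- fit_fingerprint(emb, subset = tp, label = tp)
    fps[[tp]] <- fp
    write_fingerprint(fp, file.path(out_dir, paste0("fingerprint_", tp, ".json")))
    artifacts <- c(artifacts, paste0("fingerprint_", tp, ".json"))
  }

  gof <- expand.grid(holdout = holdout, training = train_tp,
                     stringsAsFactors = FALSE)
  gof$rejection_fraction <- NA_real_
  for (r in seq_len(nrow(gof))) {
    pts <- emb_hold$points[emb_hold$labels == gof$holdout[r], , drop = FALSE]
    res <- subset_rejection_rate(fps[[gof$training[r]]], pts, N_test = N_test,
                                 alpha = alpha, seed = seed_stream(seed, 50L + r))
    gof$rejection_fraction[r] <- res$rejection_fraction
    run_log(out_dir, sprintf("held-out '%s' vs training '%s': %.1f%% rejected",
                             gof$holdout[r], gof$training[r],
                             100 * res$rejection_fraction))
  }
  utils::write.csv(gof, file.path(out_dir, "gof_holdout_vs_training.csv"),
                   row.names = FALSE)
  artifacts <- c(artifacts, "gof_holdout_vs_training.csv")
  finish_run_dir(out_dir, artifacts)
  list(model = model,
       embeddings = list(training = emb_train, holdout = emb_hold),
       fingerprints = fps, gof = gof)
}

#' Contour plot of a fingerprint
#'
#' Draws the KDE on a grid with HDR contour levels (labelled by probability
#' mass) and marks the global mode.
#'
#' @param fp A `fingerprint`.
#' @param masses HDR masses to draw.
#' @param file Optional PNG path; default plots to the active device.
#' @param grid_n Grid resolution per axis.
#' @return The HDR levels, invisibly.
#' @export
plot_fingerprint <- function(fp, masses = c(0.2, 0.4, 0.6, 0.8), file = NULL,
                             grid_n = 121L) {
  pad <- 3 * sqrt(max(diag(fp$H)))
  xr <- range(fp$points[, 1]) + c(-pad, pad)
  yr <- range(fp$points[, 2]) + c(-pad, pad)
  gx <- seq(xr[1], xr[2], length.out = grid_n)
  gy <- seq(yr[1], yr[2], length.out = grid_n)
  grid <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
  fz <- matrix(kde_pdf(fp, grid), grid_n, grid_n)
  hl <- hdr_levels(fp, masses)
  md <- global_mode(fp)
  if (!is.null(file)) grDevices::png(file, width = 700, height = 700)
  graphics::plot(fp$points, pch = 16, cex = 0.3, col = "grey60",
                 xlab = "embedding x", ylab = "embedding y",
                 main = paste("fingerprint:", fp$label))
  graphics::contour(gx, gy, fz, levels = hl$level,
                    labels = paste0(100 * hl$mass, "%"), add = TRUE,
                    col = "steelblue")
  graphics::points(md$point[1], md$point[2], pch = 4, cex = 1.5, lwd = 2,
                   col = "firebrick")
  if (!is.null(file)) grDevices::dev.off()
  invisible(hl)
}
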