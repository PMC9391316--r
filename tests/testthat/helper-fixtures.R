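# Shared fixtures, built lazily and cached for the whole test run so the
# heavier trainings happen at most once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# brute-force batch-all non-zero triplet oracle: plain triple loop
brute_triplet <- function(E, labels, margin) {
  terms <- c()
  B <- nrow(E)
  for (a in seq_len(B)) for (p in seq_len(B)) for (n in seq_len(B)) {
    if (a != p && labels[a] == labels[p] && labels[a] != labels[n]) {
      t <- sum((E[a, ] - E[p, ])^2) - sum((E[a, ] - E[n, ])^2) + margin
      if (t > 0) terms <- c(terms, t)
    }
  }
  if (length(terms) == 0) 0 else mean(terms)
}

# a clean disc spec with all stochastic terms disabled
disc_spec <- function(r = 10) {
  class_spec("disc", mean_radius_px = r, radius_cv = 0, boundary_roughness = 0,
             boundary_harmonics = 1, interior_level = 0.3, edge_level = 0.3,
             edge_width_px = 0, texture_sd = 0, background_level = 0.9,
             noise_sd = 0)
}

# small two-class dataset for quick training contracts
tiny_twoclass <- function() fixture("tiny_twoclass", function() {
  generate_dataset(example_class_specs(2), 60, c(0.8, 0, 0.2), seed = 101)
})

# the four-class / 500-per-class study of the class-recovery check
fourclass_study <- function() fixture("fourclass_study", function() {
  ds <- generate_dataset(example_class_specs(4), 500, c(0.8, 0, 0.2), seed = 401)
  model <- train_classifier(ds, train_config(seed = 402))
  list(dataset = ds, model = model, confusion = evaluate_classifier(model, ds))
})

# the six-class chance-level study
sixclass_study <- function() fixture("sixclass_study", function() {
  ds <- generate_dataset(example_class_specs(6), 300, c(0.8, 0, 0.2), seed = 601)
  model <- train_classifier(ds, train_config(seed = 602))
  list(dataset = ds, model = model, confusion = evaluate_classifier(model, ds))
})

# subtle brightness-only pair at its study size
subtle_study <- function() fixture("subtle_study", function() {
  ds <- generate_dataset(subtle_pair_specs(), 2000, c(0.8, 0, 0.2), seed = 501)
  model <- train_classifier(ds, train_config(seed = 502))
  list(dataset = ds, model = model, confusion = evaluate_classifier(model, ds))
})

# a three-class embedder shared by the embedding-quality and GOF controls
threeclass_embedder <- function() fixture("threeclass_embedder", function() {
  specs <- example_class_specs(3)
  ds <- generate_dataset(specs, 400, c(0.8, 0.2, 0), seed = 301)
  model <- train_embedder(ds, train_config(seed = 302, max_epochs = 60))
  list(specs = specs, dataset = ds, model = model)
})

# a synthetic "embedding-like" null fingerprint (two-cluster scatter)
null_fingerprint <- function(n_support = 1500, seed = 901) {
  fixture(paste0("nullfp_", n_support, "_", seed), function() {
    pts <- with_seed(seed, rbind(
      matrix(stats::rnorm(n_support, 0, 0.6), ncol = 2),
      matrix(stats::rnorm(n_support, 3, 0.8), ncol = 2)))
    fit_fingerprint(pts, label = "null")
  })
}

with_seed <- particleprint:::with_seed
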