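# Trained-detective fixtures are expensive, so each scale/kind is trained at
# most once per test session and cached.

.study_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .study_cache)) {
    assign(key, force(expr), envir = .study_cache)
  }
  get(key, envir = .study_cache)
}

# Small certification study used by unit tests: 32 px phantoms, one member,
# three epochs. Large enough that the attribute is learnable and the exam
# cohort (150 per class) pins the chance-level exam well inside its band.
micro_study <- function(kind) {
  cached(paste0("micro-", kind), {
    phantom_certification_study(
      kind, seed = 11, n_pool = 160, n_per_class = 150, side = 32,
      config = detective_config(ensemble_size = 1, epochs = 3),
      n_boot = 200)
  })
}

# Working-scale study: the package's reference conditions (1200-phantom
# pool at 64 px, 3-member small-cnn ensemble, 5 epochs, 300+300 exam
# cohort, 2000 bootstrap replicates).
desk_study <- function(kind) {
  cached(paste0("desk-", kind), {
    phantom_certification_study(
      kind, seed = 1, n_pool = 1200, n_per_class = 300, side = 64,
      config = detective_config(ensemble_size = 3, epochs = 5),
      n_boot = 2000)
  })
}
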