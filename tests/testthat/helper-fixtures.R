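# Shared fixtures: small study configurations and memoised heavy computations
# reused across test files.

linear_svm <- function(cost = 10) {
  make_learner("svm", grid = data.frame(kernel = "linear", cost = cost,
                                        gamma = NA))
}

tiny_study <- function(seed = 11, treatments = NULL, n_herb = 4, n_ctrl = 4,
                       days = 1, ...) {
  tr <- if (is.null(treatments)) default_treatments() else treatments
  study_config(treatments = tr, samples_per_herbicide = n_herb,
               control_samples = n_ctrl, rounds = 1, days = days,
               outlier_count = 0, seed = seed, ...)
}

random_cube <- function(rows, cols, bands, seed = 1, wl = NULL) {
  set.seed(seed)
  if (is.null(wl)) wl <- seq(680, by = 1.2, length.out = bands)
  hyper_cube(array(runif(rows * cols * bands), c(rows, cols, bands)), wl,
             kind = "reflectance")
}

# The default-scale study (criterion conditions: 16/herbicide + 32 controls
# per round, 2 rounds) is expensive; compute its LOO reports once.
.acceptance_cache <- new.env(parent = emptyenv())

default_study_day12 <- function() {
  if (is.null(.acceptance_cache$tab)) {
    cfg <- study_config(seed = 1, days = 1:2)
    .acceptance_cache$tab <- exclude_outliers(generate_study(cfg),
                                              quiet = TRUE)
  }
  .acceptance_cache$tab
}

default_loo <- function(family = c("svm", "plsda")) {
  family <- match.arg(family)
  key <- paste0("loo_", family)
  if (is.null(.acceptance_cache[[key]])) {
    learner <- if (family == "svm") linear_svm(10)
               else make_learner("plsda", lv = 2)
    .acceptance_cache[[key]] <-
      loo_experiment(default_study_day12(), dat = 1, learner = learner)
  }
  .acceptance_cache[[key]]
}
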