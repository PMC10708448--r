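test_that("NDVI closed forms and healthy-leaf positivity", {
  wl <- seq(460, 975, 5)
  x <- rep(0.5, length(wl))
  expect_equal(ndvi(x, wl), 0)
  x[which.min(abs(wl - 800))] <- 0.5
  x[which.min(abs(wl - 670))] <- 0.1
  expect_equal(ndvi(x, wl), 0.666667, tolerance = 1e-6)
  zero <- rep(0, length(wl))
  expect_error(ndvi(zero, wl), "zero")
  # generator guarantees NIR > red for a healthy leaf
  em <- leaf_endmember(default_grid())
  expect_gt(ndvi(em, default_grid()), 0)
})

test_that("pairwise Welch t-tests are symmetric with closed-form extremes", {
  # identical groups: no mean difference, p = 1
  v <- c(1, 2, 3, 4)
  p1 <- pairwise_ttest(c(v, v), rep(c("UTC", "Atrazine"), each = 4))
  expect_equal(p1$p["UTC", "Atrazine"], 1)
  # near-separated groups: verify against the textbook Welch formula
  set.seed(9)
  a <- rnorm(6, 0, 1e-3); b <- 1 + rnorm(6, 0, 1e-3)
  p2 <- pairwise_ttest(c(a, b), rep(c("UTC", "Atrazine"), each = 6))
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 6 + var(b) / 6)
  df <- (var(a) / 6 + var(b) / 6)^2 /
    ((var(a) / 6)^2 / 5 + (var(b) / 6)^2 / 5)
  p_oracle <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(p2$p["UTC", "Atrazine"], p_oracle, tolerance = 1e-10)
  expect_lt(p2$p["UTC", "Atrazine"], 1e-4)
  # K classes: symmetric matrix, NA diagonal, K(K-1)/2 distinct cells
  set.seed(10)
  vals <- rnorm(20)
  cls <- rep(c("UTC", "Atrazine", "Dinoseb", "Paraquat"), each = 5)
  pm <- pairwise_ttest(vals, cls)
  expect_true(all(is.na(diag(pm$p))))
  expect_equal(pm$p, t(pm$p))
  expect_equal(sum(!is.na(pm$p[upper.tri(pm$p)])), 6)
  # class with < 2 samples is left undefined with a warning
  expect_warning(
    pm2 <- pairwise_ttest(c(vals, 1), c(cls, "Glyphosate")),
    "fewer than 2|< 2 samples")
  expect_true(all(is.na(pm2$p["Glyphosate", ])))
})

test_that("null p-values are approximately uniform", {
  set.seed(42)
  pv <- replicate(400, {
    pairwise_ttest(rnorm(32), rep(c("UTC", "Atrazine"), each = 16))$p[1, 2]
  })
  ks <- max(abs(sort(pv) - (seq_along(pv) - 0.5) / length(pv)))
  expect_lt(ks, 0.07)
})

test_that("band importance recovers an injected band and normalizes", {
  mk_tab <- function(seed, amp = 0.2) {
    tr <- list(
      UTC = treatment_spec("UTC", "Control", "Untreated"),
      Atrazine = treatment_spec(
        "Atrazine", "Photosynthesis inhibition", "PS II inhibition",
        effect_bands = data.frame(center_nm = 700, width_nm = 2.5,
                                  amplitude = amp, onset_day = 0,
                                  drift_nm_per_day = 0)))
    generate_study(study_config(treatments = tr, samples_per_herbicide = 20,
                                control_samples = 20, rounds = 1, days = 1,
                                outlier_count = 0, day_curve_amplitude = 0,
                                seed = seed))
  }
  hits <- 0
  for (s in 1:5) {
    bi <- band_importance(mk_tab(300 + s), c("UTC", "Atrazine"), mode = "pair")
    expect_equal(sum(bi$importance), 1, tolerance = 1e-12)
    expect_true(all(bi$importance >= 0))
    if (abs(bi$top_band_nm - 700) <= 5) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # pure-noise labels: no band importance far above the uniform level
  # (checked on a coarse grid where the forest visits every band often)
  tr0 <- list(
    UTC = treatment_spec("UTC", "Control", "Untreated"),
    Atrazine = treatment_spec("Atrazine", "Photosynthesis inhibition",
                              "PS II inhibition"))
  for (s in 1:3) {
    tab <- generate_study(study_config(
      treatments = tr0, samples_per_herbicide = 20, control_samples = 20,
      rounds = 1, days = 1, outlier_count = 0, day_curve_amplitude = 0,
      wavelengths = seq(460, 975, 25), crop = NULL, seed = 900 + s))
    set.seed(s)
    tab$meta$treatment <- sample(tab$meta$treatment)
    bi0 <- band_importance(tab, c("UTC", "Atrazine"), mode = "pair", seed = s)
    expect_lt(max(bi0$importance), 3 / ncol(tab$X))
  }
  tab <- mk_tab(999)
  # determinism via the fixed forest seed
  bi1 <- band_importance(mk_tab(301), c("UTC", "Atrazine"), mode = "pair")
  bi2 <- band_importance(mk_tab(301), c("UTC", "Atrazine"), mode = "pair")
  expect_identical(bi1$importance, bi2$importance)
  expect_error(band_importance(st_filter(tab, treatments = "UTC"),
                               c("UTC", "Atrazine"), mode = "pair"))
})

test_that("importance recovery power grows with injected amplitude", {
  top_dist <- function(amp) {
    tr <- list(
      UTC = treatment_spec("UTC", "Control", "Untreated"),
      Atrazine = treatment_spec(
        "Atrazine", "Photosynthesis inhibition", "PS II inhibition",
        effect_bands = data.frame(center_nm = 700, width_nm = 2.5,
                                  amplitude = amp, onset_day = 0,
                                  drift_nm_per_day = 0)))
    tab <- generate_study(study_config(
      treatments = tr, samples_per_herbicide = 12, control_samples = 12,
      rounds = 1, days = 1, outlier_count = 0, day_curve_amplitude = 0,
      seed = 50))
    mean(sapply(1:5, function(s) {
      bi <- band_importance(tab, c("UTC", "Atrazine"), mode = "pair",
                            seed = s)
      abs(bi$top_band_nm - 700) <= 5
    }))
  }
  rates <- c(top_dist(0.005), top_dist(0.05), top_dist(0.3))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[3], 1)
})

test_that("top-band heatmap is symmetric with undefined self-pairs", {
  tab <- generate_study(tiny_study(
    seed = 8, treatments = default_treatments()[c("UTC", "Atrazine",
                                                  "Paraquat")],
    n_herb = 8, n_ctrl = 8))
  M <- importance_heatmap(tab)
  expect_true(all(is.na(diag(M))))
  expect_equal(M, t(M))
  expect_true(all(M[upper.tri(M)] %in% tab$wavelengths))
  f <- tempfile(fileext = ".png")
  plot_matrix_heatmap(M, f, main = "top bands")
  expect_true(file.exists(f) && file.info(f)$size > 0)
})
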