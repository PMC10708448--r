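test_that("PLS reproduces exact and full-rank least-squares fits", {
  # response perfectly collinear with one column: 1 LV fits exactly
  set.seed(1)
  y <- rep(c(0, 1), each = 5)
  X <- cbind(y, matrix(0, 10, 3))
  m1 <- pls_fit(X, y, 1)
  expect_equal(pls_predict(m1, X), y, tolerance = 1e-8)
  # at full rank, PLS predictions equal the normal-equations oracle
  X2 <- matrix(rnorm(20 * 3), 20, 3)
  y2 <- rnorm(20)
  m3 <- pls_fit(X2, y2, 3)
  ols <- lm(y2 ~ X2)
  expect_equal(pls_predict(m3, X2), unname(fitted(ols)), tolerance = 1e-8)
  Xnew <- matrix(rnorm(15), 5, 3)
  expect_equal(pls_predict(m3, Xnew),
               unname(cbind(1, Xnew) %*% coef(ols))[, 1], tolerance = 1e-8)
  expect_error(pls_fit(X2, y2, 4), "rank")
  # permuting sample order leaves the model unchanged
  set.seed(2)
  perm <- sample(20)
  m3p <- pls_fit(X2[perm, ], y2[perm], 3)
  expect_equal(pls_predict(m3p, Xnew), pls_predict(m3, Xnew),
               tolerance = 1e-8)
})

test_that("RMSEcv selection matches a brute-force LOO loop and prefers parsimony", {
  set.seed(3)
  n <- 12; p <- 6
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + 2 * y
  sel <- select_plsda(X, y, lv_grid = 1:3)
  rms <- attr(sel, "rmsecv")
  # explicit refit-per-fold oracle
  for (a in 1:3) {
    pred <- sapply(seq_len(n), function(i) {
      pls_predict(pls_fit(X[-i, ], y[-i], a), X[i, , drop = FALSE])
    })
    expect_equal(unname(rms[a]), sqrt(mean((pred - y)^2)), tolerance = 1e-10)
  }
  expect_equal(sel$n_lv, as.integer(names(which.min(rms))))
  # n = 3 boundary still runs
  sel3 <- select_plsda(matrix(rnorm(6), 3, 2), c(0, 1, 1))
  expect_s3_class(sel3, "binary_plsda")
})

test_that("one informative latent direction selects a single LV", {
  win1 <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 60; p <- 15
    y <- rep(c(0, 1), each = n / 2)
    t_ <- 2 * y + rnorm(n)
    X <- outer(t_, rnorm(p)) + matrix(rnorm(n * p, sd = 0.02), n, p)
    win1 <- win1 + (select_plsda(X, y)$n_lv == 1)
  }
  expect_gte(win1, 18)  # >= 90% of 20 seeds
})

test_that("SVM grid search finds a perfect model on wide-margin data", {
  g <- svm_grid()
  expect_equal(nrow(g), 42)       # 6 linear + 6 x 6 rbf candidates
  expect_equal(sum(g$kernel == "linear"), 6)
  expect_equal(range(g$cost), c(1e-3, 100))
  expect_equal(range(g$gamma, na.rm = TRUE), c(1e-6, 1e-1))
  set.seed(7)
  n <- 16
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 4, sd = 0.3), n, 4)
  X[, 1] <- X[, 1] + 6 * y
  m <- select_svm(X, y, g)
  # LOO accuracy of the selected hyperparameters
  acc <- mean(sapply(seq_len(n), function(i) {
    mi <- hsisoa:::svm_fit_binary(X[-i, ], y[-i], m$kernel, m$cost, m$gamma)
    (hsisoa:::svm_prob(mi, X[i, , drop = FALSE]) > 0.5) == y[i]
  }))
  expect_equal(acc, 1)
  # determinism of the selection
  m2 <- select_svm(X, y, g)
  expect_equal(m$kernel, m2$kernel)
  expect_equal(m$cost, m2$cost)
  expect_error(select_svm(X, rep(1, n)), "single-class")
})

test_that("calibrated SVM probabilities are monotone in the decision value", {
  set.seed(8)
  n <- 20
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3)
  X[, 1] <- X[, 1] + 1.5 * y
  m <- hsisoa:::svm_fit_binary(X, y, "linear", 1)
  grid <- matrix(rnorm(200 * 3), 200, 3)
  d <- m$sign * as.numeric(attr(
    predict(m$fit, grid, decision.values = TRUE), "decision.values"))
  p <- hsisoa:::svm_prob(m, grid)
  o <- order(d)
  expect_true(all(diff(p[o]) >= -1e-12))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("PLS-DA probabilities are the clipped continuous predictions", {
  m <- structure(list(coef = c(1, 0), xbar = c(0, 0), ybar = 0, n_lv = 1),
                 class = "binary_plsda")
  expect_equal(binary_probability(m, matrix(c(1.4, 0), 1)), 1)
  expect_equal(binary_probability(m, matrix(c(0.5, 0), 1)), 0.5)
  expect_equal(binary_probability(m, matrix(c(-2, 0), 1)), 0)
})

test_that("soft voting averages the K-1 relevant models with canonical ties", {
  pp <- data.frame(class_a = c("A", "A", "B"), class_b = c("B", "C", "C"),
                   p_a = c(0.9, 0.8, 0.6))
  sv <- soft_vote(pp, c("A", "B", "C"))
  expect_equal(unname(sv$avg_prob), c(0.85, 0.35, 0.30))
  expect_equal(sv$class, "A")
  # all-tied probabilities resolve to the earliest class in canonical order
  tied <- data.frame(class_a = c("A", "A", "B"), class_b = c("B", "C", "C"),
                     p_a = c(0.5, 0.5, 0.5))
  expect_equal(soft_vote(tied, c("B", "A", "C"))$class, "B")
  # K = 2: single binary model decides
  two <- data.frame(class_a = "A", class_b = "B", p_a = 0.7)
  expect_equal(soft_vote(two, c("A", "B"))$class, "A")
  expect_equal(soft_vote(data.frame(class_a = "A", class_b = "B", p_a = 0.3),
                         c("A", "B"))$class, "B")
})

test_that("OVO training builds one model per unordered pair", {
  tab <- generate_study(tiny_study(seed = 13, n_herb = 3, n_ctrl = 3))
  fit <- ovo_train(tab, linear_svm())
  expect_equal(length(fit$models), 9 * 8 / 2)
  expect_equal(fit$classes, canonical_classes())
  # every class appears in K-1 models
  cls <- c(vapply(fit$models, `[[`, character(1), "class_a"),
           vapply(fit$models, `[[`, character(1), "class_b"))
  expect_true(all(table(cls) == 8))
  # two classes: ensemble is a single binary model
  two <- st_filter(tab, treatments = c("UTC", "Atrazine"))
  fit2 <- ovo_train(two, linear_svm())
  expect_length(fit2$models, 1)
  # restricting the class order to labels present changes nothing
  fit3 <- ovo_train(tab, linear_svm(),
                    classes = c(canonical_classes(), "Absent"))
  expect_equal(fit3$classes, fit$classes)
  bad <- st_filter(tab, rows = which(tab$meta$treatment != "UTC" |
                                       seq_len(nrow(tab$X)) == 1))
  expect_error(ovo_train(bad, linear_svm()), "UTC")
})

test_that("ensemble predictions behave on training data", {
  tab <- generate_study(tiny_study(seed = 14, n_herb = 4, n_ctrl = 4))
  fit <- ovo_train(tab, linear_svm())
  p <- predict(fit, tab)
  expect_equal(mean(p$class == tab$meta$treatment), 1)  # wide-margin classes
  expect_true(all(p$prob >= 0 & p$prob <= 1))
  # pair symmetry: P(i beats j) + P(j beats i) = 1 by the probability model
  expect_true(all(abs(p$pair_probs) <= 1))
  # duplicated row gives an identical prediction
  dup <- predict(fit, tab$X[c(1, 1), , drop = FALSE])
  expect_equal(dup$class[1], dup$class[2])
  expect_equal(dup$prob[1, ], dup$prob[2, ])
})
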