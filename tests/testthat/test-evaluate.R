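test_that("confusion reports implement the accuracy/error arithmetic", {
  cls <- canonical_classes()
  perfect <- rep(cls, each = 4)
  r <- confusion(perfect, perfect, cls)
  expect_true(all(r$counts == diag(4, 9) * diag(9) | r$counts == 0))
  expect_equal(sum(diag(r$counts)), 36)
  expect_equal(r$overall_accuracy, 1)
  expect_equal(r$error_rate, 0)
  expect_equal(unname(r$per_class_accuracy), rep(1, 9))
  # all wrong
  wrong <- rep(c(cls[-1], cls[1]), each = 4)
  r0 <- confusion(perfect, wrong, cls)
  expect_equal(r0$overall_accuracy, 0)
  # 3 of 4 correct
  r34 <- confusion(c("UTC", "UTC", "UTC", "UTC"),
                   c("UTC", "UTC", "UTC", "Atrazine"), cls[1:2])
  expect_equal(r34$overall_accuracy, 0.75)
  expect_equal(r34$error_rate, 0.25)
  # row sums are per-class test counts; OA + error = 1
  expect_equal(unname(rowSums(r0$counts)), rep(4, 9))
  expect_equal(r0$overall_accuracy + r0$error_rate, 1)
  expect_error(confusion("UTC", "NotAClass", cls), "outside the class order")
})

test_that("moving an error onto the diagonal strictly raises OA", {
  set.seed(1)
  cls <- c("UTC", "Atrazine", "Dinoseb")
  true <- sample(cls, 30, TRUE)
  pred <- true
  wrong_at <- c(3, 11, 20)
  pred[wrong_at] <- vapply(true[wrong_at],
                           function(t) setdiff(cls, t)[1], character(1))
  r1 <- confusion(true, pred, cls)
  pred2 <- pred
  pred2[wrong_at[1]] <- true[wrong_at[1]]
  r2 <- confusion(true, pred2, cls)
  expect_gt(r2$overall_accuracy, r1$overall_accuracy)
  expect_lte(sum(diag(r1$counts)), r1$n)
})

test_that("LOO runs one fold per row and is row-order invariant", {
  tab <- generate_study(tiny_study(
    seed = 17, treatments = default_treatments()[c("UTC", "Atrazine",
                                                   "Paraquat")],
    n_herb = 4, n_ctrl = 4))
  r <- loo_experiment(tab, learner = make_learner("plsda", lv = 2))
  expect_equal(r$n, nrow(tab$X))               # fold count = row count
  expect_gte(r$overall_accuracy, 0.9)          # wide-margin classes
  # permuting rows changes nothing in the aggregated report
  set.seed(3)
  perm <- sample(nrow(tab$X))
  tab2 <- spectra_table(tab$X[perm, ], tab$wavelengths, tab$meta[perm, ])
  r2 <- loo_experiment(tab2, learner = make_learner("plsda", lv = 2))
  expect_equal(r2$counts, r$counts)
  # samples whose class cannot be trained in a fold are skipped with warning
  duo <- st_filter(tab, rows = c(which(tab$meta$treatment != "Paraquat"),
                                 which(tab$meta$treatment == "Paraquat")[1:2]))
  w <- capture_warnings(
    r3 <- loo_experiment(duo, learner = make_learner("plsda", lv = 2)))
  expect_match(w, "fewer than 2", all = TRUE)
  expect_length(w, 2)
  expect_equal(r3$n, nrow(duo$X) - 2)
})

test_that("day-to-day validation enforces its protocol", {
  tab <- generate_study(tiny_study(
    seed = 18, treatments = default_treatments()[c("UTC", "Atrazine",
                                                   "Glufosinate")],
    n_herb = 5, n_ctrl = 5, days = c(1, 2)))
  lr <- make_learner("plsda", lv = 2)
  r <- day_to_day(tab, 1, 2, learner = lr)
  expect_equal(r$n, sum(tab$meta$dat == 2))
  expect_equal(r$descriptor$cv, "day-to-day")
  # same-day resubstitution must be requested explicitly, and is at least as
  # accurate as LOO on the same data (optimism)
  expect_error(day_to_day(tab, 1, 1, learner = lr), "protocol violation")
  resub <- day_to_day(tab, 1, 1, learner = lr, allow_overlap = TRUE)
  loo <- loo_experiment(tab, dat = 1, learner = lr)
  expect_gte(resub$overall_accuracy, loo$overall_accuracy)
  # disjoint or missing class sets raise errors
  d1 <- which(tab$meta$dat == 1 & tab$meta$treatment == "UTC")
  d2 <- which(tab$meta$dat == 2 & tab$meta$treatment != "UTC")
  expect_error(day_to_day(st_filter(tab, rows = c(d1, d2)), 1, 2,
                          learner = lr), "disjoint|absent")
  d2b <- which(tab$meta$dat == 2)
  expect_error(day_to_day(st_filter(tab, rows = c(d1, d2b)), 1, 2,
                          learner = lr), "absent")
})

test_that("outlier exclusion removes flagged plants on every day", {
  cfg <- tiny_study(seed = 19, n_herb = 4, n_ctrl = 4, days = 1:3)
  cfg$outlier_count <- 3; cfg$outlier_day <- 2
  tab <- generate_study(cfg)
  ids <- attr(tab, "outlier_ids")
  expect_length(ids, 3)
  kept <- exclude_outliers(tab, quiet = TRUE)
  n_day <- nrow(tab$X) / 3
  for (d in 1:3) {
    expect_equal(sum(kept$meta$dat == d), n_day - 3)
  }
  expect_false(any(kept$meta$sample_id %in% ids))
  # empty flag list is the identity
  none <- generate_study(tiny_study(seed = 20))
  expect_identical(exclude_outliers(none, quiet = TRUE)$X, none$X)
  # absent ids warn and change nothing
  expect_warning(same <- exclude_outliers(none, "R9_Nothing_01"),
                 "not present")
  expect_equal(same$X, none$X)
})

test_that("reports render to CSV/PNG and the CSV round-trips", {
  set.seed(4)
  cls <- canonical_classes()[1:4]
  true <- sample(cls, 40, TRUE)
  pred <- ifelse(runif(40) < 0.75, true, sample(cls, 40, TRUE))
  r <- confusion(true, pred, cls)
  prefix <- tempfile()
  files <- render_report(r, prefix)
  expect_true(all(file.exists(files)))
  back <- read_confusion_csv(files["csv"])
  expect_equal(back$counts, r$counts)
  expect_equal(back$overall_accuracy, r$overall_accuracy)
  expect_equal(back$per_class_accuracy, r$per_class_accuracy)
  # per-class accuracy + error sum to 1 where defined
  ok <- !is.na(r$per_class_accuracy)
  expect_equal(unname(r$per_class_accuracy[ok] + r$per_class_error[ok]),
               rep(1, sum(ok)))
})

test_that("end-to-end determinism: same seed, same confusion report", {
  lr <- make_learner("plsda", lv = 2)
  r1 <- loo_experiment(generate_study(tiny_study(seed = 23, n_herb = 3,
                                                 n_ctrl = 3)), learner = lr)
  r2 <- loo_experiment(generate_study(tiny_study(seed = 23, n_herb = 3,
                                                 n_ctrl = 3)), learner = lr)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$overall_accuracy, r2$overall_accuracy)
})
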