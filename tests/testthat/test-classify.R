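# Classifier battery, hold-out, leakage-free cross-validation.

test_that("the default battery is the full ten with stated estimator counts", {
  bat <- make_battery()
  expect_length(bat, 10)
  expect_named(bat, c("lr", "lda", "knn", "cart", "nb", "svm", "rf", "et",
                      "ab", "gbm"))
  expect_equal(bat$rf$n_estimators, 100)
  expect_equal(bat$et$n_estimators, 100)
  expect_equal(bat$ab$n_estimators, 50)
  expect_equal(bat$gbm$n_estimators, 100)
  expect_error(make_battery(c("rf", "mlp")), "roster")
  expect_length(make_battery(c("nb", "knn")), 2)
})

test_that("hold-out splits by participant within group", {
  fm <- toy_fm(n_per_group = 10)       # 20 participants, 40 rows
  hs <- holdout_split(fm, 0.2, seed = 4)
  inst <- fm$instances
  held <- unique(inst$participant[hs$holdout])
  expect_length(held, 4)               # 2 per group
  for (g in c("a", "b")) {
    expect_equal(sum(unique(inst$participant[inst$group == g]) %in% held),
                 2)
  }
  # both condition rows of each held-out participant travel together
  for (p in held) {
    expect_true(all(which(inst$participant == p) %in% hs$holdout))
  }
  expect_length(intersect(hs$train, hs$holdout), 0)
  # different seeds: different sets, same sizes
  hs2 <- holdout_split(fm, 0.2, seed = 5)
  expect_length(hs2$holdout, length(hs$holdout))
  expect_false(setequal(hs$holdout, hs2$holdout))
  # too-small group errors
  tiny <- toy_fm(n_per_group = 2)
  expect_error(holdout_split(tiny, 0.2), "hold-out")
})

test_that("cross-validation refuses scaled input and degenerate folds", {
  fm <- toy_fm(n_per_group = 8)
  expect_error(cross_validate(zscale(fm), task_spec("four_class")),
               "unscaled")
  expect_error(cross_validate(fm, task_spec("four_class"), folds = 20),
               "empty|absent")
})

test_that("fold-local scaling depends only on that fold's training rows", {
  fm <- toy_fm(n_per_group = 8, seed = 3)
  task <- task_spec("group_a_condition")
  rep_ <- cross_validate(fm, task, make_battery("nb"), folds = 4,
                         seed = 6, record_scaling = TRUE)
  fms <- feature_subset(fm, task$feature_subset)
  rows <- which(task$select(fms$instances))
  x <- fms$values[rows, , drop = FALSE]
  for (k in seq_along(rep_$fold_scaling)) {
    sc <- rep_$fold_scaling[[k]]
    tr <- setdiff(seq_len(nrow(x)), sc$test_rows)
    # instrumentation oracle: scaling equals moments of the training rows
    expect_equal(unname(sc$mean), unname(colMeans(x[tr, , drop = FALSE])),
                 tolerance = 1e-12)
    # and differs from the full-data moments (leakage would make them equal)
    expect_false(isTRUE(all.equal(unname(sc$mean),
                                  unname(colMeans(x)))))
  }
})

test_that("participants never straddle train/test in any fold", {
  fm <- toy_fm(n_per_group = 8, seed = 5)
  task <- task_spec("four_class")
  rep_ <- cross_validate(fm, task, make_battery("nb"), folds = 4,
                         seed = 8, record_scaling = TRUE)
  inst <- fm$instances
  for (k in seq_along(rep_$fold_scaling)) {
    te <- rep_$fold_scaling[[k]]$test_rows
    for (p in unique(inst$participant[te])) {
      expect_true(all(which(inst$participant == p) %in% te))
    }
  }
})

test_that("a strongly separated task is solved by nearly all algorithms", {
  fm <- toy_fm(n_per_group = 10, n_feat_bins = 6, seed = 7, effect = 0)
  # separate group-a conditions on a block of features, well above noise
  hit <- fm$instances$group == "a" & fm$instances$condition == "direct"
  fm$values[hit, 3:10] <- fm$values[hit, 3:10] + 4
  rep_ <- cross_validate(fm, task_spec("group_a_condition"),
                         make_battery(), folds = 5, seed = 9)
  expect_gte(sum(rep_$cv_mean >= 0.95), 9)
})

test_that("label permutation drives accuracy to chance", {
  fm <- toy_fm(n_per_group = 10, n_feat_bins = 4, seed = 8, effect = 3,
               effect_col = 2)
  # permute condition labels within participants: break the association
  inst <- fm$instances
  perm <- withr::with_seed(10, {
    for (p in unique(inst$participant)) {
      if (stats::runif(1) < 0.5) {
        r <- which(inst$participant == p)
        fm$values[r, ] <- fm$values[rev(r), ]
      }
    }
    fm
  })
  rep_ <- cross_validate(perm, task_spec("group_a_condition"),
                         make_battery(c("nb", "knn", "cart")), folds = 5,
                         seed = 11)
  accs <- as.vector(rep_$fold_acc)
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.05)
})

test_that("run_tasks slices feature subsets and instance sets correctly", {
  fm <- small_fm()                    # 12 instances x 64 features
  tasks <- list(task_spec("four_class", feature_subset = "time_only"),
                task_spec("direct_only_group"))
  res <- run_tasks(fm, tasks, make_battery(c("nb", "cart")), folds = 3,
                   seed = 12, holdout_fraction = NULL)
  expect_equal(nrow(res$summary), 4)
  r1 <- res$reports[["four_class:time_only"]]
  expect_equal(r1$n_instances, nrow(fm$values))
  # direct_only uses half the instances
  r2 <- res$reports[["direct_only_group:amplitude_and_time"]]
  expect_equal(r2$n_instances, nrow(fm$values) / 2)
  # reproducibility bit-for-bit
  res2 <- run_tasks(fm, tasks, make_battery(c("nb", "cart")), folds = 3,
                    seed = 12, holdout_fraction = NULL)
  expect_identical(res$summary, res2$summary)
  expect_error(run_tasks(fm, list()), "empty")
})

test_that("time-only subset of the full default grid has 248 columns", {
  fn <- feature_names(frequency_grid()$centers)
  expect_length(fn, 496)
  expect_length(grep("^time_", fn), 248)
})
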