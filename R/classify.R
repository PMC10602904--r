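# Brain-state classification battery.
#
# Ten classifiers: six base algorithms -- logistic regression (the "linear
# regression" slot of a classification battery), LDA, kNN, CART, naive
# Bayes, RBF-SVM -- and four ensembles with fixed estimator counts: random
# forest (100), extremely randomised trees (100), AdaBoost (50 stumps,
# SAMME), gradient boosting (100 rounds). The harness is leakage-free:
# z-scaling is fit inside each training fold, folds group by participant
# (both condition rows of a participant travel together) and stratify by the
# participant's group, and a per-group 20% participant hold-out is scored
# only by models refit on the full training set.

BATTERY_NAMES <- c("lr", "lda", "knn", "cart", "nb", "svm",
                   "rf", "et", "ab", "gbm")

#' Build the classifier battery
#'
#' @param algorithms subset of
#'   `c("lr","lda","knn","cart","nb","svm","rf","et","ab","gbm")`;
#'   default all ten.
#' @return named list of classifier specs (`label`, `n_estimators` where
#'   applicable, `fit(x, y, seed)` returning a model, `predict(model, x)`
#'   returning class labels).
#' @export
make_battery <- function(algorithms = NULL) {
  if (is.null(algorithms)) algorithms <- BATTERY_NAMES
  unknown <- setdiff(algorithms, BATTERY_NAMES)
  if (length(unknown)) {
    stopf("unknown algorithm '%s'; roster: %s", unknown[1],
          paste(BATTERY_NAMES, collapse = ", "))
  }
  specs <- list(
    lr = list(
      label = "Logistic Regression (LR)",
      fit = function(x, y, seed) {
        with_seed(seed, suppressWarnings(
          nnet::multinom(y ~ ., data = data.frame(x, y = y),
                         trace = FALSE, MaxNWts = 1e5, decay = 1e-3,
                         maxit = 200)))
      },
      predict = function(m, x) {
        as.character(stats::predict(m, newdata = data.frame(x)))
      }),
    lda = list(
      label = "Linear Discriminant Analysis (LDA)",
      fit = function(x, y, seed) {
        suppressWarnings(MASS::lda(x, grouping = y))
      },
      predict = function(m, x) {
        as.character(stats::predict(m, x)$class)
      }),
    knn = list(
      label = "k-Nearest Neighbors (kNN)", k = 5,
      fit = function(x, y, seed) {
        list(x = x, y = y, k = min(5, nrow(x)), seed = seed)
      },
      predict = function(m, x) {
        # vote ties in class::knn are broken through the RNG; pin it so
        # the harness stays bit-reproducible
        with_seed(m$seed, as.character(class::knn(m$x, x, m$y, k = m$k)))
      }),
    cart = list(
      label = "Classification and Regression Tree (CART)",
      fit = function(x, y, seed) {
        with_seed(seed, rpart::rpart(
          y ~ ., data = data.frame(x, y = y), method = "class",
          control = rpart::rpart.control(xval = 0, minsplit = 2,
                                         minbucket = 1, cp = 0.01)))
      },
      predict = function(m, x) {
        as.character(stats::predict(m, newdata = data.frame(x),
                                    type = "class"))
      }),
    nb = list(
      label = "Naive Bayes (NB)",
      fit = function(x, y, seed) e1071::naiveBayes(x, y),
      predict = function(m, x) as.character(stats::predict(m, x))),
    svm = list(
      label = "Support Vector Machine (SVM)",
      fit = function(x, y, seed) {
        e1071::svm(x, y, kernel = "radial", cost = 1, scale = FALSE)
      },
      predict = function(m, x) as.character(stats::predict(m, x))),
    rf = list(
      label = "Random Forest (RF)", n_estimators = 100,
      fit = function(x, y, seed) {
        with_seed(seed, randomForest::randomForest(x, y, ntree = 100))
      },
      predict = function(m, x) as.character(stats::predict(m, x))),
    et = list(
      label = "Extra Trees (ET)", n_estimators = 100,
      fit = function(x, y, seed) {
        d <- data.frame(x, .y = y)
        with_seed(seed,
          ranger::ranger(.y ~ ., data = d, num.trees = 100,
                         splitrule = "extratrees", num.random.splits = 1,
                         replace = FALSE, sample.fraction = 1,
                         num.threads = 1, seed = seed))
      },
      predict = function(m, x) {
        as.character(stats::predict(m, data = data.frame(x),
                                    num.threads = 1)$predictions)
      }),
    ab = list(
      label = "AdaBoost (AB)", n_estimators = 50,
      fit = function(x, y, seed) {
        with_seed(seed, adaboost_fit(x, y, n_estimators = 50))
      },
      predict = function(m, x) adaboost_predict(m, x)),
    gbm = list(
      label = "Gradient Boosting Machine (GBM)", n_estimators = 100,
      fit = function(x, y, seed) {
        xgboost::xgboost(as.matrix(x), y, nrounds = 100, max_depth = 3,
                         learning_rate = 0.1, nthreads = 1,
                         seed = seed %% 2147483647, verbosity = 0)
      },
      predict = function(m, x) {
        as.character(stats::predict(m, as.matrix(x), type = "class"))
      })
  )
  specs[algorithms]
}

# multi-class AdaBoost (SAMME) over depth-1 rpart stumps
adaboost_fit <- function(x, y, n_estimators = 50) {
  y <- factor(y)
  K <- nlevels(y)
  n <- length(y)
  w <- rep(1 / n, n)
  d <- data.frame(x, .y = y)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       xval = 0, cp = -1,
                                                       minsplit = 2))
    pred <- stats::predict(fit, d, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    stumps[[m]] <- fit
    alphas[m] <- alpha
    if (err < 1e-9) break
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

adaboost_predict <- function(model, x) {
  d <- data.frame(x)
  votes <- matrix(0, nrow = nrow(d), ncol = length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (m in seq_along(model$stumps)) {
    pred <- as.character(stats::predict(model$stumps[[m]], d,
                                        type = "class"))
    votes[cbind(seq_len(nrow(d)), match(pred, model$levels))] <-
      votes[cbind(seq_len(nrow(d)), match(pred, model$levels))] +
      model$alphas[m]
  }
  model$levels[max.col(votes, ties.method = "first")]
}

#' Classification task definitions
#'
#' The four standard tasks over a cohort feature matrix:
#' \describe{
#'   \item{group_a_condition}{group-a rows only; classify direct vs
#'     reversed (2 classes).}
#'   \item{group_b_condition}{group-b rows only; direct vs reversed.}
#'   \item{four_class}{all rows; class = group x condition (4 classes).}
#'   \item{direct_only_group}{direct-condition rows only; classify group
#'     membership (2 classes).}
#' }
#'
#' @param name task name.
#' @param feature_subset `"amplitude_and_time"` (default), `"time_only"`,
#'   or `"amplitude_only"`.
#' @return object of class `task_spec` with `name`, `feature_subset`,
#'   `select(instances)` (row filter) and `labels(instances)` (class
#'   labels).
#' @export
task_spec <- function(name = c("group_a_condition", "group_b_condition",
                               "four_class", "direct_only_group"),
                      feature_subset = "amplitude_and_time") {
  name <- match.arg(name)
  sel <- switch(name,
    group_a_condition = function(inst) inst$group == "a",
    group_b_condition = function(inst) inst$group == "b",
    four_class = function(inst) rep(TRUE, nrow(inst)),
    direct_only_group = function(inst) inst$condition == "direct")
  lab <- switch(name,
    group_a_condition = function(inst) inst$condition,
    group_b_condition = function(inst) inst$condition,
    four_class = function(inst) paste(inst$group, inst$condition, sep = "_"),
    direct_only_group = function(inst) inst$group)
  structure(list(name = name, feature_subset = feature_subset,
                 select = sel, labels = lab), class = "task_spec")
}

#' Participant-level hold-out split
#'
#' Retains `fraction` of each group's participants (both of their condition
#' rows) as a hold-out set; the split is by participant, never by row.
#'
#' @param fm a `feature_matrix`.
#' @param fraction hold-out fraction per group (default 0.2).
#' @param seed integer seed.
#' @return list with `train` and `holdout` row indices into `fm$values`.
#' @export
holdout_split <- function(fm, fraction = 0.2, seed = 1L) {
  inst <- fm$instances
  held <- character(0)
  for (g in unique(inst$group)) {
    ps <- unique(inst$participant[inst$group == g])
    n_hold <- round(length(ps) * fraction)
    if (n_hold < 1) {
      stopf("group '%s' too small for a %.0f%% participant hold-out",
            g, fraction * 100)
    }
    held <- c(held, with_seed(derive_seed(seed, paste("holdout", g)),
                              sample(ps, n_hold)))
  }
  hold_rows <- which(inst$participant %in% held)
  list(train = setdiff(seq_len(nrow(inst)), hold_rows),
       holdout = hold_rows)
}

# participant-grouped, group-stratified fold assignment
make_folds <- function(instances, folds, seed) {
  ps <- unique(instances$participant)
  pg <- instances$group[match(ps, instances$participant)]
  fold_of <- stats::setNames(integer(length(ps)), ps)
  with_seed(derive_seed(seed, "folds"), {
    for (g in unique(pg)) {
      members <- sample(ps[pg == g])
      fold_of[members] <- rep(seq_len(folds),
                              length.out = length(members))[
                                sample(length(members))]
    }
  })
  fold_of[instances$participant]
}

#' Cross-validate the battery on one task
#'
#' Stratified (by group) participant-grouped k-fold cross-validation with
#' fold-local z-scaling: for every fold the scaling statistics are fit on
#' that fold's training rows only and applied to its test rows, so no
#' information from test rows reaches any trained model.
#'
#' @param fm an unscaled `feature_matrix` (the harness scales internally).
#' @param task a [task_spec()].
#' @param battery from [make_battery()].
#' @param folds number of folds (default 10). If any fold's training split
#'   loses a class entirely, an error is raised rather than degrading
#'   silently.
#' @param seed integer seed.
#' @param holdout optional row indices (into `fm`) of a participant
#'   hold-out; they are excluded from every fold and scored once by models
#'   refit on all training rows.
#' @param record_scaling keep each fold's scaling statistics in the report
#'   (instrumentation for leakage checks).
#' @return object of class `classification_report`: `task`, `fold_acc`
#'   (algorithm x fold accuracy matrix), `cv_mean`, `cv_sd`,
#'   `holdout_acc` (or `NA`), `n_instances`, `classes`, `seed`, and
#'   optionally `fold_scaling`.
#' @export
cross_validate <- function(fm, task, battery = make_battery(), folds = 10,
                           seed = 1L, holdout = NULL,
                           record_scaling = FALSE) {
  if (!is.null(fm$scaling)) {
    stopf("pass an unscaled feature matrix; the harness scales per fold")
  }
  fms <- feature_subset(fm, task$feature_subset)
  rows <- which(task$select(fms$instances))
  if (!is.null(holdout)) rows <- setdiff(rows, holdout)
  inst <- fms$instances[rows, , drop = FALSE]
  x <- fms$values[rows, , drop = FALSE]
  y <- factor(task$labels(inst))
  if (nlevels(y) < 2) stopf("task '%s' has fewer than 2 classes", task$name)
  fold_id <- make_folds(inst, folds, seed)
  # pin the global RNG for the whole harness (restored on exit): some fit
  # routines consume the global stream beyond their own seed arguments, and
  # results must depend only on `seed`
  with_seed(derive_seed(seed, "harness"), {
  acc <- matrix(NA_real_, nrow = length(battery), ncol = folds,
                dimnames = list(names(battery), NULL))
  fold_scaling <- if (record_scaling) vector("list", folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k; te <- !tr
    if (!any(te)) stopf("fold %d is empty; too few participants", k)
    if (nlevels(droplevels(y[tr])) < nlevels(y)) {
      stopf("class absent from training split of fold %d; stratification failed", k)
    }
    mu <- colMeans(x[tr, , drop = FALSE])
    sd_ <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ < 1e-12] <- Inf
    sc <- list(mean = mu, sd = sd_)
    xtr <- apply_scaling(x[tr, , drop = FALSE], sc)
    xte <- apply_scaling(x[te, , drop = FALSE], sc)
    if (record_scaling) fold_scaling[[k]] <- c(sc, list(test_rows = which(te)))
    for (alg in names(battery)) {
      m <- battery[[alg]]$fit(xtr, y[tr],
                              derive_seed(seed, paste(task$name, alg, k)))
      pred <- battery[[alg]]$predict(m, xte)
      acc[alg, k] <- mean(pred == as.character(y[te]))
    }
  }
  holdout_acc <- rep(NA_real_, length(battery))
  names(holdout_acc) <- names(battery)
  if (!is.null(holdout) && length(holdout)) {
    hrows <- intersect(holdout, which(task$select(fms$instances)))
    if (length(hrows)) {
      yh <- factor(task$labels(fms$instances[hrows, , drop = FALSE]),
                   levels = levels(y))
      mu <- colMeans(x); sd_ <- apply(x, 2, stats::sd)
      sd_[sd_ < 1e-12] <- Inf
      sc <- list(mean = mu, sd = sd_)
      xtr <- apply_scaling(x, sc)
      xh <- apply_scaling(fms$values[hrows, , drop = FALSE], sc)
      for (alg in names(battery)) {
        m <- battery[[alg]]$fit(xtr, y,
                                derive_seed(seed, paste(task$name, alg,
                                                        "refit")))
        holdout_acc[alg] <- mean(battery[[alg]]$predict(m, xh) ==
                                   as.character(yh))
      }
    }
  }
  structure(list(task = task$name, feature_subset = task$feature_subset,
                 fold_acc = acc,
                 cv_mean = rowMeans(acc), cv_sd = apply(acc, 1, stats::sd),
                 holdout_acc = holdout_acc,
                 n_instances = length(rows), classes = levels(y),
                 seed = seed,
                 fold_scaling = if (record_scaling) fold_scaling),
            class = "classification_report")
  })
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> task %s (%s), %d instances, %d classes\n",
              x$task, x$feature_subset, x$n_instances, length(x$classes)))
  d <- data.frame(cv_mean = round(x$cv_mean, 3),
                  cv_sd = round(x$cv_sd, 3),
                  holdout = round(x$holdout_acc, 3))
  print(d)
  invisible(x)
}

#' Run several tasks over the battery
#'
#' One [cross_validate()] per task (with a shared participant hold-out), and
#' a long-format summary table of accuracies.
#'
#' @param fm an unscaled `feature_matrix`.
#' @param tasks list of [task_spec()] (default: all four standard tasks on
#'   amplitude+time features).
#' @param battery from [make_battery()].
#' @param folds folds per task.
#' @param seed integer seed.
#' @param holdout_fraction per-group participant hold-out fraction
#'   (default 0.2; `NULL` disables the hold-out).
#' @return list with `reports` (one `classification_report` per task) and
#'   `summary` (data.frame: task, feature_subset, algorithm, cv_mean,
#'   cv_sd, holdout_acc).
#' @export
run_tasks <- function(fm, tasks = NULL, battery = make_battery(),
                      folds = 10, seed = 1L, holdout_fraction = 0.2) {
  if (is.null(tasks)) {
    tasks <- lapply(c("group_a_condition", "group_b_condition",
                      "four_class", "direct_only_group"), task_spec)
  }
  if (length(tasks) == 0) stopf("empty task list")
  holdout <- if (!is.null(holdout_fraction)) {
    holdout_split(fm, holdout_fraction, seed)$holdout
  }
  reports <- lapply(tasks, function(tk) {
    cross_validate(fm, tk, battery, folds, seed, holdout = holdout)
  })
  names(reports) <- vapply(tasks, function(tk) {
    paste(tk$name, tk$feature_subset, sep = ":")
  }, character(1))
  summary <- do.call(rbind, lapply(reports, function(r) {
    data.frame(task = r$task, feature_subset = r$feature_subset,
               algorithm = names(r$cv_mean), cv_mean = unname(r$cv_mean),
               cv_sd = unname(r$cv_sd),
               holdout_acc = unname(r$holdout_acc),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(reports = reports, summary = summary)
}
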