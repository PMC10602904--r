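# Information-based univariate feature selection.
#
# Two scorers are provided. The supervised default ranks each feature by the
# mutual information between its equal-frequency discretisation and the
# class label. The unsupervised leave-one-out entropy scorer reproduces the
# dataset-entropy reading: a feature's relevance is the change in total
# dataset entropy when it is removed, with the total entropy of the
# discretised dataset estimated as the sum of marginal entropies minus the
# sum of pairwise mutual informations (a second-order, tree-free
# approximation of the joint entropy).

#' Equal-frequency discretisation
#'
#' Bins a numeric column into (at most) `n_bins` classes with approximately
#' equal occupancy. Invariant under strictly monotone transforms of the
#' column. Ties collapse bins rather than splitting identical values.
#'
#' @param x numeric vector.
#' @param n_bins target number of bins (default `ceiling(sqrt(length(x)))`).
#' @return integer codes in `1..k`, `k <= n_bins`.
#' @export
discretize_ef <- function(x, n_bins = NULL) {
  n <- length(x)
  if (is.null(n_bins)) n_bins <- ceiling(sqrt(n))
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) {        # few distinct values: keep them distinct
    return(match(x, ux))
  }
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        type = 1, names = FALSE)
  brk <- unique(qs)
  if (length(brk) < 2) return(rep(1L, n))
  as.integer(cut(x, breaks = brk, include.lowest = TRUE, labels = FALSE))
}

entropy_bits <- function(codes) {
  p <- tabulate(as.integer(factor(codes)))
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

mi_bits <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  entropy_bits(a) + entropy_bits(b) -
    entropy_bits(a + (max(a) + 1L) * b)
}

#' Mutual information between a feature and class labels
#'
#' `I(discretised feature; label)` in bits, with equal-frequency
#' discretisation. A feature identical to a balanced binary label scores
#' exactly `H(label) = 1` bit.
#'
#' @param x numeric feature column.
#' @param labels class labels (factor or vector).
#' @param n_bins discretisation bins (default `ceiling(sqrt(n))`).
#' @return score in bits (0 with a warning if only one class is present).
#' @export
mi_score <- function(x, labels, n_bins = NULL) {
  if (any(!is.finite(x))) stopf("feature column contains non-finite values")
  labels <- factor(labels)
  if (nlevels(labels) < 2) {
    warnf("single class present; MI score set to 0")
    return(0)
  }
  mi_bits(discretize_ef(x, n_bins), labels)
}

#' Leave-one-out dataset-entropy scores for every feature
#'
#' Scores feature `f` by `H(dataset without f) - H(dataset)` where the
#' dataset entropy of the discretised matrix is estimated as
#' `sum_i H(X_i) - sum_{i<j} I(X_i; X_j)`; the score reduces to
#' `sum_{j != f} I(X_f; X_j) - H(X_f)`. A redundant (duplicated) feature
#' changes the dataset entropy by about zero when removed and therefore
#' ranks low.
#'
#' @param values numeric matrix (instances x features) or `feature_matrix`.
#' @param n_bins discretisation bins (default `ceiling(sqrt(n))`).
#' @return numeric vector of scores, one per feature (larger = removing the
#'   feature increases the estimated entropy more = more relevant).
#' @export
loo_entropy_score <- function(values, n_bins = NULL) {
  if (inherits(values, "feature_matrix")) values <- values$values
  p <- ncol(values)
  if (p < 2) stopf("need at least 2 features")
  if (p == 2) warnf("two-feature matrix: leave-one-out scores are degenerate")
  codes <- apply(values, 2, discretize_ef, n_bins = n_bins)
  H <- apply(codes, 2, entropy_bits)
  misum <- numeric(p)
  for (i in seq_len(p - 1)) {
    ci <- codes[, i]
    for (j in (i + 1):p) {
      m <- mi_bits(ci, codes[, j])
      misum[i] <- misum[i] + m
      misum[j] <- misum[j] + m
    }
  }
  misum - H
}

#' Rank features by information-based relevance
#'
#' Full ranking of all feature columns, most relevant first. Ties are broken
#' deterministically: lower frequency bin first, then region order
#' anterior < posterior < left < right, then amplitude before time (features
#' whose names do not parse fall back to name order).
#'
#' @param fm a `feature_matrix` (or plain matrix with column names).
#' @param labels class labels, required for `method = "mi"`.
#' @param method `"mi"` (supervised, default) or `"loo_entropy"`
#'   (unsupervised dataset-entropy reading).
#' @param top_k ranks to keep in the `top` table (default 4, the reporting
#'   depth used for salience tables; clipped to the feature count with a
#'   warning).
#' @param n_bins discretisation bins.
#' @return object of class `ranked_features`: data.frame `ranking` with
#'   `rank`, `feature`, `score`, plus parsed `region`, `parameter`,
#'   `bin_center_hz` where available; `top` is the first `top_k` rows;
#'   `method` records the scorer.
#' @export
ufs_rank <- function(fm, labels = NULL, method = c("mi", "loo_entropy"),
                     top_k = 4, n_bins = NULL) {
  method <- match.arg(method)
  values <- if (inherits(fm, "feature_matrix")) fm$values else fm
  fn <- colnames(values)
  scores <- if (method == "mi") {
    if (is.null(labels)) stopf("labels required for method 'mi'")
    if (length(labels) != nrow(values)) stopf("labels do not align with rows")
    apply(values, 2, mi_score, labels = labels, n_bins = n_bins)
  } else {
    loo_entropy_score(values, n_bins = n_bins)
  }
  parsed <- tryCatch(parse_feature_names(fn), error = function(e) NULL)
  if (!is.null(parsed)) {
    tie <- order(parsed$bin_center_hz,
                 match(parsed$region, REGIONS),
                 match(parsed$parameter, c("amplitude", "time")))
  } else {
    tie <- order(fn)
  }
  tie_rank <- match(seq_along(fn), tie)
  ord <- order(-scores, tie_rank)
  ranking <- data.frame(rank = seq_along(fn), feature = fn[ord],
                        score = scores[ord], stringsAsFactors = FALSE)
  if (!is.null(parsed)) {
    ranking <- cbind(ranking, parsed[ord, , drop = FALSE])
  }
  rownames(ranking) <- NULL
  if (top_k > length(fn)) {
    warnf("top_k = %d clipped to %d features", top_k, length(fn))
    top_k <- length(fn)
  }
  structure(list(ranking = ranking, top = ranking[seq_len(top_k), ],
                 method = method,
                 n_bins = n_bins %||% ceiling(sqrt(nrow(values)))),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features> %d features, method = %s; top %d:\n",
              nrow(x$ranking), x$method, nrow(x$top)))
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Write a ranking as CSV in salience-table layout
#'
#' Columns: rank, region, frequency bin, parameter type, score, method.
#'
#' @param rf a `ranked_features`.
#' @param path CSV path.
#' @export
write_ranking_csv <- function(rf, path) {
  d <- rf$ranking
  d$method <- rf$method
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
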