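# Information-based feature ranking.

test_that("MI of a feature equal to a balanced binary label is exactly 1 bit", {
  y <- rep(c("p", "q"), each = 44)
  x <- as.numeric(y == "p")
  expect_equal(mi_score(x, y), 1.0)
})

test_that("MI with label flips sits strictly between copy and independence", {
  n <- 88
  y <- rep(c(0, 1), each = n / 2)
  flip <- withr::with_seed(3, sample(n, round(0.1 * n)))
  xf <- y; xf[flip] <- 1 - xf[flip]
  # exact value from the 2x2 contingency table (brute force)
  tab <- table(xf, y) / n
  mi_oracle <- sum(tab * log2(tab / (rowSums(tab) %o% colSums(tab))),
                   na.rm = TRUE)
  got <- mi_score(xf, y)
  expect_equal(got, mi_oracle, tolerance = 1e-12)
  expect_lt(got, 1.0)
  expect_gt(got, 0.2)
})

test_that("MI of an independent feature stays below the permutation null", {
  n <- 88
  y <- rep(c(0, 1), each = n / 2)
  x <- withr::with_seed(4, stats::rnorm(n))
  obs <- mi_score(x, y)
  null <- withr::with_seed(5, vapply(1:500, function(i) {
    mi_score(x, sample(y))
  }, numeric(1)))
  expect_lte(obs, stats::quantile(null, 0.95))
})

test_that("MI is invariant under strictly monotone transforms", {
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- withr::with_seed(6, stats::rnorm(n) + y)
  base <- mi_score(x, y)
  expect_equal(mi_score(exp(x), y), base)
  expect_equal(mi_score(3 * x - 7, y), base)
  expect_equal(mi_score(rank(x), y), base)
})

test_that("single-class labels warn and score zero", {
  expect_warning(s <- mi_score(stats::rnorm(20), rep("a", 20)), "single")
  expect_equal(s, 0)
})

test_that("leave-one-out entropy matches brute force on a 3-column toy", {
  # x3 is an XOR-style combination of x1, x2: individually uninformative,
  # jointly determined
  withr::local_seed(7)
  n <- 64
  x1 <- stats::rnorm(n)
  x2 <- stats::rnorm(n)
  x3 <- (x1 > stats::median(x1)) != (x2 > stats::median(x2))
  m <- cbind(a = x1, b = x2, c = as.numeric(x3))
  nb <- 2
  got <- loo_entropy_score(m, n_bins = nb)
  # brute-force oracle from the discretised table: H(D) estimated as
  # sum H_i - sum_{i<j} I_ij, scores = H(D \ f) - H(D)
  codes <- apply(m, 2, discretize_ef, n_bins = nb)
  H1 <- function(v) { p <- table(v) / length(v); -sum(p * log2(p)) }
  H2 <- function(u, v) { p <- table(u, v) / length(u)
    -sum(p[p > 0] * log2(p[p > 0])) }
  I <- function(u, v) H1(u) + H1(v) - H2(u, v)
  Hs <- apply(codes, 2, H1)
  Is <- c(ab = I(codes[,1], codes[,2]), ac = I(codes[,1], codes[,3]),
          bc = I(codes[,2], codes[,3]))
  oracle <- c(Is["ab"] + Is["ac"] - Hs[1],
              Is["ab"] + Is["bc"] - Hs[2],
              Is["ac"] + Is["bc"] - Hs[3])
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
})

test_that("duplicated columns are redundant under leave-one-out entropy", {
  withr::local_seed(8)
  n <- 80
  dup <- stats::rnorm(n)
  latent <- stats::rnorm(n)          # factor shared by several columns
  m <- cbind(a = dup, b = dup,       # exact duplicates, isolated otherwise
             u = latent + 0.3 * stats::rnorm(n),
             v = latent + 0.3 * stats::rnorm(n),
             w = latent + 0.3 * stats::rnorm(n),
             z = latent + 0.3 * stats::rnorm(n))
  s <- loo_entropy_score(m)
  # removing either duplicate changes the estimated dataset entropy by ~0
  # (its duplicate carries the same information); a column sharing
  # information with several others ranks above both
  expect_equal(unname(s["a"]), unname(s["b"]), tolerance = 1e-9)
  expect_lt(s["a"], s["u"])
  expect_lt(s["b"], s["u"])
})

test_that("independent noise columns score within a tight dispersion band", {
  devs <- withr::with_seed(9, vapply(1:25, function(i) {
    m <- matrix(stats::rnorm(60 * 6), 60)
    colnames(m) <- paste0("f", 1:6)
    s <- loo_entropy_score(m)
    (max(s) - min(s)) / stats::sd(s)
  }, numeric(1)))
  # ranges stay a small multiple of the column sd (no runaway outliers)
  expect_lt(stats::median(devs), 4)
})

test_that("ranking is a deterministic permutation with documented tie order", {
  fm <- toy_fm(n_per_group = 16, n_feat_bins = 3, effect = 4,
               effect_col = 2)
  rows <- fm$instances$group == "a"
  labs <- fm$instances$condition[rows]
  fmv <- fm$values[rows, , drop = FALSE]
  rk <- ufs_rank(fmv, labels = labs, top_k = length(fm$feature_names))
  expect_setequal(rk$ranking$feature, fm$feature_names)
  # the injected column ranks first
  expect_equal(rk$ranking$feature[1], fm$feature_names[2])
  rk2 <- ufs_rank(fmv, labels = labs, top_k = length(fm$feature_names))
  # rerun identical
  expect_identical(rk$ranking, rk2$ranking)
  # constant matrix: everything ties, order follows (bin, region, parameter)
  fm0 <- fmv
  fm0[] <- rep(seq_len(nrow(fm0)), ncol(fm0))
  rk0 <- ufs_rank(fm0, labels = labs)
  parsed <- parse_feature_names(rk0$ranking$feature)
  expect_true(!is.unsorted(parsed$bin_center_hz[1:4]))
  # top_k clipping warns
  expect_warning(ufs_rank(fmv, labels = labs, top_k = 1000), "clipped")
})

test_that("ranking localises an injected condition difference (top-4)", {
  fm <- toy_fm(n_per_group = 12, n_feat_bins = 8, effect = 2.5,
               effect_col = 5, seed = 10)
  rows <- fm$instances$group == "a"
  rk <- ufs_rank(fm$values[rows, ], labels = fm$instances$condition[rows])
  expect_true(fm$feature_names[5] %in% rk$top$feature)
})

test_that("all-noise matrices have unstable top-4 sets across reruns", {
  tops <- withr::with_seed(11, lapply(1:12, function(i) {
    fm <- toy_fm(n_per_group = 8, n_feat_bins = 6, seed = 100 + i)
    ufs_rank(fm, labels = fm$instances$condition)$top$feature
  }))
  jac <- c()
  for (i in 1:11) {
    jac <- c(jac, length(intersect(tops[[i]], tops[[i + 1]])) /
               length(union(tops[[i]], tops[[i + 1]])))
  }
  expect_lt(mean(jac), 0.5)
})

test_that("UFS score tracks injected effect size across features", {
  # monotone relationship between per-column effect and MI rank
  withr::local_seed(12)
  n <- 88
  y <- rep(c(0, 1), each = n / 2)
  effects <- seq(0, 2.4, length.out = 8)
  m <- vapply(effects, function(e) stats::rnorm(n) + e * y,
              numeric(n))
  colnames(m) <- paste0("f", seq_along(effects))
  scores <- apply(m, 2, mi_score, labels = y)
  expect_gt(stats::cor(effects, scores, method = "spearman"), 0.6)
})
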