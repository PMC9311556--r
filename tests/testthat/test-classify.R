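# Fold construction, classifier wrappers, metrics, cross-validation flow.

make_clouds <- function(n_per_class, gap, seed, d = 4) {
  withr::with_seed(seed, {
    y <- rep(c("Healthy", "PD"), each = n_per_class)
    X <- matrix(rnorm(2 * n_per_class * d), ncol = d,
                dimnames = list(NULL, paste0("x", 1:d)))
    X[y == "PD", ] <- X[y == "PD", ] + gap
    list(X = X, y = y)
  })
}

test_that("stratified folds balance classes and sizes, deterministically", {
  y <- rep(c("Healthy", "PD"), times = c(30, 30))
  f <- make_folds(y, 10, seed = 1)
  tab <- table(f, y)
  expect_true(all(tab == 3))

  # 28 + 32: every fold has 6 subjects with 3 or 4 PD, totalling 32
  y <- rep(c("Healthy", "PD"), times = c(28, 32))
  f <- make_folds(y, 10, seed = 2)
  expect_true(all(table(f) == 6))
  pd_per_fold <- table(f[y == "PD"])
  expect_true(all(pd_per_fold %in% c(3, 4)))
  expect_equal(sum(pd_per_fold), 32)

  expect_identical(make_folds(y, 10, seed = 9), make_folds(y, 10, seed = 9))
  expect_error(make_folds(rep(c("Healthy", "PD"), c(4, 40)), 10), "at least")
})

test_that("all four classifiers solve a separable toy problem", {
  d <- make_clouds(20, gap = 8, seed = 3)
  f <- make_folds(d$y, 4, seed = 3)
  for (cl in c("knn", "cart", "rf", "svm")) {
    pred <- rep(NA_character_, length(d$y))
    for (k in 1:4) {
      tr <- f != k; te <- f == k
      res <- fit_predict(cl, d$X[tr, ], d$y[tr], d$X[te, ], seed = 10 + k)
      pred[te] <- as.character(res$pred)
      expect_equal(unname(rowSums(res$scores)), rep(1, sum(te)),
                   tolerance = 1e-9)
    }
    expect_equal(mean(pred == d$y), 1)
  }
})

test_that("1-NN on its own training set is perfect", {
  d <- make_clouds(10, gap = 1, seed = 4)
  res <- fit_predict("knn", d$X, d$y, d$X, hyper = list(k = 1), seed = 1)
  expect_equal(as.character(res$pred), d$y)
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  d <- make_clouds(50, gap = 6, seed = 5)
  y_perm <- withr::with_seed(99, sample(d$y))
  cv <- run_cv(d$X, y_perm, n_folds = 10, select_k = NULL, seed = 6,
               fusion_methods = character(0),
               hyper = list(rf = list(ntree = 200)))
  acc <- cv$metrics$accuracy
  expect_true(all(acc >= 0.35 & acc <= 0.65))
})

test_that("metrics match hand substitution and satisfy their identities", {
  m <- compute_metrics(c(Tp = 9, Tn = 8, Fp = 1, Fn = 2))
  expect_equal(unname(m), c(0.85, 0.9, 9 / 11, 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11)),
               tolerance = 1e-6)
  expect_equal(m[["f_measure"]], 0.8571, tolerance = 1e-4)

  perfect <- compute_metrics(c(Tp = 5, Tn = 5, Fp = 0, Fn = 0))
  expect_equal(unname(perfect), rep(1, 4))

  # harmonic-mean fixed point: precision == recall == p implies F1 == p
  m <- compute_metrics(c(Tp = 6, Tn = 10, Fp = 2, Fn = 2))
  expect_equal(m[["precision"]], m[["recall"]])
  expect_equal(m[["f_measure"]], m[["precision"]])

  # zero denominators are NA, never 0, and F1 <= max(precision, recall)
  m0 <- compute_metrics(c(Tp = 0, Tn = 10, Fp = 0, Fn = 5))
  expect_true(is.na(m0[["precision"]]))
  set.seed(8)
  for (rep in 1:20) {
    cts <- c(Tp = rpois(1, 5) + 1, Tn = rpois(1, 5) + 1,
             Fp = rpois(1, 2), Fn = rpois(1, 2))
    m <- compute_metrics(cts)
    expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))
    expect_lte(m[["f_measure"]], max(m[["precision"]], m[["recall"]]) + 1e-12)
  }
})

test_that("cross-validation predicts every subject once and is reproducible", {
  d <- make_clouds(15, gap = 3, seed = 7)
  cv <- run_cv(d$X, d$y, n_folds = 5, select_k = 3, seed = 11,
               hyper = list(rf = list(ntree = 200)))
  expect_equal(nrow(cv$predictions), 30)
  expect_false(anyNA(cv$predictions[, cv$config$classifiers]))
  expect_equal(sort(unique(cv$folds)), 1:5)

  cv2 <- run_cv(d$X, d$y, n_folds = 5, select_k = 3, seed = 11,
                hyper = list(rf = list(ntree = 200)))
  expect_identical(cv$predictions, cv2$predictions)
  expect_identical(cv$metrics, cv2$metrics)
})

test_that("selection and standardisation use training folds only", {
  d <- make_clouds(15, gap = 3, seed = 12)
  cv <- run_cv(d$X, d$y, n_folds = 5, select_k = 3, seed = 13,
               fusion_methods = character(0),
               hyper = list(rf = list(ntree = 200)))
  for (a in cv$audit) {
    tr <- a$train
    # scaling parameters are exactly the training-fold statistics
    expect_equal(a$center, colMeans(d$X[tr, a$selected, drop = FALSE]),
                 tolerance = 1e-12)
    expect_equal(a$scale, apply(d$X[tr, a$selected, drop = FALSE], 2, sd),
                 tolerance = 1e-12)
    # the selected set is reproducible from the training rows alone
    r <- rank_features(d$X[tr, , drop = FALSE], d$y[tr], k = 3,
                       seed = derive_seed(13, 100 + a$fold))
    expect_identical(a$selected, r$selected)
    expect_length(intersect(a$train, a$test), 0)
  }
})

test_that("doubling feature scales leaves standardised classifiers unchanged", {
  d <- make_clouds(15, gap = 3, seed = 14)
  cv1 <- run_cv(d$X, d$y, classifiers = c("knn", "svm"), n_folds = 5,
                select_k = NULL, seed = 15, fusion_methods = character(0))
  cv2 <- run_cv(d$X * 2, d$y, classifiers = c("knn", "svm"), n_folds = 5,
                select_k = NULL, seed = 15, fusion_methods = character(0))
  expect_identical(cv1$predictions$knn, cv2$predictions$knn)
  expect_identical(cv1$predictions$svm, cv2$predictions$svm)
})

test_that("cv results export as structured text with a Table-style confusion", {
  d <- make_clouds(12, gap = 5, seed = 16)
  cv <- run_cv(d$X, d$y, n_folds = 4, select_k = NULL, seed = 17,
               hyper = list(rf = list(ntree = 100)))
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_result(cv, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$seed, cv$seed)
  expect_equal(back$metrics$accuracy, cv$metrics$accuracy, tolerance = 1e-9)
  pct <- back$confusion_percent$svm
  expect_equal(rowSums(matrix(unlist(pct), 2, byrow = FALSE)), c(100, 100),
               tolerance = 1e-9)
})
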