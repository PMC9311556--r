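# Supervised classification under stratified k-fold cross-validation.

CLASS_LEVELS <- c("Healthy", "PD")  # PD is the positive class throughout

#' Stratified fold assignment
#'
#' Partitions subjects into `n_folds` folds so that each class is spread as
#' evenly as possible (per-fold class counts within one of each other) and
#' total fold sizes are balanced. Deterministic given the seed.
#'
#' @param labels Class labels.
#' @param n_folds Number of folds (default 10); no class may be smaller.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..n_folds), one per subject.
#' @export
make_folds <- function(labels, n_folds = 10L, seed = 1L) {
  y <- factor(labels)
  if (any(table(y) < n_folds)) {
    stop(sprintf("every class must have at least %d subjects for %d folds",
                 n_folds, n_folds))
  }
  fold <- integer(length(y))
  sizes <- integer(n_folds)
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      n_c <- length(idx)
      counts <- rep(n_c %/% n_folds, n_folds)
      rem <- n_c %% n_folds
      if (rem > 0L) {
        shuffled <- sample(n_folds)               # random tie-break
        extras <- shuffled[order(sizes[shuffled])][seq_len(rem)]
        counts[extras] <- counts[extras] + 1L
      }
      fold[idx] <- rep.int(seq_len(n_folds), counts)
      sizes <- sizes + counts
    }
  })
  fold
}

svm_scale_gamma <- function(x) {
  v <- mean(apply(x, 2, stats::var))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(x) * v)
}

#' Fit one classifier and predict a test set
#'
#' The four supported learners and their pinned hyperparameters: `knn`
#' (k = 5, Euclidean), `cart` (Gini splits, default pruning, unrestricted
#' depth), `rf` (500 trees), `svm` (RBF kernel, cost 1, gamma =
#' 1/(n_features * mean feature variance), probability outputs). Features are
#' expected already standardised with training-fold statistics. Returns hard
#' labels plus normalised per-class scores for the fusion stage; deterministic
#' given the seed.
#'
#' @param classifier One of `"knn"`, `"cart"`, `"rf"`, `"svm"`.
#' @param x_train,x_test Numeric feature matrices.
#' @param y_train Training labels (`Healthy`/`PD`).
#' @param hyper Named list overriding the defaults (`k`, `ntree`, `cost`,
#'   `gamma`, `cp`).
#' @param seed Integer seed for the stochastic learners.
#' @return List with `pred` (factor over Healthy/PD) and `scores`
#'   (matrix, columns Healthy and PD, rows summing to 1).
#' @export
fit_predict <- function(classifier = c("knn", "cart", "rf", "svm"),
                        x_train, y_train, x_test, hyper = list(), seed = 1L) {
  classifier <- match.arg(classifier)
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  y_train <- factor(y_train, levels = CLASS_LEVELS)
  stopifnot(ncol(x_train) == ncol(x_test), !anyNA(y_train))

  scores <- switch(classifier,
    knn = {
      k <- min(hyper$k %||% 5L, nrow(x_train))
      pred <- with_seed(seed,
        class::knn(x_train, x_test, cl = y_train, k = k, prob = TRUE))
      p_win <- attr(pred, "prob")
      s <- matrix(0, nrow = nrow(x_test), ncol = 2,
                  dimnames = list(NULL, CLASS_LEVELS))
      win <- as.character(pred)
      for (i in seq_along(win)) {
        s[i, win[i]] <- p_win[i]
        s[i, setdiff(CLASS_LEVELS, win[i])] <- 1 - p_win[i]
      }
      s
    },
    cart = {
      df <- data.frame(.y = y_train, x_train, check.names = FALSE)
      fit <- with_seed(seed,
        rpart::rpart(.y ~ ., data = df, method = "class",
                     parms = list(split = "gini"),
                     control = rpart::rpart.control(
                       cp = hyper$cp %||% 0.01, maxdepth = 30)))
      p <- predict(fit, data.frame(x_test, check.names = FALSE),
                   type = "prob")
      p[, CLASS_LEVELS, drop = FALSE]
    },
    rf = {
      fit <- with_seed(seed,
        randomForest::randomForest(x = x_train, y = y_train,
                                   ntree = hyper$ntree %||% 500L))
      p <- predict(fit, x_test, type = "prob")
      p[, CLASS_LEVELS, drop = FALSE]
    },
    svm = {
      fit <- with_seed(seed,
        e1071::svm(x_train, y_train, kernel = "radial",
                   cost = hyper$cost %||% 1,
                   gamma = hyper$gamma %||% svm_scale_gamma(x_train),
                   probability = TRUE))
      p <- attr(predict(fit, x_test, probability = TRUE), "probabilities")
      p[, CLASS_LEVELS, drop = FALSE]
    }
  )
  rownames(scores) <- NULL
  # normalise defensively; each learner already returns proper probabilities
  scores <- scores / rowSums(scores)
  pred <- factor(CLASS_LEVELS[max.col(scores, ties.method = "first")],
                 levels = CLASS_LEVELS)
  list(pred = pred, scores = scores)
}

#' Confusion counts with PD as the positive class
#'
#' @param truth,pred Label vectors over Healthy/PD.
#' @return Named integer vector `c(Tp, Tn, Fp, Fn)`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- factor(truth, levels = CLASS_LEVELS)
  pred <- factor(pred, levels = CLASS_LEVELS)
  c(Tp = sum(truth == "PD" & pred == "PD"),
    Tn = sum(truth == "Healthy" & pred == "Healthy"),
    Fp = sum(truth == "Healthy" & pred == "PD"),
    Fn = sum(truth == "PD" & pred == "Healthy"))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision (`Tp/(Tp+Fp)`), recall (`Tp/(Tp+Fn)`) and the
#' F-measure \eqn{F_\beta = (1+\beta^2)\,pr\,re / (\beta^2 pr + re)} with
#' `beta = 1` weighting precision and recall equally. Metrics with a zero
#' denominator are reported as `NA`, never silently as 0.
#'
#' @param counts Named vector with `Tp`, `Tn`, `Fp`, `Fn`.
#' @param beta F-measure weight (default 1).
#' @return Named numeric vector `c(accuracy, precision, recall, f_measure)`.
#' @export
compute_metrics <- function(counts, beta = 1) {
  tp <- counts[["Tp"]]; tn <- counts[["Tn"]]
  fp <- counts[["Fp"]]; fn <- counts[["Fn"]]
  total <- tp + tn + fp + fn
  stopifnot(total > 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) &&
           (beta^2 * precision + recall) > 0) {
    (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
  } else NA_real_
  c(accuracy = (tp + tn) / total, precision = precision, recall = recall,
    f_measure = f)
}

# Standardise columns with training statistics; zero-variance columns pass
# through centred only.
standardizer <- function(x_train) {
  center <- colMeans(x_train)
  scale <- apply(x_train, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale,
       apply = function(x) sweep(sweep(as.matrix(x), 2, center), 2, scale, "/"))
}

#' Cross-validated classification with per-fold selection and fusion
#'
#' Runs stratified `n_folds`-fold cross-validation of the full pipeline
#' stage: within each training fold, features are ranked by random-forest
#' importance and the top `select_k` retained, standardisation statistics are
#' estimated, all classifiers are fitted, and the held-out fold is predicted.
#' Feature selection and standardisation never see test rows; the per-fold
#' `audit` records the selected names and scaling parameters so this can be
#' verified externally. Classifier decisions are then fused per subject by
#' majority vote, a Bayesian rule and Dempster-Shafer combination, using
#' reliability/likelihood estimates from internal `inner_folds`-fold
#' out-of-fold predictions on the training fold only.
#'
#' Headline metrics are aggregated as the across-fold mean and standard
#' deviation of fold accuracies; pooled out-of-fold confusion counts and the
#' metrics derived from them are reported alongside.
#'
#' @param X Feature matrix (subjects x features, named columns) or the
#'   data.frame produced by [build_feature_matrix()] (its `subject_id` and
#'   `label` columns are then used).
#' @param y Labels (`Healthy`/`PD`); ignored when `X` carries a `label`
#'   column.
#' @param classifiers Subset of `c("knn","cart","rf","svm")`.
#' @param n_folds Folds (default 10).
#' @param select_k Features retained per training fold (default 5); `NULL`
#'   or `ncol(X)` disables selection.
#' @param seed Master seed; all fold/fit seeds derive from it.
#' @param fusion_methods Subset of `c("vote","bayes","ds")`.
#' @param per_fold_selection Re-select within each training fold (default
#'   TRUE); FALSE restores a single global pre-selection for comparison.
#' @param inner_folds Internal folds for reliability estimation (default 5).
#' @param hyper Named list of per-classifier hyperparameter overrides, e.g.
#'   `list(knn = list(k = 3))`.
#' @return Object of class `cv_result`; see Details.
#' @export
run_cv <- function(X, y = NULL,
                   classifiers = c("knn", "cart", "rf", "svm"),
                   n_folds = 10L, select_k = 5L, seed = 1L,
                   fusion_methods = c("vote", "bayes", "ds"),
                   per_fold_selection = TRUE, inner_folds = 5L,
                   hyper = list()) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (length(fusion_methods) > 0) {
    fusion_methods <- match.arg(fusion_methods,
                                c("vote", "bayes", "ds"), several.ok = TRUE)
  }
  subject_id <- NULL
  if (is.data.frame(X) && all(c("subject_id", "label") %in% names(X))) {
    subject_id <- X$subject_id
    y <- X$label
    X <- as.matrix(X[, setdiff(names(X), c("subject_id", "label")),
                     drop = FALSE])
  } else {
    X <- as.matrix(X)
  }
  if (is.null(subject_id)) subject_id <- sprintf("S%03d", seq_len(nrow(X)))
  y <- factor(y, levels = CLASS_LEVELS)
  if (nlevels(droplevels(y)) < 2L) stop("need both classes present")
  stopifnot(nrow(X) == length(y), !anyNA(X))
  n <- nrow(X)
  select_k <- select_k %||% ncol(X)

  fold <- make_folds(y, n_folds = n_folds, seed = derive_seed(seed, 0))
  methods <- c(classifiers, if (length(fusion_methods)) fusion_methods)
  pred <- matrix(NA_character_, n, length(methods),
                 dimnames = list(NULL, methods))
  score_pd <- matrix(NA_real_, n, length(classifiers),
                     dimnames = list(NULL, classifiers))
  audit <- vector("list", n_folds)

  global_sel <- NULL
  if (!per_fold_selection && select_k < ncol(X)) {
    global_sel <- rank_features(X, y, k = select_k,
                                seed = derive_seed(seed, 900))$selected
  }

  for (f in seq_len(n_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    sel <- if (!is.null(global_sel)) {
      global_sel
    } else if (select_k < ncol(X)) {
      rank_features(X[tr, , drop = FALSE], y[tr], k = select_k,
                    seed = derive_seed(seed, 100 + f))$selected
    } else {
      colnames(X)
    }
    std <- standardizer(X[tr, sel, drop = FALSE])
    xtr <- std$apply(X[tr, sel, drop = FALSE])
    xte <- std$apply(X[te, sel, drop = FALSE])
    audit[[f]] <- list(fold = f, selected = sel, center = std$center,
                       scale = std$scale, train = tr, test = te)

    fold_fits <- list()
    for (j in seq_along(classifiers)) {
      cl <- classifiers[j]
      res <- fit_predict(cl, xtr, y[tr], xte, hyper = hyper[[cl]] %||% list(),
                         seed = derive_seed(seed, 1000 * f + j))
      pred[te, cl] <- as.character(res$pred)
      score_pd[te, cl] <- res$scores[, "PD"]
      fold_fits[[cl]] <- res
    }

    if (length(fusion_methods) > 0) {
      est <- inner_reliability(xtr, y[tr], classifiers, inner_folds, hyper,
                               seed = derive_seed(seed, 5000 + f))
      priors <- table(y[tr]) / length(tr)
      fold_scores <- do.call(cbind, lapply(fold_fits, function(r)
        r$scores[, "PD"]))
      for (i in seq_along(te)) {
        decisions <- vapply(classifiers, function(cl)
          as.character(fold_fits[[cl]]$pred[i]), character(1))
        mean_scores <- c(Healthy = mean(1 - fold_scores[i, ]),
                         PD = mean(fold_scores[i, ]))
        if ("vote" %in% fusion_methods) {
          pred[te[i], "vote"] <- majority_vote(decisions, mean_scores)
        }
        if ("bayes" %in% fusion_methods) {
          pred[te[i], "bayes"] <- bayes_fuse(decisions, est$likelihood,
                                             priors)
        }
        if ("ds" %in% fusion_methods) {
          masses <- lapply(seq_along(classifiers), function(j)
            build_mass(decisions[j],
                       est$reliability[[classifiers[j]]][[decisions[j]]]))
          pred[te[i], "ds"] <- ds_decide(masses,
                                         fallback_decisions = decisions,
                                         fallback_scores = mean_scores)
        }
      }
    }
  }

  per_fold_acc <- sapply(methods, function(m)
    vapply(seq_len(n_folds), function(f) {
      te <- which(fold == f)
      mean(pred[te, m] == as.character(y[te]))
    }, numeric(1)))
  confusion <- lapply(stats::setNames(methods, methods), function(m)
    confusion_counts(y, pred[, m]))
  metrics <- do.call(rbind, lapply(methods, function(m) {
    pooled <- compute_metrics(confusion[[m]])
    data.frame(method = m,
               accuracy_mean = mean(per_fold_acc[, m]),
               accuracy_sd = stats::sd(per_fold_acc[, m]),
               t(pooled),
               stringsAsFactors = FALSE)
  }))

  structure(
    list(predictions = data.frame(subject_id = subject_id,
                                  truth = as.character(y), fold = fold,
                                  pred, check.names = FALSE,
                                  stringsAsFactors = FALSE),
         scores = score_pd, per_fold_accuracy = per_fold_acc,
         metrics = metrics, confusion = confusion, folds = fold,
         audit = audit, seed = as.integer(seed),
         config = list(classifiers = classifiers, n_folds = n_folds,
                       select_k = select_k, fusion_methods = fusion_methods,
                       per_fold_selection = per_fold_selection,
                       inner_folds = inner_folds, hyper = hyper)),
    class = "cv_result"
  )
}

# Out-of-fold confusion estimates on the training fold only: reliability
# (smoothed P(truth = d | classifier says d)) and likelihood (smoothed
# P(classifier says d | truth)) for the fusion stage.
inner_reliability <- function(x, y, classifiers, inner_folds, hyper, seed) {
  inner_folds <- min(inner_folds, min(table(y)))
  fold <- make_folds(y, n_folds = inner_folds, seed = seed)
  oof <- matrix(NA_character_, length(y), length(classifiers),
                dimnames = list(NULL, classifiers))
  for (f in seq_len(inner_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    for (j in seq_along(classifiers)) {
      cl <- classifiers[j]
      res <- fit_predict(cl, x[tr, , drop = FALSE], y[tr],
                         x[te, , drop = FALSE],
                         hyper = hyper[[cl]] %||% list(),
                         seed = derive_seed(seed, 10 * f + j))
      oof[te, cl] <- as.character(res$pred)
    }
  }
  reliability <- lapply(stats::setNames(classifiers, classifiers), function(cl)
    estimate_reliability(y, oof[, cl]))
  likelihood <- lapply(stats::setNames(classifiers, classifiers), function(cl)
    estimate_likelihood(y, oof[, cl]))
  list(reliability = reliability, likelihood = likelihood, oof = oof)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d subjects, %d folds, seed %d\n",
              nrow(x$predictions), x$config$n_folds, x$seed))
  m <- x$metrics
  m[, -1] <- round(m[, -1], 4)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Row-percentage confusion matrix in two-class layout
#'
#' True classes on rows, predicted on columns, each row expressed as
#' percentages summing to 100.
#'
#' @param counts Named confusion counts (`Tp`, `Tn`, `Fp`, `Fn`).
#' @return 2x2 numeric matrix of row percentages.
#' @export
confusion_percent <- function(counts) {
  m <- matrix(c(counts[["Tn"]], counts[["Fp"]],
                counts[["Fn"]], counts[["Tp"]]),
              nrow = 2, byrow = TRUE,
              dimnames = list(true = CLASS_LEVELS, predicted = CLASS_LEVELS))
  sweep(m, 1, pmax(rowSums(m), 1), "/") * 100
}

#' Write a cross-validation result as structured text
#'
#' JSON with per-method metrics, pooled confusion counts and row-percentage
#' matrices, fold assignment, seed and a config echo.
#'
#' @param x A `cv_result`.
#' @param path Output file path.
#' @export
write_cv_result <- function(x, path) {
  stopifnot(inherits(x, "cv_result"))
  out <- list(
    seed = x$seed,
    config = x$config,
    metrics = x$metrics,
    confusion_counts = x$confusion,
    confusion_percent = lapply(x$confusion, confusion_percent),
    fold_assignment = x$folds,
    predictions = x$predictions
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
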