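# Random-forest importance ranking and top-k feature selection.

#' Rank features by random-forest importance
#'
#' Fits a seeded random forest on the labelled feature matrix and orders the
#' features by mean decrease in Gini impurity, breaking importance ties by
#' feature name so the ranking is fully deterministic. The top `k` features
#' form the selected set.
#'
#' @param X Numeric matrix or data.frame of features (subjects x features),
#'   no missing values, named columns.
#' @param y Class labels, two levels, at least two subjects per class.
#' @param k Number of features to retain (default 5).
#' @param n_trees Forest size (default 500; large enough to stabilise the
#'   ranking at small cohort sizes).
#' @param seed Integer seed.
#' @return Object of class `feature_ranking`: list with `ranking`
#'   (data.frame of feature, importance, sorted non-increasing) and
#'   `selected` (character vector of length `k`).
#' @export
rank_features <- function(X, y, k = 5L, n_trees = 500L, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names")
  if (anyNA(X)) stop("X must not contain missing values")
  y <- factor(y)
  if (nlevels(y) < 2L) stop("labels must contain two classes")
  if (any(table(y) < 2L)) stop("need at least two subjects per class")
  stopifnot(k >= 1L, k <= ncol(X))
  # canonical row order: the ranking depends only on the sample set, not on
  # the order rows arrive in
  o <- do.call(order, c(as.list(as.data.frame(X)), list(as.integer(y))))
  fit <- with_seed(seed,
    randomForest::randomForest(x = X[o, , drop = FALSE], y = y[o],
                               ntree = n_trees))
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, names(imp))
  ranking <- data.frame(feature = names(imp)[ord],
                        importance = unname(imp[ord]),
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking, selected = ranking$feature[seq_len(k)],
                 k = as.integer(k), seed = as.integer(seed)),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> top %d of %d features:\n", x$k,
              nrow(x$ranking)))
  print(utils::head(x$ranking, x$k), row.names = FALSE)
  invisible(x)
}

#' Write a ranking as two-column delimited text
#'
#' @param x A `feature_ranking`.
#' @param path Output file path.
#' @export
write_ranking <- function(x, path) {
  stopifnot(inherits(x, "feature_ranking"))
  utils::write.table(x$ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
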