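#' Configuration for the class-weighted random forest
#'
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; `NULL` = `floor(sqrt(p))`.
#' @param class_weights Named positive weights per class; `NULL` =
#'   reciprocal class sizes, normalized to sum to the number of classes.
#' @param min_node Minimum node size below which a node becomes a leaf
#'   (default 1: trees grown to purity).
#' @param seed Integer seed driving bootstrap and feature sampling.
#' @return A `forest_config` object.
#' @export
forest_config <- function(n_trees = 500L, mtry = NULL,
                          class_weights = NULL, min_node = 1L,
                          seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  if (!is.null(class_weights) && any(class_weights <= 0)) {
    stop("class weights must be strictly positive", call. = FALSE)
  }
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 class_weights = class_weights,
                 min_node = as.integer(min_node),
                 seed = as.integer(seed)),
            class = "forest_config")
}

# build the numeric design matrix: one-hot encode character/factor columns
# (secondary structure), keep numerics as-is
design_matrix <- function(table, features) {
  cols <- lapply(features, function(f) {
    v <- table[[f]]
    if (is.numeric(v)) {
      m <- matrix(as.numeric(v), ncol = 1)
      colnames(m) <- f
      m
    } else {
      lev <- sort(unique(as.character(v)))
      m <- vapply(lev, function(l) as.numeric(v == l),
                  numeric(length(v)))
      if (is.null(dim(m))) m <- matrix(m, nrow = length(v))
      colnames(m) <- paste(f, lev, sep = "_")
      m
    }
  })
  do.call(cbind, cols)
}

#' Train a class-weighted random forest
#'
#' Trees are grown on bootstrap samples drawn with probability
#' proportional to the class weight, with the weights also entering the
#' split impurity (weighted Gini) and the leaf label (weighted majority
#' vote). Rows with missing feature values are dropped with a
#' recorded count. Reciprocal-size default weights give minority classes
#' (here PGx) the same aggregate influence as the majority classes.
#'
#' @param table data.frame of features.
#' @param labels Class label per row.
#' @param config A [forest_config()].
#' @param features Feature column names; default all columns of `table`.
#' @return A `forest_model`: list with `trees`, `votes` (OOB votes),
#'   `oob_trees`, `classes`, `config`, `features` (design columns),
#'   `n_dropped`, `kept` (logical row filter).
#' @export
train_weighted_forest <- function(table, labels, config = forest_config(),
                                  features = colnames(table)) {
  labels <- as.character(labels)
  if (length(labels) != nrow(table)) {
    stop("labels length must match table rows", call. = FALSE)
  }
  X <- design_matrix(table, features)
  keep <- stats::complete.cases(X) & !is.na(labels)
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message("train_weighted_forest: dropped ", n_dropped,
            " row(s) with missing values")
  }
  X <- X[keep, , drop = FALSE]
  if (any(!is.finite(X))) {
    stop("non-finite feature value", call. = FALSE)
  }
  labels <- labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("need at least 2 classes to train", call. = FALSE)
  }
  y <- match(labels, classes) - 1L
  w <- config$class_weights
  if (is.null(w)) {
    sizes <- table(factor(labels, levels = classes))
    w <- (1 / as.numeric(sizes))
    w <- w / sum(w) * length(classes)
    names(w) <- classes
  } else {
    if (!all(classes %in% names(w))) {
      stop("class_weights must name every class present", call. = FALSE)
    }
    w <- w[classes]
  }
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(X)))) else
    as.integer(config$mtry)
  if (mtry < 1L || mtry > ncol(X)) {
    stop("mtry must be in [1, n_features]", call. = FALSE)
  }
  fit <- rf_train_cpp(X, y, length(classes), as.numeric(w),
                      config$n_trees, mtry, config$min_node, config$seed)
  structure(list(trees = fit$trees, votes = fit$votes,
                 oob_trees = fit$oob_trees, classes = classes,
                 weights = w, config = config, features = colnames(X),
                 design = X, labels = labels, n_dropped = n_dropped,
                 kept = keep),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("forest_model: %d trees, classes [%s], weights [%s]\n",
              x$config$n_trees, paste(x$classes, collapse = ", "),
              paste(sprintf("%.3f", x$weights), collapse = ", ")))
  invisible(x)
}

#' Out-of-bag class scores
#'
#' For each training row, the votes of the trees for which the row was
#' out-of-bag, normalized to sum to 1. The class weights have already
#' acted inside the forest (weight-proportional bootstrap sampling,
#' weighted Gini splits, weighted leaf majority), so the normalized vote
#' fractions are the prediction scores. Rows that were never out-of-bag
#' get an all-`NA` score vector (undefined marker) and are excluded from
#' downstream metrics with a recorded count.
#'
#' @param model A `forest_model`.
#' @return Numeric matrix (rows = training rows kept by the model,
#'   columns = classes); attribute `n_undefined` counts never-OOB rows.
#' @export
oob_scores <- function(model) {
  v <- model$votes
  tot <- model$oob_trees
  scores <- sweep(v, 1, pmax(tot, 1L), "/")
  scores[tot == 0L, ] <- NA_real_
  colnames(scores) <- model$classes
  if (any(tot == 0L)) {
    message("oob_scores: ", sum(tot == 0L), " row(s) never out-of-bag")
  }
  attr(scores, "n_undefined") <- sum(tot == 0L)
  scores
}

#' Predicted label from normalized class scores
#'
#' Argmax of each score vector, with ties broken by alphabetical class
#' order. For three classes this is exactly the decision-simplex
#' partition of the neutral(x)-disease(y) plane by the three lines
#' y - x = 0, 1 - 2x - y = 0 and 1 - x - 2y = 0 meeting at (1/3, 1/3).
#'
#' @param scores Matrix of class scores (columns named by class).
#' @return Character vector of predicted labels (`NA` for undefined
#'   score rows).
#' @export
classify_scores <- function(scores) {
  classes <- colnames(scores)
  ord <- order(classes)  # alphabetical tie-break
  apply(scores, 1, function(s) {
    if (anyNA(s)) return(NA_character_)
    s_ord <- s[ord]
    classes[ord][which.max(s_ord)]
  })
}

#' Three-group classification from class scores
#'
#' @param scores Score matrix with columns including neutral, disease,
#'   pgx.
#' @return Character vector of predicted labels.
#' @export
classify_three_group <- function(scores) {
  need <- c("disease", "neutral", "pgx")
  if (!all(need %in% colnames(scores))) {
    stop("scores must have columns disease, neutral, pgx", call. = FALSE)
  }
  classify_scores(scores)
}

#' Predict class votes for new data
#'
#' @param object A `forest_model`.
#' @param newdata data.frame with the model's feature columns.
#' @param ... Unused.
#' @return Normalized score matrix (rows sum to 1).
#' @export
predict.forest_model <- function(object, newdata, ...) {
  base_feats <- unique(sub("_(helix|strand|coil)$", "",
                           object$features))
  X <- design_matrix(newdata, intersect(base_feats, colnames(newdata)))
  miss <- setdiff(object$features, colnames(X))
  if (length(miss)) {
    X <- cbind(X, matrix(0, nrow(X), length(miss),
                         dimnames = list(NULL, miss)))
  }
  X <- X[, object$features, drop = FALSE]
  v <- rf_predict_votes_cpp(object$trees, X, length(object$classes))
  colnames(v) <- object$classes
  v / rowSums(v)
}

#' Two-group weighted-forest discrimination
#'
#' Subsets the table to two classes, trains a class-weighted forest and
#' evaluates the OOB scores of the positive (first-named) class:
#' confusion metrics at the argmax decision rule plus rank-based AUC.
#'
#' @param table Feature data.frame.
#' @param labels Class label per row.
#' @param positive,negative The two class labels; `positive` is the
#'   first-named group of the comparison (e.g. disease in
#'   disease/neutral).
#' @param config A [forest_config()].
#' @param features Feature columns.
#' @return A `metrics_report` with `auc` filled in; attributes `model`
#'   and `scores`.
#' @export
run_two_group <- function(table, labels, positive, negative,
                          config = forest_config(),
                          features = setdiff(colnames(table),
                                             c("protein_id", "position",
                                               "ref", "alt", "label",
                                               "variant_id"))) {
  labels <- as.character(labels)
  sel <- labels %in% c(positive, negative)
  if (!any(labels == positive) || !any(labels == negative)) {
    stop("both classes must be present", call. = FALSE)
  }
  sub <- table[sel, , drop = FALSE]
  sub_lab <- labels[sel]
  model <- train_weighted_forest(sub, sub_lab, config, features)
  scores <- oob_scores(model)
  ok <- !is.na(scores[, positive])
  pred <- classify_scores(scores)[ok] == positive
  actual <- model$labels[ok] == positive
  rep <- binary_metrics(pred, actual)
  rep$auc <- auc_score(scores[ok, positive], actual)
  attr(rep, "model") <- model
  attr(rep, "scores") <- scores
  rep
}
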