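#' Classifier specification
#'
#' Families mirror the usual barcode-classification line-up:
#' `"nearest-neighbor"` (exhaustive Euclidean k-NN, implemented natively;
#' param `nn`), `"tree-ensemble"` (a native random forest: bootstrapped
#' CART trees with random feature subsets; params `n_trees`, `mtry`),
#' `"multinomial-logistic"` (ridge-penalised multinomial logistic
#' regression delegated to \pkg{glmnet}; param `ridge`), and
#' `"margin-based"` (a pluggable contract only: supply `fit` and
#' `predict_prob` functions; no SVM is re-implemented).
#'
#' @param family one of `"nearest-neighbor"`, `"tree-ensemble"`,
#'   `"multinomial-logistic"`, `"margin-based"`.
#' @param nn neighbour count for nearest-neighbor (1, 3 or 5 typically).
#' @param n_trees,mtry tree-ensemble size and features tried per split
#'   (`mtry = NULL` means `floor(sqrt(p))`).
#' @param ridge ridge penalty for the multinomial-logistic family.
#' @param fit,predict_prob margin-based backend:
#'   `fit(x, y)` returns a model, `predict_prob(model, x, classes)`
#'   returns an instances x classes probability matrix.
#' @param seed integer seed consumed by stochastic learners.
#' @return A `ClassifierSpec`.
#' @export
classifier_spec <- function(family = c("nearest-neighbor", "tree-ensemble",
                                       "multinomial-logistic",
                                       "margin-based"),
                            nn = 1, n_trees = 100, mtry = NULL,
                            ridge = 1e-8, fit = NULL, predict_prob = NULL,
                            seed = 1) {
  family <- match.arg(family)
  if (family == "nearest-neighbor" && nn < 1)
    stop("nn must be >= 1")
  if (family == "margin-based" &&
      (is.null(fit) || is.null(predict_prob)))
    stop("the margin-based family is a pluggable contract: ",
         "supply fit() and predict_prob() functions")
  structure(list(family = family, nn = nn, n_trees = n_trees, mtry = mtry,
                 ridge = ridge, fit = fit, predict_prob = predict_prob,
                 seed = seed),
            class = "ClassifierSpec")
}

#' Stratified fold assignment
#'
#' Instances of each class are shuffled (seeded) and dealt round-robin,
#' each class starting on the currently least-loaded fold so classes
#' smaller than `n_folds` are spread as evenly as possible.
#'
#' @param labels class label per instance.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(labels, n_folds = 10, seed = 1) {
  n <- length(labels)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n < n_folds) stop("fewer instances than folds")
  rng <- local({ set.seed(seed); sample.int(n) })
  folds <- integer(n)
  load <- integer(n_folds)
  for (cls in unique(labels[rng])) {
    idx <- rng[labels[rng] == cls]
    start <- which.min(load)
    slots <- ((start - 1L + seq_along(idx) - 1L) %% n_folds) + 1L
    folds[idx] <- slots
    load <- load + tabulate(slots, n_folds)
  }
  folds
}

#' Exhaustive Euclidean k-nearest-neighbour prediction
#'
#' Linear search over the training set. The predicted label is the
#' majority among the `nn` nearest training instances; ties are broken by
#' the smallest aggregate distance, then by first-seen class among the
#' neighbours. Probabilities are the class frequencies among the `nn`
#' neighbours.
#'
#' @param train_x,test_x numeric matrices over the same feature space.
#' @param train_y class label per training row.
#' @param nn neighbour count.
#' @param classes the full class set for the probability columns
#'   (defaults to the classes present in `train_y`).
#' @return A list with `labels` (predictions) and `prob` (instances x
#'   classes matrix).
#' @export
knn_predict <- function(train_x, train_y, test_x, nn = 1,
                        classes = NULL) {
  if (nrow(train_x) == 0L) stop("empty training set")
  classes <- classes %||% unique(train_y)
  nn <- min(nn, nrow(train_x))
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  d2[d2 < 0] <- 0
  prob <- matrix(0, nrow(test_x), length(classes),
                 dimnames = list(rownames(test_x), classes))
  labels <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    ord <- order(d2[i, ])[seq_len(nn)]
    nb <- train_y[ord]
    counts <- table(factor(nb, levels = unique(nb)))
    best <- names(counts)[counts == max(counts)]
    if (length(best) > 1L) {
      agg <- vapply(best, function(cl) sum(d2[i, ord[nb == cl]]),
                    numeric(1))
      best <- best[agg == min(agg)]
    }
    labels[i] <- best[1L]  # first-seen class among the neighbours
    tab <- table(factor(nb, levels = classes))
    prob[i, ] <- as.numeric(tab) / nn
  }
  list(labels = labels, prob = prob)
}

# ---- native random forest (no tree-ensemble package in the stack) -----

# One CART tree on a bootstrap sample; gini impurity, midpoint splits,
# `mtry` random features per node. Returned as a flat list of nodes.
.grow_tree <- function(x, y_int, n_classes, mtry, max_depth = 25L,
                       min_node = 2L) {
  nodes <- list()
  build <- function(idx, depth) {
    counts <- tabulate(y_int[idx], n_classes)
    node <- list(leaf = TRUE, prob = counts / sum(counts))
    if (depth >= max_depth || length(idx) < min_node ||
        sum(counts > 0L) == 1L) {
      nodes[[length(nodes) + 1L]] <<- node
      return(length(nodes))
    }
    feats <- sample.int(ncol(x), min(mtry, ncol(x)))
    best <- NULL
    n <- length(idx)
    for (f in feats) {
      xf <- x[idx, f]
      ord <- order(xf)
      xs <- xf[ord]
      cuts <- which(diff(xs) > 0)
      if (!length(cuts)) next
      onehot <- matrix(0L, n, n_classes)
      onehot[cbind(seq_len(n), y_int[idx][ord])] <- 1L
      cum <- apply(onehot, 2L, cumsum)
      nl <- seq_len(n)
      gl <- 1 - rowSums((cum / nl)^2)
      totals <- cum[n, ]
      nr <- n - nl
      right <- sweep(-cum, 2L, totals, "+")
      gr <- 1 - rowSums((right / pmax(nr, 1L))^2)
      cost <- (nl * gl + nr * gr) / n
      ci <- cuts[which.min(cost[cuts])]
      if (is.null(best) || cost[ci] < best$cost)
        best <- list(cost = cost[ci], feature = f,
                     cut = (xs[ci] + xs[ci + 1L]) / 2)
    }
    if (is.null(best)) {
      nodes[[length(nodes) + 1L]] <<- node
      return(length(nodes))
    }
    go_left <- x[idx, best$feature] <= best$cut
    left <- build(idx[go_left], depth + 1L)
    right <- build(idx[!go_left], depth + 1L)
    nodes[[length(nodes) + 1L]] <<- list(
      leaf = FALSE, feature = best$feature, cut = best$cut,
      left = left, right = right)
    length(nodes)
  }
  root <- build(seq_len(nrow(x)), 0L)
  list(nodes = nodes, root = root)
}

.tree_prob <- function(tree, x) {
  t(apply(x, 1L, function(row) {
    i <- tree$root
    repeat {
      nd <- tree$nodes[[i]]
      if (nd$leaf) return(nd$prob)
      i <- if (row[nd$feature] <= nd$cut) nd$left else nd$right
    }
  }))
}

.rf_fit <- function(x, y, n_trees, mtry, seed) {
  classes <- sort(unique(y))
  y_int <- match(y, classes)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(t) {
    boot <- sample.int(nrow(x), replace = TRUE)
    .grow_tree(x[boot, , drop = FALSE], y_int[boot], length(classes),
               mtry)
  })
  list(trees = trees, classes = classes)
}

.rf_prob <- function(model, x, classes) {
  acc <- matrix(0, nrow(x), length(model$classes))
  for (tr in model$trees)
    acc <- acc + .tree_prob(tr, x)
  acc <- acc / length(model$trees)
  out <- matrix(0, nrow(x), length(classes),
                dimnames = list(rownames(x), classes))
  out[, model$classes] <- acc
  out
}

.glmnet_fit <- function(x, y, ridge) {
  if (!requireNamespace("glmnet", quietly = TRUE))
    stop("the multinomial-logistic family needs the 'glmnet' package")
  if (length(unique(y)) < 2L)
    return(list(degenerate = TRUE, class = y[1L]))
  # glmnet needs >= 2 columns; pad constant column if necessary
  if (ncol(x) < 2L) x <- cbind(x, 0)
  # tiny conspecific classes are the norm for barcode data; glmnet's
  # small-class warning would fire on nearly every fold
  fit <- suppressWarnings(
    glmnet::glmnet(x, factor(y), family = "multinomial",
                   alpha = 0, lambda = ridge, standardize = FALSE))
  list(degenerate = FALSE, fit = fit, p = ncol(x))
}

.glmnet_prob <- function(model, x, classes) {
  out <- matrix(0, nrow(x), length(classes),
                dimnames = list(rownames(x), classes))
  if (model$degenerate) {
    out[, model$class] <- 1
    return(out)
  }
  if (ncol(x) < model$p) x <- cbind(x, 0)
  pr <- stats::predict(model$fit, x, type = "response")[, , 1L]
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L,
                                     dimnames = list(NULL, rownames(pr)))
  out[, colnames(pr)] <- pr
  out
}

# Fit/predict dispatch on a ClassifierSpec.
.fit_predict <- function(spec, train_x, train_y, test_x, classes, seed) {
  switch(spec$family,
    "nearest-neighbor" =
      knn_predict(train_x, train_y, test_x, spec$nn, classes),
    "tree-ensemble" = {
      model <- .rf_fit(train_x, train_y, spec$n_trees, spec$mtry, seed)
      prob <- .rf_prob(model, test_x, classes)
      list(labels = classes[max.col(prob, ties.method = "first")],
           prob = prob)
    },
    "multinomial-logistic" = {
      model <- .glmnet_fit(train_x, train_y, spec$ridge)
      prob <- .glmnet_prob(model, test_x, classes)
      list(labels = classes[max.col(prob, ties.method = "first")],
           prob = prob)
    },
    "margin-based" = {
      model <- spec$fit(train_x, train_y)
      prob <- spec$predict_prob(model, test_x, classes)
      list(labels = classes[max.col(prob, ties.method = "first")],
           prob = prob)
    })
}

#' WEKA-style classification RMSE
#'
#' `sqrt( sum_i sum_c (p_ic - y_ic)^2 / (N * C) )` with `y` the one-hot
#' truth: squared error normalised per instance and class.
#'
#' @param prob instances x classes probability matrix.
#' @param truth true class label per instance (matching `colnames(prob)`).
#' @return A number in `[0, 1]`.
#' @export
classification_rmse <- function(prob, truth) {
  y <- matrix(0, nrow(prob), ncol(prob), dimnames = dimnames(prob))
  y[cbind(seq_len(nrow(prob)), match(truth, colnames(prob)))] <- 1
  sqrt(sum((prob - y)^2) / (nrow(prob) * ncol(prob)))
}

#' Cross-validated evaluation of a classifier
#'
#' Stratified k-fold cross-validation, optionally repeated with fresh
#' fold shuffles. Every instance is tested exactly once per repeat.
#' Per-class TPR/FPR and the species-level rollups are computed over all
#' pooled test predictions.
#'
#' @param fm a `FeatureMatrix`.
#' @param spec a [classifier_spec()].
#' @param n_folds folds per repeat.
#' @param repeats number of repeats (fold shuffles).
#' @param seed integer seed governing fold assignment and stochastic
#'   learners.
#' @return A `CVResult`: `accuracy_pct`, `rmse`, `fold_scores`
#'   (accuracy per fold x repeat, for paired comparison), `per_class`
#'   (TPR/FPR per species; FPR is `NA` flagged for a single-class input),
#'   `species_any_correct_pct`, `species_all_correct_pct`,
#'   `tpr1_species_pct`, `predictions` (pooled data.frame).
#' @export
evaluate_cv <- function(fm, spec, n_folds = 10, repeats = 1, seed = 1) {
  x <- fm$values
  labels <- fm$labels
  classes <- sort(unique(labels))
  n <- nrow(x)
  pred_lab <- character(0); pred_truth <- character(0)
  pred_id <- character(0); pred_repeat <- integer(0)
  prob_all <- NULL
  fold_scores <- numeric(0)
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(labels, n_folds, seed = seed + r - 1L)
    for (f in sort(unique(folds))) {
      test <- folds == f
      res <- .fit_predict(spec, x[!test, , drop = FALSE], labels[!test],
                          x[test, , drop = FALSE], classes,
                          seed = spec$seed + 7L * r + f)
      pred_lab <- c(pred_lab, res$labels)
      pred_truth <- c(pred_truth, labels[test])
      pred_id <- c(pred_id, fm$instance_ids[test])
      pred_repeat <- c(pred_repeat, rep(r, sum(test)))
      prob_all <- rbind(prob_all, res$prob)
      fold_scores <- c(fold_scores,
                       100 * mean(res$labels == labels[test]))
    }
  }
  correct <- pred_lab == pred_truth
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    is_cl <- pred_truth == cl
    pred_cl <- pred_lab == cl
    tn_fp <- sum(!is_cl)
    data.frame(class = cl,
               tpr = sum(pred_cl & is_cl) / sum(is_cl),
               fpr = if (tn_fp == 0L) NA_real_
                     else sum(pred_cl & !is_cl) / tn_fp,
               n = sum(is_cl) / repeats,
               stringsAsFactors = FALSE)
  }))
  by_class <- split(correct, pred_truth)
  any_c <- vapply(by_class, any, logical(1))
  all_c <- vapply(by_class, all, logical(1))
  structure(list(
    classifier = spec$family,
    params = spec[c("nn", "n_trees", "ridge")],
    n_folds = n_folds, repeats = repeats, seed = seed,
    accuracy_pct = 100 * mean(correct),
    rmse = classification_rmse(prob_all, pred_truth),
    fold_scores = fold_scores,
    per_class = per_class,
    species_any_correct_pct = 100 * mean(any_c),
    species_all_correct_pct = 100 * mean(all_c),
    tpr1_species_pct = 100 * mean(per_class$tpr == 1),
    predictions = data.frame(record_id = pred_id, repeat_ = pred_repeat,
                             truth = pred_truth, predicted = pred_lab,
                             stringsAsFactors = FALSE),
    single_class = length(classes) == 1L),
    class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf(paste0(
    "CVResult [%s, %d-fold x %d]\n",
    "  accuracy %.2f%% (rmse %.4f)\n",
    "  species: %.2f%% any-correct, %.2f%% all-correct, ",
    "%.2f%% with TPR = 1\n"),
    x$classifier, x$n_folds, x$repeats, x$accuracy_pct, x$rmse,
    x$species_any_correct_pct, x$species_all_correct_pct,
    x$tpr1_species_pct))
  invisible(x)
}

#' Tabulate several CV results
#'
#' @param results list of `CVResult`s on the same dataset.
#' @param names row names (defaults to classifier families).
#' @return A data.frame, one row per result, in input order.
#' @export
evaluation_report <- function(results, names = NULL) {
  names <- names %||% vapply(results, `[[`, character(1), "classifier")
  data.frame(
    name = names,
    accuracy_pct = vapply(results, `[[`, numeric(1), "accuracy_pct"),
    rmse = vapply(results, `[[`, numeric(1), "rmse"),
    species_any_correct_pct =
      vapply(results, `[[`, numeric(1), "species_any_correct_pct"),
    species_all_correct_pct =
      vapply(results, `[[`, numeric(1), "species_all_correct_pct"),
    tpr1_species_pct =
      vapply(results, `[[`, numeric(1), "tpr1_species_pct"),
    stringsAsFactors = FALSE)
}
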