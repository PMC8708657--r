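test_that("stratified_folds balances classes across folds", {
  labels <- rep(c("A", "B"), each = 10)
  f <- stratified_folds(labels, 10, seed = 1)
  expect_equal(as.integer(table(f)), rep(2L, 10))
  per_fold <- table(f, labels)
  expect_true(all(per_fold == 1L))

  # singleton class appears in exactly one fold
  labels2 <- c(rep("A", 9), "solo")
  f2 <- stratified_folds(labels2, 5, seed = 3)
  expect_equal(length(unique(f2[labels2 == "solo"])), 1L)
  # every instance assigned
  expect_true(all(f2 %in% 1:5))

  expect_identical(stratified_folds(labels, 10, seed = 7),
                   stratified_folds(labels, 10, seed = 7))
  expect_error(stratified_folds(c("a", "b"), 3), "fewer instances")
})

test_that("knn_predict matches a brute-force distance sort", {
  train <- matrix(c(0, 0, 1, 0, 0, 1, 5, 5, 6, 5, 5, 6),
                  ncol = 2, byrow = TRUE)
  train_y <- rep(c("near", "far"), each = 3)
  test <- matrix(c(0.1, 0.1, 5.1, 5.1), ncol = 2, byrow = TRUE)
  out <- knn_predict(train, train_y, test, nn = 3)
  expect_equal(out$labels, c("near", "far"))
  expect_equal(unname(out$prob[1, "near"]), 1)

  # identical point, nn = 1
  one <- knn_predict(train, train_y, train[4, , drop = FALSE], nn = 1)
  expect_equal(one$labels, "far")
  expect_equal(unname(one$prob[1, "far"]), 1)

  # {A, A, B} neighbourhood -> A with probability 2/3
  ty <- c("A", "A", "B")
  tx <- matrix(c(0, 0, 0.2, 0, 10, 0), ncol = 2, byrow = TRUE)
  out3 <- knn_predict(tx, ty, matrix(c(0.05, 0), ncol = 2), nn = 3)
  expect_equal(out3$labels, "A")
  expect_equal(unname(out3$prob[1, "A"]), 2 / 3)

  # random data vs brute force
  set.seed(31)
  trx <- matrix(rnorm(40), ncol = 4)
  try_ <- sample(c("x", "y", "z"), 10, replace = TRUE)
  tex <- matrix(rnorm(20), ncol = 4)
  res <- knn_predict(trx, try_, tex, nn = 1)
  brute <- apply(tex, 1, function(p)
    try_[which.min(colSums((t(trx) - p)^2))])
  expect_equal(res$labels, unname(brute))

  expect_error(knn_predict(trx[0, , drop = FALSE], character(), tex, 1),
               "empty training")
})

test_that("evaluate_cv is exact on separable features and covers every instance", {
  g <- generate_dataset(n_species = 5, members_per_species = 4,
                        seq_length = 300, intra_divergence = 0.005,
                        inter_divergence = 0.1, seed = 6)
  fm <- spectrum_features(g$dataset, 4)
  cv <- evaluate_cv(fm, classifier_spec("nearest-neighbor", nn = 1),
                    n_folds = 10, seed = 2)
  expect_equal(cv$accuracy_pct, 100)
  expect_equal(cv$rmse, 0)
  expect_true(all(cv$per_class$tpr == 1))
  expect_equal(sort(cv$predictions$record_id), sort(fm$instance_ids))
  expect_equal(length(cv$fold_scores), 10L)

  # repeats: every instance tested once per repeat
  cv2 <- evaluate_cv(fm, classifier_spec("nearest-neighbor", nn = 1),
                     n_folds = 5, repeats = 3, seed = 2)
  expect_equal(as.integer(table(cv2$predictions$record_id)),
               rep(3L, n_records(g$dataset)))
  expect_equal(length(cv2$fold_scores), 15L)
})

test_that("rmse semantics: zero iff all mass on truth; uniform binary gives 0.5", {
  prob <- diag(2)[c(1, 2, 1, 2), ]
  colnames(prob) <- c("a", "b")
  expect_equal(classification_rmse(prob, c("a", "b", "a", "b")), 0)
  uni <- matrix(0.5, 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(classification_rmse(uni, c("a", "b", "a", "b")), 0.5)
  expect_gt(classification_rmse(prob, c("b", "a", "a", "b")), 0)
})

test_that("native random forest and ridge logistic separate planted classes", {
  skip_if_not_installed("glmnet")
  g <- generate_dataset(n_species = 4, members_per_species = 5,
                        seq_length = 200, intra_divergence = 0.005,
                        inter_divergence = 0.15, seed = 12)
  fm <- spectrum_features(g$dataset, 3)
  rf <- evaluate_cv(fm, classifier_spec("tree-ensemble", n_trees = 25),
                    n_folds = 5, seed = 4)
  expect_gte(rf$accuracy_pct, 90)
  mcc <- evaluate_cv(fm, classifier_spec("multinomial-logistic"),
                     n_folds = 5, seed = 4)
  expect_gte(mcc$accuracy_pct, 90)
})

test_that("neighbourhood purity: larger nn keeps a gapped dataset at 100%", {
  g <- generate_dataset(n_species = 4, members_per_species = 6,
                        seq_length = 300, intra_divergence = 0.005,
                        inter_divergence = 0.12, seed = 5)
  fm <- spectrum_features(g$dataset, 4)
  for (nn in c(1, 3, 5)) {
    cv <- evaluate_cv(fm, classifier_spec("nearest-neighbor", nn = nn),
                      n_folds = 6, seed = 1)
    expect_equal(cv$accuracy_pct, 100)
  }
})

test_that("margin-based family is a pluggable contract", {
  expect_error(classifier_spec("margin-based"), "pluggable")
  # a trivial plug-in: always predicts the majority training class
  spec <- classifier_spec(
    "margin-based",
    fit = function(x, y) names(which.max(table(y))),
    predict_prob = function(model, x, classes) {
      p <- matrix(0, nrow(x), length(classes),
                  dimnames = list(NULL, classes))
      p[, model] <- 1
      p
    })
  fm <- spectrum_features(toy_dataset(rep(c("AAAA", "TTTT"), 3),
                                      rep(c("a", "b"), 3),
                                      aligned = FALSE), 2)
  cv <- evaluate_cv(fm, spec, n_folds = 3, seed = 1)
  expect_true(cv$accuracy_pct <= 100)
  expect_equal(nrow(cv$per_class), 2L)
})

test_that("evaluation_report keeps input order and fields", {
  g <- generate_dataset(n_species = 3, members_per_species = 4,
                        seq_length = 100, seed = 8)
  fm <- spectrum_features(g$dataset, 2)
  r1 <- evaluate_cv(fm, classifier_spec("nearest-neighbor", nn = 1),
                    n_folds = 4)
  r3 <- evaluate_cv(fm, classifier_spec("nearest-neighbor", nn = 3),
                    n_folds = 4)
  tab <- evaluation_report(list(r3, r1), names = c("knn3", "knn1"))
  expect_equal(tab$name, c("knn3", "knn1"))
  expect_true(all(tab$accuracy_pct >= tab$species_all_correct_pct - 1e-9))
})
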