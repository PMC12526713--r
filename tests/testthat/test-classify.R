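two_clouds <- function(n = 50, sep = 6, d = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * d), n, d),
             matrix(rnorm(n * d, mean = sep), n, d))
  colnames(X) <- paste0("f", 1:d)
  list(X = X, y = rep(c("success", "failure"), each = n))
}

test_that("confusion-matrix metrics match hand arithmetic", {
  m <- classify_metrics(tp = 10, fn = 2, fp = 3, tn = 5)
  expect_equal(unname(m["accuracy"]), 0.75)
  expect_equal(unname(m["sensitivity"]), 10 / 12, tolerance = 1e-12)
  expect_equal(unname(m["specificity"]), 0.625)
  expect_equal(unname(m["f_score"]), 0.8, tolerance = 1e-12)
  expect_true(all(classify_metrics(5, 0, 0, 5) == 1))
  allpos <- classify_metrics(tp = 5, fn = 0, fp = 5, tn = 0)
  expect_equal(unname(allpos["specificity"]), 0)
  expect_equal(unname(allpos["accuracy"]), 0.5)
  expect_true(is.na(classify_metrics(0, 0, 2, 2)["sensitivity"]))
})

test_that("all three classifiers separate well-separated clouds", {
  tc <- two_clouds()
  tr <- c(1:35, 51:85); te <- setdiff(1:100, tr)
  for (kind in c("naive_bayes", "knn", "svm")) {
    spec <- classifier_spec(kind, knn_metric = "euclidean")
    pred <- train_predict(spec, tc$X[tr, ], tc$y[tr], tc$X[te, ])
    expect_gte(mean(pred == tc$y[te]), 0.98)
  }
})

test_that("Naive Bayes matches its probabilistic definition and the e1071 reference", {
  # symmetric one-feature problem: the origin is the decision boundary
  X <- matrix(c(-2, -1, -1.5, 1, 1.5, 2), ncol = 1, dimnames = list(NULL, "f"))
  y <- rep(c("failure", "success"), each = 3)
  spec <- classifier_spec("naive_bayes")
  # a point far on either side is classified to that side
  expect_equal(train_predict(spec, X, y, matrix(c(-3, 3), ncol = 1)),
               c("failure", "success"))
  # cross-check on random data against the independent reference implementation
  tc <- two_clouds(n = 25, sep = 1.5, seed = 7)
  tr <- c(1:18, 26:43); te <- setdiff(1:50, tr)
  ours <- train_predict(spec, tc$X[tr, ], tc$y[tr], tc$X[te, ])
  ref <- e1071::naiveBayes(tc$X[tr, ], factor(tc$y[tr]))
  theirs <- as.character(predict(ref, tc$X[te, ]))
  expect_gte(mean(ours == theirs), 0.95)
})

test_that("KNN memorises with k = 1 and supports every catalogued metric", {
  tc <- two_clouds(n = 10, sep = 2, seed = 3)
  spec1 <- classifier_spec("knn", knn_k = 1, knn_metric = "euclidean")
  pred <- train_predict(spec1, tc$X, tc$y, tc$X[c(2, 15), ])
  expect_equal(pred, tc$y[c(2, 15)])
  for (met in c("cityblock", "chebyshev", "correlation", "cosine", "euclidean",
                "hamming", "jaccard", "mahalanobis", "minkowski", "spearman")) {
    spec <- classifier_spec("knn", knn_k = 3, knn_metric = met)
    p <- train_predict(spec, tc$X, tc$y, tc$X[1:4, ])
    expect_length(p, 4)
    expect_true(all(p %in% c("success", "failure")))
  }
})

test_that("repeated stratified evaluation is deterministic and behaves at the null", {
  tc <- two_clouds(n = 15, sep = 4, seed = 5)
  spec <- classifier_spec("naive_bayes")
  r1 <- evaluate(tc$X, tc$y, spec, n_runs = 50, seed = 9)
  r2 <- evaluate(tc$X, tc$y, spec, n_runs = 50, seed = 9)
  expect_identical(r1$mean, r2$mean)
  expect_identical(r1$confusion, r2$confusion)
  expect_gte(r1$mean["accuracy"], 0.95)
  # permuted labels: chance-level accuracy
  set.seed(10)
  ynull <- sample(tc$y)
  rn <- evaluate(tc$X, ynull, spec, n_runs = 200, seed = 11)
  expect_lt(abs(rn$mean["accuracy"] - 0.5), 0.1)
  # more runs shrink the SD of the mean estimate's spread across seeds
  sd50 <- sd(vapply(1:6, function(s) evaluate(tc$X, tc$y, spec, 50, seed = s)$mean["accuracy"], 0))
  sd400 <- sd(vapply(1:6, function(s) evaluate(tc$X, tc$y, spec, 400, seed = s)$mean["accuracy"], 0))
  expect_lt(sd400, sd50 + 1e-9)
})

test_that("backward elimination removes uninformative features first", {
  set.seed(12)
  n <- 30
  X <- cbind(inf1 = c(rnorm(n), rnorm(n, 3)),
             inf2 = c(rnorm(n), rnorm(n, 3)),
             noise = rnorm(2 * n))
  y <- rep(c("success", "failure"), each = n)
  spec <- classifier_spec("naive_bayes")
  hits <- vapply(1:10, function(s) {
    e <- sequential_backward_elimination(X, y, spec, n_runs = 40, seed = s)
    e$trace$removed[2] == "noise"
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  e <- sequential_backward_elimination(X, y, spec, n_runs = 40, seed = 1)
  expect_equal(nrow(e$trace), 3) # full set + 2 eliminations, stops at 1 feature
  expect_gte(e$best_accuracy, e$trace$accuracy[1] - 1e-12) # never worse than full set
  # deterministic given the seed, even with duplicated features
  X2 <- cbind(a = X[, 1], b = X[, 1], c = X[, 3])
  t1 <- sequential_backward_elimination(X2, y, spec, n_runs = 40, seed = 2)$trace
  t2 <- sequential_backward_elimination(X2, y, spec, n_runs = 40, seed = 2)$trace
  expect_identical(t1, t2)
})
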