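#' Classifier specification
#'
#' @param kind `"naive_bayes"`, `"knn"` or `"svm"`.
#' @param knn_k Number of neighbours (odd, >= 1).
#' @param knn_metric One of `"cityblock"`, `"chebyshev"`, `"correlation"`,
#'   `"cosine"`, `"euclidean"`, `"hamming"`, `"jaccard"`, `"mahalanobis"`,
#'   `"minkowski"`, `"spearman"`.
#' @param minkowski_p Exponent for the Minkowski metric.
#' @param svm_degree Polynomial kernel degree (default 5).
#' @param svm_cost Regularisation constant.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("naive_bayes", "knn", "svm"),
                            knn_k = 5, knn_metric = "spearman", minkowski_p = 3,
                            svm_degree = 5, svm_cost = 1) {
  kind <- match.arg(kind)
  knn_metric <- match.arg(knn_metric,
                          c("cityblock", "chebyshev", "correlation", "cosine",
                            "euclidean", "hamming", "jaccard", "mahalanobis",
                            "minkowski", "spearman"))
  if (knn_k < 1 || knn_k %% 2 == 0) stop("knn_k must be odd and >= 1")
  if (svm_degree < 1) stop("svm_degree must be >= 1")
  structure(list(kind = kind, knn_k = knn_k, knn_metric = knn_metric,
                 minkowski_p = minkowski_p, svm_degree = svm_degree,
                 svm_cost = svm_cost), class = "classifier_spec")
}

# Gaussian Naive Bayes: log prior + sum of per-feature log likelihoods.
# Zero within-class variances are floored at 1e-9 x the pooled feature
# variance so degenerate features cannot produce infinite densities.
nb_fit <- function(X, y) {
  cls <- sort(unique(y))
  pooled <- apply(X, 2, stats::var)
  pooled[pooled == 0 | !is.finite(pooled)] <- 1
  fit <- lapply(cls, function(c0) {
    Xi <- X[y == c0, , drop = FALSE]
    mu <- colMeans(Xi)
    v <- apply(Xi, 2, stats::var)
    v[!is.finite(v)] <- 0
    floorv <- 1e-9 * pooled
    list(mu = mu, var = pmax(v, floorv), logprior = log(nrow(Xi) / nrow(X)))
  })
  names(fit) <- cls
  fit
}

nb_predict <- function(fit, X) {
  scores <- vapply(fit, function(f) {
    f$logprior + rowSums(
      -0.5 * log(2 * pi * rep(1, nrow(X)) %o% f$var) -
        0.5 * sweep(X, 2, f$mu, "-")^2 / (rep(1, nrow(X)) %o% f$var))
  }, numeric(nrow(X)))
  if (nrow(X) == 1) scores <- matrix(scores, 1)
  names(fit)[max.col(scores, ties.method = "first")]
}

# pairwise distances between rows of A (test) and B (train)
knn_dist <- function(A, B, metric, p = 3, cov_train = NULL) {
  switch(metric,
    euclidean = sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)),
    cityblock = apply(B, 1, function(b) colSums(abs(t(A) - b))),
    chebyshev = apply(B, 1, function(b) apply(abs(sweep(A, 2, b, "-")), 1, max)),
    minkowski = apply(B, 1, function(b) colSums(abs(t(A) - b)^p)^(1 / p)),
    correlation = 1 - stats::cor(t(A), t(B)),
    spearman = 1 - stats::cor(t(A), t(B), method = "spearman"),
    cosine = {
      num <- A %*% t(B)
      1 - num / (sqrt(rowSums(A^2)) %o% sqrt(rowSums(B^2)))
    },
    hamming = apply(B, 1, function(b) colMeans(t(A) != b)),
    jaccard = apply(B, 1, function(b) {
      az <- t(A) != 0; bz <- b != 0
      mism <- (t(A) != b) & (az | bz)
      den <- colSums(az | bz); den[den == 0] <- 1
      colSums(mism) / den
    }),
    mahalanobis = {
      S <- cov_train + diag(1e-6 * mean(diag(cov_train)), ncol(B))
      Si <- solve(S)
      apply(B, 1, function(b) {
        d <- sweep(A, 2, b, "-")
        sqrt(rowSums((d %*% Si) * d))
      })
    },
    stop("unknown metric"))
}

knn_predict <- function(Xtr, ytr, Xte, k, metric, p = 3) {
  D <- knn_dist(Xte, Xtr, metric, p,
                cov_train = if (metric == "mahalanobis") stats::cov(Xtr))
  D <- matrix(D, nrow = nrow(Xte))
  apply(D, 1, function(d) {
    nn <- order(d)[seq_len(min(k, length(d)))]
    tab <- tapply(rep(1, length(nn)), ytr[nn], sum)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) return(top)
    # tie: class with the smaller distance sum among the neighbours
    sums <- vapply(top, function(c0) sum(d[nn][ytr[nn] == c0]), 0)
    top[which.min(sums)]
  })
}

#' Train a classifier and predict test labels
#'
#' Naive Bayes uses per-class independent Gaussians on the raw features;
#' KNN (majority vote among the k nearest under the configured metric,
#' ties resolved toward the smaller distance sum) and the
#' polynomial-kernel SVM (via [e1071::svm()]) operate on features z-scored
#' with training-fold statistics.
#'
#' @param spec A [classifier_spec()].
#' @param X_train,X_test Numeric matrices (rows = patients).
#' @param y_train Character labels (`"success"`/`"failure"`).
#' @return Character vector of predicted test labels.
#' @export
train_predict <- function(spec, X_train, y_train, X_test) {
  stopifnot(length(unique(y_train)) == 2)
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (spec$kind == "naive_bayes")
    return(nb_predict(nb_fit(X_train, y_train), X_test))
  ctr <- colMeans(X_train)
  scl <- apply(X_train, 2, stats::sd)
  Xtr <- zscore_cols(X_train, ctr, scl)
  Xte <- zscore_cols(X_test, ctr, scl)
  if (spec$kind == "knn")
    return(knn_predict(Xtr, y_train, Xte, spec$knn_k, spec$knn_metric, spec$minkowski_p))
  fit <- e1071::svm(Xtr, factor(y_train), kernel = "polynomial",
                    degree = spec$svm_degree, cost = spec$svm_cost,
                    coef0 = 1, scale = FALSE)
  as.character(stats::predict(fit, Xte))
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' Weaning success is the positive class: sensitivity = TP/(TP+FN) on
#' success, specificity = TN/(TN+FP) on failure, and the F-score is the
#' harmonic mean of precision and sensitivity. Undefined ratios (zero
#' denominators) are `NA`.
#'
#' @param tp,fn,fp,tn Confusion counts (positive = success).
#' @return Named vector `c(accuracy, specificity, sensitivity, f_score)`.
#' @export
classify_metrics <- function(tp, fn, fp, tn) {
  total <- tp + fn + fp + tn
  stopifnot(total > 0)
  acc <- (tp + tn) / total
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  c(accuracy = acc, specificity = spec, sensitivity = sens, f_score = f)
}

#' Repeated stratified split evaluation
#'
#' Repeats `n_runs` times: stratified random train/test split (default
#' 70/30), train, predict, compute the four metrics; reports their mean
#' and SD over runs plus the summed confusion matrix. Runs whose metric is
#' undefined (zero denominator) are excluded from that metric's average
#' with a count.
#'
#' @param X Numeric feature matrix (rows = patients).
#' @param y Labels (`"success"`/`"failure"`, both classes >= 2 members).
#' @param spec A [classifier_spec()].
#' @param n_runs Number of repeated splits.
#' @param split_frac Training fraction.
#' @param seed Integer seed; the report is deterministic given it.
#' @return Object of class `eval_report`: per-metric `mean` and `sd`,
#'   `confusion` (summed 2x2), `n_runs`, `seed`, `n_undefined`.
#' @export
evaluate <- function(X, y, spec, n_runs = 1000, split_frac = 0.7, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(n_runs >= 1, sum(y == "success") >= 2, sum(y == "failure") >= 2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i_s <- which(y == "success"); i_f <- which(y == "failure")
  n_tr_s <- max(1L, min(length(i_s) - 1L, round(split_frac * length(i_s))))
  n_tr_f <- max(1L, min(length(i_f) - 1L, round(split_frac * length(i_f))))
  mets <- matrix(NA_real_, n_runs, 4)
  conf <- c(tp = 0, fn = 0, fp = 0, tn = 0)
  for (r in seq_len(n_runs)) {
    tr <- c(sample(i_s, n_tr_s), sample(i_f, n_tr_f))
    te <- setdiff(seq_along(y), tr)
    pred <- train_predict(spec, X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE])
    truth <- y[te]
    cc <- c(tp = sum(pred == "success" & truth == "success"),
            fn = sum(pred == "failure" & truth == "success"),
            fp = sum(pred == "success" & truth == "failure"),
            tn = sum(pred == "failure" & truth == "failure"))
    conf <- conf + cc
    mets[r, ] <- classify_metrics(cc["tp"], cc["fn"], cc["fp"], cc["tn"])
  }
  colnames(mets) <- c("accuracy", "specificity", "sensitivity", "f_score")
  structure(list(
    mean = colMeans(mets, na.rm = TRUE),
    sd = apply(mets, 2, stats::sd, na.rm = TRUE),
    confusion = conf, n_runs = n_runs, seed = seed,
    n_undefined = colSums(is.na(mets)),
    classifier = spec$kind
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s over %d runs (seed %d)\n", x$classifier, x$n_runs, x$seed))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m, x$mean[m], x$sd[m]))
  cat("  confusion (summed): TP", x$confusion["tp"], "FN", x$confusion["fn"],
      "FP", x$confusion["fp"], "TN", x$confusion["tn"], "\n")
  invisible(x)
}

#' Sequential backward feature elimination
#'
#' At each step every remaining feature's removal is scored by
#' [evaluate()] (all candidates at a step share the same splits via a
#' common derived seed) and the feature whose removal yields the highest
#' mean accuracy — the one with the least impact — is eliminated, down to
#' a single feature. Returns the full elimination trace and the attribute
#' set with the best mean accuracy anywhere along it.
#'
#' @param X Feature matrix with column names.
#' @param y Labels.
#' @param spec A [classifier_spec()].
#' @param n_runs Runs per candidate evaluation (default 100).
#' @param split_frac Training fraction.
#' @param seed Integer seed.
#' @return List with `trace` (data frame: step, removed, accuracy of the
#'   remaining set), `best_set` (character), `best_accuracy`.
#' @export
sequential_backward_elimination <- function(X, y, spec, n_runs = 100,
                                            split_frac = 0.7, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2, !is.null(colnames(X)))
  cur <- colnames(X)
  acc_full <- evaluate(X, y, spec, n_runs, split_frac, derive_seed(seed, 0))$mean["accuracy"]
  trace <- data.frame(step = 0L, removed = NA_character_, accuracy = acc_full,
                      n_features = length(cur), stringsAsFactors = FALSE)
  sets <- list(cur)
  step <- 0L
  while (length(cur) > 1) {
    step <- step + 1L
    seed_k <- derive_seed(seed, step)
    accs <- vapply(cur, function(f) {
      evaluate(X[, setdiff(cur, f), drop = FALSE], y, spec,
               n_runs, split_frac, seed_k)$mean["accuracy"]
    }, 0)
    drop <- cur[which.max(accs)] # ties: first (lowest catalogue index)
    cur <- setdiff(cur, drop)
    trace <- rbind(trace, data.frame(step = step, removed = drop,
                                     accuracy = max(accs), n_features = length(cur)))
    sets[[step + 1L]] <- cur
  }
  best <- which.max(trace$accuracy)
  list(trace = trace, best_set = sets[[best]], best_accuracy = trace$accuracy[best])
}
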