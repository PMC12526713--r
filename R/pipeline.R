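#' Extract the 80 base parameter series for one recording
#'
#' Runs preprocessing, derived-signal computation and the time-varying
#' spectral, coherence and entropy parameterisation, returning the merged
#' windows x 80 matrix of base parameters for the patient.
#'
#' @param rec A [wean_recording()].
#' @param cfg A [wean_config()].
#' @return A `wean_params` object whose `values` matrix has the 80
#'   canonical base columns; the selected channel/lead pair and SNRs are
#'   attached as attributes. Feed a list of these to
#'   [build_feature_matrix()].
#' @export
extract_params <- function(rec, cfg = wean_config()) {
  clean <- preprocess_recording(rec, cfg)
  dset <- derive_signals(clean, cfg)
  sp <- windowed_params(dset, cfg)
  en <- windowed_entropy(dset, cfg)
  values <- cbind(sp$values, en$values)
  out <- structure(list(window_start = sp$window_start, values = values,
                        patient_id = rec$patient_id, group = rec$group),
                   class = "wean_params")
  attr(out, "channel") <- dset$channel
  attr(out, "lead") <- dset$lead
  attr(out, "xcorr") <- dset$xcorr
  attr(out, "snr") <- clean$snr
  out
}

#' Run the full weaning-classification pipeline
#'
#' Orchestrates every stage on a synthetic cohort: simulate, preprocess,
#' derive, parameterise (spectral/coherence/entropy), assemble the
#' patients x 320 feature matrix, select features (significance +
#' Spearman redundancy), and evaluate the requested classifiers on the
#' retained set over repeated stratified splits. All randomness fans out
#' deterministically from `spec$seed` and `seed`.
#'
#' @param spec A [cohort_spec()] describing the cohort to simulate, or a
#'   pre-generated list of [wean_recording()] objects.
#' @param cfg A [wean_config()].
#' @param classifiers Character subset of
#'   `c("naive_bayes", "knn", "svm")`.
#' @param eliminate If `TRUE`, run sequential backward elimination for
#'   each classifier on the retained features and evaluate its best set.
#' @param seed Seed for the evaluation splits.
#' @param out_dir Optional directory; when given, the feature matrix,
#'   selection tables and a JSON report are written there.
#' @return List of class `wean_run`: `features` (data frame),
#'   `significance`, `selection`, `reports` (per classifier),
#'   `elimination` (if requested), `channel_pairs`, `snr`, `config`
#'   echo and `seed`.
#' @export
run_weaning_pipeline <- function(spec = cohort_spec(), cfg = wean_config(),
                                 classifiers = c("naive_bayes", "knn", "svm"),
                                 eliminate = FALSE, seed = 1L, out_dir = NULL) {
  classifiers <- match.arg(classifiers, c("naive_bayes", "knn", "svm"),
                           several.ok = TRUE)
  if (inherits(spec, "cohort_spec")) {
    # stream: generate, extract, discard one recording at a time
    groups <- c(rep("success", spec$n_success), rep("failure", spec$n_failure))
    message(sprintf("pipeline: %d recordings; window %gs/%.0f%% overlap; fa %g Hz",
                    length(groups), cfg$window_s, 100 * cfg$overlap, cfg$fa))
    params <- lapply(seq_along(groups), function(i) {
      rec <- generate_recording(spec, groups[i], sprintf("P%03d", i),
                                seed = derive_seed(spec$seed, i))
      extract_params(rec, cfg)
    })
  } else {
    message(sprintf("pipeline: %d recordings; window %gs/%.0f%% overlap; fa %g Hz",
                    length(spec), cfg$window_s, 100 * cfg$overlap, cfg$fa))
    params <- lapply(spec, extract_params, cfg = cfg)
  }
  catalog <- feature_catalog(cfg)
  features <- build_feature_matrix(params, catalog)
  sig <- significance_filter(features, cfg$alpha)
  sel <- spearman_filter(features, sig, cfg$rho_max)
  message(sprintf("selection: %d/%d significant, %d retained after |rho|<%g",
                  sum(sig$significant), nrow(sig), length(sel$retained), cfg$rho_max))
  reports <- list(); elim <- list()
  if (length(sel$retained) >= 1 &&
      sum(features$group == "success") >= 2 && sum(features$group == "failure") >= 2) {
    X <- as.matrix(features[sel$retained])
    y <- features$group
    for (k in classifiers) {
      cs <- classifier_spec(k, knn_k = cfg$knn_k, knn_metric = cfg$knn_metric,
                            svm_degree = cfg$svm_degree, svm_cost = cfg$svm_cost)
      if (eliminate && ncol(X) >= 2) {
        e <- sequential_backward_elimination(X, y, cs, n_runs = 100,
                                             split_frac = cfg$split_frac,
                                             seed = derive_seed(seed, match(k, classifiers)))
        elim[[k]] <- e
        Xk <- X[, e$best_set, drop = FALSE]
      } else Xk <- X
      reports[[k]] <- evaluate(Xk, y, cs, n_runs = cfg$n_runs,
                               split_frac = cfg$split_frac,
                               seed = derive_seed(seed, 100 + match(k, classifiers)))
    }
  }
  run <- structure(list(
    features = features,
    significance = sig,
    selection = sel,
    reports = reports,
    elimination = if (eliminate) elim,
    channel_pairs = data.frame(
      patient_id = vapply(params, function(p) p$patient_id, ""),
      channel = vapply(params, function(p) attr(p, "channel"), 0),
      lead = vapply(params, function(p) attr(p, "lead"), 0),
      xcorr = vapply(params, function(p) attr(p, "xcorr"), 0)),
    snr = t(vapply(params, function(p) attr(p, "snr"), numeric(8))),
    config = cfg, seed = seed
  ), class = "wean_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_features(features, file.path(out_dir, "features.csv"))
    utils::write.csv(sig, file.path(out_dir, "significance.csv"), row.names = FALSE)
    writeLines(sel$retained, file.path(out_dir, "retained_features.txt"))
    jsonlite::write_json(lapply(reports, function(r)
      list(mean = as.list(r$mean), sd = as.list(r$sd),
           confusion = as.list(r$confusion), n_runs = r$n_runs)),
      file.path(out_dir, "eval_report.json"), auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.wean_run <- function(x, ...) {
  cat(sprintf("<wean_run> %d patients, %d features\n", nrow(x$features),
              ncol(x$features) - 2))
  cat(sprintf("  significant: %d   retained: %d\n",
              sum(x$significance$significant), length(x$selection$retained)))
  for (k in names(x$reports))
    cat(sprintf("  %-12s accuracy %.3f +/- %.3f\n", k,
                x$reports[[k]]$mean["accuracy"], x$reports[[k]]$sd["accuracy"]))
  invisible(x)
}
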