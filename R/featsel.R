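#' Canonical feature catalogue
#'
#' The 80 base parameter names — 40 spectral (5 band descriptors x 2 bands
#' x 4 signals), 24 coherence (6 descriptors x 4 pairs), 8 fixed-frequency
#' coherence values (2 frequencies x 4 pairs) and 8 entropy (SampEn/ApEn x
#' 4 signals) — and the 320 feature names obtained by crossing each base
#' parameter with the four summary statistics mean, CV, kurtosis and IQR.
#'
#' @param cfg A [wean_config()] (fixed coherence frequencies are read from
#'   it).
#' @return List with `base` (80 names) and `features` (320 names).
#' @export
feature_catalog <- function(cfg = wean_config()) {
  spect <- as.vector(vapply(.dsig_names, function(sig)
    as.vector(vapply(c("LF", "HF"), function(bn)
      paste0(c("Hp", "P", "Fp", "Us", "Ds"), bn, sig), character(5))), character(10)))
  coh <- as.vector(vapply(names(.coh_pairs), function(pn)
    paste0(c("Pcoh", "RMScoh", "Fpcoh", "Hpcoh", "Uscoh", "Dscoh"), pn), character(6)))
  fixed <- as.vector(vapply(names(.coh_pairs), function(pn)
    sprintf("Hpcoh%s(%gHz)", pn, cfg$coh_fixed_freqs), character(length(cfg$coh_fixed_freqs))))
  entr <- c(paste0("SampEn", .dsig_names), paste0("ApEn", .dsig_names))
  base <- c(spect, coh, fixed, entr)
  stopifnot(!anyDuplicated(base))
  feats <- as.vector(vapply(base, function(b)
    paste0(c("mean_", "CV_", "kurt_", "IQR_"), b), character(4)))
  list(base = base, features = feats)
}

#' Summary statistics of a parameter time series
#'
#' The four distribution summaries applied to every windowed parameter
#' series: mean; coefficient of variation `CV = s / mean` (with `s` the
#' sample SD); kurtosis `sum((x - mean)^4) / (n s^4)`; and the
#' interquartile range `Q3 - Q1` with quartiles by linear interpolation of
#' order statistics (type 7). `CV` is `NA` when the mean is negligible
#' relative to `s`; kurtosis is `NA` for a constant series.
#'
#' @param x Numeric vector (>= 2 finite values).
#' @return Named vector `c(mean, CV, kurt, IQR)`.
#' @export
summarize_series <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 finite values")
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  cv <- if (abs(m) < 1e-12 * s) NA_real_ else s / m
  kurt <- if (s == 0) NA_real_ else sum((x - m)^4) / (n * s^4)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  c(mean = m, CV = cv, kurt = kurt, IQR = q[2] - q[1])
}

#' Assemble the patient x 320 feature matrix
#'
#' Applies the four summary statistics to each of the 80 base parameter
#' time series per patient, producing a data frame with `patient_id`,
#' `group`, and the 320 canonical feature columns.
#'
#' @param param_list List with one element per patient, each a
#'   windows x 80 matrix of base parameter values (spectral + coherence
#'   + entropy columns merged), carrying `patient_id` and `group`
#'   attributes, as produced by [extract_params()] or by `cbind`-ing
#'   [windowed_params()] and [windowed_entropy()] values.
#' @param catalog A [feature_catalog()].
#' @return Data frame, one row per patient, 2 + 320 columns.
#' @export
build_feature_matrix <- function(param_list, catalog = feature_catalog()) {
  rows <- lapply(param_list, function(p) {
    vals <- if (inherits(p, "wean_params")) p$values else p
    pid <- attr(p, "patient_id", exact = TRUE) %||% p$patient_id
    grp <- attr(p, "group", exact = TRUE) %||% p$group
    missing <- setdiff(catalog$base, colnames(vals))
    if (length(missing))
      stop("patient ", pid, " missing base parameter(s): ",
           paste(missing, collapse = ", "))
    feat <- unlist(lapply(catalog$base, function(b) {
      v <- summarize_series(vals[, b])
      names(v) <- paste0(c("mean_", "CV_", "kurt_", "IQR_"), b)
      v
    }))
    c(list(patient_id = pid, group = grp), as.list(feat))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  rownames(out) <- NULL
  stopifnot(ncol(out) == 2 + length(catalog$features))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group-difference significance filter
#'
#' Per-feature two-sided Mann-Whitney U test between the success and
#' failure groups; features with `p < alpha` are retained. No
#' multiple-testing correction is applied (raw alpha). Constant features
#' get `p = 1` by convention.
#'
#' @param mat Feature data frame from [build_feature_matrix()].
#' @param alpha Significance level (default 0.05).
#' @return Data frame `name`, `p`, `significant`, ordered as the input
#'   columns.
#' @export
significance_filter <- function(mat, alpha = 0.05) {
  feat <- setdiff(names(mat), c("patient_id", "group"))
  g <- mat$group
  stopifnot(all(c("success", "failure") %in% g))
  p <- vapply(feat, function(f) {
    x <- mat[[f]][g == "success"]; y <- mat[[f]][g == "failure"]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 1 || length(y) < 1) return(1)
    if (stats::sd(c(x, y)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }, 0)
  data.frame(name = feat, p = p, significant = p < alpha, row.names = NULL)
}

#' Correlation-redundancy filter
#'
#' Greedy elimination on the Spearman correlation matrix of the
#' significant features: while any pair has `|rho| >= rho_max`, the member
#' of a violating pair with the larger mean absolute correlation to all
#' other remaining features is dropped (ties broken toward the larger
#' significance p-value, then the later catalogue position). The retained
#' set has all pairwise `|rho| < rho_max`.
#'
#' @param mat Feature data frame.
#' @param sig Result of [significance_filter()].
#' @param rho_max Correlation threshold (default 0.6).
#' @return List with `retained` (names), `dropped` (names in drop order),
#'   and the Spearman matrix `rho` of the significant set.
#' @export
spearman_filter <- function(mat, sig, rho_max = 0.6) {
  keep <- sig$name[sig$significant]
  if (!length(keep)) return(list(retained = character(0), dropped = character(0), rho = NULL))
  X <- as.matrix(mat[keep])
  rho <- suppressWarnings(stats::cor(X, method = "spearman", use = "pairwise.complete.obs"))
  rho[is.na(rho)] <- 0
  pv <- stats::setNames(sig$p, sig$name)
  cur <- keep
  dropped <- character(0)
  repeat {
    r <- abs(rho[cur, cur, drop = FALSE])
    diag(r) <- 0
    if (all(r < rho_max)) break
    viol <- unique(rownames(which(r >= rho_max, arr.ind = TRUE)))
    mean_r <- rowMeans(r[viol, , drop = FALSE])
    worst <- viol[order(-mean_r, -pv[viol], -match(viol, keep))][1]
    dropped <- c(dropped, worst)
    cur <- setdiff(cur, worst)
    if (length(cur) <= 1) break
  }
  list(retained = cur, dropped = dropped, rho = rho)
}
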