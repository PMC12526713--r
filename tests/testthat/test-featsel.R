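test_that("the canonical catalogue has 80 base parameters and 320 features", {
  cat <- feature_catalog()
  expect_length(cat$base, 80)
  expect_length(cat$features, 320)
  expect_false(anyDuplicated(cat$base) > 0)
  expect_false(anyDuplicated(cat$features) > 0)
  # composition: 40 spectral + 24 coherence + 8 fixed-frequency + 8 entropy
  expect_length(grep("^(Hp|P|Fp|Us|Ds)(LF|HF)", cat$base), 40)
  expect_length(grep("^(Pcoh|RMScoh|Fpcoh|Hpcoh|Uscoh|Dscoh)", cat$base, value = TRUE) |>
                  grep(pattern = "Hz\\)$", invert = TRUE, value = TRUE), 24)
  expect_length(grep("Hz\\)$", cat$base), 8)
  expect_length(grep("^(SampEn|ApEn)", cat$base), 8)
})

test_that("summary statistics match hand-computed and formula oracles", {
  s <- summarize_series(c(2, 4, 4, 4, 5, 5, 7, 9))
  expect_equal(unname(s["mean"]), 5)
  expect_equal(unname(s["CV"]), sd(c(2, 4, 4, 4, 5, 5, 7, 9)) / 5, tolerance = 1e-12)
  expect_equal(unname(s["CV"]), 0.4276, tolerance = 1e-4)
  expect_equal(unname(s["IQR"]), unname(quantile(c(2, 4, 4, 4, 5, 5, 7, 9), 0.75) -
                                          quantile(c(2, 4, 4, 4, 5, 5, 7, 9), 0.25)))
  cst <- summarize_series(c(3, 3, 3))
  expect_equal(unname(cst["CV"]), 0)
  expect_equal(unname(cst["IQR"]), 0)
  expect_true(is.na(cst["kurt"]))
  # kurtosis by direct formula evaluation on random inputs
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(sample(5:50, 1))
    k_direct <- sum((x - mean(x))^4) / (length(x) * sd(x)^4)
    expect_equal(unname(summarize_series(x)["kurt"]), k_direct, tolerance = 1e-12)
  }
  expect_equal(unname(summarize_series(c(-1, 1, -1, 1))["kurt"]),
               sum(c(-1, 1, -1, 1)^4) / (4 * sd(c(-1, 1, -1, 1))^4))
  expect_error(summarize_series(3), "at least 2")
})

fake_params <- function(pid, group, nwin = 6, seed = 1) {
  cat <- feature_catalog()
  set.seed(seed)
  vals <- matrix(abs(rnorm(nwin * 80)) + 0.5, nwin, 80, dimnames = list(NULL, cat$base))
  structure(list(window_start = seq(0, by = 150, length.out = nwin),
                 values = vals, patient_id = pid, group = group),
            class = "wean_params")
}

test_that("the feature matrix is assembled in canonical order and validated", {
  ps <- list(fake_params("a", "success", seed = 1), fake_params("b", "failure", seed = 2))
  mat <- build_feature_matrix(ps)
  expect_equal(dim(mat), c(2, 322))
  expect_equal(names(mat)[3], "mean_HpLFEDR")
  # input order does not change content
  mat2 <- build_feature_matrix(rev(ps))
  expect_equal(mat2[order(mat2$patient_id), ], mat[order(mat$patient_id), ],
               ignore_attr = TRUE)
  broken <- ps
  broken[[1]]$values <- broken[[1]]$values[, -5]
  expect_error(build_feature_matrix(broken), "missing base parameter")
})

test_that("significance filter retains separated features and drops null ones", {
  set.seed(42)
  n <- 15
  mat <- data.frame(patient_id = sprintf("p%02d", 1:(2 * n)),
                    group = rep(c("success", "failure"), each = n))
  mat$same <- rnorm(2 * n)                       # null feature
  mat$const <- 1                                 # constant
  mat$disjoint <- c(rnorm(n), rnorm(n) + 100)    # disjoint supports
  sig <- significance_filter(mat, alpha = 0.05)
  expect_false(sig$significant[sig$name == "const"])
  expect_equal(sig$p[sig$name == "const"], 1)
  expect_true(sig$significant[sig$name == "disjoint"])
  expect_lt(sig$p[sig$name == "disjoint"], 0.001)
  # a feature identical in both groups is (almost) never retained
  expect_gt(sig$p[sig$name == "same"], 0.05 * 0.5)
})

test_that("Spearman filter greedily removes redundant features", {
  set.seed(43)
  n <- 40
  base <- rnorm(n)
  mat <- data.frame(patient_id = as.character(1:n),
                    group = rep(c("success", "failure"), n / 2))
  mat$A <- base
  mat$B <- exp(base)              # monotone transform: rho = 1
  mat$C <- rnorm(n)
  mat$D <- rnorm(n)
  mat$E <- rnorm(n)
  sig <- data.frame(name = c("A", "B", "C", "D", "E"),
                    p = c(0.01, 0.02, 0.01, 0.01, 0.01),
                    significant = TRUE)
  sel <- spearman_filter(mat, sig, rho_max = 0.6)
  expect_length(sel$retained, 4)           # exactly one of A/B dropped
  expect_length(intersect(sel$retained, c("A", "B")), 1)
  expect_true(all(c("C", "D", "E") %in% sel$retained))
  r <- abs(sel$rho[sel$retained, sel$retained]); diag(r) <- 0
  expect_true(all(r < 0.6))
  # independent features all survive
  mat2 <- mat[c("patient_id", "group", "C", "D", "E")]
  sig2 <- sig[sig$name %in% c("C", "D", "E"), ]
  expect_length(spearman_filter(mat2, sig2, 0.6)$retained, 3)
})
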