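# Independent brute-force entropy oracles: template-wise loops over the
# embedding, written without reference to the package's compiled kernels.

emb_rows <- function(x, m) {
  nvec <- length(x) - m + 1
  out <- matrix(0, nvec, m)
  for (l in 1:m) out[, l] <- x[l:(length(x) - m + l)]
  out
}

cheb_to <- function(E, row) { # Chebyshev distance of every row of E to `row`
  d <- abs(E[, 1] - row[1])
  for (l in seq_len(ncol(E))[-1]) d <- pmax(d, abs(E[, l] - row[l]))
  d
}

apen_oracle <- function(x, m, r) {
  phi <- function(k) {
    E <- emb_rows(x, k)
    nvec <- nrow(E)
    acc <- 0
    for (i in seq_len(nvec))
      acc <- acc + log(sum(cheb_to(E, E[i, ]) <= r) / nvec) # self-match included
    acc / nvec
  }
  phi(m) - phi(m + 1)
}

sampen_oracle <- function(x, m, r) {
  n <- length(x)
  Em <- emb_rows(x, m)[1:(n - m), , drop = FALSE] # templates with an extension
  nxt <- x[(m + 1):n]
  A <- 0; B <- 0
  for (i in 1:(nrow(Em) - 1)) {
    js <- (i + 1):nrow(Em)
    match_m <- cheb_to(Em[js, , drop = FALSE], Em[i, ]) <= r
    B <- B + sum(match_m)
    A <- A + sum(match_m & abs(nxt[js] - nxt[i]) <= r)
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# build a derived-signal set directly from series (bypasses the raw pipeline)
make_dset <- function(..., fa = 4, group = "unknown", patient_id = "T") {
  sigs <- list(...)
  stopifnot(all(c("EDR", "HRV", "EMGe", "EMGi") %in% names(sigs)))
  n <- length(sigs$EDR)
  structure(c(list(t = (seq_len(n) - 1) / fa), sigs,
              list(fa = fa, channel = 3L, lead = 2L, xcorr = NA_real_,
                   patient_id = patient_id, group = group)),
            class = "wean_derived")
}

# small fast cohort spec for plumbing tests
tiny_spec <- function(duration = 60, ...) {
  cohort_spec(n_success = 1, n_failure = 1, duration = duration, seed = 42, ...)
}
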