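#' Read and write weaning recordings
#'
#' Recordings are stored either as plain EDF (European Data Format, the
#' standard container for polysomnography/EMG) or as a self-describing
#' delimited text file. EDF stores samples as 16-bit integers with a
#' per-channel linear scaling, so round-trips are exact only to the
#' quantisation step (channel range / 65535); the delimited format
#' round-trips exactly.
#'
#' The EDF writer emits one 1-s data record per second, so recordings must
#' span a whole number of seconds. ECG leads are labelled `"ECG leadI"` ...
#' and sEMG channels `"EMG ch1"` ...; readers require at least the three
#' ECG and five EMG channels and never permute the canonical order.
#'
#' @param rec A [wean_recording()].
#' @param path File path.
#' @param format `"edf"` or `"delimited"`.
#' @return `read_recording()` returns a [wean_recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "delimited")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "wean_recording"))
  if (format == "edf") write_edf(rec, path) else write_rec_delim(rec, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, format = c("edf", "delimited")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "edf") read_edf(path) else read_rec_delim(path)
}

# ---- EDF ----------------------------------------------------------------

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  n_rec <- rec$duration
  if (abs(n_rec - round(n_rec)) > 1e-9)
    stop("EDF export requires a whole number of seconds")
  n_rec <- as.integer(round(n_rec))
  chans <- list()
  for (i in 1:3) chans[[i]] <- list(label = paste0("ECG lead", c("I", "II", "III")[i]),
                                    x = rec$ecg[, i], spr = as.integer(rec$fs_ecg))
  for (i in 1:5) chans[[3 + i]] <- list(label = paste0("EMG ch", i),
                                        x = rec$semg[, i], spr = as.integer(rec$fs_emg))
  ns <- length(chans)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + ns * 256L
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad(rec$patient_id, 80),
    edf_pad(paste("group:", rec$group), 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4)
  ), con, eos = NULL)
  pmin <- pmax <- numeric(ns)
  for (i in seq_len(ns)) {
    r <- range(chans[[i]]$x)
    if (diff(r) == 0) r <- r + c(0, 1) # constant channel: avoid zero gain
    pmin[i] <- r[1]; pmax[i] <- r[2]
  }
  field <- function(f, w) writeChar(paste(vapply(seq_len(ns), f, ""), collapse = ""),
                                    con, eos = NULL)
  fmt8 <- function(v) edf_pad(formatC(v, digits = 7, format = "g"), 8)
  field(function(i) edf_pad(chans[[i]]$label, 16), 16)
  field(function(i) edf_pad("", 80), 80)
  field(function(i) edf_pad("mV", 8), 8)
  field(function(i) fmt8(pmin[i]), 8)
  field(function(i) fmt8(pmax[i]), 8)
  field(function(i) edf_pad(-32768L, 8), 8)
  field(function(i) edf_pad(32767L, 8), 8)
  field(function(i) edf_pad("", 80), 80)
  field(function(i) edf_pad(chans[[i]]$spr, 8), 8)
  field(function(i) edf_pad("", 32), 32)
  # quantise each channel once, then interleave per 1-s record
  pmin_h <- as.numeric(edf_pad(formatC(pmin, digits = 7, format = "g"), 8))
  pmax_h <- as.numeric(edf_pad(formatC(pmax, digits = 7, format = "g"), 8))
  dig <- lapply(seq_len(ns), function(i) {
    g <- (pmax_h[i] - pmin_h[i]) / 65535
    d <- round((chans[[i]]$x - pmin_h[i]) / g) - 32768
    as.integer(pmin(pmax(d, -32768), 32767))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      spr <- chans[[i]]$spr
      idx <- ((r - 1L) * spr + 1L):(r * spr)
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  patient_id <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) trimws(readChar(con, w, useBytes = TRUE)), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  sig <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE, endian = "little")
      g <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      sig[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- pmin[i] + (d - dmin[i]) * g
    }
  }
  ecg_idx <- grep("^ECG", labels)
  emg_idx <- grep("^EMG", labels)
  if (length(ecg_idx) < 3 || length(emg_idx) < 5) stop("channel set incomplete")
  ecg_idx <- ecg_idx[1:3]; emg_idx <- emg_idx[1:5]
  fs_ecg <- spr[ecg_idx[1]] / rec_dur
  fs_emg <- spr[emg_idx[1]] / rec_dur
  group <- sub("^group:\\s*", "", rec_id)
  if (!group %in% c("success", "failure")) group <- "unknown"
  wean_recording(patient_id, group,
                 ecg = do.call(cbind, sig[ecg_idx]),
                 semg = do.call(cbind, sig[emg_idx]),
                 fs_ecg = fs_ecg, fs_emg = fs_emg)
}

# ---- delimited ----------------------------------------------------------

write_rec_delim <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# patient_id=", rec$patient_id),
    paste0("# group=", rec$group),
    paste0("# fs_ecg=", format(rec$fs_ecg, digits = 15)),
    paste0("# fs_emg=", format(rec$fs_emg, digits = 15)),
    "channel,value"
  ), con)
  for (ch in colnames(rec$ecg))
    writeLines(paste(ch, format(rec$ecg[, ch], digits = 17, trim = TRUE), sep = ","), con)
  for (ch in colnames(rec$semg))
    writeLines(paste(ch, format(rec$semg[, ch], digits = 17, trim = TRUE), sep = ","), con)
  invisible(path)
}

read_rec_delim <- function(path) {
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "#")]
  kv <- strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  need <- c("patient_id", "group", "fs_ecg", "fs_emg")
  if (!all(need %in% keys)) stop("delimited recording missing header keys")
  getv <- function(k) vals[match(k, keys)]
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  ecg_names <- c("leadI", "leadII", "leadIII")
  emg_names <- paste0("ch", 1:5)
  if (!all(ecg_names %in% tab$channel) || !all(emg_names %in% tab$channel))
    stop("channel set incomplete")
  pull <- function(nm) do.call(cbind, lapply(nm, function(ch) tab$value[tab$channel == ch]))
  wean_recording(getv("patient_id"), getv("group"),
                 ecg = pull(ecg_names), semg = pull(emg_names),
                 fs_ecg = as.numeric(getv("fs_ecg")),
                 fs_emg = as.numeric(getv("fs_emg")))
}

# ---- feature matrices ---------------------------------------------------

#' Read and write feature matrices
#'
#' Feature matrices are plain comma-delimited tables: one row per patient,
#' a `patient_id` and a `group` column, then one column per feature in
#' canonical catalogue order. Non-finite feature values are written as the
#' missing token `NA` and round-trip to `NA`.
#'
#' @param mat A data frame as produced by [build_feature_matrix()].
#' @param path File path.
#' @return `read_features()` returns the data frame; `write_features()`
#'   returns `path` invisibly.
#' @export
write_features <- function(mat, path) {
  stopifnot(is.data.frame(mat), c("patient_id", "group") %in% names(mat))
  feat <- names(mat)[!names(mat) %in% c("patient_id", "group")]
  if (anyDuplicated(feat)) stop("duplicate feature names")
  utils::write.csv(mat, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  mat <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("patient_id", "group") %in% names(mat)))
    stop("feature table lacks patient_id/group columns")
  if (anyDuplicated(names(mat)[!names(mat) %in% c("patient_id", "group")]))
    stop("duplicate feature names")
  mat
}
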