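#' Read and write seizure interval annotations
#'
#' Annotations travel as comma-separated text with a header row and
#' columns `patient_id`, `start_s`, `end_s` (seconds from record start,
#' half-open intervals).
#'
#' @param path file path.
#' @return `read_annotations()` returns a data.frame with the three
#'   columns, validated.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "start_s", "end_s")
  if (!all(need %in% names(tab)))
    stop_invalid("annotation file must have columns ",
                 paste(need, collapse = ", "))
  if (any(tab$start_s < 0)) stop_invalid("negative start_s in annotations")
  if (any(tab$end_s <= tab$start_s))
    stop_invalid("annotations must satisfy start_s < end_s")
  tab[need]
}

#' @rdname read_annotations
#' @param annotations data.frame with columns `patient_id`, `start_s`,
#'   `end_s`.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations[c("patient_id", "start_s", "end_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a recording as delimited text
#'
#' The delimited interchange format is a comma-separated file whose first
#' two lines are metadata comments (`# rate=...`, `# patient_id=...`),
#' followed by a header of channel labels and one row per sample. Values
#' round-trip exactly (full double precision).
#'
#' @param rec an `eeg_recording`.
#' @param path file path.
#' @param annotations optional annotation data.frame attached on read.
#' @return `read_recording_csv()` returns an `eeg_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate=%.10g", rec$rate),
               sprintf("# patient_id=%s", rec$patient_id),
               paste(rec$channel_labels, collapse = ",")), con)
  utils::write.table(format(t(rec$channels), digits = 17, trim = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path, annotations = NULL) {
  lines <- readLines(path, n = 3)
  if (length(lines) < 3 || !grepl("^# rate=", lines[1]) ||
      !grepl("^# patient_id=", lines[2]))
    stop_invalid("malformed delimited recording: missing rate/patient_id ",
                 "metadata lines")
  rate <- as.numeric(sub("^# rate=", "", lines[1]))
  pid <- sub("^# patient_id=", "", lines[2])
  labels <- strsplit(lines[3], ",")[[1]]
  mat <- as.matrix(utils::read.csv(path, skip = 2, header = TRUE,
                                   check.names = FALSE))
  if (ncol(mat) != length(labels))
    stop_invalid("channel count does not match header labels")
  eeg_recording(t(mat), rate, labels, pid,
                annotations = if (is.null(annotations))
                  data.frame(start_s = numeric(), end_s = numeric())
                else annotations)
}

# ---- minimal EDF (European Data Format, 16-bit) support -----------------

.edf_field <- function(x, width) {
  s <- sprintf(paste0("%-", width, "s"), substr(as.character(x), 1, width))
  charToRaw(s)
}

.edf_num <- function(x, width) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g")
    if (nchar(s) <= width) return(.edf_field(s, width))
  }
  .edf_field(formatC(x, digits = 0, format = "e"), width)
}

#' Write a recording as EDF
#'
#' Minimal EDF writer: one-second data records, 16-bit samples, physical
#' units microvolts. Physical min/max per channel are taken from the data,
#' so amplitudes round-trip within the 16-bit quantization step. A
#' trailing partial second is dropped (EDF records are whole seconds).
#'
#' @param rec an `eeg_recording` with an integer sampling rate.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  if (abs(rec$rate - round(rec$rate)) > 1e-9)
    stop_invalid("EDF writer needs an integer sampling rate")
  rate <- round(rec$rate)
  ns <- nrow(rec$channels)
  nrec <- floor(ncol(rec$channels) / rate)
  if (nrec < 1) stop_invalid("recording shorter than one EDF data record")
  lo <- apply(rec$channels, 1, min)
  hi <- apply(rec$channels, 1, max)
  flat <- hi - lo <= 0
  lo[flat] <- lo[flat] - 1; hi[flat] <- hi[flat] + 1
  # physical min/max must survive the 8-char ASCII header round-trip while
  # still bracketing the data, so widen until the reparsed bounds do
  reparse <- function(v) as.numeric(trimws(rawToChar(.edf_num(v, 8))))
  bound1 <- function(ref, span, sign) {
    for (w in c(0.001, 0.01, 0.05, 0.2, 1)) {
      cand <- reparse(ref + sign * w * span)
      if (!is.na(cand) && sign * (cand - ref) >= 0) return(cand)
    }
    stop_invalid("cannot encode physical range in EDF header")
  }
  pmin_ <- vapply(seq_len(ns), function(i)
    bound1(lo[i], hi[i] - lo[i], -1), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i)
    bound1(hi[i], hi[i] - lo[i], +1), numeric(1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.edf_field("0", 8), con)
  writeBin(.edf_field(rec$patient_id, 80), con)
  writeBin(.edf_field("tfseize synthetic recording", 80), con)
  writeBin(.edf_field("01.01.00", 8), con)
  writeBin(.edf_field("00.00.00", 8), con)
  writeBin(.edf_field(256 * (ns + 1), 8), con)
  writeBin(.edf_field("", 44), con)
  writeBin(.edf_field(nrec, 8), con)
  writeBin(.edf_field("1", 8), con)
  writeBin(.edf_field(ns, 4), con)
  wr <- function(vals, width)
    for (v in vals) writeBin(.edf_field(v, width), con)
  wr(rec$channel_labels, 16)
  wr(rep("", ns), 80)
  wr(rep("uV", ns), 8)
  for (v in pmin_) writeBin(.edf_num(v, 8), con)
  for (v in pmax_) writeBin(.edf_num(v, 8), con)
  wr(rep("-32768", ns), 8)
  wr(rep("32767", ns), 8)
  wr(rep("", ns), 80)
  wr(rep(rate, ns), 8)
  wr(rep("", ns), 32)
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      x <- rec$channels[s, ((r - 1) * rate + 1):(r * rate)]
      dig <- round((x - pmin_[s]) / (pmax_[s] - pmin_[s]) * 65535 - 32768)
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads 16-bit EDF files with per-channel physical scaling applied. All
#' channels must share one sampling rate. Malformed or truncated files
#' raise a parse error naming the offending field; no partial object is
#' returned.
#'
#' @param path EDF file path.
#' @param annotations optional annotation data.frame to attach.
#' @return an `eeg_recording` in physical units.
#' @export
read_edf <- function(path, annotations = NULL) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 256)
    stop_invalid("EDF parse error: truncated header (file < 256 bytes)")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(rawToChar(readBin(con, "raw", width)))
  rd(8)                                   # version
  pid <- rd(80)
  rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1)
    stop_invalid("EDF parse error: invalid number of signals field")
  if (is.na(hdr_bytes) || hdr_bytes != 256 * (ns + 1))
    stop_invalid("EDF parse error: header-bytes field inconsistent with ns")
  if (sz < hdr_bytes)
    stop_invalid("EDF parse error: truncated signal headers")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  rd(80 * ns); rd(8 * ns)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(32 * ns)
  if (any(is.na(c(pmin_, pmax_, dmin_, dmax_, spr))))
    stop_invalid("EDF parse error: non-numeric signal header field")
  if (length(unique(spr)) != 1)
    stop_invalid("EDF parse error: channels have inconsistent rates")
  if (is.na(nrec) || nrec < 1 || is.na(rec_dur) || rec_dur <= 0)
    stop_invalid("EDF parse error: invalid record count/duration fields")
  need <- hdr_bytes + 2 * nrec * sum(spr)
  if (sz < need)
    stop_invalid("EDF parse error: data section truncated")
  rate <- spr[1] / rec_dur
  ch <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[s], size = 2, signed = TRUE,
                     endian = "little")
      ch[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        pmin_[s] + (dig - dmin_[s]) / (dmax_[s] - dmin_[s]) *
          (pmax_[s] - pmin_[s])
    }
  }
  eeg_recording(ch, rate, labels, if (nzchar(pid)) pid else "unknown",
                annotations = if (is.null(annotations))
                  data.frame(start_s = numeric(), end_s = numeric())
                else annotations)
}

#' Read or write a recording in a chosen container
#'
#' Dispatch over the two supported containers: EDF (the canonical EEG
#' format) and the delimited text fallback.
#'
#' @param path file path.
#' @param format `"edf"` or `"delimited"`.
#' @param annotations optional annotations to attach on read.
#' @param rec recording to write.
#' @return `read_recording()` returns an `eeg_recording`.
#' @export
read_recording <- function(path, format = c("edf", "delimited"),
                           annotations = NULL) {
  format <- match.arg(format)
  if (format == "edf") read_edf(path, annotations)
  else read_recording_csv(path, annotations)
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path, format = c("edf", "delimited")) {
  format <- match.arg(format)
  if (format == "edf") write_edf(rec, path) else write_recording_csv(rec, path)
}

#' Read or write a segment feature table
#'
#' Comma-separated with header `segment_id, patient_id, t_start, label,
#' T1..T4, F1..F6, TF1..TF8` in that fixed order.
#'
#' @param table feature data.frame from [extract_recording_features()].
#' @param path file path.
#' @return `read_features()` returns the validated data.frame.
#' @export
write_features <- function(table, path) {
  cols <- c("segment_id", "patient_id", "t_start", "label", feature_names())
  utils::write.csv(table[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("segment_id", "patient_id", "t_start", "label", feature_names())
  if (!identical(names(tab), cols))
    stop_invalid("feature file header does not match the fixed schema")
  tab
}

#' Write per-segment detection decisions
#'
#' Comma-separated with columns `patient_id, t_start, raw, smoothed,
#' extended`.
#'
#' @param result a `seizure_loocv` object (or any data.frame carrying the
#'   five columns).
#' @param path file path.
#' @export
write_predictions <- function(result, path) {
  tab <- if (inherits(result, "seizure_loocv")) result$table else result
  utils::write.csv(tab[c("patient_id", "t_start", "raw", "smoothed",
                         "extended")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "t_start", "raw", "smoothed", "extended")
  if (!all(need %in% names(tab)))
    stop_invalid("prediction file missing required columns")
  tab[need]
}

#' Serialize a TFD as delimited text plus a JSON axis sidecar
#'
#' The matrix is written as comma-separated values (rows = time) and the
#' axes and rate as `<path>.json`.
#'
#' @param tfd a `tfd` object.
#' @param path path of the matrix file.
#' @return `read_tfd()` returns a `tfd`.
#' @export
write_tfd <- function(tfd, path) {
  utils::write.table(tfd$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(time_axis = tfd$time_axis,
                            freq_axis = tfd$freq_axis, rate = tfd$rate),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_tfd
#' @export
read_tfd <- function(path) {
  vals <- as.matrix(utils::read.csv(path, header = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dimnames(vals) <- NULL
  new_tfd(vals, side$time_axis, side$freq_axis, side$rate)
}
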