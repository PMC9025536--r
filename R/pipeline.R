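#' Channel averaging of a multi-channel recording
#'
#' Per-sample arithmetic mean across channels: the single-trace reduction
#' used before time-frequency analysis. Averaging reinforces seizure
#' activity, which is coherent across channels, against independent
#' channel noise.
#'
#' @param rec an `eeg_recording`.
#' @return a `sampled_signal` at the recording's rate.
#' @export
spatial_average <- function(rec) {
  if (!inherits(rec, "eeg_recording")) stop_invalid("expected an eeg_recording")
  sampled_signal(colMeans(rec$channels), rec$rate)
}

#' Preprocess a trace to the 32 Hz analysis rate
#'
#' Anti-alias low-pass filtering (zero-phase 128-tap FIR, cutoff
#' `0.8 * 16` Hz), decimation to 32 Hz, and the first-difference
#' pre-filter `y(n) = x(n) - x(n-1)` (with `y(1) = 0`), which whitens the
#' steep low-frequency spectrum of EEG and sharpens spikes. The
#' differencing is applied after decimation by default so it acts as a
#' high-pass at the analysis rate; `order = "differentiate_first"` swaps
#' the two steps.
#'
#' @param x a `sampled_signal` whose rate is a multiple of 32 Hz.
#' @param order `"decimate_first"` (default) or `"differentiate_first"`.
#' @param cutoff_frac anti-alias cutoff as a fraction of the 16 Hz target
#'   Nyquist frequency.
#' @return a `sampled_signal` at 32 Hz of length `floor(n / (rate/32))`.
#' @export
preprocess <- function(x, order = c("decimate_first", "differentiate_first"),
                       cutoff_frac = 0.8) {
  order <- match.arg(order)
  if (!inherits(x, "sampled_signal")) stop_invalid("expected a sampled_signal")
  m <- x$rate / 32
  if (abs(m - round(m)) > 1e-9 || m < 1)
    stop_invalid("sampling rate must be a positive multiple of 32 Hz")
  m <- round(m)
  decimate <- function(v, from_rate) {
    if (m == 1) return(v)
    fir <- signal::fir1(128, cutoff_frac * 16 / (from_rate / 2))
    # replicate-pad so the zero-phase filter sees no artificial step at
    # the record edges
    np <- 129
    padded <- c(rep(v[1], np), v, rep(v[length(v)], np))
    lp <- signal::filtfilt(fir, x = padded)[(np + 1):(np + length(v))]
    lp[seq(1, length(lp), by = m)]
  }
  differentiate <- function(v) c(0, diff(v))
  v <- x$samples
  v <- if (order == "decimate_first") differentiate(decimate(v, x$rate))
       else decimate(differentiate(v), x$rate)
  v <- v[seq_len(floor(length(x$samples) / m))]
  sampled_signal(v, 32, x$start_time)
}

#' Split a 32 Hz trace into non-overlapping 8-s segments
#'
#' Consecutive 256-sample windows; a trailing remainder shorter than one
#' segment is dropped.
#'
#' @param x a `sampled_signal` at 32 Hz with at least 256 samples.
#' @return an object of class `segment_set`: list with `segments` (list of
#'   `sampled_signal`), `start_times`, and `labels` (`NA` until
#'   [label_segments()] is applied).
#' @export
segment_signal <- function(x) {
  if (!inherits(x, "sampled_signal")) stop_invalid("expected a sampled_signal")
  if (abs(x$rate - 32) > 1e-9) stop_invalid("segmentation expects 32 Hz input")
  n <- length(x$samples)
  if (n < 256) stop_invalid("signal shorter than one 8-s segment")
  k <- floor(n / 256)
  segs <- lapply(seq_len(k), function(i) {
    t0 <- x$start_time + (i - 1) * 8
    sampled_signal(x$samples[((i - 1) * 256 + 1):(i * 256)], 32, t0)
  })
  structure(list(segments = segs,
                 start_times = x$start_time + 8 * (seq_len(k) - 1),
                 labels = rep(NA_integer_, k)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments of 8 s, %d labelled seizure\n",
              length(x$segments), sum(x$labels == 1, na.rm = TRUE)))
  invisible(x)
}

#' Label segments from seizure interval annotations
#'
#' A segment is labelled seizure (1) when more than half of its 8-s
#' duration overlaps an annotated seizure interval (majority rule),
#' otherwise 0.
#'
#' @param set a `segment_set`.
#' @param annotations data.frame with columns `start_s`, `end_s`.
#' @param threshold overlap fraction above which a segment is seizure.
#' @return the `segment_set` with `labels` filled in.
#' @export
label_segments <- function(set, annotations, threshold = 0.5) {
  ann <- as.data.frame(annotations)
  ov <- vapply(set$start_times, function(t0) {
    if (!nrow(ann)) return(0)
    sum(pmax(0, pmin(ann$end_s, t0 + 8) - pmax(ann$start_s, t0)))
  }, numeric(1))
  set$labels <- as.integer(ov > threshold * 8)
  set
}

#' Balance a training set by majority-class undersampling
#'
#' Randomly (seeded) undersamples the majority class down to the minority
#' count, the balanced-training rule used before classifier fitting.
#'
#' @param labels binary vector (0/1).
#' @param seed integer seed; the same seed yields the same selection.
#' @return sorted integer indices of the balanced subset.
#' @export
balance_training <- function(labels, seed = 1) {
  labels <- as.integer(labels)
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  if (!length(i1) || !length(i0))
    stop_invalid("both classes must be present to balance")
  n <- min(length(i0), length(i1))
  keep <- with_seed(seed, c(
    if (length(i0) > n) sample(i0, n) else i0,
    if (length(i1) > n) sample(i1, n) else i1))
  sort(keep)
}

#' Fit a random-forest seizure classifier
#'
#' Fits a seeded random forest (default 500 trees) on 18-dimensional
#' feature vectors with permutation importance enabled, so feature
#' importance is reported as the decrease in accuracy when a feature is
#' permuted out of the model.
#'
#' @param x numeric matrix or data.frame of features (columns named as
#'   [feature_names()]; any 18-column numeric input is accepted).
#' @param y binary labels (0/1).
#' @param ntree number of trees.
#' @param seed integer seed for forest growing.
#' @return an object of class `seizure_detector`.
#' @seealso [predict.seizure_detector()], [feature_importance()]
#' @export
seizure_detector <- function(x, y, ntree = 500, seed = 1) {
  x <- as.data.frame(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop_invalid("features and labels differ in length")
  if (!all(y %in% 0:1)) stop_invalid("labels must be binary 0/1")
  fit <- with_seed(seed, randomForest::randomForest(
    x = x, y = factor(y, levels = c(0, 1)),
    ntree = ntree, importance = TRUE))
  structure(list(forest = fit, feature_names = colnames(x),
                 ntree = ntree, seed = seed),
            class = "seizure_detector")
}

#' @export
print.seizure_detector <- function(x, ...) {
  cat(sprintf("<seizure_detector> random forest, %d trees, %d features\n",
              x$ntree, length(x$feature_names)))
  print(x$forest$confusion)
  invisible(x)
}

#' Predict segment classes with a fitted detector
#'
#' @param object a `seizure_detector`.
#' @param newdata feature matrix/data.frame with the training columns.
#' @param ... unused.
#' @return integer vector of 0/1 decisions.
#' @export
predict.seizure_detector <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  as.integer(as.character(stats::predict(object$forest, newdata)))
}

#' Permutation importance of a fitted detector
#'
#' @param object a `seizure_detector`.
#' @return named numeric vector of mean decrease in accuracy per feature.
#' @export
feature_importance <- function(object) {
  imp <- randomForest::importance(object$forest, type = 1)
  stats::setNames(imp[, 1], rownames(imp))
}

#' Median smoothing of a segment decision sequence
#'
#' 5-tap median filter with edge replication: a segment is kept as seizure
#' only when at least three of the five segments in the window centred on
#' it are seizure. Removes isolated false positives.
#'
#' @param decisions binary vector.
#' @return binary vector of the same length.
#' @export
median_smooth <- function(decisions) {
  d <- as.integer(decisions)
  n <- length(d)
  if (n == 0) return(integer(0))
  pad <- c(rep(d[1], 2), d, rep(d[n], 2))
  vapply(seq_len(n), function(i) as.integer(sum(pad[i:(i + 4)]) >= 3),
         integer(1))
}

#' Extend seizure boundaries by one segment
#'
#' Grows every maximal run of seizure decisions by one 8-s segment on each
#' side (clipped to the sequence; adjacent runs may merge), recovering
#' sensitivity at seizure onsets and offsets that the median filter can
#' trim.
#'
#' @param mask binary vector.
#' @return binary vector of the same length.
#' @export
extend_boundaries <- function(mask) {
  d <- as.integer(mask)
  n <- length(d)
  if (n == 0) return(integer(0))
  as.integer(d | c(d[-1], 0L) | c(0L, d[-n]))
}

#' Detection metrics from binary decisions
#'
#' Confusion-matrix metrics: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy, precision `TP/(TP+FP)`, and F1 (harmonic mean
#' of precision and sensitivity). A metric whose denominator is zero is
#' returned as 0 and named in the `undefined` attribute.
#'
#' @param pred binary predictions.
#' @param truth binary reference labels.
#' @return named numeric vector of the five metrics (fractions in
#'   `[0, 1]`), with attribute `undefined`.
#' @export
detection_metrics <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth))
    stop_invalid("prediction and truth differ in length")
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  undef <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) { undef <<- c(undef, what); return(0) }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  acc <- safe(tp + tn, length(pred), "accuracy")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- f1_score(prec, sens)
  if (prec + sens == 0) undef <- c(undef, "f1")
  out <- c(sensitivity = sens, specificity = spec, accuracy = acc,
           precision = prec, f1 = f1)
  attr(out, "undefined") <- undef
  out
}

#' F1 score from precision and sensitivity
#'
#' Harmonic mean `2 P R / (P + R)`; 0 when both are 0.
#'
#' @param precision precision (positive predictive value), fraction.
#' @param sensitivity sensitivity (recall), fraction.
#' @return the F1 score as a fraction.
#' @examples
#' f1_score(0.6436, 0.7898)  # ~0.7093
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(precision + sensitivity == 0, 0,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' Feature table of one recording
#'
#' Full per-recording pipeline: channel averaging, preprocessing to 32 Hz,
#' 8-s segmentation, majority-rule labelling, and feature extraction per
#' segment.
#'
#' @param rec an `eeg_recording`.
#' @param params a [kernel_params()] object.
#' @return data.frame with columns `segment_id`, `patient_id`, `t_start`,
#'   `label`, and the 18 features `T1..TF8`.
#' @export
extract_recording_features <- function(rec, params = kernel_params()) {
  set <- label_segments(segment_signal(preprocess(spatial_average(rec))),
                        rec$annotations)
  feats <- t(vapply(set$segments, function(s) {
    as.numeric(extract_features(s, params))
  }, numeric(18)))
  colnames(feats) <- feature_names()
  cbind(data.frame(
    segment_id = sprintf("%s_%05d", rec$patient_id,
                         as.integer(set$start_times)),
    patient_id = rec$patient_id,
    t_start = set$start_times,
    label = set$labels,
    stringsAsFactors = FALSE), as.data.frame(feats))
}

#' Leave-one-patient-out cross-validated seizure detection
#'
#' One fold per patient: the test patient's segments are held out, the
#' training segments of all other patients are balanced by seeded
#' undersampling, a random forest is fitted, and the test patient's
#' decision sequence is post-processed with the 5-tap median filter and
#' 8-s boundary extension before metric computation. Per-fold seeds are
#' derived deterministically from the patient id, and training rows are
#' assembled in sorted patient order, so results are invariant to the
#' order patients appear in. Metrics are pooled over all test segments.
#'
#' @param data either a list of `eeg_recording` objects or a feature
#'   data.frame as produced by [extract_recording_features()] (rows from
#'   several patients combined).
#' @param params a [kernel_params()] object (used only when `data` is a
#'   recording list).
#' @param ntree trees per forest.
#' @param seed master seed.
#' @param smooth apply the median filter (default `TRUE`).
#' @param extend apply boundary extension (default `TRUE`).
#' @return an object of class `seizure_loocv`: list with `pooled` (metrics
#'   over all test segments), `folds` (per-patient metrics), `table` (the
#'   feature table with `raw`, `smoothed` and `extended` decision
#'   columns), and `config`.
#' @examples
#' \donttest{
#' recs <- gen_recording(n_patients = 2, duration_s = 48,
#'                       seizure_interval = c(16, 40), seed = 1)
#' cv <- seizure_loocv(recs, seed = 1)
#' cv$pooled
#' }
#' @export
seizure_loocv <- function(data, params = kernel_params(), ntree = 500,
                          seed = 1, smooth = TRUE, extend = TRUE) {
  tab <- if (is.data.frame(data)) data
         else do.call(rbind, lapply(data, extract_recording_features,
                                    params = params))
  pats <- sort(unique(tab$patient_id))
  if (length(pats) < 2) stop_invalid("leave-one-out needs >= 2 patients")
  tab <- tab[order(tab$patient_id, tab$t_start), , drop = FALSE]
  rownames(tab) <- NULL
  fcols <- feature_names()
  tab$raw <- NA_integer_; tab$smoothed <- NA_integer_
  tab$extended <- NA_integer_
  folds <- list()
  for (p in pats) {
    test <- tab$patient_id == p
    tr <- tab[!test, , drop = FALSE]
    sub_seed <- derive_seed(seed, p)
    keep <- balance_training(tr$label, seed = sub_seed)
    det <- seizure_detector(tr[keep, fcols], tr$label[keep],
                            ntree = ntree, seed = sub_seed)
    raw <- predict(det, tab[test, fcols])
    sm <- if (smooth) median_smooth(raw) else raw
    ex <- if (extend) extend_boundaries(sm) else sm
    tab$raw[test] <- raw; tab$smoothed[test] <- sm; tab$extended[test] <- ex
    folds[[p]] <- list(metrics = detection_metrics(ex, tab$label[test]),
                       n = sum(test))
  }
  structure(list(
    pooled = detection_metrics(tab$extended, tab$label),
    folds = folds, table = tab,
    config = list(ntree = ntree, seed = seed, smooth = smooth,
                  extend = extend)),
    class = "seizure_loocv")
}

#' @export
print.seizure_loocv <- function(x, ...) {
  cat(sprintf("<seizure_loocv> %d patients, %d segments\n",
              length(x$folds), nrow(x$table)))
  cat("pooled metrics:\n")
  print(round(x$pooled, 4))
  invisible(x)
}

#' @export
summary.seizure_loocv <- function(object, ...) {
  per <- t(vapply(object$folds, function(f) f$metrics, numeric(5)))
  out <- list(pooled = object$pooled, per_patient = per)
  class(out) <- "summary.seizure_loocv"
  out
}

#' @export
print.summary.seizure_loocv <- function(x, ...) {
  cat("Pooled metrics over all test segments:\n")
  print(round(x$pooled, 4))
  cat("\nPer-patient metrics:\n")
  print(round(x$per_patient, 4))
  invisible(x)
}
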