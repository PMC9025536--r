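#' Time-marginal segment energies T1-T4
#'
#' Integrates the modified time marginal over the four consecutive 2-s
#' quarters of an 8-s segment: `T(k+1) = integral of s(t) over
#' [2k, 2(k+1))` seconds relative to segment start, `k = 0..3`. The four
#' intervals partition the segment, so `sum(T)` equals the total integral
#' of the marginal exactly.
#'
#' @param s a `tf_marginal` over time spanning 8 s (or any duration if
#'   `quarters = TRUE`, in which case the quarters of the actual duration
#'   are used).
#' @param quarters allow a non-8-s segment, splitting it into quarters.
#' @return named numeric vector `c(T1, T2, T3, T4)`.
#' @export
time_marginal_features <- function(s, quarters = FALSE) {
  if (!inherits(s, "tf_marginal") || s$axis_type != "time")
    stop_invalid("expected a time marginal")
  rel <- s$axis - s$axis[1]
  dur <- length(s$values) * s$bin_width
  if (!quarters && abs(dur - 8) > 1e-9)
    stop_invalid("time marginal must span 8 s (or set quarters = TRUE)")
  edges <- seq(0, dur, length.out = 5)
  bin <- findInterval(rel, edges, rightmost.closed = TRUE)
  bin[bin > 4] <- 4
  out <- vapply(1:4, function(k) sum(s$values[bin == k]) * s$bin_width,
                numeric(1))
  names(out) <- paste0("T", 1:4)
  out
}

#' Frequency-band energies F1-F6
#'
#' Integrates the modified frequency marginal over the sub-bands
#' (0-1, 1-2, 2-3, 3-4, 4-8, 8-16) Hz. The bands partition `[0, 16]` Hz,
#' the full analysis band at a 32 Hz sampling rate, so `sum(F)` equals the
#' total integral of the marginal.
#'
#' @param s a `tf_marginal` over frequency whose axis reaches 16 Hz.
#' @return named numeric vector `c(F1, ..., F6)`.
#' @export
frequency_marginal_features <- function(s) {
  if (!inherits(s, "tf_marginal") || s$axis_type != "frequency")
    stop_invalid("expected a frequency marginal")
  if (max(s$axis) < 16 - 1e-9)
    stop_invalid("frequency axis must reach 16 Hz (32 Hz sampling)")
  edges <- c(0, 1, 2, 3, 4, 8, 16)
  bin <- findInterval(s$axis, edges, rightmost.closed = TRUE)
  bin[bin > 6] <- 6
  out <- vapply(1:6, function(k) sum(s$values[bin == k]) * s$bin_width,
                numeric(1))
  names(out) <- paste0("F", 1:6)
  out
}

#' Statistical and image features TF1-TF8 of the filtered TFD
#'
#' Treats the direction-filtered distribution as a distribution of values
#' and as a TF image:
#' \describe{
#'   \item{TF1}{mean of the values}
#'   \item{TF2}{standard deviation}
#'   \item{TF3}{coefficient of variation, TF2/TF1}
#'   \item{TF4, TF5}{standardized sample skewness and kurtosis}
#'   \item{TF6}{spectral flatness: geometric mean of `|values|` (floored at
#'     `1e-12` times their arithmetic mean, so the measure is
#'     scale-invariant) over their arithmetic mean; 1 for a uniform
#'     distribution, near 0 for a concentrated one}
#'   \item{TF7}{energy concentration, `sum(|values|^0.5) * dt * df`}
#'   \item{TF8}{flux: `sum(|mixed first difference along t and f|) * dt * df`,
#'     a roughness measure}
#' }
#' Absolute values are used inside TF6 and TF7, whose fractional power and
#' product are undefined for the negative values a quadratic TFD can take.
#' On a degenerate segment (zero mean) TF3 and TF6 are returned as 0 and
#' the result carries attribute `degenerate = TRUE`.
#'
#' @param rho_fil a `gated_tfd` (any gate) or `tfd`.
#' @return named numeric vector `c(TF1, ..., TF8)`.
#' @export
tf_statistical_features <- function(rho_fil) {
  v <- as.vector(rho_fil$values)
  if (length(v) == 0 || !all(is.finite(v)))
    stop_invalid("TFD must be non-empty and finite")
  dt <- 1 / rho_fil$rate
  df <- diff(rho_fil$freq_axis[1:2])
  mu <- mean(v)
  sd_ <- stats::sd(v)
  degenerate <- FALSE
  if (mu == 0 || sd_ == 0) degenerate <- TRUE
  av <- abs(v)
  am <- mean(av)
  tf3 <- if (mu != 0) sd_ / mu else 0
  if (sd_ > 0) {
    zc <- (v - mu) / sd_
    tf4 <- mean(zc^3)
    tf5 <- mean(zc^4)
  } else {
    tf4 <- 0; tf5 <- 0
  }
  tf6 <- if (am > 0) exp(mean(log(pmax(av, 1e-12 * am)))) / am else 0
  tf7 <- sum(sqrt(av)) * dt * df
  m <- rho_fil$values
  dd <- m[-1, -1, drop = FALSE] - m[-nrow(m), -1, drop = FALSE] -
    m[-1, -ncol(m), drop = FALSE] + m[-nrow(m), -ncol(m), drop = FALSE]
  tf8 <- sum(abs(dd)) * dt * df
  out <- c(TF1 = mu, TF2 = sd_, TF3 = tf3, TF4 = tf4, TF5 = tf5,
           TF6 = tf6, TF7 = tf7, TF8 = tf8)
  attr(out, "degenerate") <- degenerate
  out
}

#' Full 18-dimensional feature vector of one 8-s segment
#'
#' Runs the complete chain on a 256-sample segment at 32 Hz: adaptive
#' directional TFD, ridge gating, modified marginals, and the three feature
#' groups, in the fixed order `(T1..T4, F1..F6, TF1..TF8)`. Deterministic
#' for fixed input and parameters.
#'
#' @param x a `sampled_signal`, 256 samples at 32 Hz.
#' @param params a [kernel_params()] object.
#' @return named numeric vector of length 18; attribute `degenerate` is
#'   `TRUE` for an (effectively) all-zero segment, in which case a warning
#'   is emitted.
#' @examples
#' \donttest{
#' x <- sampled_signal(sin(2 * pi * 2.5 * (0:255) / 32), rate = 32)
#' fv <- extract_features(x)
#' which.max(fv[5:10])  # F3: the 2-3 Hz band dominates
#' }
#' @export
extract_features <- function(x, params = kernel_params()) {
  if (!inherits(x, "sampled_signal"))
    stop_invalid("x must be a sampled_signal")
  if (abs(x$rate - 32) > 1e-9)
    stop_invalid("segments must be sampled at 32 Hz")
  if (length(x$samples) != 256)
    stop_invalid("segments must contain 256 samples (8 s at 32 Hz)")
  r <- compute_adtfd(x, params)
  rho_t <- select_freq_axis_ridges(r$tfd, r$dmap)
  rho_f <- select_time_axis_ridges(r$tfd, r$dmap)
  fil <- filtered_tfd(rho_t, rho_f)
  tf <- tf_statistical_features(fil)
  out <- c(time_marginal_features(time_marginal(rho_t)),
           frequency_marginal_features(frequency_marginal(rho_f)),
           tf)
  attr(out, "degenerate") <- attr(tf, "degenerate")
  if (isTRUE(attr(tf, "degenerate")))
    warning("degenerate segment: TF statistical features are trivial")
  out
}

#' Names of the 18 features in canonical order
#' @return character vector `c("T1",...,"TF8")`.
#' @export
feature_names <- function() {
  c(paste0("T", 1:4), paste0("F", 1:6), paste0("TF", 1:8))
}
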