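#' Parameters of the adaptive directional smoothing kernel
#'
#' Bundles the tunables of the directional Gaussian smoothing kernel and the
#' windowed Wigner-Ville computation. `a` and `b` are reciprocal length
#' scales (in time-frequency grid units) along the kernel's major and minor
#' axes: the major-axis Gaussian standard deviation is `1/(a*sqrt(2))` grid
#' points, the minor-axis one `1/(b*sqrt(2))`. Defaults give a 12-point
#' major / 2-point minor std on a 256-point grid, an elongated kernel that
#' hugs a ridge when aligned with it and averages across it otherwise.
#'
#' @param a reciprocal length scale along the major axis (> 0).
#' @param b reciprocal length scale along the minor axis (> 0).
#' @param theta_step angular quantization in degrees; `180 / theta_step`
#'   must be an integer. Default 3 degrees (60 orientations).
#' @param support_halfwidth half-width of the square kernel support in grid
#'   points; support is truncated to the inscribed disc so that the kernel
#'   mass is independent of orientation.
#' @param lag_window_len odd number of lag samples for the windowed WVD, or
#'   `NULL` for the full (odd-truncated) signal length.
#' @param doublet logical; multiply the Gaussian by `(1 - 2 b^2 f_theta^2)`,
#'   the second-derivative-of-Gaussian profile across the minor axis. This
#'   ridge-enhancing factor integrates to zero across the ridge, so flat
#'   regions give (near) zero response and the orientation argmax locks
#'   onto elongated structure without bias. `FALSE` gives a pure
#'   directional Gaussian for ablation.
#' @return an object of class `kernel_params`.
#' @examples
#' p <- kernel_params()
#' theta_grid(p)[1:5]
#' @export
kernel_params <- function(a = 1 / (12 * sqrt(2)),
                          b = 1 / (2 * sqrt(2)),
                          theta_step = 3,
                          support_halfwidth = 36,
                          lag_window_len = NULL,
                          doublet = TRUE) {
  if (!is.numeric(a) || a <= 0) stop_invalid("a must be > 0")
  if (!is.numeric(b) || b <= 0) stop_invalid("b must be > 0")
  if (theta_step <= 0 || theta_step > 180 ||
      abs(180 / theta_step - round(180 / theta_step)) > 1e-9)
    stop_invalid("theta_step must divide 180")
  if (support_halfwidth < 1) stop_invalid("support_halfwidth must be >= 1")
  if (!is.null(lag_window_len)) {
    if (lag_window_len %% 2 != 1)
      stop_invalid("lag_window_len must be odd")
  }
  structure(list(a = a, b = b, theta_step = theta_step,
                 support_halfwidth = as.integer(support_halfwidth),
                 lag_window_len = lag_window_len,
                 doublet = isTRUE(doublet)),
            class = "kernel_params")
}

#' Angle grid of a kernel parameter set
#' @param params a `kernel_params` object.
#' @return numeric vector of orientations in degrees, half-open `[0, 180)`.
#' @export
theta_grid <- function(params) {
  seq(0, 180 - params$theta_step, by = params$theta_step)
}

new_tfd <- function(values, time_axis, freq_axis, rate) {
  stopifnot(nrow(values) == length(time_axis),
            ncol(values) == length(freq_axis))
  structure(list(values = values, time_axis = time_axis,
                 freq_axis = freq_axis, rate = rate),
            class = "tfd")
}

#' @export
print.tfd <- function(x, ...) {
  cat(sprintf(
    "<tfd> %d time x %d freq, t = [%g, %g] s, f = [%g, %g] Hz\n",
    nrow(x$values), ncol(x$values),
    min(x$time_axis), max(x$time_axis),
    min(x$freq_axis), max(x$freq_axis)))
  invisible(x)
}

#' @export
plot.tfd <- function(x, main = "", ...) {
  graphics::image(x$time_axis, x$freq_axis, x$values,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Discrete windowed Wigner-Ville distribution
#'
#' Computes the (pseudo-)Wigner-Ville distribution of a complex signal:
#' the DFT over lag of the instantaneous autocorrelation
#' `z(n+l) conj(z(n-l))`, with an odd lag window and zero padding at the
#' signal edges. One row per time sample; `nbins` frequency bins spanning
#' `[0, rate/2]` inclusive. With the lag step of one sample the effective
#' lag is two samples, so the distribution is periodic in frequency with
#' period `rate/2`; for analytic input whose content lies below `rate/2`
#' this is the standard convention.
#'
#' @param z complex vector (typically from [analytic_signal()]) or a
#'   `sampled_signal` carrying complex samples.
#' @param rate sampling rate in Hz (taken from the signal if omitted).
#' @param lag_window_len odd lag-window length; default the odd-truncated
#'   signal length.
#' @param nbins number of frequency bins; default the signal length.
#' @param start_time start time in seconds for the time axis.
#' @param taper lag-window taper: `"hamming"` (the usual pseudo-WVD
#'   smoothing window, which suppresses the Dirichlet sidelobes an
#'   off-bin tone would otherwise spread across the whole band) or
#'   `"rectangular"`.
#' @return a `tfd` object; values are real, scaled so that the frequency
#'   integral of each row approximates `|z(t)|^2` (time-marginal identity).
#' @examples
#' z <- analytic_signal(cos(2 * pi * 4 * (0:127) / 32))
#' W <- wvd(z, rate = 32)
#' W$freq_axis[which.max(colMeans(W$values))]  # ~4 Hz
#' @export
wvd <- function(z, rate = NULL, lag_window_len = NULL, nbins = NULL,
                start_time = 0, taper = c("hamming", "rectangular")) {
  taper <- match.arg(taper)
  if (inherits(z, "sampled_signal")) {
    if (is.null(rate)) rate <- z$rate
    start_time <- z$start_time
    z <- z$samples
  }
  if (is.null(rate)) stop_invalid("rate is required")
  z <- as.complex(z)
  check_finite(c(Re(z), Im(z)), "signal")
  n <- length(z)
  if (is.null(lag_window_len)) lag_window_len <- n - (1 - n %% 2)
  if (lag_window_len %% 2 != 1)
    stop_invalid("lag_window_len must be odd")
  if (lag_window_len > n)
    stop_invalid("lag_window_len exceeds signal length")
  if (is.null(nbins)) nbins <- n
  if (nbins < 2) stop_invalid("nbins must be >= 2")
  L <- (lag_window_len - 1) / 2
  m <- nbins - 1                       # DFT period over lag
  acf_mat <- matrix(0 + 0i, m, n)
  idx <- seq_len(n)
  for (l in seq(-L, L)) {
    keep <- idx + l >= 1 & idx + l <= n & idx - l >= 1 & idx - l <= n
    h <- if (taper == "hamming" && L > 0)
      0.54 + 0.46 * cos(pi * l / L) else 1
    r <- (l %% m) + 1
    acf_mat[r, keep] <- acf_mat[r, keep] +
      h * z[idx[keep] + l] * Conj(z[idx[keep] - l])
  }
  spec <- stats::mvfft(acf_mat) * (2 / rate)  # delta-tau = 2 / rate
  tot <- sum(Mod(spec)^2)
  if (tot > 0 && sum(Im(spec)^2) / tot > 1e-8)
    warning("WVD imaginary residue exceeds 1e-8 of total energy")
  vals <- t(rbind(Re(spec), Re(spec)[1, , drop = FALSE]))  # bin at rate/2
  freq_axis <- seq(0, rate / 2, length.out = nbins)
  new_tfd(vals, start_time + (idx - 1) / rate, freq_axis, rate)
}

#' Directional smoothing kernel
#'
#' Evaluates the oriented smoothing kernel
#' `(ab / 2*pi) * exp(-a^2 t_theta^2 - b^2 f_theta^2) * (1 - a^2 t_theta^2)`
#' on the integer grid, where `t_theta = t cos(theta) + f sin(theta)` and
#' `f_theta = f cos(theta) - t sin(theta)` are the rotated coordinates
#' (t = row/time offset, f = column/frequency offset). At `theta = 0` the
#' major (smoothing) axis lies along time, so the kernel enhances ridges
#' parallel to the time axis (tones, slow chirps); at `theta = 90` it
#' enhances ridges parallel to the frequency axis (spikes). Support is
#' truncated to the disc inscribed in the square grid so the retained mass
#' does not depend on orientation.
#'
#' @param theta orientation in degrees, in `[0, 180)`.
#' @param params a [kernel_params()] object.
#' @param normalize logical; scale to unit absolute sum (default `TRUE`).
#' @return a square matrix of side `2 * support_halfwidth + 1`.
#' @examples
#' k <- directional_kernel(0, kernel_params(support_halfwidth = 8))
#' sum(abs(k))
#' @export
directional_kernel <- function(theta, params = kernel_params(),
                               normalize = TRUE) {
  if (!is.numeric(theta) || length(theta) != 1 ||
      theta < 0 || theta >= 180)
    stop_invalid("theta must be a single angle in [0, 180)")
  h <- params$support_halfwidth
  g <- seq(-h, h)
  th <- theta * pi / 180
  tt <- outer(g, g, function(t, f) t * cos(th) + f * sin(th))
  ff <- outer(g, g, function(t, f) f * cos(th) - t * sin(th))
  k <- (params$a * params$b / (2 * pi)) *
    exp(-params$a^2 * tt^2 - params$b^2 * ff^2)
  if (params$doublet) k <- k * (1 - 2 * params$b^2 * ff^2)
  k[outer(g, g, function(t, f) t^2 + f^2) > (h + 0.5)^2] <- 0
  if (normalize) {
    s <- sum(abs(k))
    if (s > 0) k <- k / s
  }
  k
}

# --- FFT-domain "same" 2-D convolution with a cached kernel transform ----

.tfseize_cache <- new.env(parent = emptyenv())

.pad_dims <- function(nr, nc, h) {
  c(stats::nextn(nr + 2 * h, c(2, 3)), stats::nextn(nc + 2 * h, c(2, 3)))
}

.params_sig <- function(params) {
  paste(params$a, params$b, params$theta_step, params$support_halfwidth,
        params$doublet, sep = "|")
}

# FFT of kernel at `theta`, centred at the origin of a P x Q padded grid.
.kernel_fft <- function(theta, params, pq) {
  key <- paste(.params_sig(params), pq[1], pq[2], theta, sep = "|")
  got <- get0(key, envir = .tfseize_cache)
  if (!is.null(got)) return(got)
  h <- params$support_halfwidth
  k <- directional_kernel(theta, params)
  pad <- matrix(0, pq[1], pq[2])
  g <- seq(-h, h)
  pad[(g %% pq[1]) + 1, (g %% pq[2]) + 1] <- k
  kf <- stats::fft(pad)
  assign(key, kf, envir = .tfseize_cache)
  kf
}

# Forward FFT of a zero-padded matrix.
.padded_fft <- function(x, pq) {
  pad <- matrix(0, pq[1], pq[2])
  pad[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  stats::fft(pad)
}

# Same-size 2-D convolution of `xf` (padded FFT) with the cached kernel FFT.
.conv_from_fft <- function(xf, theta, params, pq, nr, nc) {
  y <- stats::fft(xf * .kernel_fft(theta, params, pq), inverse = TRUE)
  Re(y[seq_len(nr), seq_len(nc)]) / (pq[1] * pq[2])
}

#' Same-size 2-D convolution with a directional kernel
#'
#' Zero-padded FFT convolution of a matrix with the kernel at orientation
#' `theta`, returning the central (same-size) part. Used by the direction
#' map and the adaptive smoothing; exported for oracle tests and ablation.
#'
#' @param x real matrix.
#' @param theta orientation in degrees.
#' @param params a [kernel_params()] object.
#' @return matrix of the same dimensions as `x`.
#' @export
conv2_directional <- function(x, theta, params = kernel_params()) {
  pq <- .pad_dims(nrow(x), ncol(x), params$support_halfwidth)
  .conv_from_fft(.padded_fft(x, pq), theta, params, pq, nrow(x), ncol(x))
}

#' Ridge-direction map of a time-frequency distribution
#'
#' For each time-frequency point, finds the orientation on the quantized
#' grid `{0, theta_step, ...} < 180` degrees that maximizes the magnitude
#' of the 2-D convolution of `|tfd|` with the directional kernel. A ridge
#' aligned with the time axis (a tone or slow chirp) yields angles near 0
#' (equivalently near 180); a spike's vertical ridge yields angles near 90.
#' Responses within a relative tolerance of 1e-9 of the per-point maximum
#' are treated as tied and the smallest angle wins, so a featureless
#' (constant or zero) distribution maps to 0 degrees everywhere.
#'
#' @param tfd a `tfd` object.
#' @param params a [kernel_params()] object.
#' @return an object of class `direction_map` with fields `values`
#'   (degrees, same shape as the TFD) and `theta_grid`.
#' @export
direction_map <- function(tfd, params = kernel_params()) {
  check_finite(tfd$values, "tfd")
  m <- abs(tfd$values)
  nr <- nrow(m); nc <- ncol(m)
  pq <- .pad_dims(nr, nc, params$support_halfwidth)
  xf <- .padded_fft(m, pq)
  grid <- theta_grid(params)
  resp <- vector("list", length(grid))
  rmax <- matrix(-Inf, nr, nc)
  for (i in seq_along(grid)) {
    resp[[i]] <- abs(.conv_from_fft(xf, grid[i], params, pq, nr, nc))
    rmax <- pmax(rmax, resp[[i]])
  }
  thr <- rmax * (1 - 1e-9)
  ang <- matrix(grid[1], nr, nc)
  for (i in rev(seq_along(grid))) {
    ang[resp[[i]] >= thr] <- grid[i]
  }
  structure(list(values = ang, theta_grid = grid), class = "direction_map")
}

#' @export
print.direction_map <- function(x, ...) {
  cat(sprintf("<direction_map> %d x %d, %d angles in [0, 180)\n",
              nrow(x$values), ncol(x$values), length(x$theta_grid)))
  invisible(x)
}

#' Adaptive directional smoothing of a time-frequency distribution
#'
#' Point-wise adaptive smoothing: the output at `(t, f)` is the 2-D
#' convolution of the input with the directional kernel oriented at
#' `theta(t, f)`, evaluated at `(t, f)`. Implemented by smoothing once per
#' orientation present in the map and selecting per point. With the map
#' following local ridge directions this concentrates auto-terms along
#' their ridges while averaging the oscillatory cross-terms to near zero.
#'
#' @param tfd a `tfd` object (typically a WVD).
#' @param dmap a `direction_map` of the same shape.
#' @param params a [kernel_params()] object.
#' @return a `tfd` object of the same shape and axes.
#' @export
adtfd <- function(tfd, dmap, params = kernel_params()) {
  if (!identical(dim(tfd$values), dim(dmap$values)))
    stop_invalid("direction map shape does not match the TFD")
  nr <- nrow(tfd$values); nc <- ncol(tfd$values)
  pq <- .pad_dims(nr, nc, params$support_halfwidth)
  xf <- .padded_fft(tfd$values, pq)
  out <- matrix(0, nr, nc)
  for (th in sort(unique(as.vector(dmap$values)))) {
    sel <- dmap$values == th
    sm <- .conv_from_fft(xf, th, params, pq, nr, nc)
    out[sel] <- sm[sel]
  }
  new_tfd(out, tfd$time_axis, tfd$freq_axis, tfd$rate)
}

#' Adaptive directional TFD of a signal
#'
#' Runs the full chain: analytic associate, windowed Wigner-Ville
#' distribution, ridge-direction map of the WVD, adaptive directional
#' smoothing, and a final direction map recomputed on the smoothed
#' distribution (the map used for downstream ridge gating).
#'
#' @param x a `sampled_signal` (real) or numeric vector.
#' @param params a [kernel_params()] object.
#' @param rate sampling rate in Hz if `x` is a bare vector.
#' @param nbins frequency bins for the WVD; default the signal length.
#' @return a list of class `adtfd_result` with elements `tfd` (the smoothed
#'   distribution), `dmap` (direction map of the smoothed distribution) and
#'   `wvd` (the raw Wigner-Ville distribution).
#' @examples
#' \donttest{
#' x <- sampled_signal(cos(2 * pi * 3 * (0:255) / 32), rate = 32)
#' r <- compute_adtfd(x)
#' }
#' @export
compute_adtfd <- function(x, params = kernel_params(), rate = NULL,
                          nbins = NULL) {
  if (!inherits(x, "sampled_signal")) {
    if (is.null(rate)) stop_invalid("rate is required for a bare vector")
    x <- sampled_signal(x, rate)
  }
  n <- length(x$samples)
  lag <- params$lag_window_len
  if (is.null(lag)) lag <- n - (1 - n %% 2)
  if (n < lag) stop_invalid("signal shorter than the lag window")
  z <- analytic_signal(x)
  w <- wvd(z, rate = x$rate, lag_window_len = lag, nbins = nbins,
           start_time = x$start_time)
  dmap0 <- direction_map(w, params)
  rho <- adtfd(w, dmap0, params)
  dmap <- direction_map(rho, params)
  structure(list(tfd = rho, dmap = dmap, wvd = w), class = "adtfd_result")
}

#' @export
print.adtfd_result <- function(x, ...) {
  cat("<adtfd_result>\n  ")
  print(x$tfd)
  invisible(x)
}
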