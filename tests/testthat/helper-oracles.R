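# Independent brute-force oracles and shared fixtures.
# Heavy ADTFD chains are cached so several test files can reuse one run.

.chain_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  got <- get0(key, envir = .chain_cache)
  if (is.null(got)) {
    got <- make()
    assign(key, got, envir = .chain_cache)
  }
  got
}

tone_signal <- function(f0 = 4, n = 256, rate = 32)
  sampled_signal(cos(2 * pi * f0 * (seq_len(n) - 1) / rate), rate)

tone_chain <- function() cached("tone4", function() compute_adtfd(tone_signal()))

spike_chain <- function() cached("spike3", function()
  compute_adtfd(gen_spike_train(c(2, 4, 6), 32, 8)))

chirp_chain <- function() cached("chirp13", function()
  compute_adtfd(gen_chirp_sum(cbind(c(0, 8), c(1, 3)), n_harmonics = 1,
                              rate = 32, duration = 8)))

chirp3_chain <- function() cached("chirp13h3", function()
  compute_adtfd(gen_chirp_sum(cbind(c(0, 8), c(1, 3)), n_harmonics = 3,
                              rate = 32, duration = 8)))

noise_chain <- function(seed) cached(paste0("noise", seed), function()
  compute_adtfd(gen_background(32, 8, seed = seed)))

# points in the top decile of the energy range
strong_points <- function(tfd) abs(tfd$values) >= 0.1 * max(abs(tfd$values))

gate_energy_fraction <- function(res, gate) {
  e <- abs(res$tfd$values)
  sum(e[gate(res$dmap$values)]) / sum(e)
}

horiz_gate <- function(th) th < 10 | th > 170
vert_gate <- function(th) th > 80 & th < 100
union_gate <- function(th) horiz_gate(th) | vert_gate(th)

# O(N^2 * Ntau) direct evaluation of the discrete windowed WVD:
# explicit lag loop and explicit DFT sum, no FFT.
brute_wvd <- function(z, rate, lag_window_len, nbins,
                      taper = "rectangular") {
  n <- length(z)
  L <- (lag_window_len - 1) / 2
  out <- matrix(0, n, nbins)
  fk <- seq(0, rate / 2, length.out = nbins)
  for (ti in seq_len(n)) {
    for (l in seq(-L, L)) {
      if (ti + l < 1 || ti + l > n || ti - l < 1 || ti - l > n) next
      h <- if (taper == "hamming" && L > 0) 0.54 + 0.46 * cos(pi * l / L) else 1
      k <- h * z[ti + l] * Conj(z[ti - l])
      out[ti, ] <- out[ti, ] + Re(k * exp(-2i * pi * fk * (2 * l / rate)))
    }
  }
  out * (2 / rate)
}

# direct spatial-domain same-size 2-D convolution
brute_conv2 <- function(x, k) {
  h <- (nrow(k) - 1) / 2
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- i - di; jj <- j - dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        acc <- acc + x[ii, jj] * k[di + h + 1, dj + h + 1]
    }
    out[i, j] <- acc
  }
  out
}

# short-time spectral-peak instantaneous-frequency estimate
stft_peak_if <- function(x, rate, win = 64, hop = 8) {
  n <- length(x$samples)
  starts <- seq(1, n - win + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  pad <- 8L  # zero-pad factor for finer peak resolution
  vapply(starts, function(s) {
    seg <- x$samples[s:(s + win - 1)] * w
    sp <- Mod(stats::fft(c(seg, numeric(win * (pad - 1)))))^2
    half <- seq_len(win * pad / 2)
    (which.max(sp[half]) - 1) * rate / (win * pad)
  }, numeric(1))
}

make_tfd <- function(values, rate = 32, fmax = rate / 2) {
  tfseize:::new_tfd(values, (seq_len(nrow(values)) - 1) / rate,
                    seq(0, fmax, length.out = ncol(values)), rate)
}

make_dmap <- function(values, step = 3) {
  structure(list(values = values, theta_grid = seq(0, 177, by = step)),
            class = "direction_map")
}
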