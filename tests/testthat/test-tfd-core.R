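test_that("analytic signal has the defining properties", {
  x <- cos(2 * pi * 4 * (0:255) / 32)
  z <- analytic_signal(x)
  expect_equal(length(z), 256)
  expect_lt(max(abs(Re(z) - x)), 1e-10)
  # unit-modulus cisoid away from edges
  expect_lt(max(abs(Mod(z[17:240]) - 1)), 1e-2)
  # spectrum vanishes on negative-frequency bins
  sp <- fft(z)
  expect_lt(max(Mod(sp[130:256])) / max(Mod(sp)), 1e-10)
  # DC passes unchanged
  expect_equal(analytic_signal(rep(1, 16)), rep(1 + 0i, 16))
  expect_error(analytic_signal(c(1, NA, 3)), "non-finite")
})

test_that("WVD localizes a tone and satisfies the time-marginal identity", {
  z <- analytic_signal(cos(2 * pi * 4 * (0:255) / 32))
  W <- wvd(z, rate = 32)
  expect_equal(dim(W$values), c(256, 256))
  expect_equal(W$freq_axis[which.max(colMeans(W$values))], 4,
               tolerance = 0.02)
  marg <- rowSums(W$values) * diff(W$freq_axis[1:2])
  i <- 30:225
  expect_lt(max(abs(marg[i] - Mod(z[i])^2) / Mod(z[i])^2), 0.02)
  expect_error(wvd(z, rate = 32, lag_window_len = 128), "odd")
})

test_that("WVD matches the brute-force lag/DFT oracle on small instances", {
  set.seed(11)
  for (case in list(
    list(z = analytic_signal(cos(2 * pi * 2 * (0:63) / 32) +
                               cos(2 * pi * 6 * (0:63) / 32)), lag = 63),
    list(z = analytic_signal(rnorm(48)), lag = 31))) {
    for (taper in c("rectangular", "hamming")) {
      W <- wvd(case$z, rate = 32, lag_window_len = case$lag,
               nbins = length(case$z), taper = taper)
      B <- brute_wvd(case$z, 32, case$lag, length(case$z), taper)
      expect_lt(max(abs(W$values - B)), 1e-8)
    }
  }
})

test_that("two-tone WVD carries an oscillating mid-band cross-term", {
  z <- analytic_signal(cos(2 * pi * 2 * (0:255) / 32) +
                         cos(2 * pi * 6 * (0:255) / 32))
  W <- wvd(z, rate = 32)
  mid <- which.min(abs(W$freq_axis - 4))
  ct <- W$values[64:192, mid]
  expect_gt(max(abs(ct)), 1)       # cross-term present at 4 Hz
  expect_lt(mean(ct), max(abs(ct)) / 4)  # and oscillating in sign
})

test_that("directional kernel has the stated geometry", {
  p <- kernel_params(support_halfwidth = 4)
  k0 <- directional_kernel(0, p, normalize = FALSE)
  # even under point reflection
  expect_equal(k0, k0[9:1, 9:1])
  # origin value before normalization is ab/(2*pi)
  expect_equal(k0[5, 5], p$a * p$b / (2 * pi))
  # rotation by 90 degrees swaps the axes
  k90 <- directional_kernel(90, p, normalize = FALSE)
  expect_lt(max(abs(k90 - t(k0))), 1e-10)
  expect_equal(sum(abs(directional_kernel(37, p))), 1, tolerance = 1e-12)
  expect_error(directional_kernel(180, p), "\\[0, 180\\)")
  expect_error(kernel_params(theta_step = 7), "divide")
  expect_error(kernel_params(lag_window_len = 64), "odd")
})

test_that("direction map recovers ridge orientation and ties break low", {
  p <- kernel_params()
  tone <- tone_chain()
  W <- tone$wvd
  dm <- direction_map(W, p)
  sp <- strong_points(W)
  expect_gte(mean(horiz_gate(dm$values[sp])), 0.9)

  spike <- spike_chain()
  dms <- direction_map(spike$wvd, p)
  sps <- strong_points(spike$wvd)
  expect_gte(mean(vert_gate(dms$values[sps])), 0.9)

  # ties resolve to the smallest grid angle: exact on a zero field, and on
  # the interior of a flat field under the all-positive Gaussian kernel
  # (the ridge-enhancing doublet has near-zero flat-field response, so its
  # direction there is immaterial -- the gated values vanish)
  zero <- make_tfd(matrix(0, 96, 96))
  expect_true(all(direction_map(zero, p)$values == 0))
  flat <- make_tfd(matrix(1, 96, 96))
  pg <- kernel_params(doublet = FALSE)
  expect_true(all(direction_map(flat, pg)$values[38:59, 38:59] == 0))
})

test_that("direction map is transpose-equivariant", {
  p <- kernel_params()
  W <- tone_chain()$wvd
  dm <- direction_map(W, p)
  Wt <- make_tfd(t(W$values))
  dmt <- direction_map(Wt, p)
  sp <- strong_points(W)
  d <- abs(((90 - t(dmt$values)) %% 180) - dm$values)
  d <- pmin(d, 180 - d)
  expect_lte(stats::quantile(d[sp], 0.9), p$theta_step)
})

test_that("adaptive smoothing is linear, per-angle exact, and shape-safe", {
  p <- kernel_params(support_halfwidth = 8)
  zeromat <- make_tfd(matrix(0, 64, 64))
  dm <- make_dmap(matrix(42, 64, 64))
  expect_true(all(adtfd(zeromat, dm, p)$values == 0))
  # uniform-angle map equals plain 2-D convolution with that kernel
  set.seed(5)
  x <- make_tfd(matrix(rnorm(64 * 64), 64))
  got <- adtfd(x, dm, p)$values
  want <- brute_conv2(x$values, directional_kernel(42, p))
  expect_lt(max(abs(got - want)), 1e-10)
  expect_error(adtfd(x, make_dmap(matrix(0, 32, 32)), p), "shape")
})

test_that("ADTFD suppresses the two-tone cross-term", {
  x <- sampled_signal(cos(2 * pi * 2 * (0:255) / 32) +
                        cos(2 * pi * 6 * (0:255) / 32), 32)
  r <- cached("twotone", function() compute_adtfd(x))
  band <- r$tfd$freq_axis >= 3.5 & r$tfd$freq_axis <= 4.5
  ratio <- sum(abs(r$tfd$values[, band])) / sum(abs(r$wvd$values[, band]))
  expect_lt(ratio, 0.2)
})

test_that("directional smoothing beats matched-area isotropic smoothing", {
  r <- tone_chain()
  conc <- function(m) {
    a <- abs(m)
    mean(apply(a, 1, max) / pmax(rowSums(a), 1e-300))
  }
  sd_iso <- sqrt(12 * 2)  # geometric mean of the directional stds
  p_iso <- kernel_params(a = 1 / (sd_iso * sqrt(2)),
                         b = 1 / (sd_iso * sqrt(2)), doublet = FALSE)
  iso <- conv2_directional(r$wvd$values, 0, p_iso)
  expect_gte(conc(r$tfd$values), conc(iso))
})

test_that("Gaussian-kernel smoothing approximately conserves interior energy", {
  p <- kernel_params(doublet = FALSE)
  r <- tone_chain()
  dm <- direction_map(r$wvd, p)
  sm <- adtfd(r$wvd, dm, p)
  interior <- 48:208
  ratio <- sum(abs(sm$values[interior, ])) / sum(abs(r$wvd$values[interior, ]))
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 1.5)
})

test_that("full chain gates the synthetic signal classes correctly", {
  expect_gte(gate_energy_fraction(spike_chain(), vert_gate), 0.7)
  expect_gte(gate_energy_fraction(chirp_chain(), horiz_gate), 0.7)
  noise <- vapply(1:10, function(s)
    gate_energy_fraction(noise_chain(s), union_gate), numeric(1))
  expect_lt(stats::median(noise),
            gate_energy_fraction(spike_chain(), union_gate))
  expect_lt(stats::median(noise),
            gate_energy_fraction(chirp_chain(), union_gate))
  expect_lt(stats::median(noise),
            gate_energy_fraction(chirp3_chain(), union_gate))
})
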