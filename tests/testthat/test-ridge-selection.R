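test_that("ridge gates copy or zero pointwise by angle", {
  set.seed(3)
  rho <- make_tfd(matrix(rnorm(32 * 32), 32))
  all90 <- make_dmap(matrix(90, 32, 32))
  all0 <- make_dmap(matrix(0, 32, 32))
  expect_equal(select_freq_axis_ridges(rho, all90)$values, rho$values)
  expect_true(all(select_freq_axis_ridges(rho, all0)$values == 0))
  expect_equal(select_time_axis_ridges(rho, all0)$values, rho$values)
  expect_true(all(select_time_axis_ridges(rho, all90)$values == 0))
  expect_error(select_freq_axis_ridges(rho, make_dmap(matrix(90, 8, 8))),
               "shape")
})

test_that("exactly the expected 3-degree grid angles pass each gate", {
  grid <- seq(0, 177, by = 3)
  passes_freq <- grid[grid > 80 & grid < 100]
  passes_time <- grid[grid < 10 | grid > 170]
  expect_equal(passes_freq, seq(81, 99, by = 3))
  expect_equal(passes_time, c(0, 3, 6, 9, 171, 174, 177))
  expect_length(intersect(passes_freq, passes_time), 0)
  rho <- make_tfd(matrix(1, 8, 8))
  for (th in grid) {
    dm <- make_dmap(matrix(th, 8, 8))
    ft <- select_freq_axis_ridges(rho, dm)$values[1, 1]
    tt <- select_time_axis_ridges(rho, dm)$values[1, 1]
    expect_equal(ft, as.numeric(th %in% passes_freq))
    expect_equal(tt, as.numeric(th %in% passes_time))
  }
})

test_that("filtered TFD is the disjoint union of the two gates", {
  r <- spike_chain()
  rho_t <- select_freq_axis_ridges(r$tfd, r$dmap)
  rho_f <- select_time_axis_ridges(r$tfd, r$dmap)
  fil <- filtered_tfd(rho_t, rho_f)
  # disjoint supports, pointwise product identically zero
  expect_true(all(rho_t$values * rho_f$values == 0))
  expect_equal(fil$values != 0, (rho_t$values != 0) | (rho_f$values != 0))
  # restricted to either support the union equals rho exactly
  on_gate <- fil$values != 0
  expect_identical(fil$values[on_gate], r$tfd$values[on_gate])
  # additive identity when one side is empty
  empty <- select_freq_axis_ridges(r$tfd, make_dmap(
    matrix(0, nrow(r$tfd$values), ncol(r$tfd$values))))
  expect_equal(filtered_tfd(empty, rho_f)$values, rho_f$values)
  expect_error(filtered_tfd(rho_f, rho_t), "gate")
})

test_that("energy retention separates seizure-like from background", {
  seiz <- cached("spiketone", function() {
    sp <- gen_spike_train(c(1, 3.2, 5.1, 7), 32, 8)
    tn <- gen_chirp_sum(cbind(0, 2.5), n_harmonics = 1, rate = 32,
                        duration = 8)
    compute_adtfd(sampled_signal(2 * sp$samples + tn$samples, 32))
  })
  r_seiz <- energy_retention(seiz$tfd, seiz$dmap)
  expect_gte(r_seiz, 0.6)
  r_noise <- vapply(1:10, function(s) {
    r <- noise_chain(s)
    energy_retention(r$tfd, r$dmap)
  }, numeric(1))
  expect_gte(sum(r_noise < r_seiz), 9)
})

test_that("marginals integrate the gated distributions correctly", {
  m <- matrix(0, 16, 16)
  rho <- make_tfd(m)
  open_t <- make_dmap(matrix(90, 16, 16))
  open_f <- make_dmap(matrix(0, 16, 16))
  # zero matrix -> zero marginals
  expect_true(all(time_marginal(
    select_freq_axis_ridges(rho, open_t))$values == 0))
  expect_true(all(frequency_marginal(
    select_time_axis_ridges(rho, open_f))$values == 0))
  # single nonzero column at t0 -> time marginal nonzero only there
  m2 <- m; m2[5, ] <- 2
  tm <- time_marginal(select_freq_axis_ridges(make_tfd(m2), open_t))
  expect_equal(which(tm$values != 0), 5)
  # single nonzero row at f0 -> frequency marginal nonzero only there
  m3 <- m; m3[, 7] <- 3
  fm <- frequency_marginal(select_time_axis_ridges(make_tfd(m3), open_f))
  expect_equal(which(fm$values != 0), 7)
  # gate mismatch is an error
  expect_error(time_marginal(select_time_axis_ridges(rho, open_f)), "gate")
  expect_error(frequency_marginal(select_freq_axis_ridges(rho, open_t)),
               "gate")
})

test_that("gated marginals localize spikes in time and tones in frequency", {
  r <- cached("spike1s_tone", function() {
    sp <- gen_spike_train(1.0, 32, 8)
    tn <- gen_chirp_sum(cbind(0, 2.5), n_harmonics = 1, rate = 32,
                        duration = 8)
    # raised-cosine onset/offset (1 s) so the tone is a smooth burst, not a
    # hard cut whose broadband switching transients would masquerade as
    # spikes
    t <- time_axis(tn)
    env <- pmin(1, pmin(t, 8 - 1 / 32 - t) / 1)
    env <- 0.5 - 0.5 * cos(pi * pmin(pmax(env, 0), 1))
    compute_adtfd(sampled_signal(3 * sp$samples + tn$samples * env, 32))
  })
  s_t <- time_marginal(select_freq_axis_ridges(r$tfd, r$dmap))
  near <- abs(s_t$axis - 1.0) <= 0.25
  expect_gte(sum(abs(s_t$values[near])) / sum(abs(s_t$values)), 0.9)
  s_f <- frequency_marginal(select_time_axis_ridges(r$tfd, r$dmap))
  band <- s_f$axis >= 2 & s_f$axis <= 3
  expect_gte(sum(abs(s_f$values[band])) / sum(abs(s_f$values)), 0.8)
})

test_that("support partition and gate-widening monotonicity hold", {
  r <- spike_chain()
  rho_t <- select_freq_axis_ridges(r$tfd, r$dmap)
  rho_f <- select_time_axis_ridges(r$tfd, r$dmap)
  df <- diff(r$tfd$freq_axis[1:2])
  # partition additivity of the time marginal over the three supports
  comp <- r$tfd$values
  comp[rho_t$values != 0 | rho_f$values != 0] <- 0
  lhs <- rowSums(rho_t$values) + rowSums(rho_f$values) + rowSums(comp)
  expect_equal(lhs * df, rowSums(r$tfd$values) * df)
  # widening the freq-axis gate can only add support
  wide <- r$tfd$values
  wide[!(r$dmap$values > 70 & r$dmap$values < 110)] <- 0
  expect_gte(sum(abs(wide)), sum(abs(rho_t$values)))
})
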