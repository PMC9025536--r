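marginal_of <- function(values, axis_type = "time", bin_width = NULL,
                        axis = NULL) {
  if (axis_type == "time") {
    if (is.null(bin_width)) bin_width <- 8 / length(values)
    if (is.null(axis)) axis <- (seq_along(values) - 1) * bin_width
  } else {
    if (is.null(axis)) axis <- seq(0, 16, length.out = length(values))
    if (is.null(bin_width)) bin_width <- diff(axis[1:2])
  }
  tfseize:::new_marginal(values, axis, axis_type, bin_width)
}

test_that("time-marginal quarters integrate as stated", {
  s1 <- marginal_of(rep(1, 256))
  expect_equal(unname(time_marginal_features(s1)), rep(2, 4))
  # all mass in the last quarter
  v <- numeric(256); v[225] <- 5
  tk <- time_marginal_features(marginal_of(v))
  expect_equal(unname(tk), c(0, 0, 0, 5 * 8 / 256))
  # an impulse at t = 1.0 s lands almost entirely in T1
  v2 <- numeric(256); v2[33] <- 1
  tk2 <- time_marginal_features(marginal_of(v2))
  expect_gte(tk2[["T1"]] / sum(tk2), 0.99)
  expect_error(time_marginal_features(marginal_of(rep(1, 100),
                                                  bin_width = 0.05)),
               "8 s")
  # partition completeness is exact
  set.seed(2)
  v3 <- rnorm(256)
  expect_equal(sum(time_marginal_features(marginal_of(v3))),
               sum(v3) * 8 / 256)
})

test_that("frequency-band energies follow the six sub-bands", {
  s1 <- marginal_of(rep(1, 1601), "frequency", bin_width = 0.01,
                    axis = seq(0, 16, by = 0.01))
  f <- frequency_marginal_features(s1)
  expect_equal(unname(f), c(1, 1, 1, 1, 4, 8), tolerance = 0.01)
  expect_true(all(frequency_marginal_features(
    marginal_of(numeric(257), "frequency")) == 0))
  expect_error(frequency_marginal_features(
    marginal_of(rep(1, 100), "frequency", axis = seq(0, 8, length.out = 100))),
    "16 Hz")
  # partition completeness
  set.seed(4)
  v <- rnorm(257)
  expect_equal(sum(frequency_marginal_features(marginal_of(v, "frequency"))),
               sum(v) * 16 / 256)
})

test_that("TF statistics behave on constant and hand-computed inputs", {
  u <- make_tfd(matrix(3, 16, 16))
  tf <- tf_statistical_features(u)
  expect_equal(unname(tf[c("TF2", "TF3", "TF8")]), c(0, 0, 0))
  expect_equal(tf[["TF6"]], 1)
  # 2x2 matrix [[0,0],[0,4]] on a unit grid
  m <- make_tfd(matrix(c(0, 0, 0, 4), 2, 2), rate = 1, fmax = 1)
  tf2 <- tf_statistical_features(m)
  expect_equal(tf2[["TF1"]], 1)
  expect_equal(tf2[["TF7"]], 2)
  expect_equal(tf2[["TF8"]], 4)
  # transpose invariance of all eight statistics
  set.seed(9)
  a <- matrix(rnorm(64 * 64), 64)
  expect_equal(tf_statistical_features(make_tfd(a)),
               tf_statistical_features(make_tfd(t(a))))
  # degenerate flag on the zero matrix
  z <- tf_statistical_features(make_tfd(matrix(0, 8, 8)))
  expect_true(attr(z, "degenerate"))
  expect_equal(unname(z[c("TF3", "TF6")]), c(0, 0))
})

test_that("feature vector has fixed order, determinism and degeneracy path", {
  r1 <- cached("featvec", function()
    extract_features(tone_signal(2.5)))
  expect_named(r1, feature_names())
  expect_true(all(is.finite(r1)))
  # the 2-3 Hz band dominates for a 2.5 Hz tone
  expect_equal(names(which.max(r1[5:10])), "F3")
  r2 <- extract_features(tone_signal(2.5))
  expect_identical(as.numeric(r1), as.numeric(r2))
  expect_warning(fz <- extract_features(sampled_signal(numeric(256), 32)),
                 "degenerate")
  expect_true(all(fz[1:10] == 0))
  expect_error(extract_features(sampled_signal(numeric(100), 32)), "256")
  expect_error(extract_features(sampled_signal(numeric(256), 64)), "32 Hz")
})

test_that("spike trains weigh time features; chirps weigh frequency features", {
  f_spike <- cached("feat_spike", function()
    extract_features(gen_spike_train(c(1, 2.1, 3, 4.2, 5, 6.1, 7), 32, 8)))
  f_chirp <- cached("feat_chirp", function()
    extract_features(gen_chirp_sum(cbind(c(0, 8), c(1, 3)), rate = 32,
                                   duration = 8)))
  ratio <- function(f) sum(abs(f[1:4])) / sum(abs(f[5:10]))
  expect_gt(ratio(f_spike), ratio(f_chirp))
})

test_that("features scale as the quadratic TFD dictates", {
  f1 <- cached("featvec", function() extract_features(tone_signal(2.5)))
  c_ <- 3.7
  f2 <- cached("featvec_scaled", function()
    extract_features(sampled_signal(c_ * tone_signal(2.5)$samples, 32)))
  quad <- c(paste0("T", 1:4), paste0("F", 1:6), "TF1", "TF2")
  expect_equal(unname(f2[quad] / f1[quad]), rep(c_^2, 12), tolerance = 1e-6)
  inv <- c("TF3", "TF4", "TF5", "TF6")
  expect_equal(unname(f2[inv]), unname(f1[inv]), tolerance = 1e-6)
})

test_that("feature statistics stay finite on fuzzed inputs", {
  set.seed(77)
  for (i in 1:200) {
    m <- matrix(rnorm(32 * 32, sd = 10^runif(1, -6, 6)), 32)
    if (i %% 7 == 0) m[] <- 0
    if (i %% 11 == 0) m[sample(1024, 512)] <- 0
    expect_true(all(is.finite(tf_statistical_features(make_tfd(m)))))
    v <- rnorm(256, sd = 10^runif(1, -6, 6))
    expect_true(all(is.finite(time_marginal_features(marginal_of(v)))))
    expect_true(all(is.finite(frequency_marginal_features(
      marginal_of(rnorm(257), "frequency")))))
  }
  # and on a handful of full-chain random segments
  for (s in 1:3) {
    fv <- suppressWarnings(
      extract_features(gen_background(32, 8, seed = 1000 + s)))
    expect_true(all(is.finite(fv)))
  }
})
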