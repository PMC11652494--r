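test_that("sliding windows cover exactly the gesture-hold period", {
  set.seed(11)
  sig <- matrix(rnorm(8 * 4000), 8)
  tr <- emg_trial(sig, fs = 2000, gesture = 1, hold_start = 2001L)
  w <- sliding_windows(tr)
  expect_length(w, 9L)                       # floor((1000-200)/100)+1
  expect_equal(ncol(w[[1]]), 400L)
  starts <- attr(w, "starts")
  expect_equal(starts[1], 2001L)             # only the hold second is used
  expect_true(all(diff(starts) == 200L))

  # 200 ms hold: exactly one window
  tr2 <- emg_trial(sig[, 1:400], fs = 2000, gesture = 1, hold_start = 1L)
  expect_length(sliding_windows(tr2), 1L)

  # hold shorter than one window is an explicit error
  tr3 <- emg_trial(sig, fs = 2000, gesture = 1, hold_start = 3801L)
  expect_error(sliding_windows(tr3), "shorter")

  # window count rule for assorted hold lengths
  for (hold_ms in c(300, 450, 1000, 1700)) {
    trh <- emg_trial(sig[, 1:(hold_ms * 2), drop = FALSE], fs = 2000,
                     gesture = 1, hold_start = 1L)
    expect_length(sliding_windows(trh), floor((hold_ms - 200) / 100) + 1)
  }
})

test_that("energy features match hand arithmetic and the naive oracle", {
  expect_equal(unname(energy_features(c(1, -2, 3, -4))[c("mav", "rms")]),
               c(2.5, sqrt(7.5)))
  expect_equal(unname(energy_features(c(1, 3, 2))[["wl"]]), 3)
  alt <- energy_features(c(1, -1, 1, -1))
  expect_equal(unname(alt[["zc"]]), 3)
  expect_equal(unname(alt[["ssc"]]), 2)

  set.seed(42)
  for (rep in 1:5) {
    x <- rnorm(400)
    got <- energy_features(x)
    expect_equal(unname(got),
                 c(naive_mav(x), naive_wl(x), naive_rms(x),
                   naive_ssc(x), naive_zc(x)),
                 tolerance = 1e-12)
  }
  expect_error(energy_features(numeric(0)), "empty")
})

test_that("skewness follows the biased convention with degenerate guard", {
  expect_equal(unname(distribution_feature(c(-2, -1, 0, 1, 2))), 0)
  expect_equal(unname(distribution_feature(rep(3, 10))), 0)
  x <- c(0, 0, 0, 1)
  expect_equal(unname(distribution_feature(x)), naive_skew(x))
  expect_gt(distribution_feature(x), 0)
})

test_that("spectral features behave on tones and match the DFT oracle", {
  fs <- 1000
  t <- (0:399) / fs
  tone <- sin(2 * pi * 50 * t)
  sf <- spectral_features(tone, fs)
  expect_equal(unname(sf[["pkf"]]), 50)
  expect_equal(unname(sf[["mnf"]]), 50, tolerance = 1e-6)
  expect_lt(sf[["vcf"]], 1e-6)

  two <- sin(2 * pi * 50 * t) + sin(2 * pi * 150 * t)
  expect_equal(unname(spectral_features(two, fs)[["mnf"]]), 100,
               tolerance = 1e-6)

  expect_equal(unname(spectral_features(rep(0, 64), fs)), rep(0, 4))
  expect_equal(unname(spectral_features(rep(2.5, 64), fs)), rep(0, 4))

  set.seed(7)
  for (rep in 1:3) {
    x <- rnorm(64)
    expect_equal(unname(spectral_features(x, 2000)),
                 unname(naive_spectral(x, 2000)), tolerance = 1e-9)
  }
})

test_that("feature vector layout is channel-major with group toggles", {
  set.seed(3)
  w <- matrix(rnorm(8 * 400), 8)
  full <- extract_features(w, fs = 2000)
  expect_length(full, 80L)
  expect_match(names(full)[1], "^ch1_mav$")
  expect_match(names(full)[80], "^ch8_vcf$")
  expect_length(extract_features(w, 2000, groups = "energy"), 40L)
  expect_length(extract_features(w, 2000, groups = c("energy", "spectrum")), 72L)
  expect_error(extract_features(w, 2000, groups = character(0)), "group")

  # channel-major: channel 2's block equals features of channel 2 alone
  ch2 <- extract_features(w[2, , drop = FALSE], fs = 2000)
  expect_equal(unname(full[11:20]), unname(ch2))
})

test_that("amplitude scaling moves energy features and nothing else", {
  set.seed(9)
  x <- rnorm(400)
  c0 <- extract_features(matrix(x, 1), fs = 2000)
  c3 <- extract_features(matrix(3 * x, 1), fs = 2000)
  scaled <- c("ch1_mav", "ch1_wl", "ch1_rms")
  expect_equal(unname(c3[scaled]), 3 * unname(c0[scaled]))
  invariant <- setdiff(names(c0), scaled)
  expect_equal(unname(c3[invariant]), unname(c0[invariant]), tolerance = 1e-9)
})

test_that("z-score normalizer fits, applies and degrades gracefully", {
  st <- fit_normalizer(matrix(c(0, 2), ncol = 1))
  expect_equal(unname(st$mean), 1)
  expect_equal(unname(st$sd), sqrt(2))

  set.seed(5)
  X <- matrix(rnorm(50 * 4), 50)
  X[, 3] <- 7 # constant dimension
  st <- fit_normalizer(X)
  Z <- apply_normalizer(st, X)
  expect_equal(unname(colMeans(Z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(Z[, -3], 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(Z[, 3] == 0))
  expect_false(anyNA(Z))
  expect_error(apply_normalizer(st, X[, 1:3]), "mismatch")
})

test_that("features depend on the signal, not on trial metadata", {
  set.seed(10)
  sig <- matrix(rnorm(8 * 2400), 8)
  a <- trial_features(emg_trial(sig, 2000, gesture = 1, position = "P5",
                                hold_start = 1L))
  b <- trial_features(emg_trial(sig, 2000, gesture = 5, position = "P8",
                                hold_start = 1L))
  expect_equal(unname(a), unname(b), ignore_attr = TRUE)
})

test_that("every feature matches its naive oracle on seeded random windows", {
  set.seed(1234)
  for (rep in 1:20) {
    x <- rnorm(80, sd = runif(1, 0.1, 5))
    e <- energy_features(x)
    expect_equal(unname(e), c(naive_mav(x), naive_wl(x), naive_rms(x),
                              naive_ssc(x), naive_zc(x)), tolerance = 1e-9)
    expect_equal(unname(distribution_feature(x)), naive_skew(x),
                 tolerance = 1e-9)
    expect_equal(unname(spectral_features(x, 2000)),
                 unname(naive_spectral(x, 2000)), tolerance = 1e-9)
  }
})
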