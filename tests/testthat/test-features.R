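test_that("segmentation uses the floor rule", {
  expect_length(segment_signal(rnorm(1024)), 2L)
  expect_length(segment_signal(rnorm(1535)), 2L)
  expect_length(segment_signal(rnorm(512)), 1L)
  expect_error(segment_signal(rnorm(511)), "too short")
})

test_that("time moments match brute-force central-moment formulas", {
  tm <- time_moments(rep(95, 1024))
  expect_equal(unname(tm), c(95, 0, 0, 0))

  x <- rep(c(90, 100), 256)
  tm <- time_moments(x)
  expect_equal(unname(tm[c("M1t", "M3t")]), c(95, 0))

  set.seed(5)
  x <- runif(512, 80, 100)
  tm <- time_moments(x)
  mu <- mean(x); m2 <- mean((x - mu)^2)
  expect_equal(unname(tm), c(mu, m2, mean((x - mu)^3) / m2^1.5,
                             mean((x - mu)^4) / m2^2))
  # Gaussian kurtosis convention: standardized 4th moment near 3
  set.seed(6)
  g <- time_moments(rnorm(512 * 64), 512)
  expect_equal(unname(g["M4t"]), 3, tolerance = 0.1)
})

test_that("Welch PSD locates peaks, is flat for white noise and obeys Parseval", {
  t <- 0:4095
  x <- 94 + 2 * sin(2 * pi * 0.02 * t)
  p <- welch_psd(x)
  expect_length(p$psd, 513L)
  expect_equal(p$resolution, 1 / 1024)
  expect_lt(abs(p$frequencies[which.max(p$psd)] - 0.02), 1.5 / 1024)

  set.seed(8)
  w <- rnorm(2^15)
  pw <- welch_psd(w)
  # flat within sampling error: CV across bins shrinks with averaging
  inner <- pw$psd[5:500]
  expect_lt(stats::sd(inner) / mean(inner), 0.5)
  expect_equal(sum(pw$psd) * pw$resolution, var(w), tolerance = 0.05 * var(w))

  expect_equal(sum(p$psd) * p$resolution, var(x - mean(x)),
               tolerance = 0.05 * var(x))
})

test_that("frequency moments, MF and SE behave on canonical spectra", {
  flat <- structure(list(frequencies = seq(0, 0.5, length.out = 100),
                         psd = rep(2, 100), resolution = 0.5 / 99),
                    class = "spectral_estimate")
  fm <- freq_moments(flat)
  expect_equal(unname(fm["M1f"]), 1 / 100)
  expect_equal(unname(fm["M2f"]), 0)
  expect_equal(spectral_entropy(flat), 1)
  expect_equal(median_frequency(flat), flat$frequencies[50])  # ~ Nyquist/2

  onehot <- flat; onehot$psd <- c(rep(0, 40), 7, rep(0, 59))
  fm1 <- freq_moments(onehot)
  # variance of a one-hot normalized vector: closed form (N-1)/N^2
  expect_equal(unname(fm1["M2f"]), 99 / 100^2)
  expect_equal(spectral_entropy(onehot), 0)
  expect_equal(median_frequency(onehot), onehot$frequencies[41])

  two <- flat; two$psd <- c(rep(0, 19), 3, rep(0, 19), 3, rep(0, 60))
  # power split between bins 20 and 40: MF is the first bin reaching 50%
  expect_equal(median_frequency(two), two$frequencies[20])

  twobin <- structure(list(frequencies = c(0, 0.5), psd = c(0.9, 0.1),
                           resolution = 0.5), class = "spectral_estimate")
  expect_equal(spectral_entropy(twobin),
               -(0.9 * log(0.9) + 0.1 * log(0.1)) / log(2), tolerance = 1e-12)

  empty <- flat; empty$psd <- rep(0, 100)
  expect_error(freq_moments(empty), "empty spectrum")
  expect_error(median_frequency(empty), "empty spectrum")
})

test_that("band powers isolate the 0.014-0.033 Hz apnea band", {
  t <- 0:8191
  set.seed(9)
  inband <- 94 + 3 * sin(2 * pi * 0.02 * t) + rnorm(length(t), 0, 0.05)
  bp <- band_powers(welch_psd(inband))
  expect_gt(bp[["PR"]], 0.9)

  outband <- 94 + 3 * sin(2 * pi * 0.25 * t)
  bp2 <- band_powers(welch_psd(outband))
  expect_lt(bp2[["PR"]], 0.01)

  p <- welch_psd(inband)
  expect_equal(band_powers(p)[["PT"]], sum(p$psd) * p$resolution)
})

test_that("sample entropy equals the brute-force template-matching oracle", {
  # constant signal: every template matches every other, -ln(A/B) = 0
  expect_equal(sample_entropy(rep(95, 50), m = 1, r = 0.5), 0)
  # over-regular signal with no matches at all: defined as 0 with warning
  expect_warning(v <- sample_entropy(10 * (1:50), m = 1, r = 0.1), "B = 0")
  expect_equal(v, 0)
  set.seed(10)
  for (m in c(1L, 2L)) {
    x <- rnorm(100)
    r <- 0.25 * sd(x)
    expect_equal(sample_entropy(x, m = m, r = r), brute_sampen(x, m, r))
    y <- cumsum(rnorm(120)) # smoother series, same oracle
    expect_equal(sample_entropy(y, m = m, r = 0.25 * sd(y)),
                 brute_sampen(y, m, 0.25 * sd(y)))
  }
  # irregularity ordering: white noise above its lowpass-filtered version
  set.seed(11)
  w <- rnorm(400)
  lp <- stats::filter(w, rep(1 / 8, 8), sides = 1)
  lp <- lp[!is.na(lp)]
  expect_gt(sample_entropy(w, 1, 0.25 * sd(w)),
            sample_entropy(lp, 1, 0.25 * sd(lp)))
})

test_that("CTM matches the point-counting oracle and its limits", {
  expect_equal(central_tendency_measure(rep(95, 100)), 1)
  expect_equal(central_tendency_measure(rep(c(85, 95), 50), rho = 1), 0)
  set.seed(12)
  x <- 94 + cumsum(rnorm(300, 0, 0.3))
  expect_equal(central_tendency_measure(x, rho = 0.25), brute_ctm(x, 0.25))
  expect_equal(central_tendency_measure(x, rho = 1), brute_ctm(x, 1))
})

test_that("LZ76 complexity matches hand parsing and the substring oracle", {
  s <- as.integer(strsplit("0001101001000101", "")[[1]])
  # classic sequence parses as 0|001|10|100|1000|101: six phrases
  expect_identical(oxiscreen:::lz76_count(s), 6L)
  expect_identical(brute_lz76(s), 6L)

  # constant signal: two-phrase parse after median binarization
  n <- 256
  expect_equal(lempel_ziv_complexity(rep(95, n)), 2 * log2(n) / n)

  set.seed(13)
  for (len in c(64L, 200L, 500L)) {
    b <- sample(0:1, len, replace = TRUE)
    expect_identical(oxiscreen:::lz76_count(b), brute_lz76(b))
  }
  # random binary sequences approach normalized complexity 1
  set.seed(14)
  big <- sample(0:1, 20000, replace = TRUE)
  lzc <- oxiscreen:::lz76_count(big) * log2(length(big)) / length(big)
  expect_gt(lzc, 0.85)
  expect_lt(lzc, 1.15)
})

test_that("the 16-feature vector is finite, deterministic and shift-equivariant", {
  s <- simulate_recording(sim_config(duration_hours = 1, event_rate = 30, seed = 15))
  x <- preprocess_spo2(s$rec)$samples
  fv <- extract_features(x)
  expect_length(fv, 16L)
  expect_named(fv, feature_names())
  expect_true(all(is.finite(fv)))
  expect_true(fv[["PR"]] >= 0 && fv[["PR"]] <= 1)
  expect_true(fv[["SE"]] >= 0 && fv[["SE"]] <= 1)
  expect_true(fv[["CTM"]] >= 0 && fv[["CTM"]] <= 1)
  expect_true(fv[["MF"]] >= 0 && fv[["MF"]] <= 0.5)
  expect_identical(fv, extract_features(x))      # purity
  # adding a constant changes only the mean level
  fv2 <- extract_features(x + 2)
  expect_equal(fv2[["M1t"]], fv[["M1t"]] + 2)
  expect_equal(fv2[setdiff(feature_names(), "M1t")],
               fv[setdiff(feature_names(), "M1t")], tolerance = 1e-10)
})

test_that("recurrent desaturations raise in-band relative power over event-free sleep", {
  ev <- simulate_recording(sim_config(duration_hours = 2, event_rate = 40,
                                      noise_sd = 0.3, seed = 16))
  quiet <- simulate_recording(sim_config(duration_hours = 2, event_rate = 0,
                                         noise_sd = 0.3, seed = 16))
  f_ev <- extract_features(preprocess_spo2(ev$rec)$samples)
  f_quiet <- extract_features(preprocess_spo2(quiet$rec)$samples)
  expect_gt(f_ev[["PR"]], f_quiet[["PR"]])
  expect_gt(f_ev[["M2t"]], f_quiet[["M2t"]])
})
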