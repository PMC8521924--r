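# The 58-feature quantitative-EEG bank: registry identities, closed forms,
# brute-force oracles and scale-covariance properties.

test_that("the feature registry has 58 names partitioned 25/27/6", {
  reg <- qeeg_feature_names()
  expect_equal(nrow(reg), 58)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_equal(unname(table(reg$family)[c("complexity", "continuity", "connectivity")]),
               c(25L, 27L, 6L), ignore_attr = TRUE)
})

test_that("histogram entropies match a brute-force probability enumeration", {
  # independent oracle: explicit per-bin counting on an 8-sample toy signal
  x <- c(0, 0.1, 0.2, 0.35, 0.5, 0.55, 0.9, 1)
  n_bins <- 4
  edges <- seq(0, 1, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  for (v in x) {
    b <- n_bins
    for (k in seq_len(n_bins - 1)) if (v >= edges[k] && v < edges[k + 1]) b <- k
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / length(x)
  expect_equal(shannon_entropy(x, n_bins), -sum(p * log2(p)))
  expect_equal(unname(tsallis_entropies(x, q_orders = 2, n_bins = n_bins)),
               (1 - sum(p^2)) / (2 - 1))
})

test_that("Shannon entropy hits its closed forms", {
  expect_equal(shannon_entropy(rep(3.7, 100)), 0)
  # square wave with equal duty cycle occupies two bins equally
  expect_equal(shannon_entropy(rep(c(-1, 1), 50), n_bins = 2), 1)
  # uniform noise fills 64 bins: ~ log2(64) bits minus the tiny finite-sample
  # bias (B-1)/(2 N ln 2)
  set.seed(1)
  u <- runif(1e6)
  expect_lt(abs(shannon_entropy(u, 64) - (6 - 63 / (2e6 * log(2)))), 0.02)
})

test_that("Tsallis entropies generalize Shannon and respect the q -> 1 limit", {
  x <- rep(c(-1, 1), 50)
  expect_equal(unname(tsallis_entropies(x, 2, n_bins = 2)), 0.5)  # 1 - 2 * 0.25
  expect_equal(unname(tsallis_entropies(rep(1, 50), tsallis_q_default)),
               rep(0, 10))
  set.seed(2)
  y <- rnorm(5000)
  s_lim <- unname(tsallis_entropies(y, 1.0001))
  s_nats <- unname(tsallis_entropies(y, 1))  # computed as Shannon in nats
  expect_lt(abs(s_lim - s_nats), 1e-3)
  expect_true(all(tsallis_entropies(y) >= 0))
})

test_that("subband information quantity tracks where the energy lives", {
  expect_equal(as.numeric(subband_information_quantity(rep(2, 256), 200)), rep(0, 5))
  set.seed(3)
  sine <- sin(2 * pi * 10 * (0:199) / 200) + rnorm(200, 0, 0.01)
  iq <- subband_information_quantity(sine, 200)
  expect_gt(iq[["iq_alpha"]], iq[["iq_gamma"]])
  # white noise: subband entropy grows with the band's share of the (flat)
  # spectrum, so the wide gamma band carries the most
  wn <- rnorm(2000)
  iqw <- subband_information_quantity(wn, 200)
  expect_true(all(iqw > 1))
  expect_equal(names(which.max(iqw)), "iq_gamma")
  expect_lt(max(iqw) / min(iqw), 2.2)
  # low sampling rates fall back to the highest subband for gamma
  low <- subband_information_quantity(rnorm(256), 50)
  expect_true(attr(low, "gamma_fallback"))
})

test_that("cepstrum coefficients see spectral shape, not amplitude", {
  set.seed(4)
  w <- rnorm(2^14)
  cc <- cepstrum_coefficients(w)
  expect_lt(abs(cc[["cepstrum_1"]]), 0.05)
  x <- rnorm(512)
  expect_equal(cepstrum_coefficients(x), cepstrum_coefficients(2 * x),
               tolerance = 1e-9)
  # echo at lag k puts a spike at quefrency k
  k <- 37
  e <- x + 0.5 * c(rep(0, k), x[1:(512 - k)])
  cep <- abs(real_cepstrum(e))
  expect_gt(cep[k + 1], stats::quantile(cep[2:200], 0.99))
})

test_that("Hjorth parameters match the discrete-difference closed form", {
  expect_equal(unname(hjorth_params(rep(5, 100))), c(0, 0))
  x <- sin(2 * pi * 10 * (0:1999) / 200)
  hp <- hjorth_params(x)
  expect_lt(abs(hp[["hjorth_mobility"]] - 2 * sin(pi * 10 / 200)), 1e-3)
  expect_lt(abs(hp[["hjorth_complexity"]] - 1), 1e-2)
})

test_that("nonlinear features behave on canonical signals", {
  x <- sin(2 * pi * 8 * (0:599) / 200)
  nl <- nonlinear_features(x, 200)
  expect_lte(nl[["lyapunov"]], 0.01)
  set.seed(5)
  expect_lt(abs(higuchi_fd(rnorm(2000)) - 2), 0.1)
  expect_lt(abs(higuchi_fd(seq(0, 1, length.out = 500)) - 1), 0.05)
  # short series return the documented sentinel
  expect_equal(nonlinear_features(rep(1, 30), 200)[["lyapunov"]], 0)
})

test_that("Yule-Walker AR(2) recovers known generating processes", {
  gen <- function(a1, a2, n, seed) {
    set.seed(seed)
    x <- numeric(n + 100)
    for (t in 3:(n + 100)) x[t] <- a1 * x[t - 1] + a2 * x[t - 2] + rnorm(1)
    x[-(1:100)]
  }
  co <- arma_coefficients(gen(0.5, 0, 1e5, 6))
  expect_lt(abs(co[["ar_1"]] - 0.5), 0.02)
  expect_lt(abs(co[["ar_2"]]), 0.02)
  set.seed(7)
  cw <- arma_coefficients(rnorm(1e5))
  expect_lt(max(abs(cw)), 0.02)
  c2 <- arma_coefficients(gen(1.2, -0.4, 1e5, 8))
  expect_lt(abs(c2[["ar_1"]] - 1.2), 0.03)
  expect_lt(abs(c2[["ar_2"]] + 0.4), 0.03)
})

test_that("spectral features summarize sinusoids correctly", {
  t <- (0:999) / 200
  s10 <- spectral_features(3 * sin(2 * pi * 10 * t), 200)
  expect_lt(abs(s10[["median_freq"]] - 10), 0.5)
  others <- s10[c("bp_delta", "bp_theta", "bp_beta", "bp_gamma")]
  expect_true(all(s10[["bp_alpha"]] > 10 * others))
  expect_equal(s10[["diffuse_slowing"]], 0)
  expect_lt(abs(s10[["std"]] - 3 / sqrt(2)) / (3 / sqrt(2)), 0.01)
  s5 <- spectral_features(sin(2 * pi * 5 * t), 200)
  expect_equal(s5[["diffuse_slowing"]], 1)
})

test_that("burst-suppression features follow their defining rules", {
  bs_c <- burst_suppression_features(rep(3, 400), 200)
  expect_equal(bs_c[["lv_5"]], 1)
  expect_equal(bs_c[["lv_20"]], 1)
  expect_equal(bs_c[["n_bursts"]], 0)
  expect_equal(bs_c[["regularity"]], 1)
  # two 0.5 s high-amplitude bursts over a near-silent background
  set.seed(9)
  x <- rnorm(1200, 0, 1)
  burst <- 40 * sin(2 * pi * 10 * (0:99) / 200)
  x[101:200] <- x[101:200] + burst
  x[701:800] <- x[701:800] + burst
  bs <- burst_suppression_features(x, 200)
  expect_equal(bs[["n_bursts"]], 2)
  expect_lt(abs(bs[["burst_len_mean"]] - 0.5), 0.05)
  expect_gt(bs[["n_suppressions"]], 0)
  # regularity oracle: direct evaluation of the sorted-squared formula
  reg_oracle <- function(v) {
    u <- sort(v^2, decreasing = TRUE); n <- length(v)
    min(1, sqrt(3 * sum(seq_len(n)^2 * u) / (n^2 * sum(u))))
  }
  sine <- 10 * sin(2 * pi * 10 * (0:1199) / 200)
  expect_equal(burst_suppression_features(sine, 200)[["regularity"]], reg_oracle(sine))
  expect_gt(burst_suppression_features(sine, 200)[["regularity"]], bs[["regularity"]])
})

test_that("spike detection applies the 3-sigma / 70 ms rule", {
  set.seed(10)
  base <- rnorm(1000)
  x <- base
  x[501:510] <- 8          # 50 ms pulse at 200 Hz
  sp <- spike_features(x, 200)
  expect_equal(sp[["n_spikes"]], 1)
  y <- base
  y[501:520] <- 8          # 100 ms pulse: too long to be a spike
  expect_equal(spike_features(y, 200)[["n_spikes"]], 0)
  z <- rnorm(1000) * 0.5
  expect_equal(unname(spike_features(sin((1:400) / 20), 200)), c(0, 0, 0))
})

test_that("extraction yields 58 deterministic, parallel-stable columns", {
  cfg <- synth_config(n_epochs = 10, n_channels = 3, n_subjects = 1,
                      subject_heterogeneity = 0, seed = 12)
  ds <- make_dataset(cfg)
  fm <- extract_features(ds$epochs)
  expect_s3_class(fm, "qeeg_features")
  expect_equal(ncol(fm), 59)            # epoch_index + 58 features
  expect_identical(setdiff(names(fm), "epoch_index"), qeeg_feature_names()$name)
  expect_true(all(is.finite(feature_matrix(fm))))
  # identical epochs give identical rows
  dup <- epoch_set(ds$epochs$data[c(1, 1), , ], ds$epochs$fs)
  fd <- extract_features(dup)
  expect_identical(as.numeric(fd[1, -1]), as.numeric(fd[2, -1]))
  # worker count does not change results
  fm2 <- extract_features(ds$epochs, workers = 2)
  expect_identical(as.data.frame(fm), as.data.frame(fm2))
  # single-channel epochs: error unless permissive
  one <- epoch_set(ds$epochs$data[, 1, , drop = FALSE], ds$epochs$fs)
  expect_error(extract_features(one), class = "eegsweep_parameter_error")
  fp <- extract_features(one, permissive = TRUE)
  expect_true(all(feature_matrix(fp)[, qeeg_feature_names()$name[53:58]] == 0))
})

test_that("standardization is an exact, invertible z-scoring", {
  cfg <- synth_config(n_epochs = 12, n_channels = 3, n_subjects = 1,
                      subject_heterogeneity = 0, seed = 13)
  fm <- extract_features(make_dataset(cfg)$epochs)
  z <- standardize_features(fm)
  m <- feature_matrix(z)
  raw <- feature_matrix(fm)
  # columns with variation above the documented numerical-constancy floor
  keep <- apply(raw, 2, stats::sd) > 1e-8 * abs(colMeans(raw))
  expect_lt(max(abs(colMeans(m[, keep]))), 1e-9)
  expect_lt(max(abs(apply(m[, keep], 2, stats::sd) - 1)), 1e-9)
  expect_true(all(m[, !keep] == 0))
  back <- destandardize_features(z)
  expect_lt(max(abs(feature_matrix(back) - feature_matrix(fm))), 1e-9)
})

test_that("features covary correctly under amplitude doubling", {
  cfg <- synth_config(n_epochs = 2, n_channels = 3, n_subjects = 1,
                      subject_heterogeneity = 0, seed = 14)
  ds <- make_dataset(cfg)
  es2 <- ds$epochs
  es2$data <- es2$data * 2
  f1 <- extract_features(ds$epochs)
  f2 <- extract_features(es2)
  r <- function(nm) as.numeric(f2[[nm]]) / as.numeric(f1[[nm]])
  expect_equal(r("std"), c(2, 2), tolerance = 1e-9)
  expect_equal(r("bp_alpha"), c(4, 4), tolerance = 1e-6)
  for (nm in c("hjorth_mobility", "pli", "coherence_delta", "regularity",
               "diffuse_slowing")) {
    expect_equal(as.numeric(f2[[nm]]), as.numeric(f1[[nm]]), tolerance = 1e-9)
  }
})

test_that("bounded features stay in their documented ranges", {
  cfg <- synth_config(n_epochs = 8, n_channels = 4, magnitude = c(5, 10), seed = 15)
  fm <- extract_features(make_dataset(cfg)$epochs)
  expect_true(all(fm$shannon >= 0))
  expect_true(all(fm[paste0("tsallis_q", tsallis_q_default)] >= 0))
  expect_true(all(fm$regularity > 0 & fm$regularity <= 1))
  expect_true(all(fm$lv_5 >= 0 & fm$lv_5 <= 1 & fm$lv_20 >= 0 & fm$lv_20 <= 1))
  expect_true(all(fm$coherence_delta >= 0 & fm$coherence_delta <= 1 + 1e-9))
  expect_true(all(fm$pli >= 0 & fm$pli <= 1))
  # channel-mean of a per-channel binary indicator
  expect_true(all(fm$diffuse_slowing >= 0 & fm$diffuse_slowing <= 1))
})
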