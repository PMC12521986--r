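make_od <- function(x, fs = 6.94) {
  n <- length(x)
  structure(list(od = array(rep(x, each = 2), c(1, 2, n)), sampling_rate = fs,
                 montage = make_montage(cbind(1, 1), 3, NULL),
                 events = NULL),
            class = "nirs_od")
}

make_hb <- function(hbo, fs = 6.94, n_ch = 1) {
  m <- matrix(rep(hbo, each = n_ch), n_ch)
  structure(list(hbo = m, hbr = m, sampling_rate = fs,
                 montage = make_montage(cbind(1, 1:n_ch), rep(3, n_ch), NULL),
                 events = NULL),
            class = "nirs_hb")
}

test_that("optical density is mean-referenced and scale invariant", {
  mon <- make_montage(cbind(1, 1), 3, NULL)
  const <- new_recording(array(2.5, c(1, 2, 50)), 6.94, mon, NULL)
  expect_true(all(to_optical_density(const)$od == 0))

  # analytic case: one sample at mean * exp(-0.5) maps to od = 0.5
  n <- 50; a <- 2
  m <- (n - 1) * a / (n - exp(-0.5))
  I <- c(rep(a, n - 1), m * exp(-0.5))
  stopifnot(abs(mean(I) - m) < 1e-12)
  rec <- new_recording(array(rep(I, each = 2), c(1, 2, n)), 6.94, mon, NULL)
  expect_equal(to_optical_density(rec)$od[1, 1, n], 0.5, tolerance = 1e-12)

  withr::with_seed(1, {
    I2 <- exp(rnorm(100, 0, 0.05))
    rec1 <- new_recording(array(rep(I2, each = 2), c(1, 2, 100)), 6.94, mon, NULL)
    rec2 <- new_recording(array(rep(3 * I2, each = 2), c(1, 2, 100)), 6.94, mon, NULL)
    expect_equal(to_optical_density(rec1)$od, to_optical_density(rec2)$od,
                 tolerance = 1e-12)
  })
})

test_that("TDDR preserves clean signals and suppresses step artifacts", {
  fs <- 6.94
  tt <- seq(0, 120, by = 1 / fs)
  clean <- 0.05 * sin(2 * pi * 0.05 * tt)
  out <- tddr(make_od(clean, fs))
  expect_gte(cor(out$od[1, 1, ], clean), 0.99)
  expect_equal(dim(out$od), dim(make_od(clean)$od))

  # step of 50x the robust SD of the signal
  rsd <- 1.4826 * median(abs(clean - median(clean)))
  spiked <- clean + (tt > 60) * 50 * rsd
  rep_od <- tddr(make_od(spiked, fs))$od[1, 1, ]
  dev_before <- sqrt(mean((spiked - mean(spiked) - (clean - mean(clean)))^2))
  dev_after <- sqrt(mean((rep_od - mean(rep_od) - (clean - mean(clean)))^2))
  expect_lt(dev_after, 0.1 * dev_before)
})

test_that("short-channel regression removes scaled copies and keeps orthogonal signal", {
  fs <- 6.94
  n <- 400
  mon <- make_montage(rbind(c(1, 1), c(9, 5)), c(3, 1), 2)
  withr::with_seed(2, {
    short <- sin(2 * pi * 0.1 * (1:n) / fs) + rnorm(n, 0, 0.1)
    # long = 2.0 x short
    od <- array(NA_real_, c(2, 2, n))
    od[1, , ] <- rep(2 * short, each = 2)
    od[2, , ] <- rep(short, each = 2)
    res <- regress_short_channel(
      structure(list(od = od, sampling_rate = fs, montage = mon,
                     events = NULL), class = "nirs_od"))
    expect_equal(dim(res$od)[1], 1)
    expect_lt(sd(res$od[1, 1, ]), 1e-10 * sd(short))
    expect_null(res$montage$short_channel_index)

    # orthogonal long channel passes through (up to its mean)
    ortho <- cos(2 * pi * 0.25 * (1:n) / fs)
    ortho <- ortho - mean(ortho)
    ortho <- ortho - short * sum(ortho * (short - mean(short))) /
      sum((short - mean(short))^2)
    od[1, , ] <- rep(ortho, each = 2)
    res2 <- regress_short_channel(
      structure(list(od = od, sampling_rate = fs, montage = mon,
                     events = NULL), class = "nirs_od"))
    expect_equal(res2$od[1, 1, ], ortho - mean(ortho), tolerance = 1e-8)

    # generator-style mixture: evoked + 0.8 x short
    evoked <- exp(-((1:n) - 150)^2 / 800)
    od[1, , ] <- rep(evoked + 0.8 * short, each = 2)
    res3 <- regress_short_channel(
      structure(list(od = od, sampling_rate = fs, montage = mon,
                     events = NULL), class = "nirs_od"))
    expect_gte(cor(res3$od[1, 1, ], evoked), 0.95)
  })
})

test_that("Beer-Lambert inversion recovers simulated concentrations within 1% RMS", {
  spec <- tiny_spec()
  truth <- ground_truth(trial_amplitude_sd = 0, mayer_amp = 0.3,
                        cardiac_amp = 0, drift_slope = 0,
                        colored_noise_sd = 0.2, white_noise_sd = 0, seed = 4)
  conc <- simulate_concentrations(spec, default_montage(), truth)
  rec <- forward_to_intensity(conc, truth)
  hb <- mbll(to_optical_density(rec), ppf = 6)
  centre <- function(m) m - rowMeans(m)
  err <- centre(hb$hbo) - centre(conc$hbo)
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(centre(conc$hbo)^2)), 0.01)
  err_r <- centre(hb$hbr) - centre(conc$hbr)
  expect_lt(sqrt(mean(err_r^2)) / sqrt(mean(centre(conc$hbr)^2)), 0.01)
})

test_that("Beer-Lambert algebra: zero OD and distance scaling", {
  mon3 <- make_montage(cbind(1, 1), 3, NULL)
  mon15 <- make_montage(cbind(1, 1), 1.5, NULL)
  odz <- structure(list(od = array(0, c(1, 2, 10)), sampling_rate = 6.94,
                        montage = mon3, events = NULL), class = "nirs_od")
  hbz <- mbll(odz)
  expect_true(all(hbz$hbo == 0) && all(hbz$hbr == 0))

  withr::with_seed(3, od_vals <- array(rnorm(2 * 20, 0, 0.01), c(1, 2, 20)))
  od3 <- structure(list(od = od_vals, sampling_rate = 6.94, montage = mon3,
                        events = NULL), class = "nirs_od")
  od15 <- structure(list(od = od_vals, sampling_rate = 6.94, montage = mon15,
                         events = NULL), class = "nirs_od")
  expect_equal(mbll(od15)$hbo, 2 * mbll(od3)$hbo, tolerance = 1e-12)
})

test_that("band-pass removes DC, passes in-band and kills cardiac frequencies", {
  fs <- 6.94
  tt <- seq(0, 600, by = 1 / fs)
  const <- make_hb(rep(1, length(tt)), fs)
  expect_lt(max(abs(bandpass(const)$hbo)), 1e-6)

  core <- function(x) x[seq(round(length(x) * 0.2), round(length(x) * 0.8))]
  s005 <- make_hb(sin(2 * pi * 0.05 * tt), fs)
  gain <- sd(core(bandpass(s005)$hbo[1, ])) / sd(core(s005$hbo[1, ]))
  expect_gte(gain, 0.9); expect_lte(gain, 1.05)

  s1 <- make_hb(sin(2 * pi * 1 * tt), fs)
  atten <- sd(core(bandpass(s1)$hbo[1, ])) / sd(core(s1$hbo[1, ]))
  expect_lte(atten, 0.05)

  expect_error(bandpass(s1, 0.4, 0.1), "invalid band")
  expect_error(bandpass(s1, 0.1, 4), "invalid band")
})

test_that("two default runs pool to 60 detrended epochs of 84 samples", {
  runs <- simulate_dataset("RESPONSIVE", seed = 11)
  hb <- lapply(runs, preprocess_run)
  ep <- pool_epochs(lapply(hb, make_epochs, chromophore = "HBO"))
  expect_equal(dim(ep$data)[1], 60)
  expect_equal(as.vector(table(ep$labels)), c(30, 30))
  expect_equal(dim(ep$data)[3], floor(12 * 6.94) + 1)
  expect_equal(dim(ep$data)[3], 84)
  # refitting a line to any detrended epoch gives ~zero slope and mean
  x <- seq_len(84) - mean(seq_len(84))
  for (i in c(1, 30, 60)) {
    slopes <- apply(ep$data[i, , ], 1, function(y) sum(y * x) / sum(x^2))
    expect_lt(max(abs(slopes)), 1e-10)
    expect_lt(max(abs(rowMeans(ep$data[i, , ]))), 1e-10)
  }
})

test_that("the BOTH chromophore stacks HbO and HbR channel blocks", {
  hb <- cached_epochs("RESPONSIVE", "HBO")
  both <- cached_epochs("RESPONSIVE", "BOTH")
  expect_equal(dim(both$data)[2], 2 * dim(hb$data)[2])
})

test_that("epochs extending past the recording are dropped with a warning", {
  runs <- simulate_run("RESPONSIVE", seed = 1, spec = tiny_spec())
  hb <- preprocess_run(runs)
  late <- hb$events
  late$onset[nrow(late)] <- ncol(hb$hbo) / hb$sampling_rate - 5
  expect_warning(ep <- make_epochs(hb, late, "HBO"), "dropping")
  expect_equal(dim(ep$data)[1], nrow(late) - 1)
})

test_that("preprocessing is deterministic", {
  rec <- simulate_run("RESPONSIVE", seed = 9, spec = tiny_spec())
  e1 <- make_epochs(preprocess_run(rec), chromophore = "BOTH")
  e2 <- make_epochs(preprocess_run(rec), chromophore = "BOTH")
  expect_identical(e1$data, e2$data)
})

test_that("the IMAGERY minus NO-IMAGERY mean recovers the injected waveform", {
  # linear chain only: TDDR is excluded because a robust artifact
  # detector on exactly-zero-noise input sees the sparse HRF derivative
  # itself as the outlier (its noise scale estimate degenerates); its
  # behaviour on noisy data is tested separately above
  spec <- paradigm_spec()
  mon <- default_montage()
  truth <- ground_truth(trial_amplitude_sd = 0, mayer_amp = 0,
                        cardiac_amp = 0, drift_slope = 0,
                        colored_noise_sd = 0, white_noise_sd = 0, seed = 5)
  conc <- simulate_concentrations(spec, mon, truth)
  rec <- forward_to_intensity(conc, truth)
  hb <- preprocess_run(rec, config = list(tddr.enabled = FALSE))
  ep <- make_epochs(hb, chromophore = "HBO")
  best <- which.max(apply(conc$evoked_hbo, 1, max))  # long-channel index
  diff_wave <- colMeans(ep$data[ep$labels == "IMAGERY", best, ]) -
    colMeans(ep$data[ep$labels == "NO_IMAGERY", best, ])
  onset1 <- round(conc$events$onset[1] * spec$sampling_rate) + 1
  injected <- conc$evoked_hbo[best, onset1:(onset1 + 83)]
  # epochs are detrended by contract, so compare on the same footing
  xs <- seq_along(injected)
  injected <- stats::residuals(stats::lm(injected ~ xs))
  expect_gte(cor(diff_wave, injected), 0.95)
  expect_equal(max(diff_wave) - min(diff_wave),
               max(injected) - min(injected), tolerance = 0.05)

  # unresponsive, noise-free: the contrast vanishes identically
  spec_u <- paradigm_spec(state = "UNRESPONSIVE")
  truth_u <- ground_truth(trial_amplitude_sd = 0, mayer_amp = 0,
                          cardiac_amp = 0, drift_slope = 0,
                          colored_noise_sd = 0, white_noise_sd = 0,
                          seed = 5, state = "UNRESPONSIVE")
  conc_u <- simulate_concentrations(spec_u, mon, truth_u)
  expect_true(all(conc_u$hbo == 0))
})
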