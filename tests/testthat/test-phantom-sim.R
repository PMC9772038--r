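test_that("pulse train has one unit-peak pulse per PRF period", {
  tr <- transducer_spec(prf = 1000, pulse_width = 2e-4)
  p <- make_pulse_train(tr, fs = 20000, duration = 1)
  expect_length(p, 20000)
  expect_equal(max(p), 1.0)
  expect_true(all(p >= 0 & p <= 1))
  # pulse count: rising edges out of the zero baseline
  starts <- sum(p > 0 & c(0, head(p, -1)) == 0)
  expect_identical(starts, 1000L)
  # each pulse spans pulse_width * fs = 4 samples above zero
  runs <- rle(p > 0)
  expect_true(all(runs$lengths[runs$values] == 4L))
})

test_that("pulse width must fit inside a PRF period", {
  expect_error(transducer_spec(prf = 1000, pulse_width = 1e-3),
               class = "abidecode_config_error")
})

test_that("focal weight is a Gaussian in distance", {
  expect_equal(focal_weight(c(0, 0), c(0, 0), 1), 1.0)
  # half-weight at the FWHM half-width
  d <- 0.6 * sqrt(2 * log(2))
  expect_equal(focal_weight(c(0, 0), c(d, 0), 0.6), 0.5)
  expect_lt(focal_weight(c(0, 0), c(10, 0), 1), 1e-20)
  # vectorized over a source table
  src <- source_spec(c(0, 3), c(0, 4), frequency = 10)
  w <- focal_weight(c(0, 0), src, 5)
  expect_equal(w, c(1, exp(-25 / 50)))
})

test_that("noiseless single-source recording peaks at gain*A0*(1+mu)", {
  cfg <- quick_config(noise_sd = 0, lf_leak_gain = 0)
  rec <- simulate_recording(cfg, focus = c(0, 0))
  a0 <- cfg$ae_constant * cfg$pressure_peak
  # peak pulse samples need not coincide exactly with the sine crest on
  # the sampling grid, hence the loose-ish tolerance
  expect_equal(max(rec$voltage), a0 * (1 + cfg$modulation_index),
               tolerance = 1e-4)
  expect_equal(nrow(rec), round(cfg$duration * cfg$fs_record))
  expect_true(all(is.finite(rec$voltage)))
})

test_that("zero-amplitude sources give a constant-amplitude pulse train", {
  cfg <- phantom_config(source_spec(0, 0, frequency = 8, amplitude = 0),
                        duration = 0.25, noise_sd = 0, lf_leak_gain = 0)
  rec <- simulate_recording(cfg, focus = c(0, 0))
  p <- make_pulse_train(cfg$transducer, cfg$fs_record, cfg$duration)
  a0 <- cfg$ae_constant * cfg$pressure_peak
  expect_equal(rec$voltage, p * a0)
})

test_that("identical config and seed reproduce the recording bit-exactly", {
  cfg <- quick_config(noise_sd = 1e-3, seed = 42L)
  r1 <- simulate_recording(cfg, c(0, 0))
  r2 <- simulate_recording(cfg, c(0, 0))
  expect_identical(r1$voltage, r2$voltage)
  r3 <- simulate_recording(cfg, c(0, 0), seed = 43L)
  expect_false(identical(r1$voltage, r3$voltage))
})

test_that("simulation does not disturb the global RNG stream", {
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(simulate_recording(quick_config(noise_sd = 1e-3),
                                            c(0, 0)))
  expect_identical(runif(1), before)
})

test_that("modulation is linear in source amplitudes", {
  # focus on source 1 of a two-source layout and read the per-source
  # envelope lines: doubling one amplitude doubles its line relative to
  # the other (M(t) is linear in the drives)
  line_ratio <- function(a1) {
    src <- source_spec(c(0, 2), 0, frequency = c(8, 12),
                       amplitude = c(a1, 20))
    cfg <- phantom_config(src, duration = 0.25, noise_sd = 0,
                          lf_leak_gain = 0)
    env <- dae_decode(preprocess(simulate_recording(cfg, c(0, 0))))
    fit <- fourier_fit(env$signal, fs = attr(env, "fs"))
    fit$c[fit$fundamental * seq_along(fit$c) == 8] /
      fit$c[fit$fundamental * seq_along(fit$c) == 12]
  }
  expect_equal(line_ratio(80) / line_ratio(40), 2, tolerance = 1e-6)
  # and scaling every amplitude together leaves the recording unchanged
  # (the pedestal depth is normalized by the total drive)
  src1 <- source_spec(c(0, 2), 0, frequency = c(8, 12), amplitude = c(40, 20))
  src2 <- source_spec(c(0, 2), 0, frequency = c(8, 12), amplitude = c(80, 40))
  mk <- function(src) {
    simulate_recording(phantom_config(src, duration = 0.25, noise_sd = 0,
                                      lf_leak_gain = 0), c(1, 0))$voltage
  }
  expect_equal(mk(src1), mk(src2), tolerance = 1e-12)
})

test_that("scan visits the grid row-major with derived per-spot seeds", {
  cfg <- quick_config(noise_sd = 1e-4, duration = 0.125, seed = 10L)
  grid <- scan_grid(-9, 0, 1, -2, 2, 1)
  expect_identical(grid$n_spots, 50L)
  scan <- simulate_scan(cfg, grid)
  expect_identical(nrow(scan), 50L)
  # x varies fastest within each y row
  expect_equal(scan$focus_x[1:11], c(seq(-9, 0), -9))
  expect_equal(scan$focus_y[1:11], c(rep(-2, 10), -1))
  expect_identical(scan$seed, 10L + 0:49)
  # 24 x 5 grid of the three-source region
  expect_identical(scan_grid(0, 23, 1, -2, 2, 1)$n_spots, 120L)
  # single-spot scan reduces to simulate_recording
  g1 <- scan_grid(0, 0, 1, 0, 0, 1)
  s1 <- simulate_scan(cfg, g1)
  expect_identical(s1$recording[[1]]$voltage,
                   simulate_recording(cfg, c(0, 0))$voltage)
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(source_spec(0, 0, frequency = 8),
                              fs_record = 1500),
               class = "abidecode_config_error")
  expect_error(source_spec(0, 0, frequency = -1),
               class = "abidecode_config_error")
  expect_error(source_spec(0, 0, frequency = 8, amplitude = -5),
               class = "abidecode_config_error")
  expect_warning(quick_config(frequency = 8.3),
                 "integer number of cycles")
})

test_that("PRF-band content of a noiseless recording demodulates to the pedestal", {
  cfg <- quick_config(frequency = 8, noise_sd = 0, duration = 0.5)
  pre <- preprocess(simulate_recording(cfg, c(0, 0)))
  env <- Mod(analytic_signal(pre$voltage))
  truth <- 1 + cfg$modulation_index * sin(2 * pi * 8 * pre$time)
  expect_gt(pearson_corr(env, truth), 0.999)
})
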