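test_that("analytic signal reproduces the cos + i sin identity", {
  t <- tgrid(1, 1000)
  x <- cos(2 * pi * 50 * t)
  z <- analytic_signal(x)
  expect_identical(Re(z), x)
  expect_lt(max(Mod(z - complex(real = cos(2 * pi * 50 * t),
                                imaginary = sin(2 * pi * 50 * t)))), 1e-10)
  zc <- analytic_signal(rep(3, 64))
  expect_lt(max(abs(Im(zc))), 1e-12)
  expect_error(analytic_signal(numeric(0)), class = "abidecode_input_error")
})

test_that("DAE envelope of a pure tone is constant and demodulates AM", {
  fs <- 5000
  t <- tgrid(2, fs)
  d <- dae_decode(5 * cos(2 * pi * 1000 * t), fs = fs)
  expect_lt(max(abs(d$signal - 5)), 1e-6)
  m <- sin(2 * pi * 8 * t)
  am <- (1 + 0.5 * m) * cos(2 * pi * 1000 * t)
  d2 <- dae_decode(am, fs = fs)
  expect_gt(pearson_corr(d2$signal, m), 0.999)
  # amplitude convention: sqrt(2) * RMS of the mean-removed envelope
  expect_equal(attr(d2, "amplitude"), 0.5, tolerance = 1e-3)
  d0 <- dae_decode(rep(0, 100), fs = fs)
  expect_equal(d0$signal, rep(0, 100))
})

test_that("fourier_fit recovers exact coefficients of synthesized harmonics", {
  # DC only
  f <- fourier_fit(rep(2, 8), fs = 8)
  expect_equal(f$a0, 2)
  expect_lt(max(f$c), 1e-12)
  # single sine on the fundamental
  n <- 32
  t <- seq_len(n) - 1
  f2 <- fourier_fit(3 * sin(2 * pi * t / n), fs = n)
  expect_equal(f2$b[1], 3, tolerance = 1e-12)
  expect_equal(f2$c[1], 3, tolerance = 1e-12)
  expect_lt(max(f2$c[-1]), 1e-10)
  # 3-4-5 amplitude at harmonic 3
  f3 <- fourier_fit(3 * cos(3 * 2 * pi * t / n) + 4 * sin(3 * 2 * pi * t / n),
                    fs = n)
  expect_equal(f3$c[3], 5, tolerance = 1e-12)
  expect_equal(f3$a[3], 3, tolerance = 1e-12)
  expect_equal(f3$b[3], 4, tolerance = 1e-12)
})

test_that("fourier_fit matches the direct discrete-Fourier oracle", {
  set.seed(5)
  for (n in c(8, 17, 64, 251, 512)) {
    x <- rnorm(n)
    fit <- fourier_fit(x, fs = 100)
    ora <- dft_oracle(x)
    expect_lt(max(abs(fit$a - ora$a)), 1e-10)
    expect_lt(max(abs(fit$b - ora$b)), 1e-10)
    expect_equal(fit$a0, ora$a0)
    expect_lt(fit$rss, 1e-16 * n * max(1, sum(x^2)))
  }
})

test_that("fit satisfies the Parseval identity", {
  set.seed(6)
  for (n in c(16, 33, 128)) {
    x <- rnorm(n)
    fit <- fourier_fit(x, fs = n)
    m <- n %/% 2
    w <- rep(0.5, m)
    if (n %% 2 == 0) w[m] <- 1      # unpaired Nyquist term
    lhs <- fit$a0^2 + sum(w * fit$c^2)
    expect_equal(lhs, mean(x^2), tolerance = 1e-8)
  }
})

test_that("fitted coefficients are the exact least-squares minimum", {
  set.seed(7)
  n <- 48
  x <- rnorm(n)
  fit <- fourier_fit(x, fs = n)
  t <- seq_len(n) - 1
  sse <- function(a, b, k) {
    r <- x - (fit$a0 + a * cos(2 * pi * k * t / n) +
                b * sin(2 * pi * k * t / n))
    # remove all other harmonics so only harmonic k's misfit remains
    for (j in setdiff(seq_along(fit$c), k)) {
      r <- r - fit$a[j] * cos(2 * pi * j * t / n) -
        fit$b[j] * sin(2 * pi * j * t / n)
    }
    sum(r^2)
  }
  for (k in c(1, 5, 11)) {
    s0 <- sse(fit$a[k], fit$b[k], k)
    for (d in c(-1e-3, 1e-3)) {
      expect_gt(sse(fit$a[k] + d, fit$b[k], k), s0)
      expect_gt(sse(fit$a[k], fit$b[k] + d, k), s0)
    }
  }
})

test_that("dominant-harmonic selection respects band, DC and ties", {
  mk <- function(c_vals, fundamental = 1) {
    structure(list(a0 = 1, a = c_vals, b = rep(0, length(c_vals)),
                   c = c_vals, n = 2 * length(c_vals),
                   fs = fundamental * 2 * length(c_vals),
                   fundamental = fundamental, rss = 0),
              class = "harmonic_fit")
  }
  expect_identical(select_dominant(mk(c(0.2, 0.9, 0.1)), band = c(1, 3)), 2L)
  expect_identical(select_dominant(mk(c(0.5, 0.5, 0.1)), band = c(1, 3)), 1L)
  # harmonics below band[1] are ineligible
  expect_identical(select_dominant(mk(c(9, 1, 2)), band = c(2, 3)), 3L)
  expect_error(select_dominant(mk(c(1, 2, 3)), band = c(100, 200)),
               class = "abidecode_input_error")
  expect_error(select_dominant(mk(c(1, 2, 3)), band = c(3, 1)),
               class = "abidecode_input_error")
})

test_that("simulated 8 Hz source selects harmonic 16 of a 2 s record", {
  cfg <- quick_config(frequency = 8, noise_sd = 0, duration = 2)
  pre <- preprocess(simulate_recording(cfg, c(0, 0)))
  d <- adaf_decode(pre)
  expect_identical(attr(d, "selected_harmonic"), 16L)
  expect_equal(attr(d, "frequency"), 8)
})

test_that("aDAF reconstructs the source timing signal almost perfectly", {
  cfg <- quick_config(frequency = 8, noise_sd = 0, duration = 2)
  pre <- preprocess(simulate_recording(cfg, c(0, 0)))
  d <- adaf_decode(pre)
  expect_gt(source_correlation(d, 8), 0.9999)
  # phase convention: harmonic is c_k * sin(2 pi f t + phase)
  recon <- attr(d, "fit")$a0 +
    attr(d, "amplitude") * sin(2 * pi * attr(d, "frequency") * d$time +
                                 attr(d, "phase"))
  expect_equal(recon, d$signal, tolerance = 1e-9)
})

test_that("constant envelope decodes to (approximately) its DC value", {
  fs <- 5000
  t <- tgrid(1, fs)
  d <- adaf_decode(5 * cos(2 * pi * 1000 * t), fs = fs)
  expect_lt(attr(d, "amplitude") / 5, 1e-6)
  expect_equal(d$signal, rep(attr(d, "fit")$a0, length(t)), tolerance = 1e-6)
})

test_that("single-harmonic residual is bounded by the envelope variance", {
  set.seed(8)
  cfg <- quick_config(frequency = 8, noise_sd = 1e-3, duration = 0.5)
  pre <- preprocess(simulate_recording(cfg, c(0, 0)))
  d <- adaf_decode(pre)
  env <- attr(d, "envelope")
  rss1 <- sum((env - d$signal)^2)
  expect_gte(rss1, 0)
  expect_lte(rss1, length(env) * mean((env - mean(env))^2) * (1 + 1e-12))
})

test_that("noisy-regime harmonic selection finds the true source bin", {
  hits <- 0L
  for (s in 1:100) {
    cfg <- quick_config(frequency = 8, noise_sd = 1.5e-3, duration = 0.5,
                        seed = s)
    pre <- preprocess(simulate_recording(cfg, c(0, 0)))
    fit <- fourier_fit(dae_decode(pre)$signal, fs = attr(pre, "fs"))
    k <- select_dominant(fit)
    if (k * fit$fundamental == 8) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("top_m > 1 keeps additional harmonics", {
  fs <- 5000
  t <- tgrid(1, fs)
  am <- (1 + 0.3 * sin(2 * pi * 8 * t) + 0.2 * sin(2 * pi * 13 * t)) *
    cos(2 * pi * 1000 * t)
  d2 <- adaf_decode(am, fs = fs, top_m = 2)
  sp <- spectrum_tbl(d2)
  nz <- sp$frequency[sp$magnitude > 1e-6 & sp$frequency > 0]
  expect_setequal(nz, c(8, 13))
})
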