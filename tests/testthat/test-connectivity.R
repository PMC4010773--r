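test_that("instantaneous phase of a cosine advances linearly", {
  fs <- 512; f <- 10
  t <- (0:4095) / fs
  ph <- instantaneous_phase(cos(2 * pi * f * t), fs, band_low = 8)
  core <- (ph$n_edge + 1):(length(ph$phase) - ph$n_edge - 1)
  steps <- diff(ph$phase)[core]
  steps <- steps + 2 * pi * (steps < -pi)  # unwrap
  expect_equal(steps, rep(2 * pi * f / fs, length(steps)), tolerance = 1e-6)
})

test_that("sin lags cos by a quarter cycle; sign flip shifts phase by pi", {
  fs <- 512
  t <- (0:2047) / fs
  pc <- instantaneous_phase(cos(2 * pi * 10 * t), fs, band_low = 8)
  ps <- instantaneous_phase(sin(2 * pi * 10 * t), fs, band_low = 8)
  keep <- 200:1800
  d <- pc$phase[keep] - ps$phase[keep]
  d <- d - 2 * pi * round(d / (2 * pi))
  expect_equal(d, rep(pi / 2, length(d)), tolerance = 1e-3)

  pn <- instantaneous_phase(-cos(2 * pi * 10 * t), fs, band_low = 8)
  dd <- abs(pc$phase[keep] - pn$phase[keep])
  expect_equal(dd - 2 * pi * round((dd - pi) / (2 * pi)),
               rep(pi, length(dd)), tolerance = 1e-3)
})

test_that("constant input has undefined phase", {
  expect_error(instantaneous_phase(rep(1, 100), 100), "constant")
})

test_that("analytic signal matches the closed form for bin-frequency tones", {
  # for sums of sinusoids at FFT bin frequencies the analytic signal is the
  # corresponding sum of complex exponentials, exactly
  set.seed(5)
  for (n in c(256, 255)) {  # even and odd lengths
    t <- seq_len(n) - 1L
    ks <- c(3, 10, 31)
    a <- runif(3, 0.5, 2); ph <- runif(3, 0, 2 * pi)
    x <- 0; z <- 0
    for (j in 1:3) {
      x <- x + a[j] * cos(2 * pi * ks[j] * t / n + ph[j])
      z <- z + a[j] * exp(1i * (2 * pi * ks[j] * t / n + ph[j]))
    }
    expect_equal(plinet:::analytic_signal(x), z, tolerance = 1e-10)
  }
})

test_that("PLI evaluates the sign-average formula", {
  # identically zero phase difference: no coupling registered
  p <- seq(0, 10, length.out = 500)
  expect_equal(pli(p, p), 0)
  # constant quarter-cycle lag: perfect consistency
  expect_equal(pli(p, p - pi / 2), 1)
  # 75/25 sign mixture: |0.75 - 0.25| = 0.5
  d <- c(rep(pi / 3, 300), rep(-pi / 4, 100))
  expect_equal(pli(p[seq_along(d)] , p[seq_along(d)] - d), 0.5)
})

test_that("PLI is symmetric and invariant to a common phase offset", {
  set.seed(6)
  a <- cumsum(rnorm(400, 0.1))
  b <- cumsum(rnorm(400, 0.1))
  expect_equal(pli(a, b), pli(b, a))
  expect_equal(pli(a + 1.2345, b + 1.2345), pli(a, b))
  expect_error(pli(a, b[-1]), "length mismatch")
})

test_that("PLI of an amplitude-scaled, phase-shifted copy is 1", {
  set.seed(7)
  fs <- 512
  x <- as.numeric(bandpass(epoch_set(list(matrix(rnorm(4096), 1)), fs, "c1"),
                           band_definition("alpha", 8, 13))$epochs[[1]])
  # rotate the analytic signal by a constant angle, scale amplitude by 3
  shift <- pi / 3
  y <- 3 * Re(plinet:::analytic_signal(x) * exp(-1i * shift))
  pa <- instantaneous_phase(x, fs, band_low = 8)
  pb <- instantaneous_phase(y, fs, band_low = 8)
  expect_gt(pli(pa, pb), 0.999)
})

test_that("mean PLI of independent noise decreases with sample count", {
  set.seed(8)
  mean_pli <- function(n) {
    mean(replicate(30, {
      a <- instantaneous_phase(rnorm(n), 512, n_edge = 8)
      b <- instantaneous_phase(rnorm(n), 512, n_edge = 8)
      pli(a, b)
    }))
  }
  expect_gt(mean_pli(128), mean_pli(2048))
})

test_that("pli_matrix averages epochs and satisfies the weight contract", {
  fs <- 512
  t <- (0:2047) / fs
  e <- rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t))
  # identical epochs repeated: equals the single-epoch matrix
  es1 <- epoch_set(list(e), fs, c("a", "b"), band = band_definition("alpha", 8, 13))
  es4 <- epoch_set(rep(list(e), 4), fs, c("a", "b"),
                   band = band_definition("alpha", 8, 13))
  m1 <- pli_matrix(es1); m4 <- pli_matrix(es4)
  expect_equal(m1$weights, m4$weights)
  # constant quarter-cycle lag: off-diagonal 1
  expect_gt(m1$weights["a", "b"], 0.999)

  set.seed(9)
  sp <- oscillator_spec(17, n_samples = 1024, n_epochs = 2, noise_sd = 0.3,
                        seed = 10)
  W <- pli_matrix(bandpass(generate_epochs(sp), band_definition("alpha", 8, 13)))
  expect_identical(dim(W$weights), c(17L, 17L))
  expect_equal(W$weights, t(W$weights))
  expect_equal(unname(diag(W$weights)), rep(0, 17))
  expect_true(all(W$weights >= 0 & W$weights <= 1))

  one_ch <- epoch_set(list(matrix(rnorm(256), 1)), 256, "a")
  expect_error(pli_matrix(one_ch), "2 channels")
})

test_that("relative power concentrates on the tone's band", {
  fs <- 512
  t <- (0:8191) / fs
  es <- epoch_set(list(rbind(cos(2 * pi * 9 * t))), fs, "c1")
  rp <- relative_power(es)
  expect_gt(rp[["alpha1"]], 0.95)
  expect_lt(max(rp[c("delta", "theta", "alpha2", "beta")]), 0.03)
  expect_lte(sum(rp), 1 + 1e-9)
})

test_that("white-noise band fractions follow bandwidth", {
  set.seed(10)
  acc <- 0
  for (s in 1:12)
    acc <- acc + relative_power(epoch_set(list(matrix(rnorm(8192), 1)), 512, "c1"))
  widths <- c(delta = 3.5, theta = 4, alpha1 = 2, alpha2 = 3, beta = 17)
  expect_equal(unname(acc / 12), unname(widths / 29.5), tolerance = 0.03)
})

test_that("relative power rejects zero signals and warns on filtered input", {
  zero <- epoch_set(list(matrix(0, 1, 1024)), 512, "c1")
  expect_error(relative_power(zero), "zero total power")
  es <- epoch_set(list(matrix(rnorm(1024), 1)), 512, "c1",
                  band = band_definition("alpha", 8, 13))
  expect_warning(relative_power(es), "broadband")
})
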