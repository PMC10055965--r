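test_that("the notch is the complement of a DC-centered Gaussian", {
  g <- make_frequency_grid(c(64, 64), 100)
  Fk <- notch_function(g, sigma = 2)
  ctr <- c(33, 33)
  expect_identical(Fk[ctr[1], ctr[2]], 0)            # zero at the maximizer
  # at r = sigma pixels: 1 - exp(-1/2)
  expect_equal(Fk[ctr[1], ctr[2] + 2], 1 - exp(-0.5), tolerance = 1e-12)
  expect_equal(1 - exp(-0.5), 0.3935, tolerance = 1e-4)
  expect_gt(Fk[1, 1], 1 - 1e-12)                     # corner: tail vanished
  expect_true(all(Fk >= 0 & Fk <= 1))
  expect_error(notch_function(g, 0), "positive")
  expect_error(notch_function(g, -2), "positive")
})

test_that("triangle apodization tapers linearly to the extended cutoff", {
  g <- make_frequency_grid(c(64, 64), 100)
  kc <- 4
  A <- apodization(g, kc)
  ctr <- c(33, 33)
  expect_equal(A[ctr[1], ctr[2]], 1)
  expect_equal(A[g$k >= kc], rep(0, sum(g$k >= kc)))
  half <- abs(g$k - kc / 2) < 1e-9
  expect_equal(A[half], rep(0.5, sum(half)))
  expect_error(apodization(g, -1), "positive")
})

test_that("band shifting is exact for zero, integer and composed shifts", {
  N <- 64
  g <- make_frequency_grid(c(N, N), 100)
  set.seed(3)
  B <- fft2c_ref(matrix(stats::runif(N * N), N, N))
  expect_identical(shift_band(B, c(0, 0), g), B)
  # integer-pixel shift equals a circular roll of the array
  sh <- c(3, -2) * g$spacing
  roll <- function(m, dr, dc) {
    n <- dim(m)
    m[((seq_len(n[1]) - 1 - dr) %% n[1]) + 1,
      ((seq_len(n[2]) - 1 - dc) %% n[2]) + 1]
  }
  expect_lt(max(Mod(shift_band(B, sh, g) - roll(B, -2, 3))) / max(Mod(B)),
            1e-12)
  # sub-pixel shift composed with its inverse returns the input
  s2 <- c(0.37, -0.81)
  expect_lt(max(Mod(shift_band(shift_band(B, s2, g), -s2, g) - B)) /
              max(Mod(B)), 1e-10)
  expect_error(shift_band(B, c(100, 0), g), "Nyquist")
})

test_that("disabling the notch makes the two reconstruction paths bit-identical", {
  N <- 96; px <- 50
  set <- std_setup(N, px, na = 1.4)
  sample <- make_phantom("filaments", c(N, N), px, seed = 1)
  illum <- standard_illumination(set$opt, frac = 0.85, modulation = 0.9)
  stack <- simulate_raw_stack(sample, illum, set$otf, set$opt,
                              noise = noise_config(0.02, 1e-4, seed = 1))
  w <- reconstruct_sim(stack, "wiener", illum = illum)
  n <- reconstruct_sim(stack, "nsim", illum = illum,
                       config = recon_config(notch_enabled = FALSE))
  expect_identical(n$pixels, w$pixels)
  expect_identical(w$method, "wiener")
  expect_identical(n$method, "nsim")
})

test_that("as the notch width vanishes the output converges to Wiener off-DC", {
  N <- 96; px <- 50
  set <- std_setup(N, px, na = 1.4)
  sample <- make_phantom("filaments", c(N, N), px, seed = 1)
  illum <- standard_illumination(set$opt, frac = 0.85, modulation = 0.9)
  stack <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  w <- reconstruct_sim(stack, "wiener", illum = illum)
  n0 <- reconstruct_sim(stack, "nsim", illum = illum,
                        config = recon_config(notch_sigma = 1e-3))
  # difference is (at most) a DC offset: zero variance
  expect_lt(stats::sd(n0$pixels - w$pixels) / stats::sd(w$pixels), 1e-10)
})

test_that("reconstruction is linear in the raw stack", {
  N <- 96; px <- 50
  set <- std_setup(N, px, na = 1.4)
  sample <- make_phantom("beads", c(N, N), px, params = list(n = 10), seed = 2)
  illum <- standard_illumination(set$opt, frac = 0.9, modulation = 0.9)
  stack <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  scaled <- stack
  scaled$frames <- stack$frames * 3.7
  for (meth in c("wiener", "nsim")) {
    a <- reconstruct_sim(stack, meth, illum = illum)
    b <- reconstruct_sim(scaled, meth, illum = illum)
    expect_equal(b$pixels, 3.7 * a$pixels, tolerance = 1e-12)
  }
  # all-zero input gives an all-zero image
  zero <- stack
  zero$frames[] <- 0
  z <- reconstruct_sim(zero, "nsim", illum = illum)
  expect_equal(max(abs(z$pixels)), 0, tolerance = 1e-14)
})

test_that("the output spectrum is confined to the apodized extended support", {
  N <- 96; px <- 50
  set <- std_setup(N, px, na = 1.4)
  sample <- make_phantom("filaments", c(N, N), px, seed = 1)
  illum <- standard_illumination(set$opt, frac = 0.9, modulation = 0.9)
  stack <- simulate_raw_stack(sample, illum, set$otf, set$opt,
                              noise = noise_config(0.05, 1e-3, seed = 4))
  sr <- reconstruct_sim(stack, "nsim", illum = illum)
  gu <- make_frequency_grid(dim(sr$pixels), sr$pixel_size)
  spec <- Mod(fft2c_ref(sr$pixels))
  edge <- set$otf$cutoff + max(sqrt(rowSums(illum$wave_vectors^2)))
  outside <- gu$k > edge + 2 * gu$spacing[1]
  expect_lt(max(spec[outside]) / max(spec), 1e-6)
})

test_that("the output is a 2x-sampled image with the method provenance", {
  N <- 96; px <- 50
  set <- std_setup(N, px, na = 1.4)
  sample <- make_phantom("filaments", c(N, N), px, seed = 1)
  illum <- standard_illumination(set$opt, frac = 0.85, modulation = 0.9)
  stack <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  sr <- reconstruct_sim(stack, "nsim", illum = illum)
  expect_equal(dim(sr$pixels), c(2 * N, 2 * N))
  expect_equal(sr$pixel_size, px / 2)
  expect_true(all(is.finite(sr$pixels)))
  expect_equal(sr$params$notch_sigma, 2)
  expect_equal(sr$params$wiener_alpha, 0.1)
})

test_that("widefield is the frame mean and is linear", {
  N <- 64; px <- 60
  set <- std_setup(N, px)
  sample <- make_phantom("filaments", c(N, N), px, seed = 3)
  illum <- standard_illumination(set$opt, frac = 0.8, modulation = 0.9)
  stack <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  wf <- widefield(stack)
  expect_equal(wf, apply(stack$frames, c(1, 2), mean))
  s2 <- stack
  s2$frames <- 2.5 * stack$frames
  expect_equal(widefield(s2), 2.5 * wf)
})

test_that("structured illumination halves the bead width against widefield", {
  N <- 128; px <- 40
  set <- std_setup(N, px)  # NA 1.5, 520 nm
  bead <- make_phantom("beads", c(N, N), px,
                       params = list(positions = matrix(c(N / 2 + 1, N / 2 + 1), 1)))
  illum <- standard_illumination(set$opt, frac = 0.95, modulation = 1)
  stack <- simulate_raw_stack(bead, illum, set$otf, set$opt)
  wf <- widefield(stack)
  ctr <- N / 2 + 1
  pw <- line_profile(wf, c(ctr, ctr - 15), c(ctr, ctr + 15),
                     n_samples = 301, pixel_size = px)
  fw_wf <- fwhm(pw)$fwhm_nm
  sr <- reconstruct_sim(stack, "nsim", illum = illum)
  cc <- N + 1
  ps <- line_profile(sr, c(cc, cc - 30), c(cc, cc + 30), n_samples = 301)
  fw_sr <- fwhm(ps)$fwhm_nm
  expect_gt(fw_wf / fw_sr, 1.7)
  expect_lt(fw_wf / fw_sr, 2.1)
})

test_that("pooling the order-0 denominator over orientations is available", {
  N <- 96; px <- 50
  set <- std_setup(N, px, na = 1.4)
  sample <- make_phantom("filaments", c(N, N), px, seed = 1)
  illum <- standard_illumination(set$opt, frac = 0.85, modulation = 0.9)
  stack <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  a <- reconstruct_sim(stack, "nsim", illum = illum)
  b <- reconstruct_sim(stack, "nsim", illum = illum,
                       config = recon_config(pool_zero_orders = TRUE))
  expect_false(identical(a$pixels, b$pixels))
  # both variants stay strongly correlated: same bands, different weights
  expect_gt(stats::cor(as.vector(a$pixels), as.vector(b$pixels)), 0.95)
})
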