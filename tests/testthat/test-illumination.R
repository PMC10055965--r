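test_that("wave vector, phases and modulation are recovered on clean fringes", {
  N <- 128; px <- 40
  set <- std_setup(N, px)
  sample <- make_phantom("filaments", c(N, N), px, params = list(n = 10),
                         seed = 3)
  ang <- 60 * pi / 180
  p_true <- 0.8 * set$opt$cutoff * c(cos(ang), sin(ang))
  illum <- illumination_params(
    rbind(p_true, 0.5 * set$opt$cutoff * diag(2)),
    0.3 + 2 * pi / 3 * (0:2), modulation = 0.9)
  stack <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  fr <- stack$frames[, , 1:3]
  wv <- estimate_wavevector(fr, set$otf)
  expect_lt(sqrt(sum((wv$wave_vector - p_true)^2)) / set$grid$spacing[1], 0.02)
  expect_lte(sqrt(sum(wv$wave_vector^2)), set$opt$cutoff)
  ph <- estimate_phases(fr, wv$wave_vector, set$grid)
  expect_lt(max(phase_diff(ph, 0.3 + 2 * pi / 3 * (0:2))), 0.05)
  # consecutive phase estimates step by ~2 pi / 3 under the nominal protocol
  expect_lt(max(phase_diff(diff(ph), rep(2 * pi / 3, 2))), 0.05)
})

test_that("modulation depth is recovered and degenerates sensibly", {
  N <- 128; px <- 40
  set <- std_setup(N, px)
  sample <- make_phantom("filaments", c(N, N), px, seed = 4)
  for (m_true in c(1.0, 0.5)) {
    illum <- standard_illumination(set$opt, frac = 0.8, modulation = m_true,
                                   phase0 = 0.3)
    stack <- simulate_raw_stack(sample, illum, set$otf, set$opt)
    fr <- stack$frames[, , 1:3]
    wv <- estimate_wavevector(fr, set$otf)
    ph <- estimate_phases(fr, wv$wave_vector, set$grid)
    bands <- separate_bands(lapply(1:3, function(j) fft2c_ref(fr[, , j])),
                            build_separation_matrix(ph, m = 1))
    m_hat <- estimate_modulation(bands, wv$wave_vector, set$otf)
    expect_lt(abs(m_hat - m_true) / m_true, 0.05)
  }
  # identically zero high bands give zero modulation
  zero <- matrix(0i, N, N)
  bands0 <- structure(list(S0 = fft2c_ref(sample$density), Sp = zero,
                           Sm = zero,
                           mix = build_separation_matrix(2 * pi / 3 * (0:2), 1)),
                      class = "spectral_bands")
  expect_equal(estimate_modulation(bands0, c(0.8 * set$opt$cutoff, 0),
                                   set$otf), 0)
})

test_that("fringe-free input raises an estimation failure", {
  N <- 64; px <- 60
  set <- std_setup(N, px)
  sample <- make_phantom("filaments", c(N, N), px, seed = 2)
  illum0 <- standard_illumination(set$opt, frac = 0.8, modulation = 0)
  clean <- simulate_raw_stack(sample, illum0, set$otf, set$opt)
  expect_error(estimate_wavevector(clean$frames[, , 1:3], set$otf),
               "estimation failure")
  noisy <- simulate_raw_stack(sample, illum0, set$otf, set$opt,
                              noise = noise_config(0.02, 1e-4, seed = 3))
  expect_error(estimate_wavevector(noisy$frames[, , 1:3], set$otf),
               "estimation failure")
})

test_that("the wave vector is canonicalized to the upper half-plane", {
  N <- 128; px <- 40
  set <- std_setup(N, px)
  sample <- make_phantom("filaments", c(N, N), px, seed = 6)
  ang <- 200 * pi / 180  # lower half-plane direction
  p_true <- 0.8 * set$opt$cutoff * c(cos(ang), sin(ang))
  illum <- illumination_params(rbind(p_true, 0.5 * set$opt$cutoff * diag(2)),
                               2 * pi / 3 * (0:2), 0.9)
  stack <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  wv <- estimate_wavevector(stack$frames[, , 1:3], set$otf)
  expect_gte(wv$wave_vector[2], 0)
  # same fringe: the estimate matches -p_true
  expect_lt(sqrt(sum((wv$wave_vector + p_true)^2)) / set$grid$spacing[1],
            0.02)
})

test_that("phases are reported modulo 2 pi and reject a DC wave vector", {
  N <- 64; px <- 60
  set <- std_setup(N, px)
  sample <- make_phantom("filaments", c(N, N), px, seed = 2)
  illum <- standard_illumination(set$opt, frac = 0.8, modulation = 0.9,
                                 phase0 = 5.9)  # wraps past 2 pi
  stack <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  ph <- estimate_phases(stack$frames[, , 1:3], illum$wave_vectors[1, ],
                        set$grid)
  expect_true(all(ph >= 0 & ph < 2 * pi))
  expect_lt(max(phase_diff(ph, 5.9 + 2 * pi / 3 * (0:2))), 0.05)
  expect_error(estimate_phases(stack$frames[, , 1:3], c(0, 0), set$grid),
               "DC")
})

test_that("parameter recovery meets the accuracy floor over random draws", {
  # 20 random (p, phi, m) draws at >= 20 dB SNR
  N <- 128; px <- 40
  set <- std_setup(N, px)
  set.seed(99)
  werr <- perr <- numeric(20)
  for (i in 1:20) {
    frac <- stats::runif(1, 0.7, 0.9)
    ang <- stats::runif(1, 5, 85) * pi / 180
    ph0 <- stats::runif(1, 0, 2 * pi)
    m <- stats::runif(1, 0.7, 1.0)
    p_true <- frac * set$opt$cutoff * c(cos(ang), sin(ang))
    illum <- illumination_params(rbind(p_true, 0.5 * set$opt$cutoff * diag(2)),
                                 ph0 + 2 * pi / 3 * (0:2), m)
    sample <- make_phantom("filaments", c(N, N), px, params = list(n = 10),
                           seed = i)
    stack <- simulate_raw_stack(sample, illum, set$otf, set$opt,
                                noise = noise_config(0.02, 1e-4, seed = i))
    fr <- stack$frames[, , 1:3]
    wv <- estimate_wavevector(fr, set$otf)
    werr[i] <- sqrt(sum((wv$wave_vector - p_true)^2)) / set$grid$spacing[1]
    ph <- estimate_phases(fr, wv$wave_vector, set$grid)
    perr[i] <- max(phase_diff(ph, ph0 + 2 * pi / 3 * (0:2)))
  }
  expect_lt(stats::median(werr), 0.05)
  expect_lt(stats::median(perr), 0.1)
})

test_that("estimates are invariant to global intensity rescaling", {
  N <- 128; px <- 40
  set <- std_setup(N, px)
  sample <- make_phantom("beads", c(N, N), px, params = list(n = 30), seed = 9)
  illum <- standard_illumination(set$opt, frac = 0.85, modulation = 0.8,
                                 phase0 = 1.1)
  stack <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  a <- estimate_illumination(stack)
  stack2 <- stack
  stack2$frames <- stack$frames * 7.3
  b <- estimate_illumination(stack2)
  expect_equal(b$wave_vectors, a$wave_vectors, tolerance = 1e-12)
  expect_equal(b$phases, a$phases, tolerance = 1e-10)
  expect_equal(b$modulation, a$modulation, tolerance = 1e-10)
  est <- attr(a, "estimation")
  expect_s3_class(est, "tbl_df")
  expect_equal(nrow(est), 3)
  expect_true(all(is.finite(est$score)))
})
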