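test_that("circular-pupil OTF matches its closed form and constraints", {
  set <- std_setup(N = 64, pixel_size = 80, na = 1.4)
  H <- set$otf$values
  ctr <- c(33, 33)
  expect_equal(H[ctr[1], ctr[2]], 1)                 # DC normalization
  expect_true(all(H >= 0 & H <= 1))
  expect_identical(H[set$grid$k >= set$otf$cutoff], rep(0, sum(set$grid$k >= set$otf$cutoff)))
  # closed form at rho = 0.5: (2/pi) (pi/3 - 0.5 sqrt(0.75))
  rho_half <- (2 / pi) * (pi / 3 - 0.5 * sqrt(0.75))
  expect_equal(rho_half, 0.3910, tolerance = 1e-4)
  k_half <- 0.5 * set$otf$cutoff
  row <- H[ctr[1], ]
  expect_equal(stats::approx(set$grid$k[ctr[1], ctr[2]:64],
                             row[ctr[2]:64], xout = k_half)$y,
               rho_half, tolerance = 1e-3)
  # radially non-increasing along the axis
  expect_true(all(diff(row[ctr[2]:64]) <= 1e-12))
})

test_that("an OTF cutoff beyond the grid Nyquist triggers the truncation warning", {
  opt <- optical_params(520, 1.4, 100, c(64, 64))  # Nyquist 5 < kem 5.38
  grid <- make_frequency_grid(c(64, 64), 100)
  expect_warning(make_otf(opt, grid), "Nyquist")
})

test_that("phantoms are deterministic, non-negative and carry ground truth", {
  for (kind in c("beads", "resolution_board", "filaments", "droplets")) {
    a <- make_phantom(kind, c(64, 64), 100, seed = 5)
    b <- make_phantom(kind, c(64, 64), 100, seed = 5)
    expect_identical(a$density, b$density)
    expect_true(all(a$density >= 0))
    d <- make_phantom(kind, c(64, 64), 100, seed = 6)
    if (kind != "resolution_board") expect_false(identical(a$density, d$density))
  }
  expect_error(make_phantom("spirals", c(64, 64), 100), "arg")
  expect_error(make_phantom("beads", c(32, 64), 100), "64")
})

test_that("bead and droplet ground truth records the requested geometry", {
  b <- make_phantom("beads", c(64, 64), 100,
                    params = list(positions = matrix(c(33, 33), 1)))
  expect_equal(nrow(b$truth), 1)
  expect_equal(c(b$truth$row, b$truth$col), c(33, 33))
  expect_equal(sum(b$density), 1)             # unit flux deposited
  expect_equal(b$density[33, 33], 1)          # integer position: one pixel
  d <- make_phantom("droplets", c(128, 128), 100,
                    params = list(radii_nm = c(3000, 600, 900)), seed = 2)
  expect_setequal(d$truth$radius_nm, c(3000, 600, 900))
  # sub-pixel bead splits its flux bilinearly over the 4 neighbours
  s <- make_phantom("beads", c(64, 64), 100,
                    params = list(positions = matrix(c(20.5, 30.25), 1)))
  expect_equal(sum(s$density), 1)
  expect_equal(s$density[20, 30], 0.5 * 0.75)
})

test_that("m = 0 gives nine identical widefield frames", {
  set <- std_setup(N = 64, pixel_size = 60)
  sample <- make_phantom("filaments", c(64, 64), 60, seed = 3)
  illum <- standard_illumination(set$opt, frac = 0.8, modulation = 0)
  st <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  wf <- widefield(st)
  for (i in 1:9) expect_equal(st$frames[, , i], wf, tolerance = 1e-12)
  # and the widefield frame is the sample blurred by the PSF
  blurred <- Re(stats::fft(stats::fft(sample$density) *
                             notchsim::ifftshift(set$otf$values),
                           inverse = TRUE)) / (64 * 64)
  expect_equal(wf, pmax(blurred, 0), tolerance = 1e-10)
})

test_that("the three phases of one orientation average to the widefield frame", {
  set <- std_setup(N = 64, pixel_size = 60)
  sample <- make_phantom("beads", c(64, 64), 60, params = list(n = 12), seed = 8)
  illum <- standard_illumination(set$opt, frac = 0.9, modulation = 1)
  st <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  wf_ref <- simulate_raw_stack(sample,
                               standard_illumination(set$opt, 0.9, modulation = 0),
                               set$otf, set$opt)$frames[, , 1]
  for (d in 1:3) {
    mean3 <- (st$frames[, , (d - 1) * 3 + 1] + st$frames[, , (d - 1) * 3 + 2] +
                st$frames[, , (d - 1) * 3 + 3]) / 3
    expect_equal(mean3, wf_ref, tolerance = 1e-10)
  }
  # noiseless, defocus-free frames are non-negative (cosine flux positivity)
  expect_true(all(st$frames >= 0))
})

test_that("defocus adds one identical phase-independent field to all frames", {
  set <- std_setup(N = 64, pixel_size = 60)
  sample <- make_phantom("filaments", c(64, 64), 60, seed = 3)
  bg <- make_phantom("filaments", c(64, 64), 60, seed = 13)
  illum <- standard_illumination(set$opt, frac = 0.8, modulation = 0.7)
  clean <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  dirty <- simulate_raw_stack(sample, illum, set$otf, set$opt,
                              defocus = defocus_config(bg, beta = 0.4,
                                                       optical = set$opt))
  field <- attr(dirty, "defocus_field")
  expect_true(all(field >= 0))
  for (i in 1:9)
    expect_equal(dirty$frames[, , i] - clean$frames[, , i], field,
                 tolerance = 1e-12)
  expect_error(defocus_config(bg, blur_sigma = 10, beta = 1,
                              optical = set$opt), "exceed")
})

test_that("noiseless frame spectra vanish outside the extended support", {
  set <- std_setup(N = 64, pixel_size = 60)
  sample <- make_phantom("beads", c(64, 64), 60, params = list(n = 10), seed = 4)
  illum <- standard_illumination(set$opt, frac = 0.8, modulation = 0.9)
  st <- simulate_raw_stack(sample, illum, set$otf, set$opt)
  pmax_mag <- max(sqrt(rowSums(illum$wave_vectors^2)))
  outside <- set$grid$k > set$otf$cutoff + pmax_mag + 2 * set$grid$spacing[1]
  for (i in c(1, 5, 9)) {
    spec <- Mod(fft2c_ref(st$frames[, , i]))
    expect_lt(max(spec[outside]) / max(spec), 1e-12)
  }
})

test_that("noise realizations are seed-reproducible and clipped at zero", {
  set <- std_setup(N = 64, pixel_size = 60)
  sample <- make_phantom("filaments", c(64, 64), 60, seed = 3)
  illum <- standard_illumination(set$opt, frac = 0.8)
  a <- simulate_raw_stack(sample, illum, set$otf, set$opt,
                          noise = noise_config(0.1, 0.1, seed = 21))
  b <- simulate_raw_stack(sample, illum, set$otf, set$opt,
                          noise = noise_config(0.1, 0.1, seed = 21))
  d <- simulate_raw_stack(sample, illum, set$otf, set$opt,
                          noise = noise_config(0.1, 0.1, seed = 22))
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, d$frames))
  expect_true(all(a$frames >= 0))
  expect_gt(mean(a$frames == 0), 0)  # heavy noise: some clipping occurred
})

test_that("wave vectors beyond the OTF cutoff are rejected", {
  set <- std_setup(N = 64, pixel_size = 60)
  sample <- make_phantom("filaments", c(64, 64), 60, seed = 3)
  illum <- illumination_params(
    rbind(c(set$otf$cutoff * 1.05, 0), c(0, 1), c(1, 1)),
    2 * pi / 3 * (0:2), 0.9)
  expect_error(simulate_raw_stack(sample, illum, set$otf, set$opt), "cutoff")
})
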