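#' Reconstruction configuration
#'
#' @param wiener_alpha Wiener regularizer `alpha` (> 0) on the OTF-normalized
#'   scale (the OTF peaks at 1). Default 0.1.
#' @param notch_sigma Notch width `sigma` in frequency-grid pixels of the raw
#'   (non-upsampled) grid (> 0). Default 2, the value at which background is
#'   suppressed without losing weak in-focus features.
#' @param notch_enabled Apply the notch to the order-0 band (`TRUE` for the
#'   N-SIM path).
#' @param apodization `"triangle"` (linear taper to the extended cutoff) or
#'   `"none"`.
#' @param pool_zero_orders If `TRUE`, the order-0 Wiener quotient pools its
#'   denominator over the three orientations
#'   (`sum_d H0 S0d / (sum_d H0^2 + alpha^2)`); by default each orientation's
#'   quotient uses its own denominator and the three are averaged.
#' @param upsample Output upsampling factor; fixed at 2.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(wiener_alpha = 0.1, notch_sigma = 2,
                         notch_enabled = TRUE, apodization = "triangle",
                         pool_zero_orders = FALSE, upsample = 2L) {
  if (!is.finite(wiener_alpha) || wiener_alpha <= 0)
    stop("wiener_alpha must be positive", call. = FALSE)
  if (notch_enabled && (!is.finite(notch_sigma) || notch_sigma <= 0))
    stop("notch_sigma must be positive when the notch is enabled",
         call. = FALSE)
  apodization <- match.arg(apodization, c("triangle", "none"))
  if (upsample != 2L) stop("upsample factor is fixed at 2", call. = FALSE)
  structure(list(wiener_alpha = wiener_alpha, notch_sigma = notch_sigma,
                 notch_enabled = notch_enabled, apodization = apodization,
                 pool_zero_orders = pool_zero_orders, upsample = 2L),
            class = "recon_config")
}

#' Gaussian notch filter
#'
#' `F(k) = 1 - exp(-r^2 / (2 sigma^2))` with `r` the distance from DC in
#' frequency-grid pixels: the complement of a DC-centered Gaussian,
#' normalized by its maximum, so `F(0) = 0` and `F -> 1` far from DC. The
#' defocus background is confined to the low-frequency band, so multiplying
#' the order-0 quotient by `F` suppresses it while the order-(+/-)1 terms
#' re-supply the in-focus low frequencies.
#'
#' @param grid A [make_frequency_grid()] (raw or upsampled). `sigma` is
#'   measured in pixels of the raw grid; the upsampled grid shares the same
#'   per-pixel spacing, so the same formula applies on both.
#' @param sigma Notch width in frequency-grid pixels (> 0).
#' @return Matrix of filter values in \[0, 1\], DC-centered (class
#'   `filter_array`).
#' @export
notch_function <- function(grid, sigma) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (!is.finite(sigma) || sigma <= 0)
    stop("notch sigma must be positive", call. = FALSE)
  r_px <- sqrt((grid$kx / grid$spacing[2])^2 + (grid$ky / grid$spacing[1])^2)
  structure(1 - exp(-r_px^2 / (2 * sigma^2)), class = "filter_array")
}

#' Triangle apodization
#'
#' `A(k) = max(0, 1 - |k| / extended_cutoff)`: a linear taper to zero at the
#' extended support edge `kem + |p|`, suppressing ringing from the sharp
#' boundary of the combined spectrum.
#'
#' @param grid A [make_frequency_grid()] (typically the upsampled grid).
#' @param extended_cutoff Taper radius in cycles/um (> 0).
#' @return Matrix of filter values in \[0, 1\] (class `filter_array`).
#' @export
apodization <- function(grid, extended_cutoff) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (!is.finite(extended_cutoff) || extended_cutoff <= 0)
    stop("extended_cutoff must be positive", call. = FALSE)
  structure(pmax(1 - grid$k / extended_cutoff, 0), class = "filter_array")
}

# upsampled (2x) frequency grid of a raw grid: twice the samples at half the
# pixel size; per-pixel frequency spacing is unchanged, Nyquist doubles
upsampled_grid <- function(grid) {
  make_frequency_grid(2L * grid$shape, grid$pixel_size / 2)
}

#' Embed a raw-grid spectrum in the 2x upsampled grid
#'
#' Zero-pads a DC-centered `N x M` spectrum into the `2N x 2M` centered grid
#' (DC stays at the center element). In real space this is exact 2x
#' band-limited (sinc) interpolation up to a constant factor.
#'
#' @param band Complex (or real) DC-centered spectrum matrix.
#' @return Matrix of twice the size in each dimension.
#' @export
embed_spectrum <- function(band) {
  n <- dim(band)
  out <- matrix(0i, 2 * n[1], 2 * n[2])
  out[(floor(n[1] / 2) + 1):(floor(n[1] / 2) + n[1]),
      (floor(n[2] / 2) + 1):(floor(n[2] / 2) + n[2])] <- band
  out
}

#' Translate a spectrum by a sub-pixel frequency vector
#'
#' Fourier-shift theorem: the band is taken to real space, multiplied by
#' `exp(+2 pi i (p . r))` and transformed back, which translates the
#' spectrum by `+p` exactly (as a periodic function), including sub-pixel
#' components.
#'
#' @param band Complex DC-centered spectrum on `grid`.
#' @param shift Length-2 shift vector `(px, py)` in cycles/um.
#' @param grid The [make_frequency_grid()] the band lives on (typically the
#'   upsampled grid).
#' @return Complex matrix: the translated spectrum.
#' @export
shift_band <- function(band, shift, grid) {
  stopifnot(inherits(grid, "frequency_grid"), length(shift) == 2)
  nyq <- grid$spacing * grid$shape / 2
  if (abs(shift[1]) > nyq[2] || abs(shift[2]) > nyq[1])
    stop("shift magnitude exceeds the grid Nyquist", call. = FALSE)
  if (all(shift == 0)) return(band)
  px_um <- grid$pixel_size * 1e-3
  x_um <- (seq_len(grid$shape[2]) - 1) * px_um
  y_um <- (seq_len(grid$shape[1]) - 1) * px_um
  ramp <- exp(2i * pi * outer(shift[2] * y_um, shift[1] * x_um, "+"))
  fft2c(ifft2c(band) * ramp)
}

# shifted OTF |H(k - n p)| evaluated analytically on the grid (exact; avoids
# interpolation error from FFT-shifting the sampled OTF)
shifted_otf <- function(grid, cutoff, shift) {
  otf_radial(sqrt((grid$kx - shift[1])^2 + (grid$ky - shift[2])^2), cutoff)
}

# Shared band-combination engine for both reconstruction paths.
#
#   g = Re ifft[ ( Q0(k) * F(k) + Q1(k) ) * A(k) ]
#
# Q0: order-0 Wiener quotient — per-orientation H0 S0d / (H0^2 + alpha^2)
#     averaged over d (or pooled over d when pool_zero_orders), the three
#     order-0 bands being redundant estimates of C(k)H(k).
# Q1: order-(+/-)1 quotient, pooled over the six shifted bands:
#     sum H_nd S_nd / (sum H_nd^2 + alpha^2).
# F == 1 when the notch is disabled, which is the generalized Wiener path.
combine_bands <- function(bands_list, illum, otf, config, notch_on) {
  grid <- otf$grid
  ugrid <- upsampled_grid(grid)
  alpha2 <- config$wiener_alpha^2
  H0 <- shifted_otf(ugrid, otf$cutoff, c(0, 0))

  num0 <- matrix(0i, ugrid$shape[1], ugrid$shape[2])
  den0 <- matrix(0, ugrid$shape[1], ugrid$shape[2])
  q0 <- matrix(0i, ugrid$shape[1], ugrid$shape[2])
  num1 <- matrix(0i, ugrid$shape[1], ugrid$shape[2])
  den1 <- matrix(0, ugrid$shape[1], ugrid$shape[2])

  for (d in 1:3) {
    b <- bands_list[[d]]
    p <- illum$wave_vectors[d, ]
    S0 <- embed_spectrum(b$S0)
    if (config$pool_zero_orders) {
      num0 <- num0 + H0 * S0
      den0 <- den0 + H0^2
    } else {
      q0 <- q0 + (H0 * S0) / (H0^2 + alpha2) / 3
    }
    # S(+1)(k) = C(k + p)H(k): translate by +p so C sits unshifted; its
    # transfer becomes H(k - p). Mirror for S(-1).
    Sp <- shift_band(embed_spectrum(b$Sp), p, ugrid)
    Hp <- shifted_otf(ugrid, otf$cutoff, p)
    Sm <- shift_band(embed_spectrum(b$Sm), -p, ugrid)
    Hm <- shifted_otf(ugrid, otf$cutoff, -p)
    num1 <- num1 + Hp * Sp + Hm * Sm
    den1 <- den1 + Hp^2 + Hm^2
  }
  if (config$pool_zero_orders) q0 <- num0 / (den0 + alpha2)
  q1 <- num1 / (den1 + alpha2)

  Fk <- if (notch_on) notch_function(ugrid, config$notch_sigma) else 1
  A <- if (config$apodization == "triangle") {
    pmax_p <- max(sqrt(rowSums(illum$wave_vectors^2)))
    apodization(ugrid, otf$cutoff + pmax_p)
  } else 1

  spec <- (q0 * Fk + q1) * A
  Re(ifft2c(spec))
}

recon_params_record <- function(config, illum, method) {
  list(method = method, wiener_alpha = config$wiener_alpha,
       notch_sigma = if (identical(method, "nsim")) config$notch_sigma else NA,
       apodization = config$apodization,
       pool_zero_orders = config$pool_zero_orders,
       modulation = illum$modulation,
       wave_vectors = illum$wave_vectors, phases = illum$phases)
}

#' Generalized Wiener reconstruction
#'
#' Combines the separated and shifted bands of all orientations into one
#' extended spectrum with Wiener quotients and apodization, then inverse
#' transforms: `g(r) = Re ifft[(Q0 + Q1) A(k)]` (see [reconstruct_nsim()] for
#' the quotient structure; this path is the `F == 1` case).
#'
#' @param bands_list List of three [separate_bands()] results (orientations
#'   1..3).
#' @param illum The [illumination_params()] used (wave vectors drive the band
#'   shifts).
#' @param otf The [make_otf()] model of the acquisition.
#' @param config A [recon_config()].
#' @return An [sr_image()] at 2x sampling (unclipped real part).
#' @export
reconstruct_wiener <- function(bands_list, illum, otf,
                               config = recon_config()) {
  px <- combine_bands(bands_list, illum, otf, config, notch_on = FALSE)
  sr_image(px, otf$grid$pixel_size / 2, "wiener",
           recon_params_record(config, illum, "wiener"))
}

#' Notch-filtered (N-SIM) reconstruction
#'
#' Identical to [reconstruct_wiener()] except that the order-0 Wiener
#' quotient is multiplied by the notch `F(k) = 1 - exp(-r^2/(2 sigma^2))`
#' before summation with the order-(+/-)1 term. The phase-independent defocus
#' background is confined to the order-0 band, so the notch suppresses it at
#' the source while the shifted bands restore the in-focus low frequencies.
#' With `config$notch_enabled = FALSE` the output is identical to the Wiener
#' path.
#'
#' @inheritParams reconstruct_wiener
#' @return An [sr_image()] at 2x sampling (unclipped real part).
#' @export
reconstruct_nsim <- function(bands_list, illum, otf,
                             config = recon_config()) {
  px <- combine_bands(bands_list, illum, otf, config,
                      notch_on = isTRUE(config$notch_enabled))
  sr_image(px, otf$grid$pixel_size / 2, "nsim",
           recon_params_record(config, illum, "nsim"))
}

#' One-call reconstruction from a raw stack
#'
#' Separates the bands of each orientation (with supplied or estimated
#' illumination parameters) and runs the chosen reconstruction path.
#'
#' @param stack A [sim_stack()].
#' @param method `"nsim"` (default) or `"wiener"`.
#' @param illum An [illumination_params()], or `NULL` to estimate the wave
#'   vectors, phases and modulation from the stack
#'   (see [estimate_illumination()]).
#' @param config A [recon_config()].
#' @return An [sr_image()].
#' @export
reconstruct_sim <- function(stack, method = c("nsim", "wiener"),
                            illum = NULL, config = recon_config()) {
  stopifnot(inherits(stack, "sim_stack"))
  method <- match.arg(method)
  opt <- stack$optical
  grid <- make_frequency_grid(opt$image_shape, opt$pixel_size)
  otf <- make_otf(opt, grid)
  if (is.null(illum)) illum <- estimate_illumination(stack, otf)
  phases <- if (is.matrix(illum$phases)) illum$phases else
    matrix(illum$phases, 3, 3, byrow = TRUE)
  bands_list <- lapply(1:3, function(d) {
    spectra <- lapply(1:3, function(j)
      fft2c(stack$frames[, , (d - 1) * 3 + j]))
    separate_bands(spectra,
                   build_separation_matrix(phases[d, ], illum$modulation),
                   illum$intensity)
  })
  if (method == "wiener")
    reconstruct_wiener(bands_list, illum, otf, config)
  else
    reconstruct_nsim(bands_list, illum, otf, config)
}
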