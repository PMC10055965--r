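#' Ideal incoherent optical transfer function of a circular pupil
#'
#' Closed-form 2-D incoherent OTF,
#' `H(rho) = (2/pi) * (acos(rho) - rho * sqrt(1 - rho^2))` for
#' `rho = |k| / kem <= 1` and 0 beyond the cutoff. Radially non-increasing,
#' 1 at DC, 0 at and beyond `kem`.
#'
#' @param optical An [optical_params()] object (supplies `kem`).
#' @param grid A [make_frequency_grid()] matching `optical$image_shape`.
#' @return An object of class `otf_model` with fields `values` (matrix on the
#'   DC-centered grid), `cutoff` (kem, cycles/um) and `grid`.
#' @export
make_otf <- function(optical, grid) {
  stopifnot(inherits(optical, "optical_params"),
            inherits(grid, "frequency_grid"))
  if (!all(grid$shape == optical$image_shape))
    stop("grid shape does not match optical$image_shape", call. = FALSE)
  nyquist <- min(grid$spacing * grid$shape / 2)
  if (optical$cutoff > nyquist)
    warning("OTF cutoff ", signif(optical$cutoff, 4),
            " cycles/um exceeds the grid Nyquist ", signif(nyquist, 4),
            " cycles/um; the OTF is truncated by sampling", call. = FALSE)
  structure(
    list(values = otf_radial(grid$k, optical$cutoff),
         cutoff = optical$cutoff, grid = grid),
    class = "otf_model"
  )
}

# closed-form pupil OTF evaluated at radial frequencies k (cycles/um)
otf_radial <- function(k, cutoff) {
  rho <- pmin(k / cutoff, 1)
  h <- (2 / pi) * (acos(rho) - rho * sqrt(pmax(0, 1 - rho^2)))
  h[k >= cutoff] <- 0
  h
}

#' @export
print.otf_model <- function(x, ...) {
  cat(sprintf("<otf_model> %d x %d, cutoff %.4g cycles/um\n",
              x$grid$shape[1], x$grid$shape[2], x$cutoff))
  invisible(x)
}

#' Fluorophore-density phantom with recorded ground truth
#'
#' Test objects for the simulator. `"beads"` places sub-pixel point emitters
#' (bilinear deposition over the four neighbouring pixels); `"droplets"`
#' places bright rings of recorded radii; `"filaments"` draws smooth random
#' curvilinear structures; `"resolution_board"` lays out bar groups of
#' geometrically decreasing period in both directions.
#'
#' @param kind One of `"beads"`, `"resolution_board"`, `"filaments"`,
#'   `"droplets"`.
#' @param shape Image shape `c(rows, cols)`, at least 64 x 64.
#' @param pixel_size Pixel size in nm.
#' @param params Named list of kind-specific parameters:
#'   * beads: `n` (count) or `positions` (2-col matrix, pixel units, 1-based),
#'     `intensity`, `margin` (pixels kept clear of the border).
#'   * droplets: `radii_nm` (vector; one ring per entry) or `n` plus
#'     `radius_range_nm`; `ring_width_nm`; `margin`; `min_gap_px`.
#'   * filaments: `n`, `step_sigma` (curvature), `length` (steps).
#'   * resolution_board: `periods_px` (bar periods), `duty` (fill fraction).
#' @param seed Integer seed; the phantom is a pure function of its arguments.
#' @return An object of class `sample_image`: `density` (non-negative
#'   matrix), `pixel_size` (nm) and `truth` (a tibble of ground-truth
#'   geometry: bead positions, droplet centers/radii, or empty).
#' @export
make_phantom <- function(kind, shape, pixel_size, params = list(),
                         seed = 1L) {
  kind <- match.arg(kind,
                    c("beads", "resolution_board", "filaments", "droplets"))
  shape <- as.integer(shape)
  if (any(shape < 64)) stop("phantom shape must be at least 64 x 64",
                            call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  img <- matrix(0, shape[1], shape[2])
  truth <- tibble::tibble()

  if (kind == "beads") {
    intensity <- params$intensity %||% 1
    margin <- params$margin %||% 8
    if (!is.null(params$positions)) {
      pos <- as.matrix(params$positions)
    } else {
      n <- params$n %||% 20
      pos <- cbind(stats::runif(n, 1 + margin, shape[1] - margin),
                   stats::runif(n, 1 + margin, shape[2] - margin))
    }
    for (i in seq_len(nrow(pos)))
      img <- deposit_point(img, pos[i, 1], pos[i, 2], intensity)
    truth <- tibble::tibble(row = pos[, 1], col = pos[, 2],
                            x_nm = (pos[, 2] - 1) * pixel_size,
                            y_nm = (pos[, 1] - 1) * pixel_size)
  } else if (kind == "droplets") {
    ring_width <- (params$ring_width_nm %||% (2 * pixel_size)) / pixel_size
    margin <- params$margin %||% 6
    min_gap <- params$min_gap_px %||% 4
    if (!is.null(params$radii_nm)) {
      radii_px <- params$radii_nm / pixel_size
    } else {
      n <- params$n %||% 10
      rr <- params$radius_range_nm %||% c(300, 900)
      radii_px <- stats::runif(n, rr[1], rr[2]) / pixel_size
    }
    centers <- place_disks(shape, radii_px, margin, min_gap)
    keep <- !is.na(centers[, 1])
    radii_px <- radii_px[keep]; centers <- centers[keep, , drop = FALSE]
    yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
    xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    for (i in seq_along(radii_px)) {
      r <- sqrt((yy - centers[i, 1])^2 + (xx - centers[i, 2])^2)
      img <- img + exp(-(r - radii_px[i])^2 / (2 * (ring_width / 2.355)^2))
    }
    truth <- tibble::tibble(row = centers[, 1], col = centers[, 2],
                            radius_nm = radii_px * pixel_size)
  } else if (kind == "filaments") {
    n <- params$n %||% 6
    step_sigma <- params$step_sigma %||% 0.25
    len <- params$length %||% (3 * max(shape))
    for (f in seq_len(n)) {
      p <- c(stats::runif(1, shape[1] * 0.2, shape[1] * 0.8),
             stats::runif(1, shape[2] * 0.2, shape[2] * 0.8))
      ang <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(len)) {
        ang <- ang + stats::rnorm(1, 0, step_sigma)
        p <- p + c(sin(ang), cos(ang)) * 0.5
        if (any(p < 2) || p[1] > shape[1] - 1 || p[2] > shape[2] - 1) break
        img <- deposit_point(img, p[1], p[2], 0.5)
      }
    }
    img <- pmin(img, 1)
  } else { # resolution_board
    periods <- params$periods_px %||% c(16, 12, 8, 6, 4, 3)
    duty <- params$duty %||% 0.5
    ng <- length(periods)
    band_w <- floor(shape[2] / ng)
    half <- floor(shape[1] / 2)
    for (g in seq_len(ng)) {
      cols <- ((g - 1) * band_w + 1):min(g * band_w - 2, shape[2])
      ph_c <- ((cols - cols[1]) %% periods[g]) / periods[g] < duty
      # vertical bars (modulated along x) in the top half
      img[seq_len(half - 2), cols] <-
        matrix(as.numeric(ph_c), half - 2, length(cols), byrow = TRUE)
      # horizontal bars (modulated along y) in the bottom half
      rows <- (half + 2):shape[1]
      ph_r <- ((rows - rows[1]) %% periods[g]) / periods[g] < duty
      img[rows, cols] <- matrix(as.numeric(ph_r), length(rows), length(cols))
    }
    truth <- tibble::tibble(group = seq_len(ng), period_px = periods,
                            period_nm = periods * pixel_size)
  }

  structure(list(density = img, pixel_size = pixel_size, truth = truth,
                 kind = kind),
            class = "sample_image")
}

#' @export
print.sample_image <- function(x, ...) {
  cat(sprintf("<sample_image> \"%s\" %d x %d at %g nm/px (%d truth rows)\n",
              x$kind, nrow(x$density), ncol(x$density), x$pixel_size,
              nrow(x$truth)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# save/restore the global RNG state so generators are pure functions
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# bilinear deposition of a sub-pixel point source
deposit_point <- function(img, row, col, intensity) {
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  for (dr in 0:1) for (dc in 0:1) {
    r <- r0 + dr; c <- c0 + dc
    if (r >= 1 && r <= nrow(img) && c >= 1 && c <= ncol(img)) {
      w <- (if (dr) fr else 1 - fr) * (if (dc) fc else 1 - fc)
      img[r, c] <- img[r, c] + intensity * w
    }
  }
  img
}

# rejection-sample non-overlapping disk centers; NA rows when space runs out
place_disks <- function(shape, radii_px, margin, min_gap) {
  n <- length(radii_px)
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in seq_len(400)) {
      cand <- c(stats::runif(1, 1 + margin + radii_px[i],
                             shape[1] - margin - radii_px[i]),
                stats::runif(1, 1 + margin + radii_px[i],
                             shape[2] - margin - radii_px[i]))
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        if (is.na(centers[j, 1])) next
        if (sqrt(sum((cand - centers[j, ])^2)) <
            radii_px[i] + radii_px[j] + min_gap) { ok <- FALSE; break }
      }
      if (ok) { centers[i, ] <- cand; break }
    }
  }
  centers
}

#' Illumination pattern parameters
#'
#' The cosine illumination of one acquisition:
#' `I0 * (1 + m * cos(2 pi p_d . r + phi_j))` per orientation `d` and phase
#' `j`. Wave vectors must stay inside the OTF support (`|p_d| <= kem`).
#'
#' @param wave_vectors 3 x 2 matrix of per-orientation wave vectors
#'   `(px, py)` in cycles/um (row `d` = orientation `d`).
#' @param phases Three pattern phases in radians (nominal step 2 pi / 3), or
#'   a 3 x 3 matrix of per-orientation phases (row `d` = orientation `d`),
#'   as produced by estimation.
#' @param modulation Modulation depth `m` in \[0, 1\].
#' @param intensity Illumination intensity `I0` (> 0); a global scale.
#' @return An object of class `illumination_params`.
#' @export
illumination_params <- function(wave_vectors, phases,
                                modulation = 0.9, intensity = 1) {
  wave_vectors <- as.matrix(wave_vectors)
  stopifnot(all(dim(wave_vectors) == c(3, 2)),
            if (is.matrix(phases)) all(dim(phases) == c(3, 3))
            else length(phases) == 3)
  if (modulation < 0 || modulation > 1)
    stop("modulation depth m must lie in [0, 1]", call. = FALSE)
  if (intensity <= 0) stop("intensity I0 must be positive", call. = FALSE)
  if (!is.matrix(phases)) phases <- as.numeric(phases)
  structure(
    list(wave_vectors = wave_vectors, phases = phases,
         modulation = modulation, intensity = intensity),
    class = "illumination_params"
  )
}

#' Standard three-orientation illumination for an optical configuration
#'
#' Wave vectors at `frac * kem` along `angles` (0, 60, 120 degrees by
#' default) with the nominal 2 pi / 3 phase stepping.
#'
#' @param optical An [optical_params()].
#' @param frac `|p| / kem`, in (0, 1].
#' @param angles Three orientation angles in degrees.
#' @param phase0 Phase of the first frame (radians).
#' @inheritParams illumination_params
#' @return An [illumination_params()] object.
#' @export
standard_illumination <- function(optical, frac = 0.9,
                                  angles = c(0, 60, 120), phase0 = 0,
                                  modulation = 0.9, intensity = 1) {
  stopifnot(inherits(optical, "optical_params"), frac > 0, frac <= 1)
  a <- angles * pi / 180
  p <- frac * optical$cutoff * cbind(cos(a), sin(a))
  illumination_params(p, phase0 + 2 * pi / 3 * (0:2), modulation, intensity)
}

#' Defocus background configuration
#'
#' Out-of-focal-plane fluorescence is modelled as an independent background
#' sample convolved with a wide Gaussian kernel and added, scaled by `beta`,
#' identically to every raw frame: defocused emitters see essentially
#' unmodulated illumination, so the term carries no pattern phase.
#'
#' @param background A [make_phantom()] result (the out-of-plane structure).
#' @param blur_sigma Gaussian blur sigma in nm; must exceed the in-focus PSF
#'   width. Default 5x the in-focus PSF FWHM if `optical` is given.
#' @param beta Non-negative background weight (default 0.5).
#' @param optical Optional [optical_params()] used for the default
#'   `blur_sigma` and its validity check.
#' @return An object of class `defocus_config`.
#' @export
defocus_config <- function(background, blur_sigma = NULL, beta = 0.5,
                           optical = NULL) {
  stopifnot(inherits(background, "sample_image"))
  if (beta < 0) stop("defocus weight beta must be >= 0", call. = FALSE)
  psf_fwhm <- if (!is.null(optical))
    0.51 * optical$emission_wavelength / optical$numerical_aperture
  else NA_real_
  if (is.null(blur_sigma)) {
    if (is.na(psf_fwhm))
      stop("supply blur_sigma or optical", call. = FALSE)
    blur_sigma <- 5 * psf_fwhm
  }
  if (!is.na(psf_fwhm) && blur_sigma <= psf_fwhm / 2.355)
    stop("defocus blur_sigma must exceed the in-focus PSF width",
         call. = FALSE)
  structure(list(background = background, blur_sigma = blur_sigma,
                 beta = beta),
            class = "defocus_config")
}

#' Additive Gaussian noise configuration
#'
#' Noise on the normalized \[0, 1\] intensity scale; the default mean 0.1 and
#' variance 0.1 match the simulation protocol used for the resolution-board
#' comparison. Negative intensities are clipped to 0 after addition.
#'
#' @param mean Noise mean (intensity units).
#' @param variance Noise variance (>= 0).
#' @param seed Integer seed for the realization.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(mean = 0.1, variance = 0.1, seed = 1L) {
  if (variance < 0) stop("noise variance must be >= 0", call. = FALSE)
  structure(list(mean = mean, variance = variance, seed = as.integer(seed)),
            class = "noise_config")
}

# blur a real image by multiplying its spectrum with an OTF-like transfer fn
apply_transfer <- function(img, transfer) {
  Re(ifft2c(fft2c(img) * transfer))
}

# Gaussian low-pass transfer function on a frequency grid (sigma in nm,
# real-space); its transfer function is exp(-2 pi^2 sigma_um^2 k^2)
gaussian_transfer <- function(grid, sigma_nm) {
  s <- sigma_nm * 1e-3
  exp(-2 * pi^2 * s^2 * grid$k^2)
}

#' Simulate a raw nine-frame SIM acquisition
#'
#' Realizes the SIM image-formation model: the sample density is multiplied
#' in real space by the cosine pattern `I0 (1 + m cos(2 pi p_d . r + phi_j))`
#' and blurred by the system OTF — spectrally identical to mixing the sample
#' spectrum with its two copies shifted by `±p_d` weighted `(m/2) e^{∓i phi}`.
#' An optional phase-independent defocus background (wide-blurred out-of-plane
#' sample, weight `beta`) is added identically to all frames, then optional
#' Gaussian noise; negatives are clipped to 0 after noise.
#'
#' @param sample A [make_phantom()] result (in-focus fluorophore density).
#' @param illum An [illumination_params()] with `|p_d| <= kem`.
#' @param otf An [make_otf()] model on the sample grid.
#' @param optical The [optical_params()] of the acquisition.
#' @param orientations Orientation angles (degrees) recorded in the stack
#'   metadata; defaults to the angles of `illum$wave_vectors`.
#' @param defocus Optional [defocus_config()].
#' @param noise Optional [noise_config()].
#' @return A [sim_stack()]; the defocus field actually added (matrix) is
#'   attached as attribute `"defocus_field"` for oracle checks.
#' @export
simulate_raw_stack <- function(sample, illum, otf, optical,
                               orientations = NULL, defocus = NULL,
                               noise = NULL) {
  stopifnot(inherits(sample, "sample_image"),
            inherits(illum, "illumination_params"),
            inherits(otf, "otf_model"),
            inherits(optical, "optical_params"))
  shape <- dim(sample$density)
  if (!all(shape == optical$image_shape))
    stop("sample shape does not match optical$image_shape", call. = FALSE)
  pmag <- sqrt(rowSums(illum$wave_vectors^2))
  if (any(pmag > otf$cutoff * (1 + 1e-12)))
    stop("illumination wave vector exceeds the OTF cutoff kem", call. = FALSE)
  if (is.null(orientations))
    orientations <- atan2(illum$wave_vectors[, 2],
                          illum$wave_vectors[, 1]) * 180 / pi

  px_um <- sample$pixel_size * 1e-3
  x_um <- matrix((seq_len(shape[2]) - 1) * px_um, shape[1], shape[2],
                 byrow = TRUE)
  y_um <- matrix((seq_len(shape[1]) - 1) * px_um, shape[1], shape[2])

  bg <- NULL
  if (!is.null(defocus) && defocus$beta > 0) {
    stopifnot(inherits(defocus, "defocus_config"))
    grid <- otf$grid
    bg <- defocus$beta *
      apply_transfer(defocus$background$density,
                     gaussian_transfer(grid, defocus$blur_sigma))
    bg <- pmax(bg, 0)
  }

  frames <- array(0, c(shape, 9L))
  for (d in 1:3) {
    p <- illum$wave_vectors[d, ]
    for (j in 1:3) {
      pattern <- illum$intensity *
        (1 + illum$modulation *
           cos(2 * pi * (p[1] * x_um + p[2] * y_um) + illum$phases[j]))
      fr <- apply_transfer(sample$density * pattern, otf$values)
      if (!is.null(bg)) fr <- fr + bg
      frames[, , (d - 1) * 3 + j] <- fr
    }
  }
  # band-limited real output: tiny negative FFT residue is numerical
  frames[frames < 0 & frames > -1e-9] <- 0
  frames <- pmax(frames, 0)

  if (!is.null(noise) && noise$variance > 0) {
    stopifnot(inherits(noise, "noise_config"))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(noise$seed)
    frames <- frames + array(
      stats::rnorm(length(frames), noise$mean, sqrt(noise$variance)),
      dim(frames))
    frames <- pmax(frames, 0)
  }

  out <- sim_stack(frames, orientations, illum$phases, optical)
  attr(out, "defocus_field") <- bg
  out
}

#' Widefield image of a raw stack
#'
#' Per-pixel mean of all nine frames: with nominal 2 pi / 3 phase stepping
#' the cosine modulation cancels, leaving the sample blurred by the PSF
#' (plus any background).
#'
#' @param stack A [sim_stack()].
#' @return Numeric matrix at the raw sampling.
#' @export
widefield <- function(stack) {
  stopifnot(inherits(stack, "sim_stack"))
  apply(stack$frames, c(1, 2), mean)
}
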