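#' Optical system parameters
#'
#' Bundle of the physical acquisition parameters shared by the simulator and
#' the reconstruction: emission wavelength, numerical aperture, sample-plane
#' pixel size and image shape. The incoherent lateral cutoff frequency of the
#' system is derived as `kem = 2 NA / lambda_em`.
#'
#' @param emission_wavelength Emission wavelength in nm (> 0).
#' @param numerical_aperture Objective numerical aperture (0 < NA <= 1.7).
#' @param pixel_size Sample-plane pixel size in nm (> 0).
#' @param image_shape Integer vector `c(rows, cols)` of the raw frame shape.
#'
#' @return An object of class `optical_params` with fields
#'   `emission_wavelength`, `numerical_aperture`, `pixel_size`, `image_shape`
#'   and the derived `cutoff` (kem, cycles/um).
#' @export
optical_params <- function(emission_wavelength, numerical_aperture,
                           pixel_size, image_shape) {
  stopifnot(length(image_shape) == 2)
  image_shape <- as.integer(image_shape)
  if (!is.finite(emission_wavelength) || emission_wavelength <= 0)
    stop("emission_wavelength must be a positive length in nm", call. = FALSE)
  if (!is.finite(numerical_aperture) || numerical_aperture <= 0 ||
      numerical_aperture > 1.7)
    stop("numerical_aperture must lie in (0, 1.7]", call. = FALSE)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive length in nm", call. = FALSE)
  if (any(image_shape < 8))
    stop("image_shape must be at least 8 x 8", call. = FALSE)
  structure(
    list(
      emission_wavelength = emission_wavelength,
      numerical_aperture  = numerical_aperture,
      pixel_size          = pixel_size,
      image_shape         = image_shape,
      # cycles/um: 2 NA / lambda with lambda converted nm -> um
      cutoff = 2 * numerical_aperture / (emission_wavelength * 1e-3)
    ),
    class = "optical_params"
  )
}

#' @export
print.optical_params <- function(x, ...) {
  cat(sprintf(
    "<optical_params> lambda_em = %g nm, NA = %g, pixel = %g nm, shape = %d x %d, kem = %.4g cycles/um\n",
    x$emission_wavelength, x$numerical_aperture, x$pixel_size,
    x$image_shape[1], x$image_shape[2], x$cutoff))
  invisible(x)
}

# ---- centered-spectrum bookkeeping -----------------------------------------
#
# Convention used throughout: arrays are row = y, col = x; all spectra are
# stored DC-centered with the DC element of an even N x M grid at 1-based
# index (N/2 + 1, M/2 + 1). Real-space pixel (i, j) sits at
# x = (j - 1) * dx, y = (i - 1) * dy.

#' Quadrant swap placing DC at the center element
#' @param x Matrix (spectrum straight out of [stats::fft()]).
#' @return Matrix with the zero-frequency element at `(nrow/2 + 1, ncol/2 + 1)`.
#' @export
fftshift <- function(x) {
  n <- dim(x)
  x[c((floor(n[1] / 2) + 1):n[1], seq_len(floor(n[1] / 2))),
    c((floor(n[2] / 2) + 1):n[2], seq_len(floor(n[2] / 2)))]
}

#' Inverse of [fftshift()]
#' @param x Matrix with DC at the center element.
#' @return Matrix with DC back at element (1, 1).
#' @export
ifftshift <- function(x) {
  n <- dim(x)
  x[c((n[1] - floor(n[1] / 2) + 1):n[1], seq_len(n[1] - floor(n[1] / 2))),
    c((n[2] - floor(n[2] / 2) + 1):n[2], seq_len(n[2] - floor(n[2] / 2)))]
}

# 2-D DFT of a real-space image, returned DC-centered.
fft2c <- function(x) fftshift(stats::fft(x))

# Inverse 2-D DFT of a DC-centered spectrum, back to real space (complex).
ifft2c <- function(X) stats::fft(ifftshift(X), inverse = TRUE) / length(X)

#' Centered spatial-frequency grid
#'
#' Builds the DC-centered frequency coordinates of an image grid: per-axis
#' spacing `1/(N * pixel_size)` and the radial magnitude `|k|` at every
#' element, in cycles/um. The DC element of an even grid sits at 1-based
#' index `(rows/2 + 1, cols/2 + 1)` and has magnitude exactly 0.
#'
#' @param shape Integer vector `c(rows, cols)`, both >= 8.
#' @param pixel_size Sample-plane pixel size in nm (> 0).
#'
#' @return An object of class `frequency_grid` with fields `shape`,
#'   `pixel_size` (nm), `spacing` (cycles/um per frequency pixel, per axis),
#'   `kx`, `ky` (coordinate matrices, cycles/um) and `k` (radial magnitude).
#' @export
make_frequency_grid <- function(shape, pixel_size) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(!is.finite(shape)) || any(shape < 8))
    stop("shape must be two integers >= 8", call. = FALSE)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive length in nm", call. = FALSE)
  px_um <- pixel_size * 1e-3
  spacing <- 1 / (shape * px_um)                     # cycles/um per axis
  fy <- (seq_len(shape[1]) - 1 - floor(shape[1] / 2)) * spacing[1]
  fx <- (seq_len(shape[2]) - 1 - floor(shape[2] / 2)) * spacing[2]
  ky <- matrix(fy, shape[1], shape[2])
  kx <- matrix(fx, shape[1], shape[2], byrow = TRUE)
  structure(
    list(shape = shape, pixel_size = pixel_size, spacing = spacing,
         kx = kx, ky = ky, k = sqrt(kx^2 + ky^2)),
    class = "frequency_grid"
  )
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> %d x %d, spacing %.4g x %.4g cycles/um\n",
              x$shape[1], x$shape[2], x$spacing[1], x$spacing[2]))
  invisible(x)
}

#' Raw SIM acquisition stack
#'
#' Container for the nine-frame raw acquisition: three illumination pattern
#' orientations times three pattern phases, orientation-major / phase-minor.
#'
#' @param frames Numeric array `rows x cols x 9` of non-negative intensities;
#'   frame `(d - 1) * 3 + j` holds orientation `d`, phase `j`.
#' @param orientations Three pattern orientation angles in degrees, pairwise
#'   distinct.
#' @param phases Three nominal pattern phases in radians (the acquisition
#'   protocol steps by 2 pi / 3).
#' @param optical An [optical_params()] object matching the frame shape.
#'
#' @return An object of class `sim_stack`.
#' @export
sim_stack <- function(frames, orientations, phases, optical) {
  if (!is.array(frames) || length(dim(frames)) != 3 || dim(frames)[3] != 9)
    stop("frames must be a rows x cols x 9 array", call. = FALSE)
  if (any(!is.finite(frames)))
    stop("frames must be finite", call. = FALSE)
  if (any(frames < 0))
    stop("frame intensities must be non-negative", call. = FALSE)
  if (length(orientations) != 3 || anyDuplicated(orientations))
    stop("orientations must be 3 pairwise-distinct angles (degrees)",
         call. = FALSE)
  if (length(phases) != 3)
    stop("phases must be 3 values (radians)", call. = FALSE)
  if (!inherits(optical, "optical_params"))
    stop("optical must be an optical_params object", call. = FALSE)
  if (!all(dim(frames)[1:2] == optical$image_shape))
    stop("frame shape does not match optical$image_shape", call. = FALSE)
  structure(
    list(frames = frames, orientations = as.numeric(orientations),
         phases = as.numeric(phases), optical = optical),
    class = "sim_stack"
  )
}

#' @export
print.sim_stack <- function(x, ...) {
  cat(sprintf(
    "<sim_stack> 9 frames of %d x %d; orientations %s deg; phases %s rad\n",
    dim(x$frames)[1], dim(x$frames)[2],
    paste(signif(x$orientations, 4), collapse = "/"),
    paste(signif(x$phases, 4), collapse = "/")))
  invisible(x)
}

# frames of one orientation d as a rows x cols x 3 slab
stack_orientation <- function(stack, d) {
  stopifnot(d %in% 1:3)
  stack$frames[, , (d - 1) * 3 + 1:3, drop = FALSE]
}

#' Super-resolved reconstruction image
#'
#' Real-valued reconstruction on the 2x upsampled grid, with the method tag
#' and the parameters that produced it attached as provenance.
#'
#' @param pixels 2-D real matrix of reconstructed intensities.
#' @param pixel_size Pixel size in nm (half the raw pixel size).
#' @param method `"wiener"` or `"nsim"`.
#' @param params Named list of reconstruction parameters (provenance record).
#'
#' @return An object of class `sr_image`.
#' @export
sr_image <- function(pixels, pixel_size, method, params = list()) {
  if (!is.matrix(pixels) || any(!is.finite(pixels)))
    stop("pixels must be a finite real matrix", call. = FALSE)
  method <- match.arg(method, c("wiener", "nsim"))
  structure(
    list(pixels = pixels, pixel_size = pixel_size, method = method,
         params = params),
    class = "sr_image"
  )
}

#' @export
print.sr_image <- function(x, ...) {
  cat(sprintf("<sr_image> %d x %d at %g nm/px, method \"%s\"\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$method))
  invisible(x)
}

# ---- TIFF stack I/O ---------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".meta")

#' Write a raw SIM stack as a multi-page TIFF plus metadata sidecar
#'
#' Frames are written as nine 32-bit TIFF pages in orientation-major,
#' phase-minor order (the writer stores 32-bit unsigned samples on \[0, 1\];
#' a power-of-two intensity scale recorded in the sidecar restores the
#' original range on read, so the round trip is exact to one 32-bit
#' quantization step, about 2e-10 of full scale). Acquisition metadata
#' travels in a flat key-value text sidecar (`<path>.meta`) because
#' multi-page TIFF tag dialects are unreliable across writers.
#'
#' @param stack A [sim_stack()].
#' @param path Output TIFF path; the sidecar is written to `<path>.meta`.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "sim_stack"))
  # TIFF storage is confined to [0, 1]; a power-of-two scale keeps the
  # round trip exact in binary floating point.
  mx <- max(stack$frames)
  scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
  pages <- lapply(seq_len(9), function(i) stack$frames[, , i] / scale)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                            reduce = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write TIFF to '", path, "'", call. = FALSE)
  opt <- stack$optical
  lines <- c(
    sprintf("intensity_scale: %.17g", scale),
    sprintf("pixel_size_nm: %.17g", opt$pixel_size),
    sprintf("emission_wavelength_nm: %.17g", opt$emission_wavelength),
    sprintf("numerical_aperture: %.17g", opt$numerical_aperture),
    sprintf("orientations_deg: [%s]",
            paste(sprintf("%.17g", stack$orientations), collapse = ", ")),
    sprintf("phases_rad: [%s]",
            paste(sprintf("%.17g", stack$phases), collapse = ", "))
  )
  writeLines(lines, sidecar_path(path))
  invisible(path)
}

#' Read a raw SIM stack from a multi-page TIFF
#'
#' Expects exactly nine pages of one shape. 16-bit unsigned data are promoted
#' to float in \[0, 1\] (the reader divides by the sample-format maximum);
#' 32-bit float data are taken as stored. Metadata come from the `<path>.meta`
#' sidecar unless supplied in `config`, which takes precedence key by key.
#'
#' @param path TIFF path written by [write_stack_tiff()] or an equivalent
#'   9-page acquisition.
#' @param config Optional named list overriding sidecar keys:
#'   `pixel_size_nm`, `emission_wavelength_nm`, `numerical_aperture`,
#'   `orientations_deg`, `phases_rad`.
#' @return A [sim_stack()].
#' @export
read_stack_tiff <- function(path, config = NULL) {
  if (!file.exists(path))
    stop("file not found: '", path, "'", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 9)
    stop("expected a 9-page stack, found ", length(pages), " page(s)",
         call. = FALSE)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("stack pages have differing shapes", call. = FALSE)
  meta <- list()
  if (file.exists(sidecar_path(path)))
    meta <- yaml::read_yaml(sidecar_path(path))
  for (key in names(config)) meta[[key]] <- config[[key]]
  required <- c("pixel_size_nm", "emission_wavelength_nm",
                "numerical_aperture", "orientations_deg", "phases_rad")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("missing acquisition metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  frames <- array(0, c(shapes[1, 1], shapes[2, 1], 9))
  for (i in seq_len(9)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse grayscale channels
    frames[, , i] <- p * scale
  }
  opt <- optical_params(meta$emission_wavelength_nm, meta$numerical_aperture,
                        meta$pixel_size_nm, shapes[, 1])
  sim_stack(frames, unlist(meta$orientations_deg), unlist(meta$phases_rad),
            opt)
}

#' Write a single image (ground truth or reconstruction) as 32-bit float TIFF
#'
#' Values outside \[0, 1\] (negative notch sidelobes, unnormalized intensities)
#' are mapped affinely onto \[0, 1\] before writing, since the TIFF writer
#' stores that range only; in-range images are written as-is.
#'
#' @param image Numeric matrix, or an [sr_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  if (inherits(image, "sr_image")) image <- image$pixels
  stopifnot(is.matrix(image))
  lo <- min(image); hi <- max(image)
  if (lo < 0 || hi > 1)
    image <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  tiff::writeTIFF(image, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
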