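#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` between a reference and a test image. Identical
#' images have zero MSE and return `Inf` (a defined sentinel, not an error).
#'
#' @param reference,test Numeric matrices of one shape.
#' @param peak Peak intensity of the dynamic range; defaults to
#'   `max(reference)` (images are compared on a normalized scale).
#' @return PSNR in decibels (`Inf` for identical images).
#' @export
psnr <- function(reference, test, peak = NULL) {
  if (!all(dim(reference) == dim(test)))
    stop("reference and test must share one shape", call. = FALSE)
  if (is.null(peak)) peak <- max(reference)
  if (!is.finite(peak) || peak <= 0)
    stop("peak must be positive", call. = FALSE)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# separable convolution with a 1-D kernel (symmetric edge padding)
conv_sep <- function(img, kernel) {
  k <- length(kernel)
  half <- (k - 1) / 2
  pad_idx <- function(n) pmin(pmax(seq(1 - half, n + half), 1), n)
  # rows direction
  tmp <- img[pad_idx(nrow(img)), , drop = FALSE]
  tmp <- apply(tmp, 2, function(col) stats::filter(col, kernel, sides = 2))
  tmp <- tmp[(half + 1):(half + nrow(img)), , drop = FALSE]
  # cols direction
  tmp2 <- tmp[, pad_idx(ncol(img)), drop = FALSE]
  tmp2 <- t(apply(tmp2, 1, function(row) stats::filter(row, kernel, sides = 2)))
  tmp2[, (half + 1):(half + ncol(img)), drop = FALSE]
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard 11-sample Gaussian window
#' (`sigma = 1.5`) and stabilizing constants `C1 = (K1 L)^2`,
#' `C2 = (K2 L)^2` from the dynamic range `L` (Wang et al. form). Local
#' means, variances and covariance are computed by separable Gaussian
#' filtering with symmetric edge padding.
#'
#' @param reference,test Numeric matrices of one shape.
#' @param dynamic_range Intensity range `L`; defaults to
#'   `max(reference) - min(reference)`.
#' @param K1,K2 Stabilizing constants (defaults 0.01 and 0.03).
#' @return Mean SSIM score in \[-1, 1\].
#' @export
ssim <- function(reference, test, dynamic_range = NULL,
                 K1 = 0.01, K2 = 0.03) {
  if (!all(dim(reference) == dim(test)))
    stop("reference and test must share one shape", call. = FALSE)
  if (is.null(dynamic_range))
    dynamic_range <- max(reference) - min(reference)
  if (dynamic_range <= 0) dynamic_range <- 1
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  g <- exp(-((-5:5)^2) / (2 * 1.5^2))
  g <- g / sum(g)
  mu_x <- conv_sep(reference, g)
  mu_y <- conv_sep(test, g)
  sxx <- conv_sep(reference^2, g) - mu_x^2
  syy <- conv_sep(test^2, g) - mu_y^2
  sxy <- conv_sep(reference * test, g) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  mean(s)
}

#' Intensity profile along a line segment
#'
#' Bilinear interpolation of the image at `n_samples` evenly spaced points
#' between two endpoints, with positions reported in nm.
#'
#' @param image Numeric matrix, or an [sr_image()].
#' @param p0,p1 Endpoints `c(row, col)` in 1-based pixel coordinates, inside
#'   the image.
#' @param n_samples Number of sample points (>= 2).
#' @param pixel_size Pixel size in nm (taken from an `sr_image` input when
#'   omitted; default 1).
#' @return An object of class `line_profile`: a tibble with strictly
#'   increasing `position_nm` and `intensity`.
#' @export
line_profile <- function(image, p0, p1, n_samples = 200, pixel_size = NULL) {
  if (inherits(image, "sr_image")) {
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
    image <- image$pixels
  }
  if (is.null(pixel_size)) pixel_size <- 1
  stopifnot(is.matrix(image), length(p0) == 2, length(p1) == 2,
            n_samples >= 2)
  inside <- function(p) p[1] >= 1 && p[1] <= nrow(image) &&
    p[2] >= 1 && p[2] <= ncol(image)
  if (!inside(p0) || !inside(p1))
    stop("profile endpoints must lie inside the image", call. = FALSE)
  t <- seq(0, 1, length.out = n_samples)
  rr <- p0[1] + t * (p1[1] - p0[1])
  cc <- p0[2] + t * (p1[2] - p0[2])
  vals <- bilinear_at(image, rr, cc)
  len_nm <- sqrt(sum((p1 - p0)^2)) * pixel_size
  out <- tibble::tibble(position_nm = t * len_nm, intensity = vals)
  class(out) <- c("line_profile", class(out))
  out
}

# vectorized bilinear interpolation at fractional (row, col) positions
bilinear_at <- function(image, rr, cc) {
  r0 <- pmin(floor(rr), nrow(image) - 1)
  c0 <- pmin(floor(cc), ncol(image) - 1)
  fr <- rr - r0
  fc <- cc - c0
  idx <- function(r, c) image[cbind(r, c)]
  idx(r0, c0) * (1 - fr) * (1 - fc) + idx(r0 + 1, c0) * fr * (1 - fc) +
    idx(r0, c0 + 1) * (1 - fr) * fc + idx(r0 + 1, c0 + 1) * fr * fc
}

#' Full width at half maximum of a single-peak profile
#'
#' Least-squares Gaussian fit (amplitude, center, width, baseline) to a line
#' profile; `FWHM = 2 sqrt(2 ln 2) * width ~= 2.3548 width`. The result is
#' invariant under intensity rescaling and baseline shifts of the profile.
#'
#' @param profile A [line_profile()], or any data frame with `position_nm`
#'   and `intensity` columns.
#' @return An object of class `fwhm_result`: `center_nm`, `width_nm` (the
#'   Gaussian sigma), `fwhm_nm`, `amplitude`, `baseline` and the root mean
#'   squared fit `residual`.
#' @export
fwhm <- function(profile) {
  stopifnot(all(c("position_nm", "intensity") %in% names(profile)))
  x <- profile$position_nm
  y <- profile$intensity
  if (length(x) < 5) stop("profile too short for a peak fit", call. = FALSE)
  span <- max(y) - min(y)
  if (span <= 0 || span < 1e-12 * max(abs(y), 1))
    stop("estimation failure: profile has no peak", call. = FALSE)
  i0 <- which.max(y)
  base0 <- min(y)
  amp0 <- y[i0] - base0
  # moment-based width start: second moment of the baseline-subtracted peak
  w <- pmax(y - base0, 0)
  s0 <- sqrt(sum(w * (x - x[i0])^2) / sum(w))
  s0 <- max(s0, diff(range(x)) / length(x))
  fit <- try(minpack.lm::nlsLM(
    y ~ b + a * exp(-(x - mu)^2 / (2 * s^2)),
    start = list(a = amp0, mu = x[i0], s = s0, b = base0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("estimation failure: Gaussian peak fit did not converge",
         call. = FALSE)
  cf <- stats::coef(fit)
  if (!is.finite(cf[["s"]]) || abs(cf[["s"]]) <= 0 || cf[["a"]] <= 0)
    stop("estimation failure: no positive peak found", call. = FALSE)
  structure(
    list(center_nm = cf[["mu"]], width_nm = abs(cf[["s"]]),
         fwhm_nm = 2 * sqrt(2 * log(2)) * abs(cf[["s"]]),
         amplitude = cf[["a"]], baseline = cf[["b"]],
         residual = sqrt(mean(stats::resid(fit)^2))),
    class = "fwhm_result"
  )
}

#' @export
print.fwhm_result <- function(x, ...) {
  cat(sprintf("<fwhm_result> FWHM %.4g nm (center %.4g nm, rms residual %.3g)\n",
              x$fwhm_nm, x$center_nm, x$residual))
  invisible(x)
}

#' Descriptive statistics over a background region
#'
#' Mean, population standard deviation (divide by N) and range of the pixels
#' selected by a logical mask or an index set; order-independent.
#'
#' @param image Numeric matrix, or an [sr_image()].
#' @param region Logical mask of the image shape, or an integer index vector.
#' @return A tibble with `mean`, `sd`, `min`, `max` and `n`.
#' @export
background_stats <- function(image, region) {
  if (inherits(image, "sr_image")) image <- image$pixels
  vals <- if (is.logical(region)) {
    if (!all(dim(region) == dim(image)))
      stop("mask shape must match the image", call. = FALSE)
    image[region]
  } else image[region]
  if (length(vals) == 0)
    stop("background region is empty", call. = FALSE)
  n <- length(vals)
  tibble::tibble(mean = mean(vals),
                 sd = sqrt(sum((vals - mean(vals))^2) / n),
                 min = min(vals), max = max(vals), n = n)
}
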