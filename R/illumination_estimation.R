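# Illumination parameter estimation: cross-correlation for the pattern wave
# vector, phase-of-peak for the per-frame phases, least-squares band ratio
# for the modulation depth. All three accept simulated or measured stacks;
# the reconstruction accepts externally supplied parameters too, so the
# estimator is swappable.

# direct (non-FFT) DFT of q evaluated on an arbitrary fine frequency grid;
# separable in x and y, so two small matrix products
local_dft <- function(q, fx, fy, pixel_um) {
  x_um <- (seq_len(ncol(q)) - 1) * pixel_um
  y_um <- (seq_len(nrow(q)) - 1) * pixel_um
  Ey <- exp(-2i * pi * outer(fy, y_um))     # |fy| x rows
  Ex <- exp(-2i * pi * outer(x_um, fx))     # cols x |fx|
  Ey %*% q %*% Ex                           # |fy| x |fx|
}

#' Estimate the illumination wave vector of one orientation
#'
#' Separates the three phase frames with the nominal protocol phases
#' (0, 2pi/3, 4pi/3) at unit modulation, forms the normalized cross-power
#' between the order-0 and order-(+1) bands in real space, and locates the
#' peak of its spectrum: for a fringe at wave vector `p` the order-(+1) band
#' is the order-0 band modulated by `exp(-2 pi i p . r)`, so the cross-power
#' spectrum peaks at `-p`. The integer-pixel peak is refined by local DFT
#' upsampling (two zoom passes, net factor 400). The representative in the
#' upper half-plane (`py > 0`, or `py == 0` and `px > 0`) is returned, since
#' a cosine fringe at `p` and `-p` is the same fringe.
#'
#' @param frames_d `rows x cols x 3` array: the three phase frames of one
#'   orientation.
#' @param otf The [make_otf()] model (supplies the grid and cutoff).
#' @param min_peak_ratio Estimation fails when the correlation peak is below
#'   this multiple of the median cross-power magnitude (no fringe contrast,
#'   e.g. `m = 0`).
#' @param highpass_sigma Width (frequency pixels) of the Gaussian high-pass
#'   applied to each band before correlating. The bands' own low-frequency
#'   skirts (the sample spectrum around DC, and around `-p` in the shifted
#'   band) otherwise beat against each other and can out-vote the fringe
#'   peak on structured samples.
#' @return List with `wave_vector` (cycles/um), `wave_vector_px` (in
#'   frequency pixels), and `score` (peak-to-median ratio).
#' @export
estimate_wavevector <- function(frames_d, otf, min_peak_ratio = 8,
                                highpass_sigma = 6) {
  stopifnot(inherits(otf, "otf_model"), length(dim(frames_d)) == 3,
            dim(frames_d)[3] == 3)
  grid <- otf$grid
  spectra <- lapply(1:3, function(j) fft2c(frames_d[, , j]))
  mix <- build_separation_matrix(2 * pi / 3 * (0:2), m = 1)
  bands <- separate_bands(spectra, mix)
  r_px <- sqrt((grid$kx / grid$spacing[2])^2 + (grid$ky / grid$spacing[1])^2)
  # absolute fringe-content floor: with m = 0 the order-(+/-)1 band is zero
  # up to numerical residue, and no peak statistic of pure residue is usable
  if (sum(Mod(bands$Sp)^2) < 1e-16 * sum(Mod(bands$S0)^2))
    stop("estimation failure: no fringe content in the order-1 band",
         call. = FALSE)
  W0 <- 1 - exp(-r_px^2 / (2 * highpass_sigma^2))
  q <- ifft2c(bands$Sp * W0) * Conj(ifft2c(bands$S0 * W0))
  Q <- Mod(fft2c(q))
  # exclude a DC disc: residual unmodulated power must not win the peak
  Qm <- Q
  Qm[r_px < 3] <- 0
  Qm[grid$k > otf$cutoff] <- 0
  peak <- which(Qm == max(Qm), arr.ind = TRUE)[1, ]
  score <- max(Qm) / (stats::median(Q) + .Machine$double.xmin)
  if (!is.finite(score) || score < min_peak_ratio)
    stop("estimation failure: no illumination correlation peak above the ",
         "noise floor", call. = FALSE)
  ky0 <- grid$ky[peak[1], 1]
  kx0 <- grid$kx[1, peak[2]]
  px_um <- grid$pixel_size * 1e-3
  step <- grid$spacing
  # Refinement with common filtering: weighting the order-0 band by
  # H(k - p) W(k) and the order-(+1) band by H(k + p) W(k + p) makes the two
  # bands equal up to the exact phase ramp exp(-2 pi i p . r) (the shifted
  # copy of either weight lands on the other), so the cross-power peak is
  # unbiased; two outer iterations re-center the filters at the refined p.
  for (iter in 1:2) {
    p_cur <- -c(kx0, ky0)
    rp1 <- sqrt(((grid$kx + p_cur[1]) / grid$spacing[2])^2 +
                  ((grid$ky + p_cur[2]) / grid$spacing[1])^2)
    W1 <- 1 - exp(-rp1^2 / (2 * highpass_sigma^2))
    B0 <- bands$S0 * shifted_otf(grid, otf$cutoff, p_cur) * W0
    B1 <- bands$Sp * shifted_otf(grid, otf$cutoff, -p_cur) * W1
    q <- ifft2c(B1) * Conj(ifft2c(B0))
    # two local DFT zooms around the current peak: 0.05 px then 0.0025 px
    for (span in c(1, 0.05)) {
      fx <- kx0 + seq(-span, span, length.out = 41) * step[2]
      fy <- ky0 + seq(-span, span, length.out = 41) * step[1]
      Qf <- Mod(local_dft(q, fx, fy, px_um))
      pk <- which(Qf == max(Qf), arr.ind = TRUE)[1, ]
      ky0 <- fy[pk[1]]; kx0 <- fx[pk[2]]
    }
  }
  p <- -c(kx0, ky0)                              # peak sits at -p
  if (p[2] < 0 || (p[2] == 0 && p[1] < 0)) p <- -p
  list(wave_vector = p, wave_vector_px = p / rev(step), score = score)
}

#' Estimate the three pattern phases of one orientation (phase of peak)
#'
#' Evaluates each raw frame's spectrum at the (sub-pixel) illumination
#' frequency by direct DFT and takes its argument: at `k = p` the dominant
#' term of the frame spectrum is `(m/2) e^{i phi} C(0) H(p)` with `C(0)`
#' real positive, so the argument is the pattern phase. The phase-averaged
#' frame of the orientation is subtracted first: under the nominal 2 pi / 3
#' stepping the modulated terms cancel in the average, so the subtraction
#' removes the unmodulated sample spectrum `C(p) H(p)` that otherwise biases
#' the peak phase on structured samples.
#'
#' @param frames_d `rows x cols x 3` array of one orientation's phase frames.
#' @param p_hat Wave-vector estimate `(px, py)` in cycles/um (nonzero).
#' @param grid The raw [make_frequency_grid()].
#' @return Numeric vector of three phases in `[0, 2 pi)`.
#' @export
estimate_phases <- function(frames_d, p_hat, grid) {
  stopifnot(inherits(grid, "frequency_grid"), length(p_hat) == 2)
  if (sqrt(sum(p_hat^2)) < min(grid$spacing) / 10)
    stop("wave vector at DC: phases are undefined", call. = FALSE)
  px_um <- grid$pixel_size * 1e-3
  mean_frame <- (frames_d[, , 1] + frames_d[, , 2] + frames_d[, , 3]) / 3
  vapply(1:3, function(j) {
    v <- local_dft(frames_d[, , j] - mean_frame,
                   p_hat[1], p_hat[2], px_um)[1, 1]
    Arg(v) %% (2 * pi)
  }, numeric(1))
}

#' Estimate the modulation depth of one orientation
#'
#' Least-squares amplitude ratio of the order-(+/-)1 bands to the order-0
#' band over the OTF overlap region. `bands` must come from a
#' unit-modulation separation matrix (built with `m = 1`), so the
#' order-(+/-)1 bands carry the true `m` as their scale: after shifting the
#' order-(+1) band by `+p` both bands estimate `C(k)` times known transfer
#' factors, and the cross-weighted ratio
#' `|sum conj(x) y| / sum |x|^2` with `x = S0 H(k-p)`, `y = S(+1,shifted) H(k)`
#' is the modulation depth.
#'
#' @param bands A [separate_bands()] result built with `m = 1`.
#' @param p_hat Wave-vector estimate (cycles/um).
#' @param otf The [make_otf()] model.
#' @param support_floor OTF values below this are excluded from the overlap
#'   (division-dominated pixels). Default 0.05.
#' @return Modulation estimate `m_hat >= 0`.
#' @export
estimate_modulation <- function(bands, p_hat, otf, support_floor = 0.05) {
  stopifnot(inherits(bands, "spectral_bands"), inherits(otf, "otf_model"))
  grid <- otf$grid
  H0 <- otf$values
  ratio_for <- function(S, shift) {
    Ss <- shift_band(S, shift, grid)
    Hs <- shifted_otf(grid, otf$cutoff, shift)
    mask <- H0 > support_floor & Hs > support_floor
    if (!any(mask))
      stop("estimation failure: empty OTF overlap region", call. = FALSE)
    x <- (bands$S0 * Hs)[mask]
    y <- (Ss * H0)[mask]
    sx <- sum(Mod(x)^2)
    if (sx == 0) return(0)
    Mod(sum(Conj(x) * y)) / sx
  }
  (ratio_for(bands$Sp, p_hat) + ratio_for(bands$Sm, -p_hat)) / 2
}

#' Estimate all illumination parameters of a raw stack
#'
#' Runs [estimate_wavevector()], [estimate_phases()] and
#' [estimate_modulation()] per orientation. Estimates are invariant to a
#' global intensity rescaling of the stack.
#'
#' @param stack A [sim_stack()].
#' @param otf Optional [make_otf()] model; built from the stack's optical
#'   parameters when omitted.
#' @return An [illumination_params()] whose `phases` is the 3 x 3 estimated
#'   matrix and whose `modulation` is the mean of the per-orientation
#'   estimates, with the per-orientation table attached as attribute
#'   `"estimation"` (a tibble: orientation, p_x, p_y, phase_1..3, m, score).
#' @export
estimate_illumination <- function(stack, otf = NULL) {
  stopifnot(inherits(stack, "sim_stack"))
  opt <- stack$optical
  grid <- make_frequency_grid(opt$image_shape, opt$pixel_size)
  if (is.null(otf)) otf <- make_otf(opt, grid)
  rows <- lapply(1:3, function(d) {
    frames_d <- stack_orientation(stack, d)
    wv <- estimate_wavevector(frames_d, otf)
    ph <- estimate_phases(frames_d, wv$wave_vector, grid)
    spectra <- lapply(1:3, function(j) fft2c(frames_d[, , j]))
    bands <- separate_bands(spectra, build_separation_matrix(ph, m = 1))
    m_hat <- estimate_modulation(bands, wv$wave_vector, otf)
    list(p = wv$wave_vector, score = wv$score, phases = ph, m = m_hat)
  })
  est <- tibble::tibble(
    orientation = 1:3,
    p_x = vapply(rows, function(r) r$p[1], numeric(1)),
    p_y = vapply(rows, function(r) r$p[2], numeric(1)),
    phase_1 = vapply(rows, function(r) r$phases[1], numeric(1)),
    phase_2 = vapply(rows, function(r) r$phases[2], numeric(1)),
    phase_3 = vapply(rows, function(r) r$phases[3], numeric(1)),
    m = vapply(rows, function(r) r$m, numeric(1)),
    score = vapply(rows, function(r) r$score, numeric(1))
  )
  illum <- illumination_params(
    cbind(est$p_x, est$p_y),
    as.matrix(est[, c("phase_1", "phase_2", "phase_3")]),
    min(1, mean(est$m)),
    intensity = 1
  )
  attr(illum, "estimation") <- est
  illum
}
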