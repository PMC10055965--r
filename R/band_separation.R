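#' Phase mixing matrix for spectral band separation
#'
#' Each raw frame spectrum of one orientation is a phase-weighted mixture of
#' the order-0 and order-(+1)/(-1) sample bands:
#' row `j` is `[1, (m/2) e^{-i phi_j}, (m/2) e^{+i phi_j}]` acting on
#' `[C(k)H(k), C(k + p)H(k), C(k - p)H(k)]`. Distinct phases and `m > 0`
#' make the system invertible.
#'
#' @param phases Three pattern phases in radians, pairwise distinct mod 2 pi.
#' @param m Modulation depth (> 0).
#' @return An object of class `mixing_matrix`: the 3 x 3 complex `matrix`,
#'   its `inverse`, the recorded `condition` number, `phases` and `m`.
#' @export
build_separation_matrix <- function(phases, m) {
  stopifnot(length(phases) == 3)
  if (!is.finite(m) || m <= 0)
    stop("singular system: modulation depth m must be positive",
         call. = FALSE)
  ph <- phases %% (2 * pi)
  if (min(abs(outer(ph, ph, function(a, b) {
        d <- abs(a - b) %% (2 * pi); pmin(d, 2 * pi - d)
      })[lower.tri(diag(3))])) < 1e-9)
    stop("singular system: phases must be pairwise distinct mod 2 pi",
         call. = FALSE)
  M <- cbind(rep(1 + 0i, 3), (m / 2) * exp(-1i * phases),
             (m / 2) * exp(1i * phases))
  sv <- svd(M)$d
  cond <- sv[1] / sv[3]
  if (!is.finite(cond) || cond > 1e12)
    stop("singular separation system (condition number ", signif(cond, 3),
         ")", call. = FALSE)
  structure(list(matrix = M, inverse = solve(M), condition = cond,
                 phases = phases, m = m),
            class = "mixing_matrix")
}

#' @export
print.mixing_matrix <- function(x, ...) {
  cat(sprintf("<mixing_matrix> m = %g, condition number %.4g\n",
              x$m, x$condition))
  invisible(x)
}

#' Separate order-0 and order-(+/-)1 spectral bands of one orientation
#'
#' Applies the inverse of the 3 x 3 mixing matrix as three weighted sums of
#' the frame spectra (the matrix is pixel-independent), then divides by the
#' illumination intensity `I0`. The inverse's first row has weights summing
#' to 1 while the other rows' weights sum to 0, so any field added
#' identically to all three frames — the phase-independent defocus
#' background — lands entirely in the order-0 band.
#'
#' @param frame_spectra List of three DC-centered complex frame spectra of
#'   one orientation, in acquisition phase order.
#' @param mix A [build_separation_matrix()] result.
#' @param I0 Illumination intensity used in acquisition (default 1).
#' @return An object of class `spectral_bands`: complex matrices `S0`
#'   (`C(k)H(k)` estimate), `Sp` (`C(k + p)H(k)`), `Sm` (`C(k - p)H(k)`),
#'   all DC-centered and un-shifted, plus the `mix` record.
#' @export
separate_bands <- function(frame_spectra, mix, I0 = 1) {
  stopifnot(inherits(mix, "mixing_matrix"), is.list(frame_spectra),
            length(frame_spectra) == 3)
  dims <- lapply(frame_spectra, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("frame spectra have differing shapes", call. = FALSE)
  W <- mix$inverse
  comb <- function(w)
    (w[1] * frame_spectra[[1]] + w[2] * frame_spectra[[2]] +
       w[3] * frame_spectra[[3]]) / I0
  structure(list(S0 = comb(W[1, ]), Sp = comb(W[2, ]), Sm = comb(W[3, ]),
                 mix = mix),
            class = "spectral_bands")
}

#' Separate all three orientations of a raw stack
#'
#' Convenience wrapper: transforms each frame, builds one mixing matrix per
#' orientation from the given (or stack-recorded) phases, and separates.
#' Orientations are independent — separation of orientation `d` reads only
#' its own three frames.
#'
#' @param stack A [sim_stack()].
#' @param phases Either one vector of 3 phases shared by the orientations or
#'   a 3 x 3 matrix (row `d` = orientation `d`); default the stack's nominal
#'   phases.
#' @param m Modulation depth used in the mixing matrix.
#' @param I0 Illumination intensity.
#' @return List of three `spectral_bands`, one per orientation.
#' @export
separate_stack <- function(stack, phases = NULL, m = 0.9, I0 = 1) {
  stopifnot(inherits(stack, "sim_stack"))
  if (is.null(phases)) phases <- stack$phases
  if (is.matrix(phases)) stopifnot(all(dim(phases) == c(3, 3)))
  lapply(1:3, function(d) {
    ph <- if (is.matrix(phases)) phases[d, ] else phases
    spectra <- lapply(1:3, function(j)
      fft2c(stack$frames[, , (d - 1) * 3 + j]))
    separate_bands(spectra, build_separation_matrix(ph, m), I0)
  })
}

#' Re-mix separated bands back into frame spectra
#'
#' Inverse of [separate_bands()]; useful as a round-trip check.
#'
#' @param bands A `spectral_bands` object.
#' @param I0 Illumination intensity used at separation.
#' @return List of three complex frame spectra.
#' @export
remix_bands <- function(bands, I0 = 1) {
  stopifnot(inherits(bands, "spectral_bands"))
  M <- bands$mix$matrix
  lapply(1:3, function(j)
    I0 * (M[j, 1] * bands$S0 + M[j, 2] * bands$Sp + M[j, 3] * bands$Sm))
}
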