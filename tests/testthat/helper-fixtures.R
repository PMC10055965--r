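# Shared fixtures: a small standard optical configuration, stack builders,
# and independent oracles used across test files.

std_optics <- function(N = 128, pixel_size = 40, na = 1.5, lambda = 520) {
  optical_params(lambda, na, pixel_size, c(N, N))
}

std_setup <- function(N = 128, pixel_size = 40, na = 1.5, lambda = 520) {
  opt <- optical_params(lambda, na, pixel_size, c(N, N))
  grid <- make_frequency_grid(c(N, N), pixel_size)
  list(opt = opt, grid = grid, otf = make_otf(opt, grid))
}

# centered 2-D DFT pair, independent of the package internals
fft2c_ref <- function(x) {
  n <- dim(x)
  sw <- function(m) m[c((floor(n[1] / 2) + 1):n[1], 1:floor(n[1] / 2)),
                      c((floor(n[2] / 2) + 1):n[2], 1:floor(n[2] / 2))]
  sw(stats::fft(x))
}

# brute-force 8-connected component count by stack-based flood fill
flood_fill_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); n <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    n <- n + 1L
    stack <- s
    lab[s] <- n
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          i <- (cc - 1L) * nr + rr
          if (mask[i] && lab[i] == 0L) { lab[i] <- n; stack <- c(stack, i) }
        }
      }
    }
  }
  n
}

# render bead ground truth on the 2x grid as narrow Gaussians, and a
# pure-background mask of pixels far from every bead
bead_truth_2x <- function(beads, N, pixel_size, sigma_nm = 50,
                          clearance_px = 20) {
  M <- 2L * N
  yy <- matrix(seq_len(M), M, M)
  xx <- t(yy)
  truth <- matrix(0, M, M)
  dmin <- matrix(Inf, M, M)
  s_px <- sigma_nm / (pixel_size / 2)
  for (i in seq_len(nrow(beads$truth))) {
    r0 <- 2 * (beads$truth$row[i] - 1) + 1
    c0 <- 2 * (beads$truth$col[i] - 1) + 1
    d2 <- (yy - r0)^2 + (xx - c0)^2
    truth <- truth + exp(-d2 / (2 * s_px^2))
    dmin <- pmin(dmin, sqrt(d2))
  }
  list(truth = truth / max(truth), bg_mask = dmin > clearance_px)
}

# display normalization: clip at zero, scale to unit maximum
norm01 <- function(m) {
  m <- pmax(m, 0)
  m / max(m)
}

# angular difference modulo 2 pi
phase_diff <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# one seeded defocus-contaminated bead acquisition (shared by the
# defocus-suppression tests and properties)
defocus_bead_stack <- function(seed, N = 128, pixel_size = 40) {
  set <- std_setup(N, pixel_size)
  illum <- standard_illumination(set$opt, frac = 0.9, modulation = 0.9)
  beads <- make_phantom("beads", c(N, N), pixel_size,
                        params = list(n = 25, margin = 40), seed = seed)
  bg <- make_phantom("filaments", c(N, N), pixel_size, seed = seed + 500)
  stack <- simulate_raw_stack(
    beads, illum, set$otf, set$opt,
    defocus = defocus_config(bg, beta = 0.5, optical = set$opt),
    noise = noise_config(0.05, 1e-3, seed = seed))
  list(stack = stack, beads = beads, illum = illum, set = set)
}
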