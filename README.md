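# notchsim

Structured illumination microscopy (SIM) reconstruction with notch-filtered
suppression of defocus background.

## The problem

2-D SIM doubles the lateral resolution of a widefield fluorescence
microscope: the sample is illuminated with a cosine fringe pattern at three
orientations and three phases (nine raw frames), which Moiré-mixes sample
frequencies from outside the optical transfer function (OTF) support into
it. Solving the per-orientation 3×3 phase system separates the order-0 and
order-±1 spectral bands; shifting the ±1 bands back to ±**p**_d and
combining everything with a generalized Wiener filter yields a
super-resolved image with support extended to k_em + |**p**_d|.

Thick, live samples break this picture: fluorophores outside the focal plane
are excited by an essentially unmodulated field, so their signal D̃_bg(**k**)
is identical in all nine frames. Band separation routes it entirely into the
order-0 band, and the Wiener reconstruction turns it into the streak
artifacts familiar from live-cell SIM. This package implements the
reconstruction used by practitioners who counter that at the algorithm
level: the order-0 Wiener quotient is multiplied by a notch filter

    F(k) = 1 − exp(−r² / (2σ²)),      r = distance from DC (frequency pixels)

(the complement of a DC-centered Gaussian, 0 at DC, →1 at high frequency)
before summation with the order-±1 terms:

    g(r) = Re ifft[ ( Q₀(k)·F(k) + Q₁(k) ) · A(k) ]
    Q₀ = mean over d of  H₀* S₀d / (|H₀|² + α²)
    Q₁ = Σ_{n=±1,d} H*_{nd} S_{nd} / ( Σ_{n=±1,d} |H_{nd}|² + α² )

With the notch disabled (F ≡ 1) this is exactly the generalized Wiener
path — the two methods differ only by F, bit for bit. The defocus band is
suppressed at its source; the shifted bands re-supply the in-focus low
frequencies.

The package is a complete desk-scale validation environment for that
method: a physically motivated forward simulator (ideal circular-pupil OTF,
cosine illumination, φ-independent defocus background, Gaussian noise, all
with recorded ground truth), illumination-parameter estimation (wave vector,
phases, modulation depth), the two reconstruction paths, image-quality
metrics (PSNR, SSIM, line profiles, Gaussian-fit FWHM, background
statistics), and the organelle quantification used downstream of such
reconstructions (8-connected component counting over time, circular Hough
droplet detection with radius histograms).

## Worked example

Simulate a defocus-contaminated bead acquisition, reconstruct it both ways,
and compare background fluctuation and fidelity:

```r
library(notchsim)

opt  <- optical_params(emission_wavelength = 520, numerical_aperture = 1.5,
                       pixel_size = 40, image_shape = c(128, 128))
grid <- make_frequency_grid(c(128, 128), pixel_size = 40)
otf  <- make_otf(opt, grid)

beads <- make_phantom("beads", c(128, 128), 40,
                      params = list(n = 25, margin = 40), seed = 1)
oof   <- make_phantom("filaments", c(128, 128), 40, seed = 501)   # out of focus
illum <- standard_illumination(opt, frac = 0.9, modulation = 0.9)
stack <- simulate_raw_stack(beads, illum, otf, opt,
                            defocus = defocus_config(oof, beta = 0.5, optical = opt),
                            noise   = noise_config(0.05, 1e-3, seed = 1))
stack
#> <sim_stack> 9 frames of 128 x 128; orientations 0/60/120 deg; phases 0/2.094/4.189 rad

rec_w <- reconstruct_sim(stack, method = "wiener", illum = illum)
rec_n <- reconstruct_sim(stack, method = "nsim",   illum = illum)
rec_n
#> <sr_image> 256 x 256 at 20 nm/px, method "nsim"
```

Scoring both reconstructions against the bead ground truth (PSNR on
display-normalized images) and over a pure-background region (standard
deviation of the display-normalized intensity — the background fluctuation
measure):

```
  method  psnr_db      bg_sd
1 wiener 16.44906 0.06056625
2   nsim 25.72005 0.04308062
```

The notch path gains ~9 dB of PSNR and reduces the background fluctuation by
~30%: the defocus field survives the Wiener path as a structured pedestal
but is removed by the notch. Omit `illum =` to have the wave vectors, phases
and modulation estimated from the stack itself
(`estimate_illumination()`), and see `sigma_sweep()` for the notch-width
trade-off around the default σ = 2.

Resolution doubling is measured the same way beads are measured on a real
instrument: a Gaussian fit to a line profile through a reconstructed bead.
Under this geometry the widefield FWHM is ≈ 175 nm and the reconstructed
FWHM ≈ 99 nm (ratio ≈ 1.77 with |p| = 0.95·k_em; see the acceptance
script's `resolution_doubling_ratio`).

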