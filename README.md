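# psvrgrappa

Cartesian parallel-MRI reconstruction in R: the GRAPPA k-space
interpolation method with weights fitted either by ordinary least squares
or by a complex-valued **proximal support vector regression** (PSVR) with
kernel mapping — plus a synthetic multi-coil phantom generator, quality
metrics, and an experiment harness for window-sensitivity and
kernel-comparison studies.

## The problem and the method

Parallel imaging accelerates MRI by acquiring only every R-th
phase-encoding line of k-space from `L` coils, plus a small fully sampled
central block (ACS). GRAPPA estimates each missing sample of coil `l` as a
linear combination of acquired neighbours over all coils,

    s_l(k_x, k_y + mΔk_y) = Σ_j Σ_h Σ_t  w_{l,m}(j,h,t) · s_j(k_x + hΔk_x, k_y + tRΔk_y),

with weights `w` calibrated on the ACS from the linear system `y ≈ A w`.
The conventional fit is least squares, which minimizes only the empirical
calibration error and makes image quality sensitive to the interpolation
window size `M = L·n_pe_blocks·n_fe_cols`. Here the weights can instead be
fitted by PSVR, which also penalizes model complexity: per (coil, offset),

    min  ½(wᴴw + bᴴb) + (C/2) Σ_k (ξ_k² + ζ_k²)
    s.t. Re(y_k − wᴴφ(x_k) − b) = ξ_k,   Im(y_k − wᴴφ(x_k) − b) = ζ_k.

The equality constraints and squared slacks reduce the dual to a linear
system with kernel Gram matrices on the real and imaginary source parts,

    (Ω_r + C⁻¹I + 11ᵀ) α = Re(y),   (Ω_i + C⁻¹I + 11ᵀ) β = Im(y),

and predictions `f(s) = Σ α_k K(Re s, Re x_k) + i Σ β_k K(Im s, Im x_k) + b`
with `b = Σ(α_k + iβ_k)`. Supported kernels: linear, polynomial
`(x·y + θ)^d`, RBF `exp(−‖x−y‖²/γ²)`, and the wavelet kernel
`Π_i cos(1.75u_i)exp(−u_i²/2)`, `u = (x−y)/q`. Data-driven defaults:
`C = max(|ȳ+3σ|, |ȳ−3σ|)` from the calibration targets,
`γ = d_max/√(2ℓ)`, `q = d_max·log ℓ`.

Reconstruction quality is scored against the fully sampled sum-of-squares
reference with `NMSE = sqrt(Σ|I − I_ref|² / Σ|I_ref|²)` and
`PSNR = 10·log10(255²/NMSE)` (note: derived from the normalized root
error, as defined above, not from a mean-squared error).

## Worked example

```r
library(psvrgrappa)

sim <- simulate_phantom_kspace(n = 128, n_coils = 8, sigma = 0.01, seed = 1)
scheme <- sampling_scheme(R = 4, n_acs = 40)
win <- interp_window(n_pe_blocks = 2, n_fe_cols = 9)

reconstruct_report(sim$kspace, scheme, win, "grappa")
#> <recon_report> grappa | R = 4, ACS = 40, window 2x9 | NMSE = 0.1911 (19.11%), PSNR = 55.32 dB

reconstruct_report(sim$kspace, scheme, win, "psvr",
                   kernel = kernel_spec("wavelet"), l_max = 1024)
#> <recon_report> psvr | R = 4, ACS = 40, window 2x9 | NMSE = 0.2152 (21.52%), PSNR = 54.80 dB
```

The report holds the reconstructed and reference magnitude images and the
two metrics: NMSE is the normalized root error against the fully sampled
reference (0 = perfect, 1 = as wrong as an all-zero image), PSNR its
decibel transform. On this noisy synthetic phantom the wavelet-PSVR
reconstruction is markedly *less sensitive* to the window choice than the
least-squares baseline (its PSNR barely moves as the FE width sweeps
1..15), at a similar overall error level.

Sweep harness and plots:

```r
cfg <- experiment_config(R_values = 3, acs_values = 24, fe_sizes = 1:15,
                         seeds = 1:10, l_max = 1024)
tab <- run_window_sweep(cfg)
plot_window_sweep(tab, "sweep.png")
```

A thin command-line driver wrapping these functions lives at
`inst/cli/psvrgrappa.R` (verbs: `simulate`, `recon`, `sweep`, `kernels`).

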