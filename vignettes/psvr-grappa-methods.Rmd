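---
title: "GRAPPA and PSVR-GRAPPA reconstruction: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GRAPPA and PSVR-GRAPPA reconstruction: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psvrgrappa)
```

# The reconstruction problem

In Cartesian parallel MRI, `L` receive coils observe the same object through
different spatial sensitivity profiles. Acquisition time is cut by sampling
only every `R`-th phase-encoding (PE) line of k-space, plus a small block of
`n_acs` fully sampled central lines (the auto-calibration signal, ACS).
GRAPPA fills each missing sample of coil `l` at PE offset `m` from the
acquired grid with a linear combination of nearby acquired samples over all
coils:

$$ s_l(k_x,\; k_y + m\,\Delta k_y) \;=\; \sum_{j=1}^{L} \sum_{h=H_1}^{H_2}
   \sum_{t=N_1}^{N_2} w_{l,m}(j,h,t)\;
   s_j(k_x + h\,\Delta k_x,\; k_y + t R\,\Delta k_y), $$

where the interpolation window spans `n_pe_blocks` acquired PE neighbours
(`t`) and `n_fe_cols` frequency-encoding (FE) columns (`h`), so each source
vector has length `M = L · n_pe_blocks · n_fe_cols`. Collecting all valid
ACS placements gives the linear system `y ≈ A w` with one row per
calibration pair.

The conventional baseline fits `w` by least squares
(`grappa_calibrate()` / `grappa_reconstruct()`). Least squares minimizes
only the empirical calibration error; as the window grows, the weights gain
degrees of freedom and the fit generalizes poorly outside the ACS — the
under-/over-fitting trade-off that makes GRAPPA sensitive to the window
choice. This package's main method replaces the least-squares fit with a
complex-valued **proximal support vector regression** (PSVR), which
penalizes the weight norm alongside the squared residuals and admits kernel
mappings (`psvr_grappa_reconstruct()`).

# The complex PSVR model

PSVR solves, per (target coil, offset) pair,

$$ \min_{w,b}\ \tfrac12\,(w^H w + b^H b) + \tfrac{C}{2}
   \sum_{k=1}^{\ell} (\xi_k^2 + \zeta_k^2), \qquad
   \Re\big(y_k - w^H\phi(x_k) - b\big) = \xi_k,\quad
   \Im\big(y_k - w^H\phi(x_k) - b\big) = \zeta_k. $$

Because the constraints are equalities with squared slacks, the dual is a
linear system, not a quadratic program. The complex problem decouples into
two real regressions — real parts of the targets against real parts of the
sources, and likewise imaginary — giving

$$ (\Omega_r + C^{-1} I + \mathbf{1}\mathbf{1}^T)\,\alpha = \Re(y), \qquad
   (\Omega_i + C^{-1} I + \mathbf{1}\mathbf{1}^T)\,\beta = \Im(y), $$

with Gram matrices `Ω_r[k,l] = K(Re x_k, Re x_l)`,
`Ω_i[k,l] = K(Im x_k, Im x_l)`, bias `b = Σα + i Σβ`, and prediction
`f(s) = Σ_k α_k K(Re s, Re x_k) + i Σ_k β_k K(Im s, Im x_k) + b`.

**Sign convention.** Published derivations of this dual disagree internally
about the sign of the bias and of the rank-one `11ᵀ` term. We re-derived
the dual from the primal above; the convention used here (`+11ᵀ`, positive
prediction sums, `b = +Σ(α + iβ)`) is the one under which the dual agrees
with a direct primal ridge solve (`primal_fit()`, the explicit
feature-space oracle kept for testing) to machine precision, and under
which the KKT residual identity `f(x_k) = y_k − (α_k + iβ_k)/C` holds. The
test suite enforces this equivalence on randomized problems.

**A structural consequence of the decoupling.** The part-decoupled model
can only represent linear maps in which real outputs depend on real inputs
(and imaginary on imaginary). A general complex linear rule
`y = A w` with complex `w` mixes the parts and lies outside the model
class, for every kernel. The exact-recovery tests therefore construct
their ground-truth interpolation rule with real weights, which both the
least-squares and the PSVR model classes contain. On measured data, whose
true coil-to-coil relationships are complex, this misspecification is an
intrinsic property of the method as published, not of this implementation.

# Kernels and hyperparameters

`kernel_spec()` supports:

| family      | definition                                        | parameters |
|-------------|---------------------------------------------------|------------|
| linear      | `x·y`                                             | — |
| polynomial  | `(x·y + θ)^d`                                     | `θ = 1`, `d = 2` |
| rbf         | `exp(−‖x−y‖² / γ²)`                               | `γ` |
| wavelet     | `Π_i cos(1.75 u_i) exp(−u_i²/2)`, `u = (x−y)/q`  | `q` |

Scales left unset are derived from the training sources at fit time:
`γ = d_max / √(2ℓ)` and `q = d_max · log ℓ` (natural log; the base is not
dictated by the rule's provenance, so it is exposed through `wavelet_q()`),
where `d_max` is the maximum pairwise distance among training points.
Because the two real subproblems see different data, scales default to
per-part resolution (`scale_mode = "per-part"`), with a `"joint"` pooled
alternative. A degenerate training set (`d_max = 0`) falls back to unit
scale.

The penalty `C` defaults to the data-driven heuristic
`C = max(|ȳ + 3σ|, |ȳ − 3σ|)` with mean and population standard deviation
taken over the pooled real sample of all real and imaginary target parts —
the natural reading once the fit has decoupled into two real regressions
sharing one `C`. It is floored at `1e-12·(1 + max|y|)` so all-zero targets
remain solvable.

Two practical regimes are worth knowing about. With calibration sources
drawn from the ACS — which contains the dominant k-space center — `d_max`
is set by the largest-magnitude samples. The resulting RBF width
`γ = d_max/√(2ℓ)` is then much smaller than typical pairwise distances, so
the RBF Gram approaches the identity and predictions collapse toward the
bias. The wavelet scale `q = d_max·log ℓ` sits at the opposite extreme:
per-coordinate arguments are small, the Gram is close to constant, and the
regression behaves as a strong smoother whose predictions vary slowly with
the sources. Both follow directly from the published scale rules; the
kernel-comparison harness (`run_kernel_comparison()`) makes the resulting
quality differences measurable.

# Interpolation geometry

* Window bounds: for `n` PE blocks, `t` runs over
  `N₁ = −(⌈n/2⌉−1) … N₂ = ⌊n/2⌋` — the acquired neighbours bracket the
  target, extra block on the preceding side for odd counts. For width `w`
  along FE, `h` runs over `−⌊w/2⌋ … ⌈w/2⌉−1` (centered, extra column left
  for even widths).
* Source ordering is coil-major, then PE block, then FE column, identically
  in calibration and synthesis; an exact-weights round trip in the test
  suite pins this down.
* Calibration placements: targets are ACS rows congruent to the offset `m`
  modulo `R` (0-based), with every window source inside the fully sampled
  block — exactly the geometry synthesis later fills. Calibration uses only
  fully interior FE columns; synthesis zero-pads sources that fall outside
  the grid, the usual GRAPPA convention.
* Acquired lines — including the ACS — are preserved verbatim in the output
  k-space; only missing samples are synthesized.
* Sampling: 0-based PE line 0 is always acquired; the ACS block of `n_acs`
  lines is centered at line `⌊n_pe/2⌋`.

# Synthetic study conditions

No scanner data ship with the package; every experiment runs on a
synthetic acquisition with known ground truth
(`simulate_phantom_kspace()`):

* a 128×128 Shepp-Logan-style complex phantom (ten ellipses, additive
  intensities) with a mild global linear phase ramp (0.5 and 0.3 cycles
  across the FOV) so the object is genuinely complex;
* `L = 8` coils evenly spaced on a circle of radius `0.6·n` around the FOV,
  Gaussian magnitude profiles with decay length `0.75·n` pixels and mild
  per-coil linear phases (±0.25 cycles) — a smooth head-array surrogate
  with no dead zone;
* centered, unitary 2-D Fourier transforms (DC at `⌊n/2⌋`), which make
  round-trip and energy checks exact;
* i.i.d. complex Gaussian noise added in k-space (matching where MR noise
  enters), with std `sigma` **relative to the peak k-space magnitude**
  (real and imaginary parts each `sigma·peak/√2`); the default
  `sigma = 0.01` puts the outer k-space well below the noise floor, a
  deliberately harsh high-acceleration regime. All randomness flows
  through one integer seed, and the caller's RNG state is left untouched.

What the phantom does *not* emulate: anatomical texture (its k-space is
dominated by ellipse edges), electromagnetic coil physics (profiles are
Gaussian, not Biot–Savart), coil noise correlation, and motion/physiology.
Conclusions from passing tests are therefore about the algorithms'
internal consistency and their relative behavior under this noise model,
not about in-vivo image quality.

# Numerical choices

* Least-squares calibration uses the complex SVD pseudoinverse
  (minimum-norm solution under rank deficiency). On *noiseless* smooth
  phantoms the calibration matrix is numerically low-rank and the retained
  small singular values can make the weights explode outside the ACS — the
  textbook over-fitting failure; noise, or the exact-model fixtures, keep
  the system well conditioned.
* The PSVR dual matrix `Ω + C⁻¹I + 11ᵀ` is symmetric positive definite for
  PSD kernels; it is solved by Cholesky with an LU fallback (the wavelet
  Gram is only near-PSD; the suite monitors its smallest eigenvalue).
* The dual solve is `O(ℓ³)`; calibration sets larger than `l_max`
  (default 2048) are uniformly subsampled with a dedicated seeded stream.
  Within one offset the Gram and cross-kernel matrices depend only on the
  shared source windows, so they are computed once and reused across the
  eight coils; the wavelet cosine product is evaluated in compiled code
  via `cos(a(x−y)) = cos(ax)cos(ay) + sin(ax)sin(ay)`, which turns the
  transcendental work into one pass over each input matrix.
* Problem sizes in the shipped tests: unit tests run at 16–64 grids with
  2–4 coils; the end-to-end property tests run the full 128×128, 8-coil
  conditions (R = 3 with 24 ACS lines sweeping FE widths 1..15, and R = 4
  with 40 ACS lines, window 2×9) over ten noise seeds with
  `l_max = 1024`.

# Known limitations

* The decoupled real/imaginary regression cannot represent complex
  weight rules (above); on data with strongly phase-coupled coils the PSVR
  arm starts from a structural handicap relative to complex least squares.
* Under the published scale rules the wavelet PSVR acts as a heavy
  smoother: its reconstructions are nearly insensitive to the
  interpolation window (the property the method advertises), but on this
  synthetic phantom its R = 4 error can exceed the GRAPPA baseline's,
  because the baseline's noise amplification here is milder than on
  in-vivo data. The acceptance script reports both numbers rather than
  adjudicating.
* The PSNR reported is derived from the normalized *root* error (NMSE as
  defined here) with the literal `255²` numerator, so absolute values are
  offset from the conventional MSE-based PSNR; orderings and differences
  between methods are unaffected. `nmse()`/`psnr()` document this.
* Only 1-D regular Cartesian undersampling with an integer `R` and a
  contiguous centered ACS block is supported.

# A worked example

```{r example, eval = FALSE}
sim <- simulate_phantom_kspace(n = 128, n_coils = 8, sigma = 0.01, seed = 1)
scheme <- sampling_scheme(R = 4, n_acs = 40)
win <- interp_window(n_pe_blocks = 2, n_fe_cols = 9)

reconstruct_report(sim$kspace, scheme, win, "grappa")
reconstruct_report(sim$kspace, scheme, win, "psvr",
                   kernel = kernel_spec("wavelet"), l_max = 1024)
```

The two reports print NMSE (also as a percentage) and PSNR against the
fully sampled SOS reference; `run_window_sweep()` and
`run_kernel_comparison()` tabulate the same quantities over grids of
sampling conditions, windows and kernels.
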