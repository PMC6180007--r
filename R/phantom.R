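#' Phantom specification
#'
#' Describes a piecewise-smooth complex test object as a superposition of
#' ellipses with additive intensities, modulated by a global linear phase
#' ramp.  The phantom plays the role of the unknown magnetization image in
#' simulated multi-coil acquisitions.
#'
#' @param grid_size integer pair `(ny, nx)`, both at least 16.
#' @param ellipses list of ellipse descriptors; each a list with fields
#'   `center` (pair, in normalized field-of-view coordinates, -1..1),
#'   `axes` (pair of strictly positive semi-axes, same units),
#'   `angle` (rotation in radians, counter-clockwise) and
#'   `intensity` (real additive intensity; may be negative, overlapping
#'   ellipses sum).
#' @param phase_ramp real pair: cycles of linear phase across the field of
#'   view along y and x.
#' @return an object of class `phantom_spec`.
#' @seealso [make_phantom()], [shepp_logan_spec()]
#' @export
phantom_spec <- function(grid_size = c(128L, 128L),
                         ellipses = list(),
                         phase_ramp = c(0, 0)) {
  grid_size <- as.integer(grid_size)
  stopifnot(length(grid_size) == 2L, all(grid_size >= 16L))
  stopifnot(length(phase_ramp) == 2L, all(is.finite(phase_ramp)))
  for (e in ellipses) {
    stopifnot(is.list(e),
              all(c("center", "axes", "angle", "intensity") %in% names(e)))
    if (any(e$axes <= 0))
      stop("degenerate ellipse: semi-axes must be strictly positive")
  }
  structure(list(grid_size = grid_size,
                 ellipses = ellipses,
                 phase_ramp = as.numeric(phase_ramp)),
            class = "phantom_spec")
}

#' Shepp-Logan-style ellipse phantom specification
#'
#' A head-like arrangement of ten ellipses (outer skull ring, brain matter,
#' ventricles and small lesions) on the classical Shepp-Logan layout, with a
#' mild linear phase ramp so the object is genuinely complex-valued, as MR
#' images are.
#'
#' @inheritParams phantom_spec
#' @param phase_ramp cycles of linear phase across the FOV; default `c(0.5, 0.3)`.
#' @return a `phantom_spec`.
#' @export
shepp_logan_spec <- function(grid_size = c(128L, 128L),
                             phase_ramp = c(0.5, 0.3)) {
  ell <- function(cy, cx, ay, ax, ang, val)
    list(center = c(cy, cx), axes = c(ay, ax), angle = ang, intensity = val)
  # intensities follow the "modified" contrast variant so soft tissue is visible
  ellipses <- list(
    ell( 0.00,  0.00, 0.92, 0.69,  0.0,  1.0),
    ell(-0.0184, 0.00, 0.874, 0.6624, 0.0, -0.80),
    ell( 0.00,  0.22, 0.31, 0.11, -18 * pi / 180, -0.20),
    ell( 0.00, -0.22, 0.41, 0.16,  18 * pi / 180, -0.20),
    ell(-0.35,  0.00, 0.25, 0.21,  0.0,  0.10),
    ell(-0.10,  0.00, 0.046, 0.046, 0.0, 0.10),
    ell( 0.10,  0.00, 0.046, 0.046, 0.0, 0.10),
    ell( 0.605, -0.08, 0.023, 0.046, 0.0, 0.10),
    ell( 0.605,  0.00, 0.023, 0.023, 0.0, 0.10),
    ell( 0.605,  0.06, 0.046, 0.023, 0.0, 0.10))
  phantom_spec(grid_size = grid_size, ellipses = ellipses,
               phase_ramp = phase_ramp)
}

#' Render a phantom specification to a complex image
#'
#' Evaluates the ellipse superposition on the pixel grid: each pixel gets the
#' sum of intensities of the ellipses containing it, then the whole image is
#' multiplied by `exp(2i*pi*(ry*y + rx*x))` where `(ry, rx)` is the phase
#' ramp in cycles across the field of view.  The map is deterministic.
#'
#' @param spec a [phantom_spec()].
#' @return complex matrix `ny x nx`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ny <- spec$grid_size[1]; nx <- spec$grid_size[2]
  # normalized coordinates in [-1, 1)
  yy <- (seq_len(ny) - 1 - floor(ny / 2)) / (ny / 2)
  xx <- (seq_len(nx) - 1 - floor(nx / 2)) / (nx / 2)
  Y <- matrix(yy, ny, nx)
  X <- matrix(xx, ny, nx, byrow = TRUE)
  img <- matrix(0, ny, nx)
  for (e in spec$ellipses) {
    dy <- Y - e$center[1]; dx <- X - e$center[2]
    ca <- cos(e$angle); sa <- sin(e$angle)
    u <- ca * dy + sa * dx
    v <- -sa * dy + ca * dx
    inside <- (u / e$axes[1])^2 + (v / e$axes[2])^2 <= 1
    img <- img + e$intensity * inside
  }
  ramp <- exp(2i * pi * (spec$phase_ramp[1] * (Y + 1) / 2 +
                           spec$phase_ramp[2] * (X + 1) / 2))
  out <- img * ramp
  stopifnot(all(is.finite(Re(out))), all(is.finite(Im(out))))
  out
}

#' Coil-array specification
#'
#' Describes a circular array of `n_coils` receive coils.  Each coil has a
#' Gaussian magnitude profile of decay length `profile_width` (pixels)
#' centred at a point on or outside the field-of-view boundary, and a
#' per-coil linear phase.
#'
#' @param n_coils number of coils `L >= 1`.
#' @param profile_centers optional `L x 2` matrix of (y, x) centers in pixel
#'   units; defaults to `L` points evenly spaced on a circle of radius
#'   `0.6 * grid` around the FOV center (set when maps are rendered).
#' @param profile_width Gaussian decay length in pixels; `Inf` gives flat
#'   unit magnitude.
#' @param phase_coeffs optional `L x 2` matrix of linear-phase coefficients
#'   (cycles across FOV along y, x) per coil; default mild distinct ramps.
#' @return an object of class `coil_array_spec`.
#' @export
coil_array_spec <- function(n_coils = 8L,
                            profile_centers = NULL,
                            profile_width = 96,
                            phase_coeffs = NULL) {
  n_coils <- as.integer(n_coils)
  if (n_coils < 1L) stop("n_coils must be at least 1")
  stopifnot(profile_width > 0)
  if (!is.null(profile_centers)) {
    profile_centers <- as.matrix(profile_centers)
    stopifnot(nrow(profile_centers) == n_coils, ncol(profile_centers) == 2L)
  }
  if (!is.null(phase_coeffs)) {
    phase_coeffs <- as.matrix(phase_coeffs)
    stopifnot(nrow(phase_coeffs) == n_coils, ncol(phase_coeffs) == 2L)
  }
  structure(list(n_coils = n_coils,
                 profile_centers = profile_centers,
                 profile_width = profile_width,
                 phase_coeffs = phase_coeffs),
            class = "coil_array_spec")
}

#' Render complex coil-sensitivity maps
#'
#' Magnitude is `exp(-d^2 / (2 w^2))` in the distance `d` to the coil center;
#' phase is linear per coil.  The sum over coils of squared magnitudes is
#' checked to be strictly positive everywhere (no dead zone), which the
#' default circular arrangement guarantees.
#'
#' @param spec a [coil_array_spec()].
#' @param grid integer pair `(ny, nx)`.
#' @return complex array `ny x nx x L`.
#' @export
make_sensitivities <- function(spec, grid) {
  stopifnot(inherits(spec, "coil_array_spec"))
  grid <- as.integer(grid)
  ny <- grid[1]; nx <- grid[2]
  L <- spec$n_coils
  centers <- spec$profile_centers
  if (is.null(centers)) {
    ang <- 2 * pi * (seq_len(L) - 1) / L
    rad <- 0.6 * max(ny, nx)
    centers <- cbind(ny / 2 + rad * sin(ang), nx / 2 + rad * cos(ang))
  }
  phases <- spec$phase_coeffs
  if (is.null(phases)) {
    ang <- 2 * pi * (seq_len(L) - 1) / L
    phases <- cbind(0.25 * cos(ang), 0.25 * sin(ang))
  }
  yy <- seq_len(ny) - 1
  xx <- seq_len(nx) - 1
  Y <- matrix(yy, ny, nx)
  X <- matrix(xx, ny, nx, byrow = TRUE)
  out <- array(0i, dim = c(ny, nx, L))
  w <- spec$profile_width
  for (l in seq_len(L)) {
    d2 <- (Y - centers[l, 1])^2 + (X - centers[l, 2])^2
    mag <- if (is.finite(w)) exp(-d2 / (2 * w^2)) else matrix(1, ny, nx)
    ph <- exp(2i * pi * (phases[l, 1] * Y / ny + phases[l, 2] * X / nx))
    out[, , l] <- mag * ph
  }
  sos2 <- apply(abs(out)^2, c(1, 2), sum)
  if (min(sos2) <= 0)
    stop("coil array has a dead zone: sum of squared sensitivities reaches 0")
  out
}

#' Noise specification for simulated acquisitions
#'
#' @param sigma standard deviation of the additive complex Gaussian noise
#'   per k-space sample, relative to the peak k-space magnitude (so the
#'   absolute complex noise std is `sigma * max(abs(kspace))`).  Real and
#'   imaginary parts each get std `sigma_abs / sqrt(2)`.
#' @param seed integer seed; identical seeds give identical realizations.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, seed = 1L) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  structure(list(sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate fully sampled multi-coil k-space
#'
#' Forms per-coil images `sens[,,l] * image`, applies the centered unitary
#' 2-D Fourier transform, and adds i.i.d. complex Gaussian noise of std
#' `sigma * peak` where `peak` is the largest noiseless k-space magnitude
#' over all coils.  All randomness flows through `noise$seed`; the RNG state
#' of the caller is left untouched.
#'
#' @param image complex matrix `ny x nx`.
#' @param sens complex array `ny x nx x L` of coil sensitivities.
#' @param noise a [noise_spec()].
#' @return a fully sampled [multicoil_kspace()].
#' @export
simulate_kspace <- function(image, sens, noise = noise_spec()) {
  stopifnot(inherits(noise, "noise_spec"))
  if (length(dim(sens)) != 3L || !all(dim(sens)[1:2] == dim(image)))
    stop("shape mismatch between image and sensitivity maps")
  ny <- dim(image)[1]; nx <- dim(image)[2]; L <- dim(sens)[3]
  ks <- array(0i, dim = c(ny, nx, L))
  for (l in seq_len(L)) ks[, , l] <- fft2c(sens[, , l] * image)
  if (noise$sigma > 0) {
    peak <- max(abs(ks))
    s <- noise$sigma * peak / sqrt(2)
    n <- length(ks)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(noise$seed)
    ks <- ks + array(complex(real = stats::rnorm(n, sd = s),
                             imaginary = stats::rnorm(n, sd = s)),
                     dim = dim(ks))
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  multicoil_kspace(ks, acquired_mask = rep(TRUE, ny))
}

#' One-call synthetic acquisition
#'
#' Convenience wrapper reproducing the package's default study object: a
#' Shepp-Logan-style complex phantom observed by a circular array of `L`
#' coils, with complex Gaussian k-space noise.
#'
#' @param n grid size (square `n x n`).
#' @param n_coils number of coils.
#' @param sigma relative k-space noise std (see [noise_spec()]).
#' @param seed integer seed for the noise realization.
#' @return list with `kspace` (fully sampled [multicoil_kspace()]),
#'   `image` (ground-truth complex phantom), `sens` (coil maps) and
#'   `reference` (the SOS reference image from the noiseless coil images).
#' @export
simulate_phantom_kspace <- function(n = 128L, n_coils = 8L, sigma = 0.01,
                                    seed = 1L) {
  img <- make_phantom(shepp_logan_spec(grid_size = c(n, n)))
  sens <- make_sensitivities(coil_array_spec(n_coils = n_coils,
                                             profile_width = 0.75 * n),
                             grid = c(n, n))
  ks <- simulate_kspace(img, sens, noise_spec(sigma = sigma, seed = seed))
  coil_imgs <- array(0i, dim = dim(sens))
  for (l in seq_len(n_coils)) coil_imgs[, , l] <- sens[, , l] * img
  reference <- sqrt(apply(abs(coil_imgs)^2, c(1, 2), sum))
  list(kspace = ks, image = img, sens = sens, reference = reference)
}
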