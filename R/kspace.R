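#' Centered unitary 2-D Fourier transforms
#'
#' `fft2c` maps an image to k-space with the DC component at the grid
#' center (`floor(n/2)` in 0-based indexing) and unitary normalization, so
#' `ifft2c(fft2c(x))` recovers `x` to machine precision and both transforms
#' preserve the Frobenius norm.
#'
#' @param x complex matrix.
#' @return complex matrix of the same shape.
#' @export
fft2c <- function(x) {
  fftshift(stats::fft(fftshift(x, inverse = TRUE))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  fftshift(stats::fft(fftshift(x, inverse = TRUE), inverse = TRUE)) /
    sqrt(length(x))
}

#' Quadrant swap placing DC at the grid center
#'
#' @param x matrix.
#' @param inverse logical; `TRUE` undoes the shift (relevant for odd sizes).
#' @return shifted matrix.
#' @export
fftshift <- function(x, inverse = FALSE) {
  d <- dim(x)
  s <- if (inverse) -floor(d / 2) else floor(d / 2)
  i <- 1L + (seq_len(d[1]) - 1L + s[1]) %% d[1]
  j <- 1L + (seq_len(d[2]) - 1L + s[2]) %% d[2]
  x[i, j, drop = FALSE]
}

#' Multi-coil k-space container
#'
#' The central object of the package: complex k-space samples for `L` coils
#' on an `n_pe x n_fe` Cartesian grid (phase-encoding along rows), plus a
#' per-PE-line acquisition mask.  Grid steps are unit (`delta_k = c(1, 1)`).
#'
#' @param data complex array `n_pe x n_fe x L` (a matrix is promoted to a
#'   single-coil array).
#' @param acquired_mask logical vector of length `n_pe`; which PE lines were
#'   acquired.  Default: all.
#' @param delta_k sampling intervals along (PE, FE) in grid units.
#' @return an object of class `mc_kspace` with fields `data`, `mask`,
#'   `delta_k`.
#' @export
multicoil_kspace <- function(data, acquired_mask = NULL, delta_k = c(1, 1)) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, is.complex(data))
  n_pe <- dim(data)[1]
  if (is.null(acquired_mask)) acquired_mask <- rep(TRUE, n_pe)
  stopifnot(length(acquired_mask) == n_pe, is.logical(acquired_mask))
  if (!any(acquired_mask)) stop("at least one PE line must be acquired")
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data))))
    stop("k-space data must be finite")
  structure(list(data = data, mask = acquired_mask,
                 delta_k = as.numeric(delta_k)),
            class = "mc_kspace")
}

#' @export
print.mc_kspace <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mc_kspace> %d x %d k-space, %d coil(s), %d/%d PE lines acquired\n",
              d[1], d[2], d[3], sum(x$mask), d[1]))
  invisible(x)
}

#' Regular undersampling scheme with an ACS block
#'
#' Acquired PE lines are `{lines == 0 mod R}` (0-based) plus a contiguous
#' block of `n_acs` auto-calibration lines centered at line
#' `floor(n_pe / 2)`; line 0 is always acquired.
#'
#' @param R integer reduction factor `>= 1`.
#' @param n_acs number of contiguous fully sampled central PE lines.
#' @return an object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(R = 2L, n_acs = 24L) {
  R <- as.integer(R); n_acs <- as.integer(n_acs)
  stopifnot(R >= 1L, n_acs >= 0L)
  structure(list(R = R, n_acs = n_acs), class = "sampling_scheme")
}

#' Acquired PE lines under a scheme
#'
#' @param scheme a [sampling_scheme()].
#' @param n_pe number of PE lines.
#' @return 1-based integer indices of acquired lines, sorted.
#' @export
acquired_lines <- function(scheme, n_pe) {
  if (scheme$n_acs > n_pe) stop("n_acs exceeds the number of PE lines")
  reg <- which((seq_len(n_pe) - 1L) %% scheme$R == 0L)
  acs <- acs_lines(scheme, n_pe)
  sort(union(reg, acs))
}

#' ACS block line indices (1-based)
#'
#' @inheritParams acquired_lines
#' @return integer vector (possibly empty).
#' @export
acs_lines <- function(scheme, n_pe) {
  if (scheme$n_acs == 0L) return(integer(0))
  start0 <- floor(n_pe / 2) - floor(scheme$n_acs / 2)  # 0-based
  if (start0 < 0L || start0 + scheme$n_acs > n_pe)
    stop("ACS block does not fit in the PE extent")
  start0 + seq_len(scheme$n_acs)
}

#' Retrospectively undersample fully sampled k-space
#'
#' Zeroes every PE line outside the acquired set of `scheme` and records the
#' acquired set in the mask.  With `R = 1` the output equals the input.
#'
#' @param full a fully sampled [multicoil_kspace()].
#' @param scheme a [sampling_scheme()].
#' @return an `mc_kspace` with zeroed missing lines.
#' @export
undersample <- function(full, scheme) {
  stopifnot(inherits(full, "mc_kspace"), inherits(scheme, "sampling_scheme"))
  if (!all(full$mask)) stop("input must be fully sampled")
  n_pe <- dim(full$data)[1]
  acq <- acquired_lines(scheme, n_pe)
  mask <- rep(FALSE, n_pe); mask[acq] <- TRUE
  data <- full$data
  data[!mask, , ] <- 0i
  multicoil_kspace(data, acquired_mask = mask, delta_k = full$delta_k)
}

#' Interpolation-window specification
#'
#' The GRAPPA interpolation window: `n_pe_blocks` acquired PE neighbours
#' (blocks of spacing `R`) times `n_fe_cols` FE columns, over all `L` coils,
#' so a source vector has length `M = L * n_pe_blocks * n_fe_cols`.
#'
#' Block offsets `t` run over `N1..N2` with `N1 = -(ceiling(n/2) - 1)`,
#' `N2 = floor(n/2)`: the acquired neighbours bracket the target, with the
#' extra block on the preceding side for odd counts.  Column offsets `h`
#' run over `H1..H2` with `H1 = -floor(w/2)`, `H2 = ceiling(w/2) - 1`
#' (centered, extra column on the left for even widths).
#'
#' @param n_pe_blocks integer `>= 1`, acquired PE neighbours per source.
#' @param n_fe_cols integer `>= 1`, FE columns per source.
#' @return an object of class `interp_window` with fields `n_pe_blocks`,
#'   `n_fe_cols`, `t_range`, `h_range`.
#' @export
interp_window <- function(n_pe_blocks = 2L, n_fe_cols = 9L) {
  nb <- as.integer(n_pe_blocks); w <- as.integer(n_fe_cols)
  stopifnot(nb >= 1L, w >= 1L)
  N1 <- -(ceiling(nb / 2) - 1L); N2 <- floor(nb / 2)
  H1 <- -floor(w / 2); H2 <- ceiling(w / 2) - 1L
  structure(list(n_pe_blocks = nb, n_fe_cols = w,
                 t_range = as.integer(N1:N2), h_range = as.integer(H1:H2)),
            class = "interp_window")
}

#' Inverse transform and sum-of-squares coil combination
#'
#' Applies the centered unitary inverse 2-D Fourier transform per coil and
#' combines magnitudes pixelwise as `sqrt(sum_l |img_l|^2)`.
#'
#' @param ks an [multicoil_kspace()].
#' @return real matrix `n_pe x n_fe`.
#' @export
ifft_and_sos <- function(ks) {
  stopifnot(inherits(ks, "mc_kspace"))
  d <- dim(ks$data)
  acc <- matrix(0, d[1], d[2])
  for (l in seq_len(d[3])) acc <- acc + abs(ifft2c(ks$data[, , l]))^2
  sqrt(acc)
}
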