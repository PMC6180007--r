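#' Kernel specification
#'
#' Describes the kernel used to map interpolation sources before fitting.
#' Supported families:
#' \describe{
#'   \item{linear}{`K(x, y) = x . y`}
#'   \item{polynomial}{`K(x, y) = (x . y + theta)^d`}
#'   \item{rbf}{`K(x, y) = exp(-||x - y||^2 / gamma^2)`}
#'   \item{wavelet}{`K(x, y) = prod_i h((x_i - y_i) / q)` with
#'     `h(u) = cos(1.75 u) * exp(-u^2 / 2)`}
#' }
#' `gamma` and `q` may be left `NULL` ("auto"): they are then derived from
#' the training sources via [rbf_gamma()] / [wavelet_q()] at fit time.
#'
#' @param family one of `"linear"`, `"polynomial"`, `"rbf"`, `"wavelet"`.
#' @param theta polynomial constant term (default 1).
#' @param degree polynomial order (default 2).
#' @param gamma RBF width, `> 0` or `NULL` for auto.
#' @param q wavelet scale factor, `> 0` or `NULL` for auto.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("wavelet", "linear", "polynomial", "rbf"),
                        theta = 1, degree = 2L, gamma = NULL, q = NULL) {
  family <- match.arg(family)
  if (family == "polynomial")
    stopifnot(is.finite(theta), degree >= 1L)
  if (!is.null(gamma)) stopifnot(gamma > 0)
  if (!is.null(q)) stopifnot(q > 0)
  structure(list(family = family, theta = theta, degree = as.integer(degree),
                 gamma = gamma, q = q),
            class = "kernel_spec")
}

#' Evaluate a kernel on one pair of real vectors
#'
#' Scalar reference implementation, written directly from the kernel
#' definitions; [kernel_matrix()] must agree with it elementwise.
#'
#' @param spec a [kernel_spec()] with all needed parameters set.
#' @param x,y real vectors of equal length.
#' @return real scalar.
#' @export
kernel_eval <- function(spec, x, y) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(y)) stop("kernel inputs have different lengths")
  switch(spec$family,
    linear = sum(x * y),
    polynomial = (sum(x * y) + spec$theta)^spec$degree,
    rbf = {
      if (is.null(spec$gamma)) stop("rbf kernel width gamma is unset")
      exp(-sum((x - y)^2) / spec$gamma^2)
    },
    wavelet = {
      if (is.null(spec$q)) stop("wavelet scale q is unset")
      u <- (x - y) / spec$q
      prod(cos(1.75 * u) * exp(-u^2 / 2))
    })
}

#' Kernel matrix between row sets
#'
#' Computes `K[i, j] = K(X[i, ], Y[j, ])` for all row pairs.  Inner-product
#' kernels go through BLAS; the RBF Gaussian uses the squared-distance
#' expansion; the wavelet kernel factors into its Gaussian envelope (same
#' expansion) times a cosine product evaluated in compiled code.
#'
#' @param spec a fully parameterized [kernel_spec()].
#' @param X real matrix `n x M`.
#' @param Y real matrix `k x M`; default `X`.
#' @return real matrix `n x k`.
#' @export
kernel_matrix <- function(spec, X, Y = X) {
  stopifnot(inherits(spec, "kernel_spec"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("kernel inputs have different widths")
  switch(spec$family,
    linear = tcrossprod(X, Y),
    polynomial = (tcrossprod(X, Y) + spec$theta)^spec$degree,
    rbf = {
      if (is.null(spec$gamma)) stop("rbf kernel width gamma is unset")
      exp(-pair_sqdist(X, Y) / spec$gamma^2)
    },
    wavelet = {
      if (is.null(spec$q)) stop("wavelet scale q is unset")
      exp(-pair_sqdist(X, Y) / (2 * spec$q^2)) *
        cosprod_cross(X, Y, 1.75 / spec$q)
    })
}

# pairwise squared Euclidean distances, clipped at 0 against cancellation
pair_sqdist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

#' Maximum pairwise distance of a training set
#'
#' @param points real matrix, one point per row (at least 2 rows).
#' @return largest Euclidean distance between any two rows.
#' @export
d_max <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("d_max needs at least 2 points")
  sqrt(max(pair_sqdist(points, points)))
}

#' Data-driven kernel scales
#'
#' `rbf_gamma` sets the RBF width to `d_max / sqrt(2 l)`; `wavelet_q` sets
#' the wavelet scale to `d_max * log(l)` (natural log), where `d_max` is the
#' maximum pairwise distance of the training points and `l` their count.
#' A degenerate training set (`d_max = 0`) is an error; callers fall back
#' to a configured floor.
#'
#' @param points real matrix of training points (rows).
#' @param l training-set size for the scale rule; defaults to `nrow(points)`.
#' @return positive real scalar.
#' @export
rbf_gamma <- function(points, l = nrow(points)) {
  dm <- d_max(points)
  if (dm == 0) stop("degenerate training set: d_max = 0")
  dm / sqrt(2 * l)
}

#' @rdname rbf_gamma
#' @export
wavelet_q <- function(points, l = nrow(points)) {
  dm <- d_max(points)
  if (dm == 0) stop("degenerate training set: d_max = 0")
  if (l < 2L) stop("wavelet_q needs at least 2 points")
  dm * log(l)
}

# Fill auto scales of `spec` from training points X; on a degenerate set
# fall back to `floor` (unit scale).
resolve_kernel <- function(spec, X, floor = 1) {
  if (spec$family == "rbf" && is.null(spec$gamma)) {
    spec$gamma <- tryCatch(rbf_gamma(X), error = function(e) floor)
  }
  if (spec$family == "wavelet" && is.null(spec$q)) {
    spec$q <- tryCatch(wavelet_q(X), error = function(e) floor)
  }
  spec
}

#' Gram matrices of a complex source set
#'
#' The complex sources decouple into two real regression problems: one on
#' real parts, one on imaginary parts.  `gram_matrices` returns the two
#' kernel Gram matrices `Omega_r[k, l] = K(Re x_k, Re x_l)` and
#' `Omega_i[k, l] = K(Im x_k, Im x_l)`, each symmetrized exactly.  Auto
#' kernel scales are resolved per part (`scale_mode = "per-part"`) or from
#' the pooled real/imaginary rows (`"joint"`).
#'
#' @param sources complex matrix `l x M`.
#' @param kernel a [kernel_spec()].
#' @param scale_mode how auto scales see the data; see Details.
#' @return list with `omega_r`, `omega_i` (real `l x l`), and the resolved
#'   per-part kernel specs `kernel_r`, `kernel_i`.
#' @export
gram_matrices <- function(sources, kernel, scale_mode = c("per-part", "joint")) {
  scale_mode <- match.arg(scale_mode)
  sources <- as.matrix(sources)
  Xr <- Re(sources); Xi <- Im(sources)
  if (scale_mode == "joint") {
    kr <- ki <- resolve_kernel(kernel, rbind(Xr, Xi))
  } else {
    kr <- resolve_kernel(kernel, Xr)
    ki <- resolve_kernel(kernel, Xi)
  }
  Or <- kernel_matrix(kr, Xr)
  Oi <- kernel_matrix(ki, Xi)
  Or <- (Or + t(Or)) / 2
  Oi <- (Oi + t(Oi)) / 2
  if (!all(is.finite(Or)) || !all(is.finite(Oi)))
    stop("non-finite kernel value in Gram matrix")
  list(omega_r = Or, omega_i = Oi, kernel_r = kr, kernel_i = ki)
}
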