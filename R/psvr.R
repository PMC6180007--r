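#' Heuristic penalty factor for PSVR
#'
#' `C = max(|ybar + 3 s|, |ybar - 3 s|)` where `ybar` and `s` are the mean
#' and (population) standard deviation of the calibration targets.  For
#' complex targets the statistics are computed on the pooled real sample of
#' all real parts and all imaginary parts, since the complex fit decouples
#' into two real regressions sharing one `C`.  The result is floored at
#' `1e-12 * (1 + max |y|)` so degenerate (all-zero) targets still give a
#' strictly positive penalty.
#'
#' @param targets complex (or real) vector of calibration targets.
#' @return positive real scalar.
#' @export
heuristic_C <- function(targets) {
  stopifnot(length(targets) >= 1L)
  v <- c(Re(targets), Im(targets))
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  C <- max(abs(m + 3 * s), abs(m - 3 * s))
  max(C, 1e-12 * (1 + max(abs(targets))))
}

#' Fit a complex proximal support vector regression
#'
#' Solves the PSVR dual: with Gram matrix `Omega`, the real-part
#' coefficients satisfy `(Omega_r + I/C + 11') alpha = Re(y)` and the
#' imaginary-part coefficients the analogous system with `Omega_i` and
#' `Im(y)`; the bias is `b = sum(alpha) + 1i * sum(beta)`.  This is the
#' self-consistent convention obtained by deriving the dual of the primal
#' problem
#' `min 1/2 (w'w + b^2) + C/2 sum(xi^2 + zeta^2)` subject to the equality
#' constraints `Re(y_k - w'phi(x_k) - b) = xi_k` (and likewise for the
#' imaginary part); the KKT conditions give `xi_k = alpha_k / C`, so every
#' training point contributes (no sparse support-vector selection).
#'
#' The linear system is strictly positive definite for PSD kernels thanks
#' to the `I/C` ridge; it is solved by Cholesky factorization, with an LU
#' fallback should the (possibly indefinite) wavelet Gram defeat it.
#'
#' @param sources complex matrix `l x M` of training source vectors.
#' @param targets complex vector of length `l`.
#' @param C penalty factor `> 0`, or `"auto"` for [heuristic_C()].
#' @param kernel a [kernel_spec()]; auto scales resolved from the sources.
#' @param scale_mode passed to [gram_matrices()].
#' @param grams optional precomputed result of [gram_matrices()] on the same
#'   sources (lets callers share Gram matrices across fits).
#' @return an object of class `psvr_model` with fields `alpha`, `beta`,
#'   `b`, `C`, `kernel_r`, `kernel_i`, `train_re`, `train_im`.
#' @export
psvr_fit <- function(sources, targets, C = "auto",
                     kernel = kernel_spec("wavelet"),
                     scale_mode = c("per-part", "joint"),
                     grams = NULL) {
  sources <- as.matrix(sources)
  l <- nrow(sources)
  stopifnot(length(targets) == l, l >= 1L)
  if (!all(is.finite(Re(sources))) || !all(is.finite(Im(sources))) ||
      !all(is.finite(Re(targets))) || !all(is.finite(Im(targets))))
    stop("non-finite values in PSVR training data")
  if (identical(C, "auto")) C <- heuristic_C(targets)
  stopifnot(is.numeric(C), C > 0)
  if (is.null(grams)) grams <- gram_matrices(sources, kernel, scale_mode)
  alpha <- psvr_dual_solve(grams$omega_r, Re(targets), C)
  beta <- psvr_dual_solve(grams$omega_i, Im(targets), C)
  structure(list(alpha = alpha, beta = beta,
                 b = complex(real = sum(alpha), imaginary = sum(beta)),
                 C = C,
                 kernel_r = grams$kernel_r, kernel_i = grams$kernel_i,
                 train_re = Re(sources), train_im = Im(sources)),
            class = "psvr_model")
}

# solve (Omega + I/C + 11') a = y by Cholesky, LU fallback
psvr_dual_solve <- function(omega, y, C) {
  A <- omega + matrix(1, nrow(omega), ncol(omega))
  diag(A) <- diag(A) + 1 / C
  a <- tryCatch({
    U <- chol(A)
    backsolve(U, forwardsolve(t(U), y))
  }, error = function(e) solve(A, y))
  if (!all(is.finite(a)))
    stop("PSVR dual system is singular beyond the ridge regularization")
  drop(a)
}

#' @export
print.psvr_model <- function(x, ...) {
  cat(sprintf("<psvr_model> l = %d, M = %d, kernel = %s, C = %.4g\n",
              length(x$alpha), ncol(x$train_re), x$kernel_r$family, x$C))
  invisible(x)
}

#' Predict missing samples from a fitted PSVR model
#'
#' `f(s) = sum_k alpha_k K(Re s, Re x_k) + 1i * sum_k beta_k K(Im s, Im x_k)
#' + b`, evaluated for each row of `sources`.
#'
#' @param model a [psvr_fit()] result.
#' @param sources complex matrix `n x M` (or a single length-`M` vector).
#' @param cross optional list with precomputed cross-kernel matrices `r`
#'   (`n x l`, kernel between `Re(sources)` and training real parts) and
#'   `i` (imaginary counterpart); lets callers share them across models
#'   fitted on the same sources.
#' @return complex vector of length `n`.
#' @export
psvr_predict <- function(model, sources, cross = NULL) {
  stopifnot(inherits(model, "psvr_model"))
  if (!is.matrix(sources)) sources <- matrix(sources, nrow = 1L)
  if (ncol(sources) != ncol(model$train_re))
    stop("source vectors have wrong length for this model")
  if (is.null(cross)) {
    cross <- list(
      r = kernel_matrix(model$kernel_r, Re(sources), model$train_re),
      i = kernel_matrix(model$kernel_i, Im(sources), model$train_im))
  }
  drop(cross$r %*% model$alpha) + 1i * drop(cross$i %*% model$beta) + model$b
}

#' Linear-kernel primal oracle for PSVR
#'
#' Minimizes the PSVR primal objective directly in the explicit linear
#' feature space: each real subproblem
#' `min 1/2 (||u||^2 + b^2) + C/2 sum(y_k - u'z_k - b)^2` is the ridge
#' problem with augmented design `Z = [P, 1]` and is solved exactly via its
#' normal equations `(Z'Z + I/C) theta = Z'y`.  Used as an independent
#' check of the dual solver; not part of the reconstruction path.
#'
#' @param sources complex matrix `l x M`.
#' @param targets complex vector of length `l`.
#' @param C penalty factor `> 0`.
#' @return list with complex `w` (length `M`; real part acts on real source
#'   parts, imaginary part on imaginary source parts) and complex bias `b`.
#' @export
primal_fit <- function(sources, targets, C) {
  sources <- as.matrix(sources)
  stopifnot(nrow(sources) == length(targets), C > 0)
  solve_part <- function(P, y) {
    Z <- cbind(P, 1)
    A <- crossprod(Z)
    diag(A) <- diag(A) + 1 / C
    drop(solve(A, crossprod(Z, y)))
  }
  th_r <- solve_part(Re(sources), Re(targets))
  th_i <- solve_part(Im(sources), Im(targets))
  M <- ncol(sources)
  list(w = complex(real = th_r[seq_len(M)], imaginary = th_i[seq_len(M)]),
       b = complex(real = th_r[M + 1L], imaginary = th_i[M + 1L]))
}

#' @rdname primal_fit
#' @param fit a `primal_fit()` result.
#' @param sources complex matrix of evaluation points.
#' @export
primal_predict <- function(fit, sources) {
  if (!is.matrix(sources)) sources <- matrix(sources, nrow = 1L)
  drop(Re(sources) %*% Re(fit$w)) + Re(fit$b) +
    1i * (drop(Im(sources) %*% Im(fit$w)) + Im(fit$b))
}
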