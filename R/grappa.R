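#' Least-squares GRAPPA weight calibration
#'
#' Fits the interpolation weights of one (target coil, offset) pair by
#' minimizing `||y - A w||_2` over the calibration set.  The solve goes
#' through the complex SVD pseudoinverse, which returns the minimum-norm
#' solution when `A` is rank-deficient.
#'
#' @param cal a [extract_calibration_pairs()] result.
#' @param bias if `TRUE`, augment `A` with a constant column and return a
#'   weight vector of length `M + 1` whose last entry is the bias (the
#'   conventional GRAPPA model has no bias term).
#' @return complex weight vector.
#' @export
grappa_calibrate <- function(cal, bias = FALSE) {
  stopifnot(inherits(cal, "calibration_set"))
  A <- cal$A
  if (bias) A <- cbind(A, 1 + 0i)
  drop(complex_pinv_solve(A, cbind(cal$y)))
}

# minimum-norm least-squares solve via complex SVD; Y may have many columns
complex_pinv_solve <- function(A, Y) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0i, ncol(A), ncol(Y)))
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  V %*% ((Conj(t(U)) %*% Y) / sv$d[pos])
}

#' GRAPPA reconstruction by least squares
#'
#' For every offset `m = 1..R-1` builds the calibration system once (the
#' source matrix is shared by all target coils), solves the least-squares
#' weights for all coils, and fills every missing sample with the linear
#' interpolation `A_miss w`.  Acquired lines, including the ACS block, are
#' preserved verbatim.
#'
#' @param ks an undersampled [multicoil_kspace()].
#' @param scheme the [sampling_scheme()] used to undersample.
#' @param win an [interp_window()].
#' @param bias include a constant (bias) term in the linear model; the
#'   conventional GRAPPA baseline does not.
#' @return reconstructed `mc_kspace`.
#' @export
grappa_reconstruct <- function(ks, scheme, win, bias = FALSE) {
  stopifnot(inherits(ks, "mc_kspace"), inherits(scheme, "sampling_scheme"),
            inherits(win, "interp_window"))
  R <- scheme$R
  if (R == 1L || all(ks$mask)) return(ks)
  d <- dim(ks$data)
  L <- d[3]
  weights <- vector("list", R - 1L)
  for (m in seq_len(R - 1L)) {
    pl <- calibration_placements(d[1], d[2], scheme, win, m)
    A <- build_source_matrix(ks$data, pl$rows, pl$cols, win, m, R)
    if (bias) A <- cbind(A, 1 + 0i)
    tr <- rep(pl$rows, times = length(pl$cols))
    tc <- rep(pl$cols, each = length(pl$rows))
    Y <- vapply(seq_len(L),
                function(l) ks$data[cbind(tr, tc, l)],
                complex(length(tr)))
    weights[[m]] <- complex_pinv_solve(A, Y)   # (M [+1]) x L
  }
  predictor <- function(l, m, S) {
    if (bias) S <- cbind(S, 1 + 0i)
    drop(S %*% weights[[m]][, l])
  }
  synthesize_missing(ks, predictor, win, scheme)
}

#' PSVR-GRAPPA reconstruction
#'
#' Replaces the least-squares weight fit with a complex proximal support
#' vector regression per (target coil, offset): the penalty `C` comes from
#' [heuristic_C()] on that coil's calibration targets (unless overridden),
#' kernel scales from the `d_max` rules, and missing samples are predicted
#' with [psvr_predict()].  Gram and cross-kernel matrices depend only on
#' the shared source windows, so they are computed once per offset and
#' reused across coils.  Acquired data are preserved verbatim.
#'
#' @param ks an undersampled [multicoil_kspace()].
#' @param scheme the [sampling_scheme()] used to undersample.
#' @param win an [interp_window()].
#' @param kernel a [kernel_spec()]; default wavelet with auto scale.
#' @param C `"auto"` (per-coil heuristic) or a positive override shared by
#'   all fits.
#' @param l_max cap on calibration-set size; larger sets are uniformly
#'   subsampled (the dual solve is O(l^3)).
#' @param subsample_seed seed for the (deterministic) subsampling draw.
#' @param scale_mode kernel auto-scale mode, see [gram_matrices()].
#' @return reconstructed `mc_kspace`.
#' @export
psvr_grappa_reconstruct <- function(ks, scheme, win,
                                    kernel = kernel_spec("wavelet"),
                                    C = "auto", l_max = 2048L,
                                    subsample_seed = 1L,
                                    scale_mode = c("per-part", "joint")) {
  stopifnot(inherits(ks, "mc_kspace"), inherits(scheme, "sampling_scheme"),
            inherits(win, "interp_window"), inherits(kernel, "kernel_spec"))
  scale_mode <- match.arg(scale_mode)
  R <- scheme$R
  if (R == 1L || all(ks$mask)) return(ks)
  d <- dim(ks$data)
  L <- d[3]
  data <- ks$data
  cols <- seq_len(d[2])
  for (m in seq_len(R - 1L)) {
    pl <- calibration_placements(d[1], d[2], scheme, win, m)
    A <- build_source_matrix(ks$data, pl$rows, pl$cols, win, m, R)
    tr <- rep(pl$rows, times = length(pl$cols))
    tc <- rep(pl$cols, each = length(pl$rows))
    keep <- seq_len(nrow(A))
    if (nrow(A) > l_max) {
      rng <- local_rng(subsample_seed + m)
      keep <- sort(rng$sample(nrow(A), l_max))
    }
    A <- A[keep, , drop = FALSE]
    tr <- tr[keep]; tc <- tc[keep]
    grams <- gram_matrices(A, kernel, scale_mode)
    rows_miss <- which(!ks$mask & ((seq_len(d[1]) - 1L) %% R == m))
    if (length(rows_miss) == 0L) next
    S <- build_source_matrix(ks$data, rows_miss, cols, win, m, R)
    cross <- list(
      r = kernel_matrix(grams$kernel_r, Re(S), Re(A)),
      i = kernel_matrix(grams$kernel_i, Im(S), Im(A)))
    mr <- rep(rows_miss, times = d[2])
    mc <- rep(cols, each = length(rows_miss))
    for (l in seq_len(L)) {
      y <- ks$data[cbind(tr, tc, l)]
      model <- psvr_fit(A, y, C = C, kernel = kernel, grams = grams)
      pred <- psvr_predict(model, S, cross = cross)
      if (!all(is.finite(Re(pred))) || !all(is.finite(Im(pred))))
        stop("PSVR prediction produced non-finite values")
      data[cbind(mr, mc, rep(l, length(mr)))] <- pred
    }
  }
  multicoil_kspace(data, acquired_mask = ks$mask, delta_k = ks$delta_k)
}

# self-contained RNG stream that never touches the caller's .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  restore <- function() {
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
  }
  restore()
  list(sample = function(n, k) {
    cur <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- sample.int(n, k)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(cur)) assign(".Random.seed", cur, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    out
  })
}
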