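#' Source-vector gathering for GRAPPA interpolation
#'
#' For target positions `(rows, cols)` (1-based) in coil-independent k-space
#' geometry, gathers the interpolation sources
#' `s_j(row - m + t*R, col + h)` for every coil `j`, PE block offset `t` and
#' FE column offset `h` of the window, into an `n_targets x M` complex
#' matrix.  Targets are enumerated column-by-column with PE rows varying
#' fastest; source entries are ordered coil-major, then PE block, then FE
#' column.  Sources falling outside the grid are zero (zero-padding).
#'
#' @param data complex array `n_pe x n_fe x L`.
#' @param rows,cols 1-based target PE rows / FE columns (all combinations
#'   are used).
#' @param win an [interp_window()].
#' @param offset target offset `m` from the preceding acquired regular line.
#' @param R reduction factor (PE block spacing).
#' @return complex matrix `length(rows)*length(cols) x M`.
#' @keywords internal
build_source_matrix <- function(data, rows, cols, win, offset, R) {
  d <- dim(data)
  L <- d[3]
  nr <- length(rows); nc <- length(cols)
  tr <- rep(rows, times = nc)
  tc <- rep(cols, each = nr)
  M <- L * win$n_pe_blocks * win$n_fe_cols
  A <- matrix(0i, nr * nc, M)
  k <- 0L
  for (j in seq_len(L)) {
    for (t in win$t_range) {
      sr <- tr - offset + t * R
      ok_r <- sr >= 1L & sr <= d[1]
      for (h in win$h_range) {
        k <- k + 1L
        sc <- tc + h
        ok <- ok_r & sc >= 1L & sc <= d[2]
        if (all(ok)) {
          A[, k] <- data[cbind(sr, sc, j)]
        } else if (any(ok)) {
          A[ok, k] <- data[cbind(sr[ok], sc[ok], j)]
        }
      }
    }
  }
  A
}

#' Calibration placements fully inside the ACS block
#'
#' @return list with `rows`, `cols`: 1-based target rows/cols such that the
#'   target and every window source lie in the fully sampled region.
#' @keywords internal
calibration_placements <- function(n_pe, n_fe, scheme, win, offset) {
  acs <- acs_lines(scheme, n_pe)
  if (length(acs) == 0L) stop("scheme has no ACS block to calibrate on")
  R <- scheme$R
  lo <- min(acs); hi <- max(acs)
  tmin <- min(win$t_range); tmax <- max(win$t_range)
  # target row r needs r and r - offset + t*R in [lo, hi] for all t,
  # and must sit at offset `offset` from the regular R-grid (0-based),
  # the same geometry synthesis fills
  rlo <- max(lo, lo + offset - tmin * R)
  rhi <- min(hi, hi + offset - tmax * R)
  rows <- if (rlo <= rhi) rlo:rhi else integer(0)
  rows <- rows[(rows - 1L) %% R == offset]
  h1 <- min(win$h_range); h2 <- max(win$h_range)
  clo <- 1L - h1
  chi <- n_fe - h2
  if (length(rows) == 0L || clo > chi)
    stop("interpolation window too large for the ACS block: no valid calibration placement")
  list(rows = as.integer(rows), cols = as.integer(clo:chi))
}

#' Extract a GRAPPA calibration set
#'
#' Builds the linear system `y ~ A w` for one (target coil, offset) pair
#' from the auto-calibration region: one row of `A` (the window sources over
#' all coils) and one entry of `y` (the target sample) per placement whose
#' target and all `M` sources lie inside the fully sampled ACS block.
#' Target rows sit at offset `m` from the regular R-grid — exactly the
#' geometry that synthesis later fills — so the fitted weights see the same
#' source layout they will be applied to.
#'
#' @param ks an [multicoil_kspace()].
#' @param scheme the [sampling_scheme()] that defines ACS geometry.
#' @param win an [interp_window()].
#' @param target_coil 1-based coil index of the target samples.
#' @param offset offset `m` in `1..R-1` from the preceding acquired line.
#' @return an object of class `calibration_set` with fields `A`
#'   (`l x M` complex), `y` (length-`l` complex), `target_coil`, `offset`,
#'   `rows`, `cols`, `window`.
#' @export
extract_calibration_pairs <- function(ks, scheme, win, target_coil, offset) {
  stopifnot(inherits(ks, "mc_kspace"), inherits(scheme, "sampling_scheme"),
            inherits(win, "interp_window"))
  d <- dim(ks$data)
  stopifnot(target_coil >= 1L, target_coil <= d[3],
            offset >= 1L, offset <= scheme$R - 1L)
  pl <- calibration_placements(d[1], d[2], scheme, win, offset)
  A <- build_source_matrix(ks$data, pl$rows, pl$cols, win, offset, scheme$R)
  tr <- rep(pl$rows, times = length(pl$cols))
  tc <- rep(pl$cols, each = length(pl$rows))
  y <- ks$data[cbind(tr, tc, target_coil)]
  structure(list(A = A, y = y, target_coil = as.integer(target_coil),
                 offset = as.integer(offset), rows = pl$rows, cols = pl$cols,
                 window = win),
            class = "calibration_set")
}

#' Fill missing k-space samples with a predictor
#'
#' For every non-acquired PE line, applies the per-(coil, offset) predictor
#' to the window source vectors of each missing sample and writes the
#' predictions in place.  Acquired samples — including the ACS block — are
#' preserved verbatim.  Source ordering equals that of
#' [extract_calibration_pairs()]; sources outside the grid are zeros.
#'
#' @param ks an undersampled [multicoil_kspace()].
#' @param predictor `function(coil, offset, sources)` returning a complex
#'   vector of one prediction per row of the `n x M` source matrix.  Must be
#'   defined for every coil and every offset `1..R-1`.
#' @param win an [interp_window()].
#' @param scheme the [sampling_scheme()].
#' @return an `mc_kspace` with every line filled (mask unchanged, recording
#'   what was actually measured).
#' @export
synthesize_missing <- function(ks, predictor, win, scheme) {
  stopifnot(inherits(ks, "mc_kspace"), is.function(predictor))
  d <- dim(ks$data)
  R <- scheme$R
  if (R == 1L || all(ks$mask)) return(ks)
  data <- ks$data
  cols <- seq_len(d[2])
  for (m in seq_len(R - 1L)) {
    rows <- which(!ks$mask & ((seq_len(d[1]) - 1L) %% R == m))
    if (length(rows) == 0L) next
    S <- build_source_matrix(ks$data, rows, cols, win, m, R)
    tr <- rep(rows, times = d[2])
    tc <- rep(cols, each = length(rows))
    for (l in seq_len(d[3])) {
      pred <- predictor(l, m, S)
      if (length(pred) != nrow(S))
        stop("predictor returned wrong number of values")
      if (!all(is.finite(Re(pred))) || !all(is.finite(Im(pred))))
        stop("predictor returned non-finite values")
      data[cbind(tr, tc, rep(l, length(tr)))] <- pred
    }
  }
  multicoil_kspace(data, acquired_mask = ks$mask, delta_k = ks$delta_k)
}
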