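# Shared fixtures, all generated in code.

# k-space in which every missing sample is an exact linear combination of
# its window sources.  The interpolation rule uses one real weight vector
# per target coil so the part-decoupled (real/imaginary) regression model
# also contains the truth; acquired regular lines are i.i.d. complex
# Gaussian, rows at each offset are then overwritten by the rule.
make_exact_linear_kspace <- function(n = 64L, L = 3L, R = 2L,
                                     win = interp_window(2, 3),
                                     n_acs = 16L, seed = 1L,
                                     complex_weights = FALSE) {
  set.seed(seed)
  M <- L * win$n_pe_blocks * win$n_fe_cols
  W <- if (complex_weights) {
    matrix(complex(real = rnorm(M * L, sd = 0.3),
                   imaginary = rnorm(M * L, sd = 0.3)), M, L)
  } else {
    matrix(rnorm(M * L, sd = 0.3), M, L) + 0i
  }
  data <- array(complex(real = rnorm(n * n * L), imaginary = rnorm(n * n * L)),
                c(n, n, L))
  full <- data
  cols <- seq_len(n)
  for (m in seq_len(R - 1L)) {
    rows <- which((seq_len(n) - 1L) %% R == m)
    S <- psvrgrappa:::build_source_matrix(data, rows, cols, win, m, R)
    tr <- rep(rows, times = n)
    tc <- rep(cols, each = length(rows))
    for (l in seq_len(L)) full[cbind(tr, tc, l)] <- S %*% W[, l]
  }
  list(full = multicoil_kspace(full), weights = W,
       scheme = sampling_scheme(R, n_acs), win = win)
}

# independent brute-force enumeration of calibration placements and pairs,
# written directly from the interpolation geometry (per-sample loops)
brute_force_calibration <- function(ks, scheme, win, target_coil, offset) {
  d <- dim(ks$data)
  acs <- acs_lines(scheme, d[1])
  R <- scheme$R
  rows <- integer(0); cols <- integer(0)
  for (r in seq_len(d[1])) {
    if (!(r %in% acs)) next
    if ((r - 1L) %% R != offset) next
    src_ok <- all((r - offset + win$t_range * R) %in% acs)
    if (!src_ok) next
    for (cc in seq_len(d[2])) {
      if (any(cc + win$h_range < 1L) || any(cc + win$h_range > d[2])) next
      rows <- c(rows, r); cols <- c(cols, cc)
    }
  }
  if (length(rows) == 0L) return(NULL)
  M <- d[3] * win$n_pe_blocks * win$n_fe_cols
  A <- matrix(0i, length(rows), M)
  y <- complex(length(rows))
  for (i in seq_along(rows)) {
    k <- 0L
    for (j in seq_len(d[3])) {
      for (t in win$t_range) {
        for (h in win$h_range) {
          k <- k + 1L
          A[i, k] <- ks$data[rows[i] - offset + t * R, cols[i] + h, j]
        }
      }
    }
    y[i] <- ks$data[rows[i], cols[i], target_coil]
  }
  list(A = A, y = y, rows = rows, cols = cols)
}

# small noiseless multi-coil phantom acquisition for pipeline tests
small_phantom <- function(n = 64L, L = 4L, sigma = 0, seed = 1L) {
  simulate_phantom_kspace(n = n, n_coils = L, sigma = sigma, seed = seed)
}
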