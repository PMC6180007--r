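test_that("undersampling keeps every R-th line plus the centered ACS block", {
  full <- multicoil_kspace(array(complex(real = rnorm(16 * 8 * 2),
                                         imaginary = rnorm(16 * 8 * 2)),
                                 c(16, 8, 2)))
  # R=1: identity
  u1 <- undersample(full, sampling_scheme(1, 0))
  expect_identical(u1$data, full$data)
  expect_true(all(u1$mask))

  # n_pe=16, R=4, 4 ACS centered: {0,4,8,12} u {6,7,8,9} (0-based) = 7 lines
  u4 <- undersample(full, sampling_scheme(4, 4))
  expect_identical(which(u4$mask) - 1L, c(0L, 4L, 6L, 7L, 8L, 9L, 12L))
  expect_true(all(u4$data[!u4$mask, , ] == 0))
  expect_identical(u4$data[u4$mask, , ], full$data[u4$mask, , ])

  # R=2, no ACS: ceiling(n/2) lines
  u2 <- undersample(full, sampling_scheme(2, 0))
  expect_identical(sum(u2$mask), 8L)
  u2b <- undersample(multicoil_kspace(full$data[1:15, , ]), sampling_scheme(2, 0))
  expect_identical(sum(u2b$mask), 8L)  # ceiling(15/2)

  expect_error(undersample(full, sampling_scheme(2, 32)), "n_acs|ACS")
})

test_that("interpolation window bounds follow the bracketing convention", {
  expect_identical(interp_window(2, 1)$t_range, c(0L, 1L))
  expect_identical(interp_window(3, 1)$t_range, c(-1L, 0L, 1L))
  expect_identical(interp_window(4, 1)$t_range, c(-1L, 0L, 1L, 2L))
  expect_identical(interp_window(1, 1)$t_range, 0L)
  expect_identical(interp_window(2, 9)$h_range, -4:4)
  expect_identical(interp_window(2, 2)$h_range, c(-1L, 0L))
  expect_identical(interp_window(2, 1)$h_range, 0L)
})

test_that("calibration extraction matches brute-force enumeration", {
  set.seed(11)
  cases <- list(
    list(n_pe = 16L, n_fe = 4L, L = 1L, R = 2L, acs = 3L, win = interp_window(1, 1)),
    list(n_pe = 24L, n_fe = 12L, L = 2L, R = 3L, acs = 9L, win = interp_window(2, 3)),
    list(n_pe = 32L, n_fe = 16L, L = 3L, R = 2L, acs = 10L, win = interp_window(2, 4)),
    list(n_pe = 32L, n_fe = 10L, L = 2L, R = 4L, acs = 12L, win = interp_window(2, 5)))
  for (cs in cases) {
    data <- array(complex(real = rnorm(cs$n_pe * cs$n_fe * cs$L),
                          imaginary = rnorm(cs$n_pe * cs$n_fe * cs$L)),
                  c(cs$n_pe, cs$n_fe, cs$L))
    scheme <- sampling_scheme(cs$R, cs$acs)
    ks <- undersample(multicoil_kspace(data), scheme)
    for (m in seq_len(cs$R - 1L)) {
      cal <- extract_calibration_pairs(ks, scheme, cs$win, 1L, m)
      bf <- brute_force_calibration(ks, scheme, cs$win, 1L, m)
      expect_identical(nrow(cal$A), nrow(bf$A))
      # same pair set (possibly different enumeration order)
      cr <- rep(cal$rows, times = length(cal$cols))
      cc <- rep(cal$cols, each = length(cal$rows))
      oc <- order(cr, cc); ob <- order(bf$rows, bf$cols)
      expect_equal(cal$A[oc, , drop = FALSE], bf$A[ob, , drop = FALSE])
      expect_equal(cal$y[oc], bf$y[ob])
    }
  }
})

test_that("calibration errors when the window cannot fit the ACS", {
  sim <- small_phantom(n = 32, L = 2)
  scheme <- sampling_scheme(2, 4)
  ks <- undersample(sim$kspace, scheme)
  expect_error(extract_calibration_pairs(ks, scheme, interp_window(8, 3), 1, 1),
               "window too large")
  expect_error(extract_calibration_pairs(ks, sampling_scheme(2, 0),
                                         interp_window(2, 3), 1, 1),
               "ACS")
})

test_that("synthesize_missing preserves acquired data and obeys the predictor", {
  sim <- small_phantom(n = 32, L = 2)
  scheme <- sampling_scheme(2, 8)
  win <- interp_window(2, 3)
  und <- undersample(sim$kspace, scheme)

  # constant-zero predictor: missing samples zero, acquired untouched
  z <- synthesize_missing(und, function(l, m, S) rep(0i, nrow(S)), win, scheme)
  expect_identical(z$data[und$mask, , ], und$data[und$mask, , ])
  expect_true(all(z$data[!z$mask, , ] == 0))

  # R=1: identity
  full <- sim$kspace
  expect_identical(synthesize_missing(full, function(l, m, S) stop("never"),
                                      win, sampling_scheme(1, 0)),
                   full)

  # non-finite predictions rejected
  expect_error(synthesize_missing(und, function(l, m, S) rep(NaN + 0i, nrow(S)),
                                  win, scheme),
               "non-finite")
})

test_that("exact ground-truth linear rule round-trips through synthesis", {
  fx <- make_exact_linear_kspace(n = 48, L = 2, R = 3, win = interp_window(2, 3),
                                 n_acs = 15, seed = 3)
  und <- undersample(fx$full, fx$scheme)
  predictor <- function(l, m, S) drop(S %*% fx$weights[, l])
  rec <- synthesize_missing(und, predictor, fx$win, fx$scheme)
  expect_lt(max(abs(rec$data - fx$full$data)), 1e-12)
})

test_that("ifft_and_sos combines coil magnitudes pixelwise", {
  # single coil: |coil image|
  img <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  ks1 <- multicoil_kspace(array(fft2c(img), c(8, 8, 1)))
  expect_equal(ifft_and_sos(ks1), Mod(img), tolerance = 1e-12)

  # 3-4-5 at a pixel
  a <- matrix(0i, 8, 8); a[3, 5] <- 3 + 0i
  b <- matrix(0i, 8, 8); b[3, 5] <- 4i
  ks2 <- multicoil_kspace(array(c(fft2c(a), fft2c(b)), c(8, 8, 2)))
  expect_equal(ifft_and_sos(ks2)[3, 5], 5, tolerance = 1e-12)

  # all-zero k-space -> all-zero image (mask must keep one line "acquired")
  ks0 <- multicoil_kspace(array(0i, c(8, 8, 1)))
  expect_true(all(ifft_and_sos(ks0) == 0))
})
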