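test_that("grappa_calibrate solves the least-squares system", {
  set.seed(50)
  # full-rank recovery of known weights
  A <- matrix(complex(real = rnorm(40 * 6), imaginary = rnorm(40 * 6)), 40, 6)
  w <- complex(real = rnorm(6), imaginary = rnorm(6))
  cal <- structure(list(A = A, y = drop(A %*% w), target_coil = 1L,
                        offset = 1L), class = "calibration_set")
  expect_lt(max(abs(grappa_calibrate(cal) - w)) / max(abs(w)), 1e-10)

  # identity source matrix returns the targets
  y <- complex(real = rnorm(5), imaginary = rnorm(5))
  cal_i <- structure(list(A = diag(5) + 0i, y = y), class = "calibration_set")
  expect_equal(grappa_calibrate(cal_i), y)

  # zero targets give the zero (minimum-norm) solution
  cal_0 <- structure(list(A = A, y = rep(0 + 0i, 40)), class = "calibration_set")
  expect_equal(grappa_calibrate(cal_0), rep(0 + 0i, 6))
})

test_that("reconstructions are identity at R = 1 and preserve acquired data", {
  sim <- small_phantom(n = 32, L = 2, sigma = 0.01)
  s1 <- sampling_scheme(1, 0)
  expect_identical(grappa_reconstruct(sim$kspace, s1, interp_window(2, 3)),
                   sim$kspace)
  expect_identical(psvr_grappa_reconstruct(sim$kspace, s1, interp_window(2, 3)),
                   sim$kspace)

  scheme <- sampling_scheme(2, 10); win <- interp_window(2, 3)
  und <- undersample(sim$kspace, scheme)
  for (rec in list(grappa_reconstruct(und, scheme, win),
                   psvr_grappa_reconstruct(und, scheme, win,
                                           kernel = kernel_spec("linear")))) {
    expect_identical(rec$data[und$mask, , ], und$data[und$mask, , ])
    expect_true(all(rec$data[!und$mask, , ] != 0))
  }
})

test_that("exact linear model is recovered by both reconstruction paths", {
  fx <- make_exact_linear_kspace(n = 64, L = 3, R = 2,
                                 win = interp_window(2, 3), n_acs = 16, seed = 1)
  und <- undersample(fx$full, fx$scheme)
  ref <- ifft_and_sos(fx$full)

  rec_ls <- grappa_reconstruct(und, fx$scheme, fx$win)
  expect_lt(nmse(ifft_and_sos(rec_ls), ref), 1e-8)

  rec_psvr <- psvr_grappa_reconstruct(und, fx$scheme, fx$win,
                                      kernel = kernel_spec("linear"))
  expect_lt(nmse(ifft_and_sos(rec_psvr), ref), 1e-3)
})

test_that("PSVR with huge C approaches biased least squares (ridge limit)", {
  fx <- make_exact_linear_kspace(n = 48, L = 2, R = 2,
                                 win = interp_window(2, 3), n_acs = 12, seed = 2)
  und <- undersample(fx$full, fx$scheme)
  a <- ifft_and_sos(psvr_grappa_reconstruct(und, fx$scheme, fx$win,
                                            kernel = kernel_spec("linear"),
                                            C = 1e8))
  b <- ifft_and_sos(grappa_reconstruct(und, fx$scheme, fx$win, bias = TRUE))
  expect_lt(nmse(a, b), 1e-3)
})

test_that("reconstruction error grows with the reduction factor (noiseless)", {
  sim <- small_phantom(n = 64, L = 4, sigma = 0)
  win <- interp_window(2, 5)
  e2 <- reconstruct_report(sim$kspace, sampling_scheme(2, 16), win, "grappa")$nmse
  e4 <- reconstruct_report(sim$kspace, sampling_scheme(4, 16), win, "grappa")$nmse
  expect_lt(e2, e4)
})

test_that("PSVR-GRAPPA is deterministic for fixed inputs", {
  sim <- small_phantom(n = 32, L = 2, sigma = 0.02, seed = 9)
  scheme <- sampling_scheme(2, 10); win <- interp_window(2, 3)
  und <- undersample(sim$kspace, scheme)
  r1 <- psvr_grappa_reconstruct(und, scheme, win, l_max = 50L)
  r2 <- psvr_grappa_reconstruct(und, scheme, win, l_max = 50L)
  expect_identical(r1$data, r2$data)
})

test_that("all-zero missing input reconstructs to zero under PSVR", {
  d <- array(0i, c(16, 16, 1))
  scheme <- sampling_scheme(2, 8)
  mask <- rep(FALSE, 16); mask[acquired_lines(scheme, 16)] <- TRUE
  ks <- multicoil_kspace(d, acquired_mask = mask)
  rec <- psvr_grappa_reconstruct(ks, scheme, interp_window(2, 3))
  expect_true(all(rec$data == 0))
})

test_that("NMSE and PSNR identities hold", {
  ref <- matrix(runif(64, 0.1, 1), 8, 8)
  expect_equal(nmse(ref, ref), 0)
  expect_equal(nmse(2 * ref, ref), 1)
  expect_equal(nmse(matrix(0, 8, 8), ref), 1)
  expect_error(nmse(ref, matrix(0, 8, 8)), "zero")
  expect_error(nmse(ref, matrix(1, 4, 4)), "shapes")

  expect_equal(psnr(1), 10 * log10(255^2))
  expect_equal(psnr(255^2), 0)
  expect_equal(psnr(0.5) - psnr(1), 10 * log10(2))
  expect_identical(psnr(0), Inf)
  # strictly decreasing
  v <- sapply(c(0.01, 0.1, 1, 10), psnr)
  expect_true(all(diff(v) < 0))
})

test_that("reconstruct_report ties the pieces together", {
  sim <- small_phantom(n = 32, L = 2, sigma = 0.01)
  rep <- reconstruct_report(sim$kspace, sampling_scheme(2, 10),
                            interp_window(2, 3), "grappa")
  expect_s3_class(rep, "recon_report")
  expect_equal(rep$reference_image, ifft_and_sos(sim$kspace))
  expect_equal(rep$psnr, psnr(rep$nmse))
  expect_gt(rep$nmse, 0)
})
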