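test_that("phantom rendering follows the ellipse superposition", {
  # empty superposition
  img0 <- make_phantom(phantom_spec(c(16, 16)))
  expect_true(all(img0 == 0))

  # one huge ellipse, unit intensity, no ramp: indicator image
  big <- phantom_spec(c(32, 32), list(list(center = c(0, 0), axes = c(10, 10),
                                           angle = 0, intensity = 1)))
  img1 <- make_phantom(big)
  expect_equal(img1[17, 17], 1 + 0i)  # grid center (0-based 16)
  expect_true(all(img1 %in% c(0 + 0i, 1 + 0i)))

  # overlapping ellipses add, checked against per-pixel brute force
  spec <- phantom_spec(c(24, 24), list(
    list(center = c(0, -0.2), axes = c(0.6, 0.5), angle = 0.3, intensity = 1),
    list(center = c(0.1, 0.2), axes = c(0.5, 0.7), angle = -0.2, intensity = 0.5)))
  img <- make_phantom(spec)
  ny <- 24; nx <- 24
  brute <- matrix(0, ny, nx)
  for (iy in 1:ny) for (ix in 1:nx) {
    y <- (iy - 1 - floor(ny / 2)) / (ny / 2)
    x <- (ix - 1 - floor(nx / 2)) / (nx / 2)
    for (e in spec$ellipses) {
      dy <- y - e$center[1]; dx <- x - e$center[2]
      u <- cos(e$angle) * dy + sin(e$angle) * dx
      v <- -sin(e$angle) * dy + cos(e$angle) * dx
      if ((u / e$axes[1])^2 + (v / e$axes[2])^2 <= 1)
        brute[iy, ix] <- brute[iy, ix] + e$intensity
    }
  }
  expect_equal(Re(img), brute, tolerance = 1e-12)
  expect_true(any(abs(img - 1.5) < 1e-12))  # overlap pixels sum

  # degenerate ellipse rejected
  expect_error(phantom_spec(c(16, 16), list(list(center = c(0, 0),
                                                 axes = c(0, 1), angle = 0,
                                                 intensity = 1))),
               "degenerate")
})

test_that("coil sensitivity maps are smooth, complex and dead-zone free", {
  # flat limit: one coil, infinite width, zero phase
  flat <- make_sensitivities(coil_array_spec(1, profile_width = Inf,
                                             phase_coeffs = matrix(0, 1, 2)),
                             grid = c(16, 16))
  expect_equal(flat[, , 1], matrix(1 + 0i, 16, 16))

  # default circular array: no dead zone
  sens <- make_sensitivities(coil_array_spec(8, profile_width = 24),
                             grid = c(32, 32))
  sos2 <- apply(abs(sens)^2, c(1, 2), sum)
  expect_gt(min(sos2), 0)

  # two mirrored coils give mirrored magnitude maps
  n <- 32
  c1 <- c(n / 2, -4)
  c2 <- c(n / 2, (n - 1) - (-4))
  sens2 <- make_sensitivities(
    coil_array_spec(2, profile_centers = rbind(c1, c2), profile_width = 10,
                    phase_coeffs = matrix(0, 2, 2)),
    grid = c(n, n))
  m1 <- Mod(sens2[, , 1]); m2 <- Mod(sens2[, , 2])
  expect_equal(m2, m1[, n:1], tolerance = 1e-12)

  expect_error(coil_array_spec(0), "n_coils")
})

test_that("k-space simulation is a unitary transform plus seeded noise", {
  sim <- small_phantom(n = 32, L = 3, sigma = 0)
  # noiseless Fourier round trip recovers each coil image
  for (l in 1:3) {
    back <- ifft2c(sim$kspace$data[, , l])
    truth <- sim$sens[, , l] * sim$image
    expect_lt(max(abs(back - truth)) / max(abs(truth)), 1e-10)
  }

  # impulse image with flat sensitivity: constant k-space magnitude
  img <- matrix(0i, 16, 16); img[9, 9] <- 1  # center (0-based 8)
  flat <- array(1 + 0i, c(16, 16, 1))
  ks <- simulate_kspace(img, flat, noise_spec(0))
  expect_equal(max(abs(ks$data)) - min(abs(ks$data)), 0, tolerance = 1e-12)

  # determinism and seed sensitivity
  a <- simulate_kspace(img, flat, noise_spec(0.1, seed = 5))
  b <- simulate_kspace(img, flat, noise_spec(0.1, seed = 5))
  c <- simulate_kspace(img, flat, noise_spec(0.1, seed = 6))
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))

  expect_error(simulate_kspace(img, array(1 + 0i, c(8, 8, 1)), noise_spec(0)),
               "shape")
})

test_that("noise level matches its specification empirically", {
  n <- 64; L <- 4  # 16384 samples
  sim0 <- simulate_phantom_kspace(n = n, n_coils = L, sigma = 0, seed = 1)
  sig <- 0.05
  sim1 <- simulate_phantom_kspace(n = n, n_coils = L, sigma = sig, seed = 1)
  noise <- sim1$kspace$data - sim0$kspace$data
  target <- sig * max(abs(sim0$kspace$data))
  emp <- sqrt(mean(Mod(noise)^2))
  expect_lt(abs(emp - target) / target, 0.05)
})

test_that("SOS of noiseless coil images equals |image| * sqrt(sum |sens|^2)", {
  sim <- small_phantom(n = 32, L = 4, sigma = 0)
  sos <- ifft_and_sos(sim$kspace)
  direct <- Mod(sim$image) * sqrt(apply(abs(sim$sens)^2, c(1, 2), sum))
  expect_equal(sos, direct, tolerance = 1e-10)
})
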