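# Forward operator, least-squares reconstruction, SNR propagation and PSF
# characterization.

test_that("kernel and brute-force system matrices agree on a 9x9 grid", {
  p <- smooth_protocol(n_projections = 4, n_points = 9)
  grid <- recon_grid(3, 3, 0.04)
  Ak <- build_system_matrix(p, grid, method = "kernel")
  Ad <- build_system_matrix(p, grid, method = "direct")
  expect_equal(dim(Ak), c(4 * 9, 9))
  expect_lt(max(abs(Ak - Ad)) / max(abs(Ad)), 1e-6)
})

test_that("reconstruction inverts the forward model", {
  p <- smooth_protocol(n_projections = 12, n_points = 15)
  grid <- recon_grid(5, 5, 0.03)
  A <- build_system_matrix(p, grid)
  set.seed(1)
  x_true <- runif(25)
  b <- as.vector(A %*% x_true)
  for (method in c("cg", "direct")) {
    img <- reconstruct(b, A, ridge = 0, method = method)
    expect_lt(max(abs(img$pixels - x_true)) / max(x_true), 1e-7)
  }
  expect_error(reconstruct(b[-1], A), "size mismatch")
})

test_that("direct reconstruction is exactly linear in the data", {
  p <- smooth_protocol(n_projections = 6, n_points = 9)
  grid <- recon_grid(5, 5, 0.03)
  A <- build_system_matrix(p, grid)
  set.seed(2)
  b1 <- rnorm(nrow(A)); b2 <- rnorm(nrow(A))
  r <- default_ridge(A)
  x1 <- reconstruct(b1, A, ridge = r, method = "direct")$pixels
  x2 <- reconstruct(b2, A, ridge = r, method = "direct")$pixels
  x12 <- reconstruct(b1 + 2 * b2, A, ridge = r, method = "direct")$pixels
  expect_equal(x12, x1 + 2 * x2, tolerance = 1e-10)
})

test_that("noiseless point sources localize to their pixel at 9 offsets", {
  p <- smooth_protocol(n_projections = 8, n_points = 11)
  grid <- default_grid(p)          # 11 x 11 over the FOV
  A <- build_system_matrix(p, grid)
  r <- default_ridge(A)
  for (ix in c(3, 6, 9)) {
    for (iy in c(3, 6, 9)) {
      pix <- ix + (iy - 1) * grid$n_x
      ph <- make_point_phantom(grid$centers[pix, ], 1e-9)
      b <- acquire_sinogram(ph, p, noiseless = TRUE)
      img <- reconstruct(b, A, ridge = r, method = "direct")
      expect_equal(which.max(img$pixels), pix)
    }
  }
})

test_that("analytic SNR scales as 1/sigma and sqrt(n_averages)", {
  grid <- recon_grid(7, 7, 0.025)
  ph <- make_point_phantom(c(0.025, 0, 0), 1e-9)
  p1 <- smooth_protocol(n_projections = 6, n_points = 9,
                        noise_sigma = 1e-9, n_averages = 1)
  A <- build_system_matrix(p1, grid)
  s1 <- snr_map(ph, p1, grid, system_matrix = A)
  p2 <- smooth_protocol(n_projections = 6, n_points = 9,
                        noise_sigma = 2e-9, n_averages = 1)
  s2 <- snr_map(ph, p2, grid, system_matrix = A)
  expect_equal(s1$max_snr / s2$max_snr, 2, tolerance = 1e-12)
  p200 <- smooth_protocol(n_projections = 6, n_points = 9,
                          noise_sigma = 1e-9, n_averages = 200)
  s200 <- snr_map(ph, p200, grid, system_matrix = A)
  expect_equal(s200$max_snr / s1$max_snr, sqrt(200), tolerance = 1e-12)
  # Monte-Carlo with a shared seed reproduces the averaging law exactly
  m1 <- snr_map(ph, p1, grid, method = "monte_carlo", seed = 5, system_matrix = A)
  m200 <- snr_map(ph, p200, grid, method = "monte_carlo", seed = 5, system_matrix = A)
  expect_equal(m200$max_snr / m1$max_snr, sqrt(200), tolerance = 1e-9)
  expect_error(snr_map(ph, smooth_protocol(), grid), "noise_sigma")
})

test_that("Monte-Carlo SNR agrees with analytic propagation", {
  grid <- recon_grid(5, 5, 0.03)
  ph <- make_point_phantom(c(0, 0, 0), 1e-9)
  p <- smooth_protocol(n_projections = 6, n_points = 9, noise_sigma = 1e-9)
  A <- build_system_matrix(p, grid)
  sa <- snr_map(ph, p, grid, system_matrix = A)
  sm <- snr_map(ph, p, grid, method = "monte_carlo", n_realizations = 500,
                seed = 11, system_matrix = A)
  expect_equal(sm$max_snr, sa$max_snr, tolerance = 0.1)
  expect_equal(sm$image, sa$image, tolerance = 1e-12)   # same noiseless image
})

test_that("PSF fits recover synthetic Gaussian and Lorentzian shapes", {
  x <- seq(-0.1, 0.1, length.out = 81)
  g <- 3 * exp(-(x - 0.01)^2 / (2 * 0.02^2))
  fg <- fit_projection_psf(g, x)
  expect_identical(fg$best, "gaussian")
  expect_equal(fg$fwhm, 2 * sqrt(2 * log(2)) * 0.02, tolerance = 1e-6)
  l <- 2 / (1 + ((x + 0.005) / 0.015)^2)
  fl <- fit_projection_psf(l, x)
  expect_identical(fl$best, "lorentzian")
  expect_equal(fl$fwhm, 2 * 0.015, tolerance = 1e-6)
  expect_equal(unname(fl$lorentzian$par[["mu"]]), -0.005, tolerance = 1e-6)
})

test_that("projection FWHM scales inversely with the gradient", {
  fwhm_at <- function(G) {
    p <- scan_protocol(drive_amplitude = 25e-3, drive_frequency = 1e4, Gx = G,
                       fov = 0.2, n_projections = 1, n_points = 41,
                       sample_rate = 2e5, periods_per_point = 2,
                       spion = spion_model(128, 80),
                       receive = uniform_receive(9.26e-5))
    sg <- acquire_sinogram(make_point_phantom(c(0, 0, 0), 1e-9), p,
                           noiseless = TRUE)
    fit_projection_psf(sg$values[1, ], sg$shift_positions)$fwhm
  }
  w15 <- fwhm_at(1.5)
  w30 <- fwhm_at(3.0)
  expect_gt(w15, 0)
  expect_equal(w15 / w30, 2, tolerance = 0.05)
})

test_that("grids and image reshaping are consistent", {
  g <- recon_grid(4, 3, 0.01)
  expect_equal(nrow(g$centers), 12)
  expect_equal(mean(g$x), 0, tolerance = 1e-15)
  expect_equal(diff(g$x), rep(0.01, 3), tolerance = 1e-15)
  img <- structure(list(pixels = 1:12), class = "ffl_image")
  m <- image_matrix(img, g)
  expect_equal(dim(m), c(4, 3))
  expect_equal(m[2, 3], 10)
  dg <- default_grid(human_protocol())
  expect_equal(dg$n_x, 35)
  expect_equal(dg$pitch, 0.2 / 35, tolerance = 1e-15)
  path <- tempfile(fileext = ".csv")
  image_to_csv(m, g, path)
  expect_equal(read.csv(path)$value, 1:12)
})
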