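# Field geometry, signal synthesis, harmonic detection and sinogram
# acquisition.

test_that("rotation matrix is orthonormal and maps the projection axis as expected", {
  for (th in c(0, 0.3, pi / 2, 2, pi)) {
    R <- rotation_matrix(th)
    expect_equal(R %*% t(R), diag(3), tolerance = 1e-14)
    expect_equal(det(R), 1, tolerance = 1e-14)
  }
  # at 90 degrees the gantry x' axis lies along patient -y
  expect_equal(as.vector(rotation_matrix(pi / 2) %*% c(1, 0, 0)), c(0, -1, 0),
               tolerance = 1e-14)
})

test_that("ideal FFL field has the right gradients and zero locus", {
  f <- function(p) ideal_ffl_field(1.5, 1.5, 0, 0, p)
  expect_equal(gradient_at(f, c(0, 0, 0), c(1, 0, 0)), 1.5, tolerance = 1e-9)
  expect_equal(gradient_at(f, c(0, 0, 0), c(0, 0, 1)), -1.5, tolerance = 1e-9)
  expect_equal(gradient_at(f, c(0, 0, 0), c(0, 1, 0)), 0, tolerance = 1e-12)
  # shifted FFL: zero along the line x' = -shift/Gx at any y'
  for (th in c(0, 0.7)) {
    Rm <- rotation_matrix(th)
    p <- as.vector(Rm %*% c(-0.06 / 1.5, 0.03, 0))
    B <- ideal_ffl_field(1.5, 1.5, th, 0.06, p)
    expect_lt(max(abs(B)), 1e-15)
  }
  expect_error(ideal_ffl_field(0, 1, 0, 0.1, c(0, 0, 0)), "degenerate")
})

test_that("shift schedule spans the FOV with the published amplitudes", {
  s <- shift_schedule(human_protocol())
  expect_equal(range(s$positions), c(-0.1, 0.1), tolerance = 1e-15)
  expect_equal(range(s$amplitudes), c(-0.15, 0.15), tolerance = 1e-15)
  mid <- (length(s$positions) + 1) / 2
  expect_equal(s$amplitudes[mid], 0, tolerance = 1e-15)
  # 81 points over 20 cm -> 2.5 mm pitch
  p81 <- smooth_protocol(n_points = 81)
  d <- diff(shift_schedule(p81)$positions)
  expect_equal(d, rep(0.0025, 80), tolerance = 1e-12)
})

test_that("total field is the static FFL field plus the z drive", {
  p <- smooth_protocol()
  t <- c(0, 1e-5, 2.5e-5)
  pt <- c(0.03, -0.01, 0.02)
  B <- total_field(p, 0.4, 2, pt, t)
  stat <- ideal_ffl_field(p$Gx, p$Gz, 0.4, shift_schedule(p)$amplitudes[2], pt)
  drive <- p$drive_amplitude * sin(2 * pi * p$drive_frequency * t)
  expect_equal(B, cbind(stat[1, 1], stat[1, 2], stat[1, 3] + drive),
               tolerance = 1e-14)
  expect_error(total_field(p, 0, 99, pt, 0), "schedule")
})

test_that("spectral derivative is exact for band-limited periodic records", {
  fs <- 2e5
  t <- (0:199) / fs
  x <- 3 * sin(2 * pi * 1e4 * t + 0.2) + 0.5 * cos(2 * pi * 3e4 * t)
  dx <- 3 * 2 * pi * 1e4 * cos(2 * pi * 1e4 * t + 0.2) -
    0.5 * 2 * pi * 3e4 * sin(2 * pi * 3e4 * t)
  expect_equal(spectral_derivative(x, fs), dx, tolerance = 1e-9)
})

test_that("spectral derivative agrees with an independent fine-grid finite difference", {
  # independent path: synthesize the same flux at 400 samples/period,
  # differentiate by 2nd-order central differences there, compare at the
  # 20-per-period subsamples
  f0 <- 1e4
  fs <- 2e5
  sp <- spion_model(128, 300)
  # a mild drive keeps the response harmonic-limited so both 20-sample
  # representations are band-limited; harder drives alias above Nyquist in
  # both paths identically and are covered by the acquisition tests
  flux_at <- function(fsamp) {
    n <- round(4 * fsamp / f0)
    tt <- (0:(n - 1)) / fsamp
    d <- 5e-3 * sin(2 * pi * f0 * tt)
    bx <- 1.5 * 0.004
    nb <- sqrt(bx^2 + d^2)
    9e-5 * 1e-9 * sp$s_sat * langevin(sp$beta * nb) / nb * d
  }
  v_spec <- spectral_derivative(flux_at(fs), fs)
  up <- 20
  xf <- flux_at(fs * up)
  nf <- length(xf)
  v_fd <- (xf[c(2:nf, 1)] - xf[c(nf, 1:(nf - 1))]) * fs * up / 2
  v_fd <- v_fd[seq(1, nf, by = up)]
  rms_rel <- sqrt(mean((v_spec - v_fd)^2)) / sqrt(mean(v_fd^2))
  expect_lt(rms_rel, 1e-3)
})

test_that("harmonic coefficients recover amplitude and phase of known tones", {
  fs <- 2e5
  n <- 400   # 20 periods of 10 kHz
  t <- (0:(n - 1)) / fs
  x <- 2.5 * cos(2 * pi * 3e4 * t + 0.4) + 1.2 * cos(2 * pi * 5e4 * t - 1.1)
  ch <- harmonic_coefficients(x, 1e4, c(1, 3, 5), sample_rate = fs)
  expect_lt(Mod(ch[1]), 1e-12)
  expect_equal(Mod(ch[2]), 2.5, tolerance = 1e-12)
  expect_equal(Arg(ch[2]), 0.4, tolerance = 1e-12)
  expect_equal(Mod(ch[3]), 1.2, tolerance = 1e-12)
  expect_equal(Arg(ch[3]), -1.1, tolerance = 1e-12)
  expect_error(harmonic_coefficients(x[1:399], 1e4, 3, sample_rate = fs),
               "leakage")
  expect_error(harmonic_coefficients(x, 1e4, 11, sample_rate = fs), "Nyquist")
})

test_that("even harmonics of the Langevin response are suppressed", {
  p <- smooth_protocol(n_points = 3, fov = 0.02)
  ph <- make_point_phantom(c(0.004, 0, 0), 1e-9)
  ts <- simulate_voltage(ph, p, 0, 2)
  ch <- harmonic_coefficients(ts, p$drive_frequency, c(2, 3, 4, 6))
  expect_lt(max(Mod(ch[c(1, 3, 4)])) / Mod(ch[2]), 1e-10)
})

test_that("projection of a centered source is symmetric and shift-consistent", {
  p <- smooth_protocol(n_projections = 1, n_points = 9, fov = 0.08)
  ph <- make_point_phantom(c(0, 0, 0), 1e-9)
  for (method in c("kernel", "direct")) {
    sg <- acquire_sinogram(ph, p, noiseless = TRUE, method = method)
    v <- sg$values[1, ]
    expect_equal(v, rev(v), tolerance = 1e-8)
  }
  # direct path: moving the source with the FFL leaves the value unchanged
  pos <- shift_schedule(p)$positions
  v_moved <- simulate_voltage(make_point_phantom(c(pos[7], 0, 0), 1e-9), p, 0, 7)
  v_centered <- simulate_voltage(ph, p, 0, 5)
  expect_equal(v_moved$samples, v_centered$samples, tolerance = 1e-12)
})

test_that("sinograms are linear in iron mass", {
  p <- smooth_protocol(n_projections = 3, n_points = 7)
  pos <- rbind(c(0.02, 0.01, 0), c(-0.03, 0.04, 0))
  s1 <- acquire_sinogram(make_point_phantom(pos, c(1e-9, 2e-9)), p, noiseless = TRUE)
  s2 <- acquire_sinogram(make_point_phantom(pos, 3 * c(1e-9, 2e-9)), p, noiseless = TRUE)
  expect_equal(s2$values, 3 * s1$values, tolerance = 1e-12)
  # and additive over sources
  sa <- acquire_sinogram(make_point_phantom(pos[1, ], 1e-9), p, noiseless = TRUE)
  sb <- acquire_sinogram(make_point_phantom(pos[2, ], 2e-9), p, noiseless = TRUE)
  expect_equal(s1$values, sa$values + sb$values, tolerance = 1e-10)
})

test_that("kernel and direct acquisition agree for an off-center source", {
  p <- smooth_protocol(n_projections = 4, n_points = 9)
  ph <- make_point_phantom(rbind(c(0.03, -0.02, 0)), 1e-9)
  sk <- acquire_sinogram(ph, p, noiseless = TRUE, method = "kernel")
  sd <- acquire_sinogram(ph, p, noiseless = TRUE, method = "direct")
  expect_equal(sk$values, sd$values, tolerance = 1e-6)
})

test_that("add_noise is reproducible, unbiased and leaves the RNG state intact", {
  x <- numeric(1e5)
  expect_identical(add_noise(x, 0), x)
  n1 <- add_noise(x, 2, seed = 7)
  n2 <- add_noise(x, 2, seed = 7)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_noise(x, 2, seed = 8)))
  expect_equal(sd(n1), 2, tolerance = 2e-2)
  expect_equal(mean(n1), 0, tolerance = 2e-2 * 2)
  set.seed(123); before <- .Random.seed
  invisible(add_noise(x[1:10], 1, seed = 5))
  expect_identical(.Random.seed, before)
  expect_error(add_noise(x, -1), ">= 0")
})

test_that("sinogram noise has the comb-filtered per-projection std", {
  p <- smooth_protocol(n_projections = 30, n_points = 30,
                       noise_sigma = 1e-8, n_averages = 1)
  empty <- make_point_phantom()
  sg <- acquire_sinogram(empty, p, seed = 3)
  # per-sample sigma through the comb filter: sigma*sqrt(2/N) per harmonic
  expected <- 1e-8 * sqrt(2 / record_length(p)) * sqrt(length(p$harmonics))
  expect_equal(sd(as.vector(sg$values)), expected, tolerance = 0.1)
  # averaging 100 acquisitions reduces the std by 10
  p100 <- smooth_protocol(n_projections = 30, n_points = 30,
                          noise_sigma = 1e-8, n_averages = 100)
  sg100 <- acquire_sinogram(empty, p100, seed = 3)
  expect_equal(sd(as.vector(sg100$values)), expected / 10, tolerance = 0.1)
  # seeded acquisition is reproducible
  expect_identical(acquire_sinogram(empty, p, seed = 3)$values, sg$values)
})

test_that("projection angles cover the half circle uniformly", {
  a <- projection_angles(human_protocol())
  expect_equal(a[1], 0)
  expect_equal(length(a), 53)
  expect_equal(diff(a), rep(pi / 53, 52), tolerance = 1e-12)
  expect_lt(max(a), pi)
})

test_that("sinogram CSV export is long-format and faithful", {
  p <- smooth_protocol(n_projections = 2, n_points = 3)
  sg <- acquire_sinogram(make_point_phantom(c(0, 0, 0), 1e-9), p, noiseless = TRUE)
  path <- tempfile(fileext = ".csv")
  sinogram_to_csv(sg, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 6)
  expect_equal(df$value_V, as.vector(sg$values), tolerance = 1e-12)
})
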