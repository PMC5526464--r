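# Coil construction and Biot-Savart field evaluation against closed forms.

mu0 <- ffl_constants()$mu0

test_that("single circular loop matches the closed-form center field", {
  loop <- make_solenoid(0.05, 0, 1, segments_per_loop = 64)
  B <- biot_savart(loop, c(0, 0, 0))
  # a regular 64-gon inscribed in the circle overshoots mu0/(2R) by
  # n*tan(pi/n)/pi - 1 ~ 8e-4
  expect_equal(B[1, 3], mu0 / (2 * 0.05), tolerance = 2e-3)
  expect_lt(abs(B[1, 1]), 1e-15)
  expect_lt(abs(B[1, 2]), 1e-15)
})

test_that("on-axis loop field matches the exact axial formula", {
  R <- 0.01
  loop <- make_solenoid(R, 0, 1)
  z <- c(0.02, 0.05, 0.1)
  B <- biot_savart(loop, cbind(0, 0, z))
  exact <- mu0 * R^2 / (2 * (R^2 + z^2)^1.5)
  expect_equal(B[, 3], exact, tolerance = 5e-3)
  # far field approaches the dipole law mu0 m / (2 pi z^3), m = pi R^2 I
  dip <- mu0 * pi * R^2 / (2 * pi * 0.1^3)
  expect_equal(B[3, 3], dip, tolerance = 2e-2)
})

test_that("finite solenoid center field matches the closed form", {
  # B_center = mu0 N I / sqrt(l^2 + 4 R^2)
  for (seg in c(32, 64)) {
    a <- make_solenoid(0.025, 0.05, 25, segments_per_loop = seg)
    Ba <- biot_savart(a, c(0, 0, 0))[1, 3]
    expect_equal(Ba, mu0 * 25 / sqrt(0.05^2 + 4 * 0.025^2), tolerance = 5e-3)
  }
  cc <- make_solenoid(0.12, 0.24, 25)
  Bc <- biot_savart(cc, c(0, 0, 0))[1, 3]
  expect_equal(Bc, mu0 * 25 / sqrt(0.24^2 + 4 * 0.12^2), tolerance = 5e-3)
})

test_that("fields superpose and scale linearly with the current multiplier", {
  c1 <- make_solenoid(0.03, 0.02, 3)
  c2 <- make_maxwell_pair(0.05, 0.06, turns = 2)
  pts <- rbind(c(0.01, 0.005, -0.01), c(0, 0.02, 0.015), c(-0.02, 0, 0))
  both <- coil_concat(c1, c2)
  expect_equal(biot_savart(both, pts),
               biot_savart(c1, pts) + biot_savart(c2, pts),
               tolerance = 1e-12)
  doubled <- ffl_coil(c1$start, c1$end, c1$mult * 2)
  expect_equal(biot_savart(doubled, pts), 2 * biot_savart(c1, pts),
               tolerance = 1e-12)
})

test_that("Maxwell and Helmholtz pairs behave as gradient and uniform coils", {
  mx <- make_maxwell_pair(0.1, 0.12, turns = 10, anti_parallel = TRUE)
  Bc <- biot_savart(mx, c(0, 0, 0))
  expect_lt(max(abs(Bc)), 1e-12)             # opposed fields cancel
  f <- coil_field_fun(mx)
  gz <- gradient_at(f, c(0, 0, 0), c(0, 0, 1))
  expect_gt(abs(gz), 0)
  hh <- make_maxwell_pair(0.1, 0.12, turns = 10, anti_parallel = FALSE)
  single <- make_solenoid(0.1, 0, 10)
  B1 <- biot_savart(single, c(0, 0, 0.06))[1, 3] +
    biot_savart(single, c(0, 0, -0.06))[1, 3]
  expect_equal(biot_savart(hh, c(0, 0, 0))[1, 3], B1, tolerance = 1e-12)
  gz_h <- gradient_at(coil_field_fun(hh), c(0, 0, 0), c(0, 0, 1))
  expect_lt(abs(gz_h), 1e-6 * abs(gz))       # uniform sense: null gradient
  expect_equal(maxwell_gradient_estimate(0.13, 0.15), 2 * 0.13 / 0.15)
})

test_that("opposed racetrack pair produces a field-free line with equal transverse gradients", {
  rt <- make_racetrack_pair(1.5, 0.3, 0.3, turns = 360, current = 140)
  f <- coil_field_fun(rt)           # uses the nominal 140 A
  expect_lt(max(abs(f(matrix(c(0, 0, 0), 1)))), 1e-9)
  gx <- gradient_at(f, c(0, 0, 0), c(1, 0, 0), h = 2e-3)
  gz <- gradient_at(f, c(0, 0, 0), c(0, 0, 1), h = 2e-3)
  gy <- gradient_at(f, c(0, 0, 0), c(0, 1, 0), h = 2e-3)
  expect_gt(abs(gx), 0.1)
  # divergence-free, no gradient along the line: Gx ~ -Gz, Gy ~ 0
  expect_equal(gz, -gx, tolerance = 2e-2)
  expect_lt(abs(gy), 1e-2 * abs(gx))
  # field per amp is linear in current
  f2 <- coil_field_fun(rt, current = 280)
  expect_equal(gradient_at(f2, c(0, 0, 0), c(1, 0, 0), h = 2e-3), 2 * gx,
               tolerance = 1e-12)
})

test_that("wire length accounting matches the winding", {
  s <- make_solenoid(0.025, 0.05, 25, segments_per_loop = 64)
  expect_equal(coil_wire_length(s), 25 * 2 * pi * 0.025, tolerance = 1e-3)
  mx <- make_maxwell_pair(0.1, 0.12, turns = 10)
  expect_equal(coil_wire_length(mx), 2 * 10 * 2 * pi * 0.1, tolerance = 1e-3)
  expect_equal(coil_wire_length(mx, weighted = FALSE), 2 * 2 * pi * 0.1,
               tolerance = 1e-3)
})

test_that("degenerate geometries are rejected", {
  expect_error(make_solenoid(-0.01, 0.05, 25), "radius")
  expect_error(make_solenoid(0.01, 0.05, 0), "turns")
  expect_error(make_maxwell_pair(0.1, 0), "spacing")
  expect_error(make_racetrack_pair(0.3, 0.3, 0.3), "long_axis > short_axis")
  expect_error(ffl_coil(rbind(c(0, 0, 0)), rbind(c(0, 0, 0))), "zero-length")
})

test_that("field points on a conductor trigger the singularity guard", {
  loop <- make_solenoid(0.05, 0, 1)
  expect_error(biot_savart(loop, c(0.05, 0, 0)), "singularity")
  expect_silent(biot_savart(loop, c(0.049, 0, 0)))
})

test_that("coil JSON round trip preserves the geometry exactly", {
  rt <- make_racetrack_pair(1.5, 0.3, 0.3, turns = 360, current = 140,
                            segments_per_arc = 8)
  js <- coil_to_json(rt)
  back <- coil_from_json(js)
  expect_equal(back$start, rt$start, tolerance = 1e-12)
  expect_equal(back$end, rt$end, tolerance = 1e-12)
  expect_identical(back$mult, rt$mult)
  expect_equal(back$nominal_current, 140)
  pts <- rbind(c(0.01, 0.02, 0.03))
  expect_equal(biot_savart(back, pts), biot_savart(rt, pts), tolerance = 1e-9)
  # file round trip too
  path <- tempfile(fileext = ".json")
  coil_to_json(rt, path)
  expect_equal(coil_from_json(path)$start, rt$start, tolerance = 1e-12)
})
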