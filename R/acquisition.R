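# Signal synthesis over the discrete shift-and-rotate schedule: total-field
# assembly, reciprocity voltage synthesis, white-noise injection, harmonic
# (comb-filter) detection and sinogram acquisition.
#
# Steady state is assumed throughout: the Langevin magnetization is
# memoryless, so a single drive-periodic record per (angle, shift step)
# suffices and the time derivative is taken by spectral differentiation on
# the periodic record.

#' Shift-field schedule
#'
#' `n_points` FFL positions equally spaced over `[-fov/2, +fov/2]`
#' (inclusive) and the homogeneous shift-field amplitude that places the FFL
#' at each: with the gantry-frame field `Gx * x' + shift`, the FFL sits at
#' `x' = p` for `shift = -Gx * p`, so the amplitudes sweep `-/+ Gx * fov/2`.
#'
#' @param protocol an `ffl_protocol`.
#' @return List with `positions` (m) and `amplitudes` (T).
#' @export
#' @examples
#' rng <- range(shift_schedule(human_protocol())$amplitudes)  # -/+ 0.15 T
shift_schedule <- function(protocol) {
  n <- protocol$n_points
  positions <- if (n == 1) 0 else seq(-protocol$fov / 2, protocol$fov / 2,
                                      length.out = n)
  list(positions = positions, amplitudes = -protocol$Gx * positions)
}

#' Total applied field at a point and time
#'
#' Vector sum of the z-directed sinusoidal drive, the rotated gradient field
#' and the rotated homogeneous shift field for shift step `step`.
#'
#' @param protocol an `ffl_protocol`.
#' @param theta gantry angle (rad).
#' @param step shift-step index (1-based, within the schedule).
#' @param point patient-frame 3-vector (m).
#' @param t time or vector of times (s).
#' @return length(t) x 3 matrix of field vectors (T).
#' @export
total_field <- function(protocol, theta, step, point, t) {
  sched <- shift_schedule(protocol)
  if (step < 1 || step > length(sched$positions)) stop("step outside schedule", call. = FALSE)
  stat <- ideal_ffl_field(protocol$Gx, protocol$Gz, theta,
                          sched$amplitudes[step], point)[1, ]
  drive <- protocol$drive_amplitude * sin(2 * pi * protocol$drive_frequency * t)
  cbind(stat[1], stat[2], stat[3] + drive)
}

#' Spectral time derivative of a periodic record
#'
#' Differentiates a real record assumed exactly periodic over its length via
#' the DFT (multiplication by `i * 2 * pi * f`), zeroing the Nyquist bin.
#'
#' @param x real samples over an integer number of periods.
#' @param sample_rate Hz.
#' @return Differentiated samples.
#' @export
spectral_derivative <- function(x, sample_rate) {
  n <- length(x)
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k[n / 2 + 1] <- 0
  f <- k * sample_rate / n
  Re(stats::fft(stats::fft(x) * (2i * pi * f), inverse = TRUE)) / n
}

# Sample times for one record.
.record_times <- function(protocol) {
  n <- record_length(protocol)
  (seq_len(n) - 1) / protocol$sample_rate
}

#' Receive-coil voltage record for one (angle, shift step)
#'
#' For each phantom source, the Langevin magnetic moment is evaluated over
#' one steady-state drive-periodic record under the total field, projected
#' onto the receive coil's reciprocity field at the source (so the flux is
#' `B1(r) . m(t)` in webers, with the moment `m = mass * s_sat * L * Bhat`
#' in A m^2), summed over sources, and differentiated in time.
#'
#' @param phantom an `ffl_phantom`.
#' @param protocol an `ffl_protocol`.
#' @param theta gantry angle (rad).
#' @param step shift-step index (1-based).
#' @return List of class `ffl_timeseries` with `samples` (V) and
#'   `sample_rate` (Hz).
#' @export
simulate_voltage <- function(phantom, protocol, theta, step) {
  t <- .record_times(protocol)
  flux <- numeric(length(t))
  if (length(phantom$mass) > 0) {
    b1 <- .receive_b1(protocol$receive, phantom$position)
    sched <- shift_schedule(protocol)
    if (step < 1 || step > length(sched$positions)) stop("step outside schedule", call. = FALSE)
    stat <- ideal_ffl_field(protocol$Gx, protocol$Gz, theta,
                            sched$amplitudes[step], phantom$position)
    drive <- protocol$drive_amplitude * sin(2 * pi * protocol$drive_frequency * t)
    sp <- protocol$spion
    for (s in seq_len(length(phantom$mass))) {
      if (phantom$mass[s] == 0) next
      bx <- stat[s, 1]; by <- stat[s, 2]; bz <- stat[s, 3] + drive
      nb <- sqrt(bx^2 + by^2 + bz^2)
      amp <- phantom$mass[s] * sp$s_sat * langevin(sp$beta * nb) / ifelse(nb > 0, nb, 1)
      amp[nb == 0] <- 0
      flux <- flux + amp * (b1[s, 1] * bx + b1[s, 2] * by + b1[s, 3] * bz)
    }
  }
  structure(list(samples = spectral_derivative(flux, protocol$sample_rate),
                 sample_rate = protocol$sample_rate),
            class = "ffl_timeseries")
}

#' Add white Gaussian noise to a record
#'
#' @param ts an `ffl_timeseries` (or numeric vector).
#' @param sigma per-sample noise std (V), >= 0.
#' @param seed optional integer seed for reproducibility.
#' @return Same type as `ts`.
#' @export
add_noise <- function(ts, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  x <- if (inherits(ts, "ffl_timeseries")) ts$samples else ts
  if (sigma > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    x <- x + stats::rnorm(length(x), 0, sigma)
  }
  if (inherits(ts, "ffl_timeseries")) {
    structure(list(samples = x, sample_rate = ts$sample_rate), class = "ffl_timeseries")
  } else {
    x
  }
}

#' Harmonic coefficients of a record (comb filter)
#'
#' DFT coefficients at integer multiples of the drive frequency, normalized
#' so a pure sinusoid of amplitude A at `k * f0` yields `|c_k| = A`. The
#' record must span an integer number of drive periods (otherwise the
#' requested bins leak).
#'
#' @param ts an `ffl_timeseries` (or numeric vector, with `sample_rate`).
#' @param f0 drive frequency (Hz).
#' @param harmonics integer harmonic numbers.
#' @param sample_rate required if `ts` is a bare vector.
#' @return Complex vector, one coefficient per requested harmonic (V).
#' @export
harmonic_coefficients <- function(ts, f0, harmonics, sample_rate = NULL) {
  if (inherits(ts, "ffl_timeseries")) {
    x <- ts$samples; fs <- ts$sample_rate
  } else {
    x <- ts; fs <- sample_rate
  }
  n <- length(x)
  periods <- n * f0 / fs
  if (abs(periods - round(periods)) > 1e-9) {
    stop("spectral leakage: record does not span an integer number of drive periods",
         call. = FALSE)
  }
  periods <- round(periods)
  bins <- harmonics * periods
  if (any(bins >= n / 2)) stop("requested harmonic beyond Nyquist", call. = FALSE)
  F <- stats::fft(x)
  2 * F[bins + 1] / n
}

# Reference phases per harmonic: from the noiseless response of a unit point
# source at the isocenter with the FFL centered (theta = 0, shift = 0),
# computed once per protocol. Projection values are the real parts of the
# coefficients after rotation by these phases, preserving linearity and
# zero-mean noise (a magnitude convention would Rician-bias the noise floor).
.reference_phase <- function(protocol) {
  ref <- make_point_phantom(c(0, 0, 0), 1, label = "phase reference")
  p0 <- protocol
  p0$n_points <- 1L   # single centered step
  ts <- simulate_voltage(ref, p0, 0, 1)
  ch <- harmonic_coefficients(ts, protocol$drive_frequency, protocol$harmonics)
  ph <- Arg(ch)
  ph[Mod(ch) < 1e-300] <- 0
  ph
}

# Phase-referenced real projection value from complex harmonic coefficients.
.project_value <- function(ch, ref_phase) {
  sum(Re(ch * exp(-1i * ref_phase)))
}

# Effective std of one phase-referenced projection value: per-sample sigma
# through the DFT (std sigma*sqrt(2/N) per coefficient real part),
# independent across harmonic bins, divided by sqrt(n_averages).
.sinogram_noise_sigma <- function(protocol) {
  n <- record_length(protocol)
  protocol$noise_sigma * sqrt(2 / n) * sqrt(length(protocol$harmonics)) /
    sqrt(protocol$n_averages)
}

#' Gantry angles of a protocol
#'
#' `theta_j = j * pi / n_projections`, `j = 0 .. n_projections - 1` (uniform
#' over the half-open interval `[0, 180)` degrees).
#' @param protocol an `ffl_protocol`.
#' @return Angles in radians.
#' @export
projection_angles <- function(protocol) {
  n <- protocol$n_projections
  (seq_len(n) - 1) * pi / n
}

#' Acquire a sinogram
#'
#' Runs the discrete shift-and-rotate schedule: for each of the
#' `n_projections` gantry angles and each shift step, synthesize the
#' steady-state record, optionally add noise, comb-filter the selected
#' harmonics, and store the phase-referenced real projection value.
#'
#' `method = "kernel"` exploits shift invariance: with the ideal FFL field
#' and a uniform receive descriptor, the projection value of a point source
#' depends only on the signed x' distance between source and FFL, so a 1D
#' kernel is simulated once on a fine grid and interpolated (natural cubic
#' spline). `"direct"` runs the full per-(angle, step, source) simulation.
#' `"auto"` picks the kernel path whenever it is exact for the protocol.
#'
#' Averaging: the mean of `n_averages` independent noisy acquisitions is
#' drawn in one step at noise std `sigma / sqrt(n_averages)` (identical in
#' distribution).
#'
#' @param phantom an `ffl_phantom`.
#' @param protocol an `ffl_protocol`.
#' @param seed integer seed for the noise stream; `NULL` leaves the RNG
#'   state alone.
#' @param noiseless if `TRUE`, skip noise regardless of the protocol sigma.
#' @param method `"auto"`, `"kernel"` or `"direct"`.
#' @return An `ffl_sinogram`: matrix `values` (n_projections x n_points, V),
#'   plus `angles` (rad) and `shift_positions` (m).
#' @export
acquire_sinogram <- function(phantom, protocol, seed = NULL, noiseless = FALSE,
                             method = c("auto", "kernel", "direct")) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (inherits(protocol$receive, "uniform_receive")) "kernel" else "direct"
  }
  if (method == "kernel" && !inherits(protocol$receive, "uniform_receive")) {
    stop("kernel path requires a uniform receive descriptor", call. = FALSE)
  }
  angles <- projection_angles(protocol)
  sched <- shift_schedule(protocol)
  vals <- matrix(0, protocol$n_projections, protocol$n_points)
  if (length(phantom$mass) > 0) {
    if (method == "kernel") {
      kern <- projection_kernel(protocol)
      for (j in seq_along(angles)) {
        xp <- phantom$position[, 1] * cos(angles[j]) -
          phantom$position[, 2] * sin(angles[j])
        for (i in seq_along(sched$positions)) {
          vals[j, i] <- sum(phantom$mass * kern$fun(xp - sched$positions[i]))
        }
      }
    } else {
      ref_phase <- .reference_phase(protocol)
      for (j in seq_along(angles)) {
        for (i in seq_along(sched$positions)) {
          ts <- simulate_voltage(phantom, protocol, angles[j], i)
          ch <- harmonic_coefficients(ts, protocol$drive_frequency, protocol$harmonics)
          vals[j, i] <- .project_value(ch, ref_phase)
        }
      }
    }
  }
  if (!noiseless && protocol$noise_sigma > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    vals <- vals + matrix(stats::rnorm(length(vals), 0, .sinogram_noise_sigma(protocol)),
                          nrow(vals), ncol(vals))
  }
  structure(list(values = vals, angles = angles,
                 shift_positions = sched$positions, protocol = protocol),
            class = "ffl_sinogram")
}

#' @export
print.ffl_sinogram <- function(x, ...) {
  cat(sprintf("<ffl_sinogram> %d angles x %d points, peak |value| %.4g V\n",
              nrow(x$values), ncol(x$values), max(abs(x$values))))
  invisible(x)
}

#' Shift-invariant projection kernel
#'
#' Phase-referenced projection value of a unit point mass as a function of
#' the signed x' distance `d` between source and FFL (valid for the ideal
#' FFL field with a uniform receive descriptor, source in the z = 0 slice).
#' Sampled on a grid fine relative to both the kernel's intrinsic width
#' `2 * drive_amplitude / Gx` and the shift-step pitch, then interpolated
#' with a natural cubic spline (zero outside the sampled support).
#'
#' @param protocol an `ffl_protocol`.
#' @param d_max kernel half-support to sample (m); defaults to the maximum
#'   source-FFL distance reachable within the FOV corner circle.
#' @param d_step sample spacing (m); defaults to 1/32 of the smaller of the
#'   intrinsic kernel width and the shift-step pitch.
#' @return List with `d`, `values`, and interpolant `fun(d)`.
#' @export
projection_kernel <- function(protocol, d_max = NULL, d_step = NULL) {
  if (!inherits(protocol$receive, "uniform_receive")) {
    stop("kernel path requires a uniform receive descriptor", call. = FALSE)
  }
  if (is.null(d_max)) d_max <- protocol$fov / 2 * (1 + sqrt(2)) + 2e-3
  width <- 2 * protocol$drive_amplitude / protocol$Gx
  pitch <- if (protocol$n_points > 1) protocol$fov / (protocol$n_points - 1) else width
  # resolve both the intrinsic width (drive scale) and the Langevin-knee
  # feature near d = 0
  knee_d <- 1 / (protocol$spion$beta * protocol$Gx)
  if (is.null(d_step)) d_step <- min(min(width, pitch) / 32, knee_d / 6)
  d <- seq(0, d_max + 2 * d_step, by = d_step)
  t <- .record_times(protocol)
  drive <- protocol$drive_amplitude * sin(2 * pi * protocol$drive_frequency * t)
  sp <- protocol$spion
  b1z <- protocol$receive$B1z
  ref_phase <- NULL
  vals <- numeric(length(d))
  for (k in seq_along(d)) {
    bx <- protocol$Gx * d[k]
    nb <- sqrt(bx^2 + drive^2)
    amp <- sp$s_sat * langevin(sp$beta * nb) / ifelse(nb > 0, nb, 1)
    amp[nb == 0] <- 0
    flux <- b1z * amp * drive
    v <- spectral_derivative(flux, protocol$sample_rate)
    ch <- harmonic_coefficients(v, protocol$drive_frequency, protocol$harmonics,
                                sample_rate = protocol$sample_rate)
    if (is.null(ref_phase)) {  # d = 0 is the centered unit source
      ref_phase <- Arg(ch)
      ref_phase[Mod(ch) < 1e-300] <- 0
    }
    vals[k] <- .project_value(ch, ref_phase)
  }
  dd <- c(-rev(d[-1]), d)           # kernel is even in d
  vv <- c(rev(vals[-1]), vals)
  sf <- stats::splinefun(dd, vv, method = "natural")
  fun <- function(x) ifelse(abs(x) > d_max, 0, sf(x))
  list(d = dd, values = vv, fun = fun)
}

#' Export a sinogram (or one projection) to CSV
#'
#' Long format: columns `angle_rad`, `shift_m`, `value_V`.
#' @param sinogram an `ffl_sinogram`.
#' @param path output path.
#' @return The data frame, invisibly.
#' @export
sinogram_to_csv <- function(sinogram, path) {
  df <- expand.grid(angle_rad = sinogram$angles, shift_m = sinogram$shift_positions,
                    KEEP.OUT.ATTRS = FALSE)
  df$value_V <- as.vector(sinogram$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
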