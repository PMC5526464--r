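# Scan protocols: drive, gradients, FOV, sampling and noise settings, plus
# the named rodent- and human-scale presets used throughout the design
# analysis.

#' Scan protocol for discrete shift-and-rotate FFL acquisition
#'
#' @param drive_amplitude drive-field amplitude (T, as mu0*H).
#' @param drive_frequency drive frequency f0 (Hz).
#' @param Gx gradient along the projection axis x' (T/m).
#' @param Gz gradient magnitude along z (T/m, applied with opposite sign).
#' @param fov field of view along the projection axis (m).
#' @param n_projections number of gantry angles, equally spaced over
#'   `[0, 180)` degrees.
#' @param n_points shift steps per projection, spanning `[-fov/2, fov/2]`.
#' @param sample_rate digitization rate (Hz); `sample_rate / drive_frequency`
#'   must be an even integer >= 4.
#' @param periods_per_point drive periods recorded per shift step.
#' @param harmonics integer harmonics detected (default 3).
#' @param receive receive-coil descriptor: an [ffl_coil()] (reciprocity field
#'   by Biot-Savart per source point) or [uniform_receive()].
#' @param noise_sigma per-sample white Gaussian noise std (V).
#' @param n_averages repeated acquisitions averaged per image.
#' @param spion a [spion_model()]; default [default_spion()].
#' @param label preset name.
#' @return An object of class `ffl_protocol`.
#' @export
scan_protocol <- function(drive_amplitude, drive_frequency, Gx, Gz = Gx, fov,
                          n_projections, n_points, sample_rate = 2e5,
                          periods_per_point = 16, harmonics = 3L,
                          receive = uniform_receive(1e-4),
                          noise_sigma = 0, n_averages = 1,
                          spion = default_spion(), label = "custom") {
  spp <- sample_rate / drive_frequency
  if (abs(spp - round(spp)) > 1e-9 || round(spp) %% 2 != 0 || spp < 4) {
    stop("sample_rate / drive_frequency must be an even integer >= 4", call. = FALSE)
  }
  structure(
    list(drive_amplitude = drive_amplitude, drive_frequency = drive_frequency,
         Gx = Gx, Gz = Gz, fov = fov, n_projections = as.integer(n_projections),
         n_points = as.integer(n_points), sample_rate = sample_rate,
         periods_per_point = as.integer(periods_per_point),
         harmonics = as.integer(harmonics), receive = receive,
         noise_sigma = noise_sigma, n_averages = as.integer(n_averages),
         spion = spion, label = label),
    class = "ffl_protocol"
  )
}

#' @export
print.ffl_protocol <- function(x, ...) {
  st <- scan_time(x)
  cat(sprintf(paste0(
    "<ffl_protocol> %s\n",
    "  drive: %.3g mT @ %.3g kHz; gradients: Gx = %.3g, Gz = %.3g T/m\n",
    "  FOV %.3g cm, %d projections x %d points, %d periods/point @ %.0f ksps\n",
    "  noise sigma %.3g nV, %d averages; scan %.3f s/image, %.1f s total\n"),
    x$label, 1e3 * x$drive_amplitude, 1e-3 * x$drive_frequency, x$Gx, x$Gz,
    100 * x$fov, x$n_projections, x$n_points, x$periods_per_point,
    x$sample_rate / 1e3, 1e9 * x$noise_sigma, x$n_averages,
    st[["per_image_s"]], st[["total_s"]]))
  invisible(x)
}

#' Ideal uniform receive-coil descriptor
#'
#' A spatially uniform z-directed reciprocity field (T/A). Exact for a
#' sample at the center of a long solenoid; also the prerequisite for the
#' shift-invariant fast acquisition path.
#'
#' @param B1z reciprocity field per unit current (T/A).
#' @return An object of class `uniform_receive`.
#' @export
uniform_receive <- function(B1z) {
  structure(list(B1z = B1z), class = "uniform_receive")
}

# Reciprocity field (T/A) at given source points, n x 3.
.receive_b1 <- function(receive, points) {
  pts <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  if (inherits(receive, "uniform_receive")) {
    cbind(0, 0, rep(receive$B1z, nrow(pts)))
  } else {
    biot_savart(receive, pts)
  }
}

#' Samples per record for a protocol
#' @param protocol an `ffl_protocol`.
#' @return Integer record length.
#' @export
record_length <- function(protocol) {
  as.integer(round(protocol$periods_per_point *
                     protocol$sample_rate / protocol$drive_frequency))
}

#' Scan timing
#'
#' Per-image time is `n_projections * n_points * periods_per_point / f0`;
#' total time multiplies by the number of averages.
#'
#' @param protocol an `ffl_protocol`.
#' @return Named numeric `c(per_image_s, total_s)`.
#' @export
#' @examples
#' scan_time(human_protocol())  # 2.968 s/image, 593.6 s for 200 averages
scan_time <- function(protocol) {
  per <- protocol$n_projections * protocol$n_points *
    protocol$periods_per_point / protocol$drive_frequency
  c(per_image_s = per, total_s = per * protocol$n_averages)
}

#' Receive-coil presets
#'
#' Named solenoid receive geometries: `"a"` is the rodent head solenoid
#' (radius 2.5 cm, length 5 cm, 25 turns), `"c"` the human head solenoid
#' (radius 12 cm, length 24 cm, 25 turns).
#'
#' @param name `"a"` or `"c"`.
#' @return An `ffl_coil`.
#' @export
coil_preset <- function(name = c("a", "c")) {
  name <- match.arg(name)
  switch(name,
         a = make_solenoid(0.025, 0.05, 25, label = "coil (a): rodent solenoid"),
         c = make_solenoid(0.12, 0.24, 25, label = "coil (c): human head solenoid"))
}

#' Human-scale scanner preset
#'
#' 25 mT drive at 10 kHz, 1.5 T/m gradients, 20 cm FOV, 53 projections x 35
#' points, 16 drive periods per point at 200 ksps, 3rd-harmonic detection,
#' 200 averages. Receive is the ideal-uniform equivalent of the human head
#' solenoid (center reciprocity field of [coil_preset()] `"c"`); the noise
#' level is the Johnson noise of its 63.3 mOhm AC resistance at 273 K over
#' the 100 kHz digitization bandwidth.
#'
#' @param spion a `spion_model`; default [default_spion()].
#' @param n_averages averages per image (default 200).
#' @return An `ffl_protocol`.
#' @export
human_protocol <- function(spion = default_spion(), n_averages = 200) {
  b1 <- biot_savart(coil_preset("c"), c(0, 0, 0))[1, 3]
  scan_protocol(
    drive_amplitude = 25e-3, drive_frequency = 1e4, Gx = 1.5, Gz = 1.5,
    fov = 0.20, n_projections = 53, n_points = 35, sample_rate = 2e5,
    periods_per_point = 16, harmonics = 3L, receive = uniform_receive(b1),
    noise_sigma = johnson_noise_v(63.3e-3, 273, 1e5), n_averages = n_averages,
    spion = spion, label = "human"
  )
}

#' Rodent-scale scanner preset
#'
#' 50 mT drive at 10 kHz, 7 T/m gradients, 4 cm FOV, 53 projections x 35
#' points, 16 periods per point at 200 ksps, 3rd-harmonic detection, 200
#' averages. Receive is the ideal-uniform equivalent of the rodent solenoid
#' (coil "a"); noise is the Johnson noise of its 13.2 mOhm AC resistance at
#' 273 K over 100 kHz.
#'
#' @inheritParams human_protocol
#' @return An `ffl_protocol`.
#' @export
rodent_protocol <- function(spion = default_spion(), n_averages = 200) {
  b1 <- biot_savart(coil_preset("a"), c(0, 0, 0))[1, 3]
  scan_protocol(
    drive_amplitude = 50e-3, drive_frequency = 1e4, Gx = 7, Gz = 7,
    fov = 0.04, n_projections = 53, n_points = 35, sample_rate = 2e5,
    periods_per_point = 16, harmonics = 3L, receive = uniform_receive(b1),
    noise_sigma = johnson_noise_v(13.2e-3, 273, 1e5), n_averages = n_averages,
    spion = spion, label = "rodent"
  )
}

#' Serialize a protocol to YAML
#'
#' Receive descriptors are stored as either the uniform B1z or the coil's
#' JSON; the SPION model is stored by its parameters.
#'
#' @param protocol an `ffl_protocol`.
#' @param path file path; if `NULL`, returns the YAML string.
#' @return Path (invisibly) or YAML string.
#' @export
protocol_to_yaml <- function(protocol, path = NULL) {
  p <- protocol
  obj <- list(
    label = p$label, drive_amplitude = p$drive_amplitude,
    drive_frequency = p$drive_frequency, Gx = p$Gx, Gz = p$Gz, fov = p$fov,
    n_projections = p$n_projections, n_points = p$n_points,
    sample_rate = p$sample_rate, periods_per_point = p$periods_per_point,
    harmonics = p$harmonics, noise_sigma = p$noise_sigma,
    n_averages = p$n_averages,
    spion = list(s_sat = p$spion$s_sat, beta = p$spion$beta, label = p$spion$label),
    receive = if (inherits(p$receive, "uniform_receive")) {
      list(kind = "uniform", B1z = p$receive$B1z)
    } else {
      list(kind = "coil", json = coil_to_json(p$receive))
    }
  )
  ytxt <- yaml::as.yaml(obj, precision = 15L)
  if (is.null(path)) return(ytxt)
  writeLines(ytxt, path)
  invisible(path)
}

#' Read a protocol from YAML
#' @param x path to a YAML file (or YAML string).
#' @return An `ffl_protocol`.
#' @export
protocol_from_yaml <- function(x) {
  o <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  receive <- if (identical(o$receive$kind, "uniform")) {
    uniform_receive(o$receive$B1z)
  } else {
    coil_from_json(o$receive$json)
  }
  scan_protocol(
    drive_amplitude = o$drive_amplitude, drive_frequency = o$drive_frequency,
    Gx = o$Gx, Gz = o$Gz, fov = o$fov, n_projections = o$n_projections,
    n_points = o$n_points, sample_rate = o$sample_rate,
    periods_per_point = o$periods_per_point, harmonics = o$harmonics,
    receive = receive, noise_sigma = o$noise_sigma, n_averages = o$n_averages,
    spion = spion_model(o$spion$s_sat, o$spion$beta, label = o$spion$label),
    label = o$label
  )
}
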