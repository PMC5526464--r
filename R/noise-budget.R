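# Closed-form receiver noise budgeting: Johnson-Nyquist coil noise,
# cylindrical body-load loss, Litz AC resistance, and the relative detection
# sensitivity figure of merit used to rank receive coil designs.

#' Johnson-Nyquist noise voltage
#'
#' `sqrt(4 kB T R bandwidth)`.
#'
#' @param R resistance (Ohm).
#' @param T_K temperature (K); the receiver budget convention here is 273 K.
#' @param bandwidth detection bandwidth (Hz).
#' @return RMS noise voltage (V).
#' @export
#' @examples
#' johnson_noise_v(63.3e-3, 273, 1e5)  # ~9.77 nV (human head solenoid)
#' johnson_noise_v(13.2e-3, 273, 1e5)  # ~4.46 nV (rodent solenoid)
johnson_noise_v <- function(R, T_K = 273, bandwidth = 1e5) {
  if (any(c(R, T_K, bandwidth) < 0)) stop("R, T, bandwidth must be >= 0", call. = FALSE)
  sqrt(4 * .kB * T_K * R * bandwidth)
}

#' Effective body-load series resistance
#'
#' Power dissipated in a uniform conducting cylinder (axis along the
#' reciprocity field) by a coil producing a uniform `B1` per unit current:
#' `P = (1/8) w^2 sigma B1^2 (pi/32) D^4 l` per A^2, which is the effective
#' series resistance referred to the coil terminals.
#'
#' @param B1_per_A reciprocity field at the sample (T/A).
#' @param f frequency (Hz), typically the detected harmonic.
#' @param conductivity sample conductivity (S/m).
#' @param diameter cylinder diameter (m).
#' @param length cylinder length (m).
#' @return Resistance (Ohm).
#' @export
body_load_resistance <- function(B1_per_A, f, conductivity, diameter, length) {
  if (any(c(B1_per_A, f, conductivity, diameter, length) < 0)) {
    stop("all inputs must be >= 0", call. = FALSE)
  }
  w <- 2 * pi * f
  (1 / 8) * w^2 * conductivity * B1_per_A^2 * (pi / 32) * diameter^4 * length
}

#' Litz-wire AC resistance from a DC spec and conversion factor
#'
#' `(wire_length * Rdc_per_m / n_parallel) * ac_dc_factor`. The AC-to-DC
#' conversion factor is vendor-specified at the detection frequency and is a
#' free input here.
#'
#' @param wire_length total wound length (m).
#' @param Rdc_per_m DC resistance per meter (Ohm/m).
#' @param n_parallel parallel strands.
#' @param ac_dc_factor dimensionless AC/DC resistance ratio.
#' @return Resistance (Ohm).
#' @export
litz_ac_resistance <- function(wire_length, Rdc_per_m, n_parallel = 1, ac_dc_factor = 1) {
  if (any(c(wire_length, Rdc_per_m, n_parallel, ac_dc_factor) <= 0)) {
    stop("all inputs must be > 0", call. = FALSE)
  }
  wire_length * Rdc_per_m / n_parallel * ac_dc_factor
}

#' Relative detection sensitivity
#'
#' Center reciprocity field per unit current divided by the receiver noise
#' voltage, reported in uT/A/nV (the figure of merit for comparing receive
#' coils of different scale).
#'
#' @param B1_per_A center reciprocity field (T/A).
#' @param noise_v RMS noise voltage (V), > 0.
#' @return Sensitivity in uT/A per nV.
#' @export
#' @examples
#' relative_sensitivity(443.7e-6, 4.46e-9)  # ~99.5 (rodent solenoid)
relative_sensitivity <- function(B1_per_A, noise_v) {
  if (any(noise_v <= 0)) stop("noise_v must be > 0", call. = FALSE)
  (B1_per_A / 1e-6) / (noise_v / 1e-9)
}

#' Receiver noise-budget table
#'
#' One row per receive coil: center reciprocity field, body-load resistance
#' and noise for the stated cylindrical sample, coil AC resistance (an
#' authoritative input, not derived from the wire spec) and its Johnson
#' noise, and the relative detection sensitivity with respect to the coil
#' noise.
#'
#' @param coils named list of `ffl_coil` objects.
#' @param R_ac named numeric of AC resistances (Ohm), same names.
#' @param body list with `conductivity` (S/m), `diameter` (m), `length` (m);
#'   either one spec for all coils or a named list of per-coil specs.
#' @param f_harmonic frequency for the body-load estimate (Hz, default 30 kHz).
#' @param T_K Johnson-noise temperature (K, default 273).
#' @param bandwidth noise bandwidth (Hz, default 100 kHz).
#' @param path optional CSV export path.
#' @return Data frame with columns `coil`, `B1_per_A_uT`, `R_body_mOhm`,
#'   `v_body_noise_nV`, `R_ac_mOhm`, `v_coil_noise_nV`,
#'   `relative_sensitivity_uT_per_A_nV`.
#' @export
noise_budget_table <- function(coils, R_ac, body, f_harmonic = 30e3,
                               T_K = 273, bandwidth = 1e5, path = NULL) {
  if (length(coils) == 0) {
    out <- data.frame(coil = character(), B1_per_A_uT = numeric(),
                      R_body_mOhm = numeric(), v_body_noise_nV = numeric(),
                      R_ac_mOhm = numeric(), v_coil_noise_nV = numeric(),
                      relative_sensitivity_uT_per_A_nV = numeric())
    return(out)
  }
  per_coil_body <- !is.null(names(body)) && all(names(coils) %in% names(body))
  rows <- lapply(names(coils), function(nm) {
    b1 <- biot_savart(coils[[nm]], c(0, 0, 0))[1, 3]
    bd <- if (per_coil_body) body[[nm]] else body
    rb <- body_load_resistance(b1, f_harmonic, bd$conductivity, bd$diameter, bd$length)
    vb <- johnson_noise_v(rb, T_K, bandwidth)
    vc <- johnson_noise_v(R_ac[[nm]], T_K, bandwidth)
    data.frame(coil = nm, B1_per_A_uT = b1 / 1e-6, R_body_mOhm = rb * 1e3,
               v_body_noise_nV = vb / 1e-9, R_ac_mOhm = R_ac[[nm]] * 1e3,
               v_coil_noise_nV = vc / 1e-9,
               relative_sensitivity_uT_per_A_nV = relative_sensitivity(b1, vc))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Reference noise budget for the rodent and human solenoids
#'
#' Coils "a" (rodent) and "c" (human head) with their published AC
#' resistances (13.2 and 63.3 mOhm) and the corresponding cylindrical body
#' models (4.5 cm and 22 cm, 0.5 S/m).
#'
#' @inheritParams noise_budget_table
#' @return Data frame (see [noise_budget_table()]).
#' @export
reference_noise_budget <- function(path = NULL) {
  noise_budget_table(
    coils = list(a = coil_preset("a"), c = coil_preset("c")),
    R_ac = c(a = 13.2e-3, c = 63.3e-3),
    body = list(a = list(conductivity = 0.5, diameter = 0.045, length = 0.045),
                c = list(conductivity = 0.5, diameter = 0.22, length = 0.22)),
    path = path
  )
}
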