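# Amplitude and dB/dt safety screening: shift-field magnetostimulation,
# gantry-rotation retinal exposure, and PNS drive-field limits.

#' Physiological safety limits
#'
#' @param pns_anchors data frame with columns `frequency` (Hz) and
#'   `amplitude` (T): published peripheral-nerve-stimulation thresholds;
#'   defaults to the torso anchors 9.9 mT at 4.5 kHz and 7.6 mT at 25 kHz.
#' @param phosphene_amplitude magneto-phosphene amplitude threshold (T) at
#'   `phosphene_frequency`; default 40 mT at 20 Hz.
#' @param phosphene_frequency reference frequency (Hz) for the amplitude
#'   threshold.
#' @param phosphene_dbdt phosphene dB/dt threshold (T/s); default 5 (the
#'   40 mT / 20 Hz sinusoid's peak slew).
#' @return An object of class `ffl_safety_limits`.
#' @export
safety_limits <- function(pns_anchors = data.frame(frequency = c(4500, 25000),
                                                   amplitude = c(9.9e-3, 7.6e-3)),
                          phosphene_amplitude = 40e-3,
                          phosphene_frequency = 20,
                          phosphene_dbdt = 5) {
  if (nrow(pns_anchors) < 1) stop("configuration error: empty PNS anchor table", call. = FALSE)
  if (any(pns_anchors$amplitude <= 0)) stop("PNS amplitudes must be > 0", call. = FALSE)
  pns_anchors <- pns_anchors[order(pns_anchors$frequency), ]
  structure(list(pns_anchors = pns_anchors,
                 phosphene_amplitude = phosphene_amplitude,
                 phosphene_frequency = phosphene_frequency,
                 phosphene_dbdt = phosphene_dbdt),
            class = "ffl_safety_limits")
}

#' PNS amplitude limit at a drive frequency
#'
#' Log-log linear interpolation between the anchor thresholds, constant
#' extrapolation outside, times an optional head-coil multiplier (head-only
#' drive coils tolerate roughly 2-3x the torso limit).
#'
#' @param limits an [safety_limits()].
#' @param frequency drive frequency (Hz).
#' @param head_multiplier multiplier on the torso anchors (default 1).
#' @return Amplitude limit (T).
#' @export
pns_limit <- function(limits, frequency, head_multiplier = 1) {
  a <- limits$pns_anchors
  la <- stats::approx(log(a$frequency), log(a$amplitude), xout = log(frequency),
                      rule = 2)$y
  head_multiplier * exp(la)
}

#' Shift-field dB/dt
#'
#' Full linear sweep of the shift amplitude (`G * fov`) over one projection
#' interval.
#'
#' @param G gradient strength (T/m).
#' @param fov swept field of view (m).
#' @param t_projection time per projection (s).
#' @return dB/dt in T/s.
#' @export
#' @examples
#' shift_dbdt(1.5, 0.2, 2.97 / 53)  # ~5.4 T/s
shift_dbdt <- function(G, fov, t_projection) {
  if (any(c(G, fov, t_projection) < 0) || t_projection == 0) {
    stop("need G, fov >= 0 and t_projection > 0", call. = FALSE)
  }
  G * fov / t_projection
}

#' Gantry-rotation dB/dt at an off-center point
#'
#' Maximum over gantry angle of the numerically differentiated patient-frame
#' field vector at a point `radius` from the isocenter in the rotation
#' plane, for the ideal FFL gradient rotating at `f_rot`. For that field the
#' closed form is `2 * pi * f_rot * G * radius`.
#'
#' @param G gradient strength (T/m).
#' @param radius distance from isocenter in the rotation plane (m).
#' @param f_rot gantry rotation rate (Hz).
#' @param n_theta angular samples for the numerical maximum.
#' @return dB/dt in T/s.
#' @export
rotation_dbdt <- function(G, radius, f_rot, n_theta = 720) {
  if (any(c(G, radius, f_rot) < 0)) stop("inputs must be >= 0", call. = FALSE)
  if (radius == 0 || G == 0 || f_rot == 0) return(0)
  p <- c(radius, 0, 0)
  th <- seq(0, pi, length.out = n_theta + 1)
  dth <- th[2] - th[1]
  Bs <- t(vapply(th, function(a) ideal_ffl_field(G, G, a, 0, p)[1, ], numeric(3)))
  dB <- (Bs[-1, , drop = FALSE] - Bs[-nrow(Bs), , drop = FALSE]) / dth
  max(sqrt(rowSums(dB^2))) * 2 * pi * f_rot
}

#' Screen a protocol against safety limits
#'
#' Checks (i) the drive amplitude against the PNS limit interpolated at the
#' drive frequency (with head-coil multiplier), (ii) the shift-field dB/dt
#' against the phosphene dB/dt threshold, and (iii) the shift amplitude
#' against the phosphene amplitude threshold. A margin < 1 means the
#' protocol exceeds the limit; margins within 20% of the limit are flagged
#' "near threshold".
#'
#' @param protocol an `ffl_protocol`.
#' @param limits an [safety_limits()].
#' @param head_multiplier PNS head-coil multiplier (default 3).
#' @return Data frame with one row per constraint: `constraint`, `value`,
#'   `limit`, `margin` (= limit / value), `status` (`"pass"`,
#'   `"near threshold"` or `"over"`).
#' @export
check_protocol <- function(protocol, limits = safety_limits(), head_multiplier = 3) {
  if (!inherits(limits, "ffl_safety_limits")) stop("configuration error: invalid limits", call. = FALSE)
  t_proj <- protocol$n_points * protocol$periods_per_point / protocol$drive_frequency
  shift_amp <- protocol$Gx * protocol$fov / 2
  rows <- list(
    list(constraint = "drive amplitude vs PNS",
         value = protocol$drive_amplitude,
         limit = pns_limit(limits, protocol$drive_frequency, head_multiplier)),
    list(constraint = "shift dB/dt vs phosphene dB/dt",
         value = shift_dbdt(protocol$Gx, protocol$fov, t_proj),
         limit = limits$phosphene_dbdt),
    list(constraint = "shift amplitude vs phosphene amplitude",
         value = shift_amp,
         limit = limits$phosphene_amplitude)
  )
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$margin <- ifelse(df$value == 0, Inf, df$limit / df$value)
  df$status <- ifelse(df$margin < 1, "over",
                      ifelse(df$margin < 1.2, "near threshold", "pass"))
  df
}

#' Write a safety report as JSON
#' @param report data frame from [check_protocol()].
#' @param path output path.
#' @return Path, invisibly.
#' @export
safety_report_json <- function(report, path) {
  jsonlite::write_json(report, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
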