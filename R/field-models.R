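# Ideal analytic field models and field probes. All fields are mu0*H in
# tesla; gradients in T/m.

#' Gantry rotation matrix
#'
#' Rotation taking gantry-frame (primed) coordinates to patient-frame
#' coordinates, `(x, y, z) = R(theta) (x', y', z')`:
#' rows `(cos, sin, 0; -sin, cos, 0; 0, 0, 1)`.
#'
#' @param theta gantry angle in radians.
#' @return 3 x 3 orthonormal matrix with determinant 1.
#' @export
rotation_matrix <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0,
           -s_, c_, 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Ideal field-free-line selection-plus-shift field
#'
#' Gradient tensor field in the gantry frame with a homogeneous shift field
#' added along the projection axis x', rotated into the patient frame. The
#' gantry-frame field is `(Gx * x' + shift, 0, -Gz * z')`; the z-gradient is
#' applied with sign opposite the x'-gradient so the field is divergence-free
#' when the quoted magnitudes are equal. The zero locus is the line parallel
#' to y' at `x' = -shift / Gx`, z = 0.
#'
#' @param Gx gradient along the projection axis x' (T/m).
#' @param Gz gradient magnitude along z (T/m), applied with opposite sign.
#' @param theta gantry angle (rad).
#' @param shift homogeneous shift-field amplitude along x' (T).
#' @param points 3-vector or n x 3 matrix of patient-frame points (m).
#' @return n x 3 matrix of patient-frame field vectors (T).
#' @export
ideal_ffl_field <- function(Gx, Gz, theta, shift, points) {
  if (Gx == 0 && shift != 0) {
    stop("degenerate encoding: zero x'-gradient with nonzero shift field", call. = FALSE)
  }
  pts <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  R <- rotation_matrix(theta)
  prime <- pts %*% R      # x' = R^T p  (row-vector form)
  bx <- Gx * prime[, 1] + shift
  bz <- -Gz * prime[, 3]
  cbind(bx, 0, bz) %*% t(R)
}

#' Directional field-derivative probe
#'
#' Central finite difference of a field evaluator along a direction. By
#' default differentiates the component of the field along the probe
#' direction (the diagonal element of the gradient tensor, well-defined even
#' at a field null); `component = "magnitude"` differentiates `|B|` instead.
#'
#' @param field function mapping an n x 3 matrix of points to an n x 3 matrix
#'   of field vectors (T).
#' @param point 3-vector (m).
#' @param direction 3-vector, normalized internally.
#' @param h step (m, > 0); default 1e-3.
#' @param component `"along"` (default) or `"magnitude"`.
#' @return Derivative in T/m.
#' @export
#' @examples
#' f <- function(p) ideal_ffl_field(1.5, 1.5, 0, 0, p)
#' gradient_at(f, c(0, 0, 0), c(1, 0, 0))  # 1.5
gradient_at <- function(field, point, direction, h = 1e-3,
                        component = c("along", "magnitude")) {
  component <- match.arg(component)
  stopifnot(h > 0)
  d <- direction / sqrt(sum(direction^2))
  B <- field(rbind(point + h * d, point - h * d))
  v <- switch(component,
              along = B %*% d,
              magnitude = sqrt(rowSums(B^2)))
  (v[1] - v[2]) / (2 * h)
}

#' Field evaluator for a coil at a fixed current
#'
#' Convenience wrapper returning a `function(points) -> n x 3 T` closure over
#' [biot_savart()], suitable for [gradient_at()].
#'
#' @param coil an `ffl_coil`.
#' @param current drive current (A); defaults to the coil's nominal current
#'   or 1 A.
#' @return A function of an n x 3 point matrix.
#' @export
coil_field_fun <- function(coil, current = NULL) {
  if (is.null(current)) {
    current <- if (is.finite(coil$nominal_current)) coil$nominal_current else 1
  }
  force(coil)
  function(points) biot_savart(coil, points) * current
}
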