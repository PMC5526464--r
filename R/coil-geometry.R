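# Coil windings as ordered straight current segments; the unit of
# field-per-amp computation for every receive, gradient and shift coil.

#' Construct a coil geometry from straight segments
#'
#' A coil geometry is an ordered set of straight current segments. Each
#' segment carries a signed current multiplier; winding turns are folded into
#' the multiplier, so [biot_savart()] always reports field per unit drive
#' current.
#'
#' @param start n x 3 matrix of segment start points (m).
#' @param end n x 3 matrix of segment end points (m).
#' @param mult numeric vector of signed current multipliers (recycled).
#' @param label text label.
#' @param nominal_current optional nominal operating current (A), carried as
#'   metadata for design presets.
#' @return An object of class `ffl_coil`.
#' @export
ffl_coil <- function(start, end, mult = 1, label = "coil", nominal_current = NA_real_) {
  start <- matrix(as.numeric(start), ncol = 3)
  end <- matrix(as.numeric(end), ncol = 3)
  if (nrow(start) != nrow(end)) {
    stop("invalid coil geometry: start/end segment counts differ", call. = FALSE)
  }
  len <- sqrt(rowSums((end - start)^2))
  if (any(len <= 0)) {
    stop("invalid coil geometry: zero-length segment", call. = FALSE)
  }
  mult <- rep_len(as.numeric(mult), nrow(start))
  structure(
    list(start = start, end = end, mult = mult, label = label,
         nominal_current = nominal_current),
    class = "ffl_coil"
  )
}

#' @export
print.ffl_coil <- function(x, ...) {
  cat(sprintf("<ffl_coil> %s: %d segments, wire length %.3f m (x multiplicity %.3f m)\n",
              x$label, nrow(x$start), coil_wire_length(x, weighted = FALSE),
              coil_wire_length(x)))
  invisible(x)
}

#' Total wire length of a coil geometry
#'
#' @param coil an [ffl_coil()].
#' @param weighted multiply each segment by the absolute current multiplier
#'   (i.e. count every physical turn); default `TRUE`.
#' @return Length in meters.
#' @export
coil_wire_length <- function(coil, weighted = TRUE) {
  len <- sqrt(rowSums((coil$end - coil$start)^2))
  if (weighted) sum(len * abs(coil$mult)) else sum(len)
}

#' Concatenate coil geometries
#'
#' Fields of the combined geometry are the superposition of the parts.
#'
#' @param ... `ffl_coil` objects.
#' @param label label for the combined coil.
#' @return An `ffl_coil`.
#' @export
coil_concat <- function(..., label = "combined") {
  coils <- list(...)
  ffl_coil(
    do.call(rbind, lapply(coils, `[[`, "start")),
    do.call(rbind, lapply(coils, `[[`, "end")),
    unlist(lapply(coils, `[[`, "mult")),
    label = label
  )
}

# Polygonal circular loop, axis z, centered at (0, 0, z0).
.circle_loop <- function(radius, z0, n_seg, mult = 1) {
  phi <- seq(0, 2 * pi, length.out = n_seg + 1)
  v <- cbind(radius * cos(phi), radius * sin(phi), z0)
  list(start = v[-(n_seg + 1), , drop = FALSE], end = v[-1, , drop = FALSE],
       mult = rep(mult, n_seg))
}

#' Solenoid winding
#'
#' `turns` coaxial circular loops (polygonal approximation) wound at uniform
#' pitch `length / turns` filling the axial extent `length`, centered on the
#' origin, axis along z: loop centers sit at the mid-pitch positions
#' `(i - (turns + 1) / 2) * length / turns`, as a physically wound wire lies.
#'
#' @param radius loop radius (m).
#' @param length axial extent of the winding (m); `0` stacks all turns at z = 0.
#' @param turns number of turns (>= 1).
#' @param segments_per_loop straight segments used per loop (default 64).
#' @param label text label.
#' @return An `ffl_coil`.
#' @export
#' @examples
#' rodent <- make_solenoid(0.025, 0.05, 25)   # rodent head receive coil
#' human  <- make_solenoid(0.12, 0.24, 25)    # human head receive coil
make_solenoid <- function(radius, length, turns, segments_per_loop = 64,
                          label = sprintf("solenoid r=%g l=%g N=%d", radius, length, turns)) {
  if (!is.finite(radius) || radius <= 0) stop("invalid coil geometry: radius must be > 0", call. = FALSE)
  if (length < 0) stop("invalid coil geometry: length must be >= 0", call. = FALSE)
  turns <- as.integer(turns)
  if (is.na(turns) || turns < 1) stop("invalid coil geometry: turns must be >= 1", call. = FALSE)
  z <- if (turns == 1) 0 else (seq_len(turns) - (turns + 1) / 2) * (length / turns)
  loops <- lapply(z, function(zi) .circle_loop(radius, zi, segments_per_loop))
  ffl_coil(
    do.call(rbind, lapply(loops, `[[`, "start")),
    do.call(rbind, lapply(loops, `[[`, "end")),
    unlist(lapply(loops, `[[`, "mult")),
    label = label
  )
}

#' Maxwell / Helmholtz loop pair
#'
#' Two coaxial circular loop stacks at z = +/- spacing/2. With
#' `anti_parallel = TRUE` (Maxwell pair) the currents oppose and the pair
#' produces a linear axial gradient with zero field at the midpoint; with
#' `FALSE` (Helmholtz sense) the fields add and the gradient vanishes at the
#' center.
#'
#' @param radius loop radius (m).
#' @param spacing axial center-to-center spacing (m), > 0.
#' @param turns turns per coil (folded into the current multiplier).
#' @param anti_parallel opposing currents (Maxwell) if `TRUE` (default).
#' @param segments_per_loop straight segments per loop.
#' @return An `ffl_coil`.
#' @export
make_maxwell_pair <- function(radius, spacing, turns = 1, anti_parallel = TRUE,
                              segments_per_loop = 64) {
  if (!is.finite(radius) || radius <= 0) stop("invalid coil geometry: radius must be > 0", call. = FALSE)
  if (!is.finite(spacing) || spacing <= 0) stop("invalid coil geometry: spacing must be > 0", call. = FALSE)
  a <- .circle_loop(radius, -spacing / 2, segments_per_loop, mult = turns)
  b <- .circle_loop(radius, +spacing / 2, segments_per_loop,
                    mult = if (anti_parallel) -turns else turns)
  ffl_coil(rbind(a$start, b$start), rbind(a$end, b$end), c(a$mult, b$mult),
           label = sprintf("%s pair r=%g d=%g", if (anti_parallel) "Maxwell" else "Helmholtz",
                           radius, spacing))
}

#' Linear-swing gradient estimate for a Maxwell pair
#'
#' Engineering estimate for the axial gradient of an opposed coil pair: each
#' coil alone produces `peak_field` at its working point and the field swings
#' linearly from +peak to -peak across the `spacing`, giving
#' `2 * peak_field / spacing`.
#'
#' @param peak_field peak field of one coil alone (T).
#' @param spacing coil spacing (m).
#' @return Gradient in T/m.
#' @export
#' @examples
#' maxwell_gradient_estimate(0.13, 0.15)  # ~1.7 T/m
maxwell_gradient_estimate <- function(peak_field, spacing) {
  2 * peak_field / spacing
}

# One stadium ("racetrack") loop in the plane x = x0: straight sides along y
# at z = +/-R, semicircular ends of radius R = short_axis/2 centered at
# y = +/-(long_axis - short_axis)/2.
.racetrack_loop <- function(long_axis, short_axis, x0, n_arc, mult = 1) {
  R <- short_axis / 2
  hy <- (long_axis - short_axis) / 2
  # traverse counter-clockwise in the (y, z) plane viewed from +x
  p <- list()
  p[[1]] <- cbind(seq(-hy, hy, length.out = 2), R)            # top side, +y direction
  ang <- seq(pi / 2, -pi / 2, length.out = n_arc + 1)
  p[[2]] <- cbind(hy + R * cos(ang), R * sin(ang))            # +y end arc
  p[[3]] <- cbind(seq(hy, -hy, length.out = 2), -R)           # bottom side, -y direction
  ang <- seq(-pi / 2, -3 * pi / 2, length.out = n_arc + 1)
  p[[4]] <- cbind(-hy + R * cos(ang), R * sin(ang))           # -y end arc
  yz <- do.call(rbind, p)
  # drop duplicated junction vertices
  keep <- c(TRUE, rowSums(abs(diff(yz))) > 1e-12)
  yz <- yz[keep, , drop = FALSE]
  v <- cbind(x0, yz[, 1], yz[, 2])
  n <- nrow(v) - 1
  list(start = v[-nrow(v), , drop = FALSE], end = v[-1, , drop = FALSE],
       mult = rep(mult, n))
}

#' Opposed racetrack (stadium) coil pair
#'
#' Two stadium-shaped coils (two straight sides joined by semicircular ends),
#' long axis along y, lying in the planes x = +/- spacing/2 with opposing
#' currents. This is the eccentric "Maxwell-like" winding that produces a
#' field-free line along y with equal-magnitude gradients along the two axes
#' transverse to the line.
#'
#' @param long_axis overall long-axis extent of each coil (m).
#' @param short_axis overall short-axis extent (m); must be < `long_axis`.
#' @param spacing separation of the two coil planes (m).
#' @param turns turns per coil.
#' @param current nominal operating current (A), stored as metadata; fields
#'   from [biot_savart()] remain per unit current.
#' @param segments_per_arc straight segments per semicircular end.
#' @return An `ffl_coil`.
#' @export
make_racetrack_pair <- function(long_axis, short_axis, spacing, turns = 1,
                                current = NA_real_, segments_per_arc = 64) {
  if (!is.finite(long_axis) || !is.finite(short_axis) ||
      short_axis <= 0 || long_axis <= short_axis) {
    stop("invalid coil geometry: need long_axis > short_axis > 0", call. = FALSE)
  }
  if (!is.finite(spacing) || spacing <= 0) {
    stop("invalid coil geometry: spacing must be > 0", call. = FALSE)
  }
  a <- .racetrack_loop(long_axis, short_axis, -spacing / 2, segments_per_arc, mult = turns)
  b <- .racetrack_loop(long_axis, short_axis, +spacing / 2, segments_per_arc, mult = -turns)
  ffl_coil(rbind(a$start, b$start), rbind(a$end, b$end), c(a$mult, b$mult),
           label = sprintf("racetrack pair %gx%g d=%g N=%d", long_axis, short_axis,
                           spacing, turns),
           nominal_current = current)
}

#' Biot-Savart field of a coil geometry
#'
#' Exact analytic straight-segment Biot-Savart sum, times mu0, per unit drive
#' current. For segment endpoints a, b and field point p the contribution is
#' `mu0/(4*pi) * (r1 x r2) * (|r1|+|r2|) / (|r1||r2|(|r1||r2| + r1.r2))`
#' with r1 = p - a, r2 = p - b (numerically stable form).
#'
#' @param coil an `ffl_coil`.
#' @param points 3-vector or n x 3 matrix of field points (m).
#' @param guard singularity guard distance to any conductor (m, default 1e-6).
#' @return n x 3 matrix of field vectors in tesla per ampere.
#' @export
#' @examples
#' loop <- make_solenoid(0.05, 0, 1)
#' biot_savart(loop, c(0, 0, 0))  # ~ mu0 / (2 * 0.05)
biot_savart <- function(coil, points, guard = 1e-6) {
  pts <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  out <- matrix(0, nrow(pts), 3)
  s <- coil$start; e <- coil$end; m <- coil$mult
  for (k in seq_len(nrow(pts))) {
    p <- pts[k, ]
    r1 <- cbind(p[1] - s[, 1], p[2] - s[, 2], p[3] - s[, 3])
    r2 <- cbind(p[1] - e[, 1], p[2] - e[, 2], p[3] - e[, 3])
    n1 <- sqrt(rowSums(r1^2)); n2 <- sqrt(rowSums(r2^2))
    dot <- rowSums(r1 * r2)
    # perpendicular distance to the segment line; also guards endpoint contact
    cr <- cbind(r1[, 2] * r2[, 3] - r1[, 3] * r2[, 2],
                r1[, 3] * r2[, 1] - r1[, 1] * r2[, 3],
                r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1])
    seglen <- sqrt(rowSums((e - s)^2))
    perp <- sqrt(rowSums(cr^2)) / seglen
    on_span <- dot < 0 # obtuse-angle test: foot of perpendicular within segment
    if (any(n1 < guard | n2 < guard | (on_span & perp < guard))) {
      stop("singularity: field point within guard distance of a conductor", call. = FALSE)
    }
    denom <- n1 * n2 * (n1 * n2 + dot)
    scale <- m * (n1 + n2) / denom
    out[k, ] <- .mu0 / (4 * pi) * colSums(cr * scale)
  }
  out
}

#' Serialize a coil geometry to JSON
#'
#' @param coil an `ffl_coil`.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
coil_to_json <- function(coil, path = NULL) {
  obj <- list(label = coil$label, nominal_current = coil$nominal_current,
              start = coil$start, end = coil$end, mult = coil$mult)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a coil geometry from JSON
#'
#' @param x file path or JSON string produced by [coil_to_json()].
#' @return An `ffl_coil`.
#' @export
coil_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  nc <- obj$nominal_current
  ffl_coil(obj$start, obj$end, obj$mult, label = obj$label,
           nominal_current = if (is.null(nc) || length(nc) == 0) NA_real_ else nc)
}

#' Evaluate a coil field on a regular grid and export to CSV
#'
#' Writes columns x, y, z, Bx, By, Bz (fields in T per ampere).
#'
#' @param coil an `ffl_coil`.
#' @param x,y,z numeric vectors of grid coordinates (m).
#' @param path output CSV path.
#' @param current drive current (A) to scale the per-amp field by.
#' @return The data frame, invisibly.
#' @export
coil_field_map <- function(coil, x, y, z = 0, path = NULL, current = 1) {
  g <- expand.grid(x = x, y = y, z = z, KEEP.OUT.ATTRS = FALSE)
  B <- biot_savart(coil, as.matrix(g)) * current
  df <- cbind(g, Bx = B[, 1], By = B[, 2], Bz = B[, 3])
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
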