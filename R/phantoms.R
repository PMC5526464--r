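# Synthetic phantoms and functional-contrast dose arithmetic.

#' Point-source phantom
#'
#' A phantom is a set of point iron masses; voxel phantoms are represented
#' as point masses at voxel centers (the sub-resolution extent of a voxel is
#' immaterial to the projection kernel).
#'
#' @param position n x 3 matrix (or 3-vector) of positions (m).
#' @param mass iron masses (kg Fe), one per source, >= 0.
#' @param label text label.
#' @return An object of class `ffl_phantom`.
#' @export
#' @examples
#' # two 50 ug Fe samples, 5 cm apart
#' make_point_phantom(rbind(c(0, 0, 0), c(0.05, 0, 0)), c(50e-9, 50e-9))
make_point_phantom <- function(position = matrix(numeric(0), 0, 3),
                               mass = numeric(0), label = "points") {
  pos <- if (is.null(dim(position))) matrix(position, ncol = 3) else as.matrix(position)
  if (nrow(pos) != length(mass)) stop("one mass per source required", call. = FALSE)
  if (any(mass < 0)) stop("negative iron mass", call. = FALSE)
  structure(list(position = pos, mass = as.numeric(mass), label = label),
            class = "ffl_phantom")
}

#' @export
print.ffl_phantom <- function(x, ...) {
  cat(sprintf("<ffl_phantom> %s: %d sources, total %.4g ng Fe\n",
              x$label, length(x$mass), sum(x$mass) * 1e12))
  invisible(x)
}

#' Two-sample phantom preset
#'
#' Two 50 ug Fe samples at (0, 0, 0) and (5 cm, 0, 0).
#' @return An `ffl_phantom`.
#' @export
two_sample_phantom <- function() {
  make_point_phantom(rbind(c(0, 0, 0), c(0.05, 0, 0)), c(50e-9, 50e-9),
                     label = "two 50 ug samples")
}

#' Activation-scale point sample
#'
#' A single 22 ng Fe point source at the isocenter: the expected iron change
#' of one 3 mm cortical voxel during activation.
#' @param mass_ng iron mass in ng Fe (default 22).
#' @return An `ffl_phantom`.
#' @export
activation_sample_phantom <- function(mass_ng = 22) {
  make_point_phantom(c(0, 0, 0), mass_ng * 1e-12,
                     label = sprintf("%g ng sample", mass_ng))
}

#' Iron mass of a cortical voxel for a given tracer dose
#'
#' Dose arithmetic for CBV functional contrast: the blood in a cubic voxel
#' of edge `voxel_edge_mm` at blood fraction `cbv_fraction`, and the iron it
#' carries when `dose_mg` of Fe is distributed over `blood_volume_L` of
#' blood.
#'
#' @param dose_mg injected iron dose (mg Fe).
#' @param blood_volume_L total blood volume (L).
#' @param cbv_fraction voxel blood fraction (dimensionless).
#' @param voxel_edge_mm isotropic voxel edge (mm).
#' @return Named numeric `c(blood_uL, iron_ng)`.
#' @export
#' @examples
#' voxel_iron_mass(400, 5, 0.05, 3)  # ~1.35 uL blood, ~108 ng Fe
voxel_iron_mass <- function(dose_mg, blood_volume_L, cbv_fraction, voxel_edge_mm) {
  if (any(c(dose_mg, blood_volume_L, cbv_fraction, voxel_edge_mm) < 0)) {
    stop("all inputs must be >= 0", call. = FALSE)
  }
  if (blood_volume_L == 0) stop("zero blood volume", call. = FALSE)
  blood_uL <- voxel_edge_mm^3 * cbv_fraction          # 1 mm^3 = 1 uL
  iron_ng <- dose_mg / blood_volume_L * blood_uL      # mg/L = ng/uL
  c(blood_uL = blood_uL, iron_ng = iron_ng)
}

#' Synthetic gray/white brain ring phantom
#'
#' A 2D stand-in for a segmented axial brain slice: an annular "cortical
#' ribbon" at gray-matter iron concentration enclosing an interior disc at
#' white-matter concentration, discretized to point masses at voxel centers
#' of a square grid in the z = 0 plane. Voxels are cubes of edge
#' `grid_pitch` (mass = concentration x pitch^3).
#'
#' @param grid_pitch voxel edge (m); default 6 mm.
#' @param outer_radius outer ribbon radius (m); default 9 cm.
#' @param ribbon_thickness ribbon thickness (m); default 1.2 cm; must be
#'   smaller than `outer_radius`.
#' @param gray_conc gray-matter iron concentration (kg Fe/m^3); default
#'   4e-3 (4 ng Fe/mm^3).
#' @param white_conc white-matter concentration (kg Fe/m^3); default 0.8e-3.
#' @return An `ffl_phantom` with attribute `concentration_image` (the voxel
#'   grid) and `grid` (x/y voxel centers).
#' @export
make_brain_phantom <- function(grid_pitch = 6e-3, outer_radius = 0.09,
                               ribbon_thickness = 0.012,
                               gray_conc = 4e-3, white_conc = 0.8e-3) {
  if (ribbon_thickness >= outer_radius) {
    stop("ribbon_thickness must be < outer_radius", call. = FALSE)
  }
  half <- ceiling(outer_radius / grid_pitch)
  centers <- (-half:half) * grid_pitch
  g <- expand.grid(x = centers, y = centers, KEEP.OUT.ATTRS = FALSE)
  r <- sqrt(g$x^2 + g$y^2)
  conc <- ifelse(r <= outer_radius - ribbon_thickness, white_conc,
                 ifelse(r <= outer_radius, gray_conc, 0))
  keep <- conc > 0
  out <- make_point_phantom(cbind(g$x[keep], g$y[keep], 0),
                            conc[keep] * grid_pitch^3,
                            label = "synthetic gray/white brain ring")
  attr(out, "concentration_image") <- matrix(conc, length(centers), length(centers))
  attr(out, "grid") <- centers
  out
}

#' Serialize a phantom to JSON / read it back
#' @param phantom an `ffl_phantom`.
#' @param path file path; if `NULL`, returns the JSON string.
#' @return Path (invisibly) or JSON string.
#' @export
phantom_to_json <- function(phantom, path = NULL) {
  js <- jsonlite::toJSON(list(label = phantom$label, position = phantom$position,
                              mass = phantom$mass),
                         digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname phantom_to_json
#' @param x path or JSON string.
#' @export
phantom_from_json <- function(x) {
  o <- jsonlite::fromJSON(x)
  make_point_phantom(o$position, o$mass, label = o$label)
}
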