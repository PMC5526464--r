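# Langevin magnetization model of superparamagnetic iron oxide nanoparticles
# (SPIONs): the quasi-static, memoryless tracer model driving all signal
# synthesis. Specific magnetization is expressed per kg of elemental Fe.

#' Langevin function
#'
#' `L(x) = coth(x) - 1/x`, the equilibrium magnetization law for an ideal
#' superparamagnet; odd, monotone, bounded in (-1, 1). For `|x| < 1e-4` the
#' series `x/3 - x^3/45` is used to avoid cancellation.
#'
#' @param x dimensionless argument (field energy over thermal energy).
#' @return Values in (-1, 1).
#' @export
#' @examples
#' langevin(1)  # 0.3130353...
langevin <- function(x) {
  out <- x
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 45
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' SPION Langevin model
#'
#' @param s_sat specific saturation moment, A m^2 per kg elemental Fe (> 0).
#' @param beta field-scale parameter in 1/T, acting on the field expressed as
#'   mu0*H in tesla (> 0).
#' @param label text label.
#' @return An object of class `spion_model`.
#' @export
spion_model <- function(s_sat, beta, label = "SPION") {
  if (!is.finite(s_sat) || s_sat <= 0) stop("s_sat must be > 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  structure(list(s_sat = s_sat, beta = beta, label = label), class = "spion_model")
}

#' @export
print.spion_model <- function(x, ...) {
  cat(sprintf("<spion_model> %s: s_sat = %.4g A m^2/kg Fe, beta = %.4g 1/T (knee ~%.3g mT)\n",
              x$label, x$s_sat, x$beta, 1000 / x$beta))
  invisible(x)
}

#' Equilibrium SPION magnetization
#'
#' `M = c * s_sat * L(beta * |B|) * B / |B|` (A/m when the concentration is
#' in kg Fe / m^3); the zero vector where `|B| = 0`.
#'
#' @param model a [spion_model()].
#' @param concentration iron concentration, kg Fe / m^3 (>= 0; scalar or
#'   length-n).
#' @param B 3-vector or n x 3 matrix of applied fields (T, as mu0*H).
#' @return n x 3 matrix of magnetization vectors.
#' @export
magnetization <- function(model, concentration, B) {
  if (any(concentration < 0)) stop("concentration must be >= 0", call. = FALSE)
  Bm <- if (is.null(dim(B))) matrix(B, ncol = 3) else as.matrix(B)
  nb <- sqrt(rowSums(Bm^2))
  mag <- concentration * model$s_sat * langevin(model$beta * nb)
  unit <- Bm / ifelse(nb > 0, nb, 1)
  unit * ifelse(nb > 0, mag, 0)
}

#' Fit a Langevin model to M(H) samples
#'
#' Nonlinear least-squares fit of `(s_sat, beta)` to sampled specific
#' magnetization versus applied field, as measured magnetization curves are
#' fit for a particular tracer batch.
#'
#' @param field applied fields (T, as mu0*H).
#' @param specific_moment specific moments (A m^2 per kg Fe).
#' @param start optional list with starting `s_sat`, `beta`; a heuristic
#'   (90th-percentile moment, knee from the initial slope) is used otherwise.
#' @return A `spion_model` with attributes `residual_norm` and `fit`.
#' @export
fit_mh_curve <- function(field, specific_moment, start = NULL) {
  keep <- is.finite(field) & is.finite(specific_moment)
  field <- field[keep]; specific_moment <- specific_moment[keep]
  if (length(unique(field)) < 3) {
    stop("fit error: need >= 3 distinct field values spanning the knee", call. = FALSE)
  }
  if (is.null(start)) {
    s0 <- stats::quantile(abs(specific_moment), 0.9, names = FALSE)
    if (s0 <= 0) stop("fit error: degenerate magnetization samples", call. = FALSE)
    # initial slope of L is beta/3
    sm <- abs(field) < stats::quantile(abs(field), 0.3, names = FALSE) + 1e-30
    slope <- tryCatch(stats::coef(stats::lm(specific_moment[sm] ~ 0 + field[sm]))[[1]],
                      error = function(e) NA_real_)
    b0 <- if (is.finite(slope) && slope > 0) 3 * slope / s0 else 1 / max(abs(field))
    start <- list(s_sat = s0, beta = max(b0, 1e-6))
  }
  fit <- minpack.lm::nlsLM(
    specific_moment ~ s_sat * langevin(beta * field),
    start = start,
    lower = c(s_sat = 1e-12, beta = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  out <- spion_model(cf[["s_sat"]], cf[["beta"]], label = "fitted SPION")
  attr(out, "residual_norm") <- sqrt(sum(stats::resid(fit)^2))
  attr(out, "fit") <- fit
  out
}

#' Read M(H) samples from CSV and fit
#'
#' Expects two columns: field in tesla and specific moment in A m^2 per kg
#' Fe (named `field_T`, `specific_moment_Am2_per_kgFe`, or the first two
#' columns).
#'
#' @param path CSV path.
#' @return A fitted `spion_model` (see [fit_mh_curve()]).
#' @export
fit_mh_csv <- function(path) {
  df <- utils::read.csv(path)
  f <- if ("field_T" %in% names(df)) df$field_T else df[[1]]
  m <- if ("specific_moment_Am2_per_kgFe" %in% names(df)) {
    df$specific_moment_Am2_per_kgFe
  } else {
    df[[2]]
  }
  fit_mh_curve(f, m)
}

#' Default single-core SPION model from physical parameters
#'
#' Builds a Langevin model for a monodisperse spherical magnetite core:
#' per-particle moment `m_p = (pi/6) d^3 Ms_bulk`, field-scale parameter
#' `beta = m_p / (kB T)` (1/T, since fields are mu0*H in tesla), and specific
#' saturation moment `s_sat = Ms_bulk / (rho_magnetite * fe_mass_fraction)`
#' per kg elemental Fe.
#'
#' @param core_diameter magnetic core diameter (m); default 25 nm.
#' @param Ms_bulk bulk saturation magnetization (A/m); default 4.8e5
#'   (magnetite).
#' @param temperature tracer environment temperature (K); default 300.
#' @return A `spion_model` with attribute `m_p` (per-particle moment, A m^2).
#' @export
#' @examples
#' default_spion()
default_spion <- function(core_diameter = 25e-9, Ms_bulk = 4.8e5, temperature = 300) {
  if (any(c(core_diameter, Ms_bulk, temperature) <= 0)) {
    stop("all inputs must be > 0", call. = FALSE)
  }
  k <- ffl_constants()
  m_p <- pi / 6 * core_diameter^3 * Ms_bulk
  beta <- m_p / (k$kB * temperature)
  s_sat <- Ms_bulk / (k$rho_magnetite * k$fe_mass_fraction)
  out <- spion_model(s_sat, beta,
                     label = sprintf("%.0f nm magnetite core", core_diameter * 1e9))
  attr(out, "m_p") <- m_p
  out
}

#' Serialize a SPION model to JSON
#' @param model a `spion_model`.
#' @param path file path; if `NULL`, returns the JSON string.
#' @return Path (invisibly) or JSON string.
#' @export
spion_to_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(list(s_sat = model$s_sat, beta = model$beta,
                              label = model$label),
                         digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a SPION model from JSON
#' @param x path or JSON string.
#' @return A `spion_model`.
#' @export
spion_from_json <- function(x) {
  o <- jsonlite::fromJSON(x)
  spion_model(o$s_sat, o$beta, label = o$label)
}
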