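# Linear forward operator from the protocol physics, least-squares image
# reconstruction, analytic and Monte-Carlo SNR propagation, and projection
# point-spread-function fits.

#' Reconstruction grid
#'
#' Square pixel grid in the z = 0 slice, centered on the isocenter.
#'
#' @param n_x,n_y pixel counts.
#' @param pitch pixel pitch (m, > 0).
#' @return An object of class `ffl_grid` with pixel-center coordinates.
#' @export
#' @examples
#' recon_grid(35, 35, 0.20 / 35)  # human default: 35 x 35 over 20 cm
recon_grid <- function(n_x, n_y = n_x, pitch) {
  stopifnot(pitch > 0, n_x >= 1, n_y >= 1)
  x <- (seq_len(n_x) - (n_x + 1) / 2) * pitch
  y <- (seq_len(n_y) - (n_y + 1) / 2) * pitch
  g <- expand.grid(x = x, y = y, KEEP.OUT.ATTRS = FALSE)
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y), pitch = pitch,
                 x = x, y = y, centers = cbind(g$x, g$y, 0)),
            class = "ffl_grid")
}

#' Default grid for a protocol
#'
#' `n_points` x `n_points` pixels spanning the protocol FOV (pitch =
#' fov / n_points), matching the sampling the protocol was designed for.
#' @param protocol an `ffl_protocol`.
#' @return An `ffl_grid`.
#' @export
default_grid <- function(protocol) {
  recon_grid(protocol$n_points, protocol$n_points, protocol$fov / protocol$n_points)
}

#' Build the linear forward (system) matrix
#'
#' Column p is the vectorized noiseless sinogram of a unit iron mass at
#' pixel p's center. The fast path uses the shift-invariant 1D projection
#' kernel plus rotation geometry (exact for the ideal field model with a
#' uniform receive descriptor); `method = "direct"` simulates every
#' (pixel, angle, step) record by brute force.
#'
#' @param protocol an `ffl_protocol`.
#' @param grid an `ffl_grid` within the FOV.
#' @param method `"kernel"` (default) or `"direct"`.
#' @return Matrix of size `(n_projections * n_points) x n_pixels` (V per kg
#'   Fe); measurement index runs angle-fastest (angle varies down columns of
#'   the sinogram stacking, i.e. `vec(values)`).
#' @export
build_system_matrix <- function(protocol, grid, method = c("kernel", "direct")) {
  method <- match.arg(method)
  n_meas <- protocol$n_projections * protocol$n_points
  n_pix <- nrow(grid$centers)
  A <- matrix(0, n_meas, n_pix)
  if (method == "kernel") {
    kern <- projection_kernel(protocol)
    angles <- projection_angles(protocol)
    sched <- shift_schedule(protocol)
    for (j in seq_along(angles)) {
      xp <- grid$centers[, 1] * cos(angles[j]) - grid$centers[, 2] * sin(angles[j])
      for (i in seq_along(sched$positions)) {
        row <- j + (i - 1) * protocol$n_projections
        A[row, ] <- kern$fun(xp - sched$positions[i])
      }
    }
  } else {
    for (p in seq_len(n_pix)) {
      ph <- make_point_phantom(grid$centers[p, ], 1)
      sg <- acquire_sinogram(ph, protocol, noiseless = TRUE, method = "direct")
      A[, p] <- as.vector(sg$values)
    }
  }
  A
}

#' Default ridge parameter
#'
#' `1e-6 * trace(A^T A) / n_pixels`, a conditioning floor scaled to the
#' operator's energy.
#' @param A system matrix.
#' @return Scalar ridge.
#' @export
default_ridge <- function(A) {
  1e-6 * sum(A^2) / ncol(A)
}

#' Least-squares image reconstruction
#'
#' Solves `min ||A x - b||^2 + ridge * ||x||^2`. `method = "cg"` (default)
#' runs conjugate gradients on the normal equations; `"direct"` factorizes
#' `A^T A + ridge I` (exactly linear in `b`, used by the analytic SNR path).
#'
#' @param sinogram an `ffl_sinogram` or numeric vector `b` of length
#'   `nrow(A)` (vectorized angle-fastest).
#' @param system_matrix matrix from [build_system_matrix()].
#' @param ridge Tikhonov weight (>= 0); default [default_ridge()].
#' @param method `"cg"` or `"direct"`.
#' @param tol CG relative-residual tolerance.
#' @param maxit CG iteration cap; exceeding it is an error.
#' @return An `ffl_image`: matrix `pixels` (kg Fe per pixel) with the grid
#'   dimensions when they can be inferred, else a vector; attribute
#'   `residual` reports the final normal-equation relative residual.
#' @export
reconstruct <- function(sinogram, system_matrix, ridge = NULL,
                        method = c("cg", "direct"), tol = 1e-10, maxit = NULL) {
  method <- match.arg(method)
  b <- if (inherits(sinogram, "ffl_sinogram")) as.vector(sinogram$values) else as.numeric(sinogram)
  if (length(b) != nrow(system_matrix)) stop("sinogram/system matrix size mismatch", call. = FALSE)
  if (is.null(ridge)) ridge <- default_ridge(system_matrix)
  rhs <- crossprod(system_matrix, b)
  if (method == "direct") {
    G <- crossprod(system_matrix)
    diag(G) <- diag(G) + ridge
    x <- solve(G, rhs)
    res <- NA_real_
  } else {
    n <- ncol(system_matrix)
    if (is.null(maxit)) maxit <- 4L * n
    x <- numeric(n)
    Aop <- function(v) crossprod(system_matrix, system_matrix %*% v) + ridge * v
    r <- rhs
    p <- r
    rs <- sum(r^2)
    rhs_norm <- sqrt(sum(rhs^2))
    if (rhs_norm == 0) rhs_norm <- 1
    it <- 0
    while (sqrt(rs) / rhs_norm > tol) {
      it <- it + 1
      if (it > maxit) {
        stop(sprintf("CG failed to converge: relative residual %.3g after %d iterations",
                     sqrt(rs) / rhs_norm, maxit), call. = FALSE)
      }
      Ap <- Aop(p)
      alpha <- rs / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      rs_new <- sum(r^2)
      p <- r + (rs_new / rs) * p
      rs <- rs_new
    }
    res <- sqrt(rs) / rhs_norm
  }
  structure(list(pixels = as.numeric(x)), class = "ffl_image", residual = res)
}

#' Reshape a reconstructed image onto its grid
#' @param image an `ffl_image` (or numeric vector).
#' @param grid the `ffl_grid` used to build the system matrix.
#' @return `n_x` x `n_y` matrix (x varies down rows).
#' @export
image_matrix <- function(image, grid) {
  v <- if (inherits(image, "ffl_image")) image$pixels else as.numeric(image)
  matrix(v, grid$n_x, grid$n_y)
}

#' Per-pixel SNR map
#'
#' Reconstructs the noiseless sinogram of the phantom, then attaches a noise
#' std to every pixel.
#'
#' `method = "analytic"`: the per-measurement noise std (per-sample sigma
#' through the comb filter, `sigma * sqrt(2/N)` per harmonic real part,
#' `/sqrt(n_averages)`) is propagated through the explicit reconstruction
#' operator `R = (A^T A + ridge I)^-1 A^T`; the pixel std is the row norm of
#' `R` times that std. `method = "monte_carlo"`: empirical std of the
#' reconstruction over `n_realizations` seeded coefficient-noise draws.
#'
#' @param phantom an `ffl_phantom`.
#' @param protocol an `ffl_protocol` with `noise_sigma > 0`.
#' @param grid an `ffl_grid`; default [default_grid()].
#' @param method `"analytic"` or `"monte_carlo"`.
#' @param ridge ridge weight; default [default_ridge()].
#' @param n_realizations Monte-Carlo sample count (default 200).
#' @param seed seed for the Monte-Carlo draws.
#' @param system_matrix optional precomputed matrix (must match protocol and
#'   grid).
#' @return An `ffl_snr_map`: `snr` (pixel matrix), `max_snr`,
#'   `noise_sigma_per_pixel`, `image` (noiseless reconstruction).
#' @export
snr_map <- function(phantom, protocol, grid = default_grid(protocol),
                    method = c("analytic", "monte_carlo"), ridge = NULL,
                    n_realizations = 200, seed = 1, system_matrix = NULL) {
  method <- match.arg(method)
  if (protocol$noise_sigma <= 0) {
    stop("undefined SNR: protocol noise_sigma must be > 0", call. = FALSE)
  }
  A <- if (is.null(system_matrix)) build_system_matrix(protocol, grid) else system_matrix
  if (is.null(ridge)) ridge <- default_ridge(A)
  b <- as.vector(acquire_sinogram(phantom, protocol, noiseless = TRUE)$values)
  sig_meas <- .sinogram_noise_sigma(protocol)
  G <- crossprod(A)
  diag(G) <- diag(G) + ridge
  Rop <- solve(G, t(A))          # reconstruction operator, n_pix x n_meas
  x <- as.vector(Rop %*% b)
  if (method == "analytic") {
    pix_sd <- sig_meas * sqrt(rowSums(Rop^2))
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    n_meas <- length(b)
    acc <- matrix(0, length(x), n_realizations)
    for (k in seq_len(n_realizations)) {
      acc[, k] <- Rop %*% (b + stats::rnorm(n_meas, 0, sig_meas))
    }
    pix_sd <- apply(acc, 1, stats::sd)
  }
  snr <- abs(x) / pix_sd
  structure(list(snr = matrix(snr, grid$n_x, grid$n_y),
                 max_snr = max(snr),
                 noise_sigma_per_pixel = matrix(pix_sd, grid$n_x, grid$n_y),
                 image = matrix(x, grid$n_x, grid$n_y),
                 grid = grid, method = method),
            class = "ffl_snr_map")
}

#' @export
print.ffl_snr_map <- function(x, ...) {
  cat(sprintf("<ffl_snr_map> %d x %d pixels (%s), max SNR = %.1f\n",
              nrow(x$snr), ncol(x$snr), x$method, x$max_snr))
  invisible(x)
}

#' Fit Gaussian and Lorentzian shapes to a single projection
#'
#' Least-squares fits of `a * exp(-(x - mu)^2 / (2 s^2))` and
#' `a / (1 + ((x - mu) / gamma)^2)` to a single-peak projection, as used to
#' characterize the FFL point-spread function. Returns both fits and the
#' full width at half maximum of the better one (by residual sum of
#' squares).
#'
#' @param projection numeric vector of projection values.
#' @param positions shift positions (m), same length.
#' @return List with `gaussian`, `lorentzian` (each: `par`, `rss`, `fwhm`),
#'   `best` (`"gaussian"` or `"lorentzian"`) and `fwhm` (m).
#' @export
fit_projection_psf <- function(projection, positions) {
  stopifnot(length(projection) == length(positions))
  pk <- which.max(abs(projection))
  sgn <- sign(projection[pk])
  y <- projection * sgn
  n_max <- sum(diff(sign(diff(y))) < 0)
  if (n_max > 1 && stats::sd(y) > 0) {
    warning("projection does not look unimodal; PSF fit may be unreliable")
  }
  # normalize the amplitude so the Jacobian columns are commensurate
  # (projection values can be ~1e-12 V, which otherwise makes the position
  # and width gradient columns numerically rank-deficient)
  scale <- max(y)
  if (scale <= 0) stop("fit error: projection has no positive peak", call. = FALSE)
  y <- y / scale
  a0 <- 1
  mu0 <- positions[pk]
  above <- positions[y >= a0 / 2]
  w0 <- max(diff(range(above)), diff(range(positions)) / length(positions))
  # a center start of exactly zero yields a zero numeric-derivative column
  # (relative step sizing), so nudge it off the origin
  if (mu0 == 0) mu0 <- 1e-3 * w0
  gfit <- minpack.lm::nlsLM(y ~ a * exp(-(positions - mu)^2 / (2 * s^2)),
                            start = list(a = a0, mu = mu0, s = w0 / 2.355),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  lfit <- minpack.lm::nlsLM(y ~ a / (1 + ((positions - mu) / g)^2),
                            start = list(a = a0, mu = mu0, g = w0 / 2),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  gp <- stats::coef(gfit); lp <- stats::coef(lfit)
  gp[["a"]] <- gp[["a"]] * scale
  lp[["a"]] <- lp[["a"]] * scale
  gauss <- list(par = gp, rss = sum(stats::resid(gfit)^2) * scale^2,
                fwhm = 2 * sqrt(2 * log(2)) * abs(gp[["s"]]))
  lorentz <- list(par = lp, rss = sum(stats::resid(lfit)^2) * scale^2,
                  fwhm = 2 * abs(lp[["g"]]))
  best <- if (gauss$rss <= lorentz$rss) "gaussian" else "lorentzian"
  list(gaussian = gauss, lorentzian = lorentz, best = best,
       fwhm = if (best == "gaussian") gauss$fwhm else lorentz$fwhm)
}

#' Export an image or SNR map to CSV
#'
#' Long format: `x`, `y`, `value`.
#' @param image matrix (e.g. `$snr` or `$image` of an [snr_map()]), or an
#'   `ffl_image` with `grid`.
#' @param grid the `ffl_grid`.
#' @param path output path.
#' @return The data frame, invisibly.
#' @export
image_to_csv <- function(image, grid, path) {
  m <- if (inherits(image, "ffl_image")) image_matrix(image, grid) else image
  df <- expand.grid(x = grid$x, y = grid$y, KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(m)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
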