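# Moments and diagnostics of radial density series, plus the closed-form
# MSD limits of bounded diffusion.

#' Mean squared displacement of a density series
#'
#' Computes \eqn{\langle r^2\rangle(t) = \int_\Omega r^2 \phi\, dA} by
#' exact cell-wise quadrature (each cell contributes its density times the
#' exact second moment of its annulus). For shrinking-domain series the
#' moment is returned in physical coordinates.
#'
#' @param series a `density_series` from one of the solvers.
#' @return An `msd_curve` data frame (`se = 0`, `n = 0`: model curve).
#' @export
density_msd <- function(series) {
  w <- series$grid$m2
  msd <- as.numeric(crossprod(series$phi, w))
  if (series$scaled) msd <- msd * series$R^4
  out <- data.frame(t = series$times, msd = msd, se = 0, n = 0L)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Total probability mass of a density series
#'
#' Conservation diagnostic for the zero-flux boundaries: returns
#' \eqn{\int \phi \, dA} (physical mass) at each output time.
#'
#' @param series a `density_series`.
#' @return Numeric vector of masses, one per output time.
#' @export
total_mass <- function(series) {
  m <- as.numeric(crossprod(series$phi, series$grid$areas))
  if (series$scaled) m <- m * series$R^2
  m
}

#' Boundary density trace of a density series
#'
#' Density at the domain edge per output time (outermost cell average;
#' second-order accurate under the zero-flux condition).
#'
#' @param series a `density_series`.
#' @return Numeric vector \eqn{\phi(R, t)} per output time.
#' @export
boundary_density <- function(series) {
  series$phi[series$grid$n, ]
}

#' Short-time and uniform-limit MSD of bounded diffusion
#'
#' `msd_short_time` evaluates the free-diffusion law
#' \eqn{\langle r^2\rangle = 4Dt}, valid while \eqn{t \ll R^2/D};
#' `msd_uniform_limit` evaluates the long-time plateau \eqn{R^2/2} of a
#' uniform density on a disk of radius `R`.
#'
#' @param D diffusion rate (m^2/s).
#' @param t time (s), >= 0.
#' @param R disk radius (m).
#' @return MSD in m^2.
#' @export
msd_short_time <- function(D, t) {
  if (D <= 0 || any(t < 0)) stop("need D > 0 and t >= 0")
  4 * D * t
}

#' @rdname msd_short_time
#' @export
msd_uniform_limit <- function(R) {
  if (R <= 0) stop("'R' must be positive")
  R^2 / 2
}

#' MSD of bounded diffusion from the boundary density history
#'
#' Evaluates the exact moment identity for zero-flux radial diffusion,
#' \deqn{\langle r^2\rangle(t) = 4D\left(t - \pi R^2 \int_0^t
#'   \phi(R, \tau)\, d\tau\right),}
#' with the time integral by cumulative trapezoid over the sampled history.
#'
#' @param D diffusion rate (m^2/s).
#' @param R disk radius (m).
#' @param times history sampling times (s), starting at or near 0 and dense
#'   enough for trapezoidal quadrature.
#' @param phi_R boundary density \eqn{\phi(R, t)} at `times` (1/m^2),
#'   non-negative.
#' @return Numeric vector of MSD values (m^2) at `times`.
#' @export
msd_bounded <- function(D, R, times, phi_R) {
  stopifnot(length(times) == length(phi_R))
  if (any(phi_R < 0)) stop("boundary density history must be non-negative")
  4 * D * (times - pi * R^2 * cumtrapz(times, phi_R))
}

# exponent(r) = int_0^r chi f(s) / D ds, vectorised over r
convection_exponent <- function(D, conv, r) {
  chi <- conv$chi
  switch(conv$form,
    none = rep(0, length(r)),
    uniform = chi * r / D,
    power = chi * r^(conv$n + 1) / ((conv$n + 1) * D),
    saturating = {
      grid <- seq(0, max(r), length.out = 4001L)
      cum <- cumtrapz(grid, chi * conv$f(grid) / D)
      approx(grid, cum, xout = r)$y
    }
  )
}

#' Steady-state density of radial convection-diffusion
#'
#' The zero-flux steady state of inward convection balanced by diffusion,
#' \eqn{\phi_s(r) \propto \exp(-\int_0^r \chi f(s)/D \, ds)}, normalised
#' numerically to unit mass on the disk.
#'
#' @param D diffusion rate (m^2/s).
#' @param conv a [convection_spec()] (`uniform`, `power` or `saturating`).
#' @param R disk radius (m).
#' @param grid optional [build_radial_grid()] at whose cell centres the
#'   profile is returned.
#' @return Data frame with columns `r` (m) and `phi` (1/m^2).
#' @export
steady_state_density <- function(D, conv, R, grid = NULL) {
  stopifnot(inherits(conv, "convection_spec"))
  if (D <= 0 || R <= 0) stop("need D > 0 and R > 0")
  if (is.null(grid)) grid <- build_radial_grid(R, 400L)
  shape <- function(r) exp(-convection_exponent(D, conv, r))
  norm <- integrate(function(r) 2 * pi * r * shape(r), 0, R,
                    rel.tol = 1e-10)$value
  data.frame(r = grid$centres, phi = shape(grid$centres) / norm)
}

#' Steady-state MSD of radial convection-diffusion
#'
#' \eqn{\langle r_s^2\rangle = \int_\Omega r^2 \phi_s \, dA} from the
#' normalised steady profile; always positive, decreasing in `chi` and
#' increasing in `D`.
#'
#' @inheritParams steady_state_density
#' @return Steady-state MSD (m^2).
#' @export
steady_state_msd <- function(D, conv, R) {
  stopifnot(inherits(conv, "convection_spec"))
  if (D <= 0 || R <= 0) stop("need D > 0 and R > 0")
  shape <- function(r) exp(-convection_exponent(D, conv, r))
  norm <- integrate(function(r) 2 * pi * r * shape(r), 0, R,
                    rel.tol = 1e-10)$value
  num <- integrate(function(r) 2 * pi * r^3 * shape(r), 0, R,
                   rel.tol = 1e-10)$value
  num / norm
}

#' Export a density series as long-format CSV
#'
#' Columns `t_s,r_m,phi_per_m2,R_m` (physical radius per row).
#'
#' @param series a `density_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_density_series <- function(series, path) {
  nt <- length(series$times)
  rho <- series$grid$centres
  r_phys <- if (series$scaled) outer(rho, series$R) else matrix(rho, length(rho), nt)
  out <- data.frame(
    t_s = rep(series$times, each = series$grid$n),
    r_m = as.vector(r_phys),
    phi_per_m2 = as.vector(series$phi),
    R_m = rep(series$R, each = series$grid$n)
  )
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
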