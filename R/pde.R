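# Conservative finite-volume solvers for the radially symmetric movement
# PDEs on a disk: plain diffusion, (non-)autonomous convection-diffusion,
# and diffusion on an apically shrinking domain in the scaled coordinate
# rho = r / R(t).
#
# Discretisation: uniform cell edges, exact annulus areas, central edge
# fluxes, stiff adaptive implicit integration (lsoda, banded Jacobian).
# The cell Peclet number is small for all parameter sets of interest, so
# central convection fluxes are stable and second-order.

#' Build a uniform radial finite-volume grid on a disk
#'
#' @param R domain radius (m), or 1 for the scaled coordinate.
#' @param n_cells number of cells; at least 50 so that a 100 m comparison
#'   radius spans several cells at field scales.
#' @return An object of class `radial_grid`: edges, centres, exact annulus
#'   areas, and the exact per-cell second-moment weights
#'   \eqn{\int_{cell} r^2 \, dA}.
#' @export
build_radial_grid <- function(R, n_cells = 400L) {
  if (R <= 0) stop("'R' must be positive")
  if (n_cells < 50L) stop("'n_cells' must be >= 50 (under-resolved)")
  edges <- seq(0, R, length.out = n_cells + 1L)
  structure(list(
    R = R, n = as.integer(n_cells), h = edges[2],
    edges = edges,
    centres = (edges[-1] + edges[-(n_cells + 1L)]) / 2,
    areas = pi * diff(edges^2),
    m2 = (pi / 2) * diff(edges^4)
  ), class = "radial_grid")
}

#' Radial convection specification
#'
#' Inward radial drift \eqn{v(r, t) = \chi f(r)} for `t >= t_s` (zero
#' before), with `f` one of: `none` (0), `uniform` (1), `power`
#' (\eqn{r^n}), `saturating` (\eqn{1/(1+r^n)}). Positive `chi` transports
#' density toward the origin.
#'
#' @param form convection form.
#' @param chi convection strength, >= 0 (m/s for `uniform`; m^(1-n)/s for
#'   `power`; m/s scale for `saturating`).
#' @param n exponent, >= 0.
#' @param t_s activation time (s); drift is zero before `t_s`.
#' @return An object of class `convection_spec`.
#' @export
convection_spec <- function(form = c("none", "uniform", "power", "saturating"),
                            chi = 0, n = 2, t_s = 0) {
  form <- match.arg(form)
  if (chi < 0) stop("'chi' must be non-negative")
  if (n < 0) stop("'n' must be non-negative")
  f <- switch(form,
    none = function(r) rep(0, length(r)),
    uniform = function(r) rep(1, length(r)),
    power = function(r) r^n,
    saturating = function(r) 1 / (1 + r^n)
  )
  structure(list(form = form, chi = chi, n = n, t_s = t_s, f = f),
            class = "convection_spec")
}

#' Time-dependent domain radius
#'
#' Wraps a callable radius `R(t)` (m) and its derivative (m/s) over a
#' validity window. If `dR` is omitted it is obtained by central
#' differencing.
#'
#' @param R function of time returning the radius (m).
#' @param dR optional derivative function (m/s).
#' @param t_max end of validity window (s); `R(t)` must stay positive on
#'   `[0, t_max]`.
#' @return An object of class `domain_radius`.
#' @export
domain_radius <- function(R, dR = NULL, t_max) {
  stopifnot(is.function(R), t_max > 0)
  if (is.null(dR)) {
    eps <- 1e-3
    dR <- function(t) (R(pmin(t + eps, t_max)) - R(pmax(t - eps, 0))) /
      (pmin(t + eps, t_max) - pmax(t - eps, 0))
  }
  probe <- seq(0, t_max, length.out = 201L)
  if (any(R(probe) <= 0))
    stop("R(t) must remain positive on the validity window")
  structure(list(R = R, dR = dR, t_max = t_max), class = "domain_radius")
}

#' Piecewise-parabolic shrinking radius schedule
#'
#' The apical-shrinkage schedule used for the leap-frog return phase:
#' `R(t) = R0` for `t < t_s`, then
#' \eqn{R(t) = R_0\sqrt{1 - ((t - t_s)/(t_{end} - t_s))^2}}, reaching 0 at
#' `t_end` (dawn).
#'
#' @param R0 initial radius (m).
#' @param t_s shrink onset (s).
#' @param t_end collapse time (s).
#' @param t_max validity window end (s); must be `< t_end`.
#' @return A [domain_radius()] object.
#' @export
parabolic_radius <- function(R0 = 2000, t_s = 5400, t_end = 28800,
                             t_max = t_end - 360) {
  stopifnot(t_s < t_end, t_max < t_end)
  tau2 <- t_end - t_s
  Rf <- function(t) ifelse(t < t_s, R0,
                           R0 * sqrt(pmax(1 - ((t - t_s) / tau2)^2, 0)))
  dRf <- function(t) ifelse(t < t_s, 0,
                            -R0^2 * (t - t_s) / (tau2^2 * Rf(t)))
  domain_radius(Rf, dRf, t_max)
}

new_density_series <- function(grid, times, phi, R, scaled) {
  neg <- phi < 0
  if (any(phi < -1e-12))
    warning("density undershoot below -1e-12 clipped to 0")
  phi[neg] <- 0
  structure(list(grid = grid, times = times, phi = phi, R = R,
                 scaled = scaled),
            class = "density_series")
}

# Shared fixed-domain method-of-lines driver.
# D_fun(t): diffusion rate; v_fun(r, t): inward radial drift speed (>= 0
# pulls density toward the origin).
solve_radial_fv <- function(grid, times, D_fun, v_fun,
                            rtol = 1e-10, atol = 1e-18) {
  n <- grid$n
  h <- grid$h
  re <- grid$edges[2:n]          # interior edges
  areas <- grid$areas
  phi0 <- numeric(n)
  phi0[1] <- 1 / areas[1]        # unit mass in the innermost cell (delta IC)
  rhs <- function(t, phi, p) {
    G <- D_fun(t) * diff(phi) / h +
      v_fun(re, t) * (phi[-1] + phi[-n]) / 2
    list(2 * pi * diff(c(0, re * G, 0)) / areas)
  }
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::ode(y = phi0, times = tt, func = rhs, parms = NULL,
                      method = "lsoda", jactype = "bandint",
                      bandup = 1L, banddown = 1L, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed (istate = ", attr(sol, "istate")[1], ")")
  keep <- match(times, tt)
  phi <- t(unname(sol[keep, -1, drop = FALSE]))   # n_cells x n_times
  new_density_series(grid, times, phi, R = rep(grid$R, length(times)),
                     scaled = FALSE)
}

#' Solve radial diffusion on a disk
#'
#' Integrates \eqn{\phi_t = (D/r)(r \phi_r)_r} on `[0, R]` with unit mass
#' initially in the innermost cell (delta initial condition in the weak
#' sense) and zero-flux boundaries, by a conservative finite-volume method
#' of lines.
#'
#' @param D diffusion rate (m^2/s), > 0.
#' @param R disk radius (m).
#' @param t_out output times (s).
#' @param grid optional [build_radial_grid()]; default 400 cells on `[0, R]`.
#' @param n_cells cells used when `grid` is `NULL`.
#' @param rtol,atol relative/absolute tolerances of the stiff integrator
#'   (defaults keep mass conserved to better than 1e-8 relative).
#' @return A `density_series`: cell-average density (1/m^2) per output time.
#' @export
solve_diffusion <- function(D, R, t_out, grid = NULL, n_cells = 400L,
                            rtol = 1e-10, atol = 1e-18) {
  if (D <= 0) stop("'D' must be positive")
  if (is.null(grid)) grid <- build_radial_grid(R, n_cells)
  solve_radial_fv(grid, t_out,
                  D_fun = function(t) D,
                  v_fun = function(r, t) rep(0, length(r)),
                  rtol = rtol, atol = atol)
}

#' Solve radial convection-diffusion on a disk
#'
#' Adds an inward radial drift (see [convection_spec()]) to
#' [solve_diffusion()]: \eqn{\phi_t = (1/r)(r(D\phi_r + v\phi))_r}, so
#' positive `chi` transports density toward the origin. Zero total flux at
#' `r = R`; mass is conserved.
#'
#' @param D diffusion rate (m^2/s).
#' @param conv a [convection_spec()] with form `uniform`, `power`,
#'   `saturating` (or `none`).
#' @inheritParams solve_diffusion
#' @return A `density_series`.
#' @export
solve_convection_diffusion <- function(D, conv, R, t_out, grid = NULL,
                                       n_cells = 400L,
                                       rtol = 1e-10, atol = 1e-18) {
  stopifnot(inherits(conv, "convection_spec"))
  if (D <= 0) stop("'D' must be positive")
  if (is.null(grid)) grid <- build_radial_grid(R, n_cells)
  solve_radial_fv(grid, t_out,
                  D_fun = function(t) D,
                  v_fun = function(r, t)
                    if (t < conv$t_s) rep(0, length(r))
                    else conv$chi * conv$f(r),
                  rtol = rtol, atol = atol)
}

#' Solve the non-autonomous convection-diffusion model
#'
#' Time-dependent coefficients \eqn{D(t) = D_c |1 - t/t_c|} and inward
#' drift speed \eqn{\chi_c t} for `t >= t_s` (zero before), on a fixed disk
#' of radius `R` with delta initial condition and zero-flux boundaries.
#'
#' @param D_c diffusion scale (m^2/s), > 0.
#' @param t_c diffusion turnover time (s), > 0.
#' @param chi_c inward drift acceleration (m/s^2), > 0.
#' @param t_s drift activation time (s), default 1.5 h.
#' @inheritParams solve_diffusion
#' @return A `density_series`.
#' @export
solve_nonautonomous <- function(D_c, t_c, chi_c, t_s = 5400, R = 2000,
                                t_out, grid = NULL, n_cells = 400L,
                                rtol = 1e-10, atol = 1e-18) {
  if (D_c <= 0 || chi_c < 0) stop("'D_c' must be > 0 and 'chi_c' >= 0")
  if (t_c <= 0) stop("'t_c' must be positive")
  if (is.null(grid)) grid <- build_radial_grid(R, n_cells)
  solve_radial_fv(grid, t_out,
                  D_fun = function(t) D_c * abs(1 - t / t_c),
                  v_fun = function(r, t)
                    if (t < t_s) rep(0, length(r))
                    else rep(chi_c * t, length(r)),
                  rtol = rtol, atol = atol)
}

#' Solve diffusion on an apically shrinking disk
#'
#' Maps diffusion on a disk with moving radius `R(t)` onto the stationary
#' scaled coordinate \eqn{\rho = r/R(t) \in [0, 1]}:
#' \deqn{\phi_t = \frac{D}{R^2}\nabla_\rho^2 \phi +
#'   \frac{\dot R}{R}\,\rho\,\phi_\rho,}
#' with symmetry at \eqn{\rho = 0} and the moving-boundary no-flux condition
#' \eqn{D\phi_\rho(1, t) + R\dot R\,\phi(1, t) = 0}, under which the
#' physical mass \eqn{R^2 \int_0^1 2\pi\rho\,\phi\,d\rho} is conserved.
#' The stored density is the physical density \eqn{\phi(R\rho, t)} (1/m^2).
#'
#' @param D diffusion rate (m^2/s).
#' @param Rfun a [domain_radius()]; must stay positive over `t_out`.
#' @param t_out output times (s), all within `Rfun$t_max`.
#' @param grid optional scaled grid from `build_radial_grid(1, n_cells)`.
#' @param n_cells cells used when `grid` is `NULL`.
#' @return A `density_series` with `scaled = TRUE` and per-time radius.
#' @export
solve_shrinking_domain <- function(D, Rfun, t_out, grid = NULL,
                                   n_cells = 400L) {
  stopifnot(inherits(Rfun, "domain_radius"))
  if (D <= 0) stop("'D' must be positive")
  if (max(t_out) > Rfun$t_max)
    stop("t_out exceeds the validity window of R(t)")
  if (is.null(grid)) grid <- build_radial_grid(1, n_cells)
  if (abs(grid$R - 1) > 1e-12)
    stop("shrinking-domain grid must live on the scaled coordinate [0, 1]")
  n <- grid$n
  h <- grid$h
  re <- grid$edges[2:n]
  areas <- grid$areas
  R0 <- Rfun$R(0)
  phi0 <- numeric(n)
  phi0[1] <- 1 / (R0^2 * areas[1])   # unit physical mass in innermost cell
  rhs <- function(t, phi, p) {
    Rt <- Rfun$R(t)
    dRt <- Rfun$dR(t)
    G <- (D / Rt^2) * diff(phi) / h +
      (dRt / Rt) * re * (phi[-1] + phi[-n]) / 2
    # boundary edge: G(1) = 0 is the moving-boundary no-flux condition
    list(2 * pi * diff(c(0, re * G, 0)) / areas - 2 * (dRt / Rt) * phi)
  }
  tt <- sort(unique(c(0, t_out)))
  sol <- deSolve::ode(y = phi0, times = tt, func = rhs, parms = NULL,
                      method = "lsoda", jactype = "bandint",
                      bandup = 1L, banddown = 1L,
                      rtol = 1e-9, atol = 1e-18)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed (istate = ", attr(sol, "istate")[1], ")")
  keep <- match(t_out, tt)
  phi <- t(unname(sol[keep, -1, drop = FALSE]))
  new_density_series(grid, t_out, phi, R = Rfun$R(t_out), scaled = TRUE)
}
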