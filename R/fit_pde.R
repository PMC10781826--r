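# Nonlinear least-squares fit of the non-autonomous convection-diffusion
# model to an MSD curve.

#' Fit the non-autonomous convection-diffusion model to an MSD curve
#'
#' Least-squares fit of the model MSD (from [solve_nonautonomous()] followed
#' by [density_msd()]) to an observed curve over the parameters
#' `(D_c, t_c, chi_c)` of \eqn{D(t) = D_c|1 - t/t_c|} and inward drift
#' speed \eqn{\chi_c t}. Internally the optimiser (Levenberg--Marquardt)
#' works in an equivalent, better-conditioned parametrisation — the
#' diffusion rate at sunset and its total drop across the night — because
#' `D_c` and `t_c` are strongly correlated in their effect on the curve;
#' estimates are mapped back exactly. `chi_c` is bounded below by 0.
#' Confidence intervals come from the linearised covariance
#' \eqn{\sigma^2 (J^\top J)^{-1}} with t-distribution quantiles.
#'
#' @param curve an `msd_curve` covering the night.
#' @param R disk radius (m) used for the solves.
#' @param t_s drift activation time (s); 0 for the ungated form.
#' @param n_cells radial cells for the solves (a fitting resolution; final
#'   reporting can re-solve at 400 cells).
#' @param start optional numeric vector `c(D_c, t_c, chi_c)` used as the
#'   single starting point; default a small multistart grid around field
#'   magnitudes.
#' @param level confidence level.
#' @return An object of class `nonauto_fit`: `par` (named vector), `ci`
#'   matrix, `r2`, deviance, and a multistart trace.
#' @export
fit_nonautonomous_model <- function(curve, R = 2000, t_s = 5400,
                                    n_cells = 120L, start = NULL,
                                    level = 0.95) {
  stopifnot(inherits(curve, "data.frame"), all(c("t", "msd") %in% names(curve)))
  tt <- curve$t[curve$t > 0]
  y <- curve$msd[curve$t > 0]
  if (length(y) < 4L || max(y) <= 0 || sd(y) == 0)
    stop("degenerate (flat or too short) MSD curve: nothing to fit")
  grid <- build_radial_grid(R, n_cells)
  Tn <- max(tt)
  model_msd <- function(theta) {
    # extreme multistart parameter values can trip the solver's tiny-
    # undershoot clip; that is expected during optimisation
    s <- suppressWarnings(
      solve_nonautonomous(theta[1], theta[2], theta[3], t_s = t_s,
                          R = R, t_out = tt, grid = grid,
                          rtol = 1e-8, atol = 1e-16))
    density_msd(s)$msd
  }
  # internal parametrisation: u = (D0, drop, chi) / scale with
  # D(t) = D0 * |1 - t/t_c|, t_c = Tn * D0 / drop
  scale <- c(100, 100, 1e-5)
  to_theta <- function(u) {
    D0 <- u[1] * scale[1]
    drop <- u[2] * scale[2]
    c(D_c = D0, t_c = Tn * D0 / drop, chi_c = u[3] * scale[3])
  }
  from_theta <- function(theta)
    c(theta[1], theta[1] * Tn / theta[2], theta[3]) / scale
  resid_fun <- function(u) model_msd(to_theta(u)) - y
  starts <- if (!is.null(start)) list(from_theta(unlist(start))) else
    list(c(1, 1, 1), c(0.5, 0.6, 0.5), c(2, 1.5, 2))
  best <- NULL
  trace <- character(0)
  for (u0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = u0, fn = resid_fun,
                         lower = c(1e-3, 1e-4, 0),
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-14, ptol = 1e-12, maxiter = 200,
                           epsfcn = 1e-8)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      trace <- c(trace, conditionMessage(fit))
      next
    }
    trace <- c(trace, sprintf("start (%s): deviance %.4g",
                              paste(signif(u0, 3), collapse = ", "),
                              fit$deviance))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance < 1e-10 * sum(y^2)) break
  }
  if (is.null(best))
    stop("non-autonomous fit failed from every start:\n",
         paste(trace, collapse = "\n"))
  theta <- to_theta(best$par)
  # linearised covariance in the reported parametrisation
  v <- theta / c(100, 3e4, 1e-5)   # order-one for differencing
  rfun_rep <- function(w) model_msd(w * c(100, 3e4, 1e-5)) - y
  J <- numeric_jacobian(rfun_rep, v, rel = 1e-4)
  dof <- length(y) - 3L
  s2 <- best$deviance / dof
  cov_v <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  ci <- matrix(NA_real_, 3, 2,
               dimnames = list(c("D_c", "t_c", "chi_c"), c("lo", "hi")))
  if (!is.null(cov_v)) {
    half <- qt(1 - (1 - level) / 2, dof) * sqrt(pmax(diag(cov_v), 0))
    ci[, 1] <- (v - half) * c(100, 3e4, 1e-5)
    ci[, 2] <- (v + half) * c(100, 3e4, 1e-5)
    ci["chi_c", 1] <- max(ci["chi_c", 1], 0)
  }
  structure(list(
    par = theta, ci = ci,
    r2 = goodness_of_fit(y, model_msd(theta)),
    deviance = best$deviance, at_boundary = best$par[3] <= 0,
    trace = trace, R = R, t_s = t_s, n_cells = n_cells
  ), class = "nonauto_fit")
}

numeric_jacobian <- function(fn, x, rel = 1e-5) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- max(abs(x[j]), 1e-3) * rel
    xp <- x; xp[j] <- x[j] + h
    J[, j] <- (fn(xp) - f0) / h
  }
  J
}

#' @export
print.nonauto_fit <- function(x, ...) {
  cat("Non-autonomous convection-diffusion fit\n")
  tab <- cbind(estimate = x$par, x$ci)
  print(signif(tab, 4))
  cat(sprintf("R2 = %.4f (R = %g m, t_s = %g s, %d cells)\n",
              x$r2, x$R, x$t_s, x$n_cells))
  if (x$at_boundary) cat("note: chi_c estimate at its lower bound 0\n")
  invisible(x)
}
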