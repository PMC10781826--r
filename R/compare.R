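# Within-radius return curves and the pull-vs-leapfrog mechanism comparison.

#' Proportion of the population within a radius of the roost
#'
#' Integrates the density profile over the disk of the given radius at each
#' output time, \eqn{\int_0^{radius} 2\pi r \phi \, dr}, with linear
#' partial-cell handling at the radius (density uniform within a cell, so
#' the cut cell contributes in proportion to annulus area). For
#' shrinking-domain series the radius is applied in physical coordinates;
#' once the domain radius falls below it the proportion is 1.
#'
#' @param series a `density_series`.
#' @param radius comparison radius (m), default 100.
#' @param label source label for the returned curve.
#' @return A `return_curve` data frame: `t` (s), `prop` in \[0, 1\],
#'   `source`.
#' @export
proportion_within_radius <- function(series, radius = 100,
                                     label = "model") {
  grid <- series$grid
  nt <- length(series$times)
  prop <- numeric(nt)
  for (j in seq_len(nt)) {
    mass_cells <- series$phi[, j] * grid$areas
    total <- sum(mass_cells)
    rstar <- if (series$scaled) radius / series$R[j] else radius
    if (rstar >= grid$R) {
      inside <- total
    } else {
      cum <- c(0, cumsum(mass_cells))           # mass within each edge
      i <- findInterval(rstar, grid$edges)      # cell containing rstar
      inside <- cum[i] +
        series$phi[i, j] * pi * (rstar^2 - grid$edges[i]^2)
    }
    scale2 <- if (series$scaled) series$R[j]^2 else 1
    prop[j] <- inside * scale2 / (total * scale2)
  }
  out <- data.frame(t = series$times, prop = pmin(pmax(prop, 0), 1),
                    source = label)
  class(out) <- c("return_curve", "data.frame")
  out
}

#' Empirical cumulative return curve from tracks
#'
#' Cumulative fraction of tracks whose final return time (see
#' [extract_return_times()]) is at or before each grid time. Tracks that
#' never settle within the radius contribute 0 throughout.
#'
#' @param tracks detection table or tracks data frame.
#' @param radius comparison radius (m).
#' @param times evaluation time grid (s).
#' @return A `return_curve` data frame with `source = "data"`.
#' @export
empirical_return_curve <- function(tracks, radius = 100,
                                   times = seq(0, 28800, by = 200)) {
  if (is.null(tracks) || nrow(tracks) == 0) stop("empty track set")
  rt <- extract_return_times(tracks, radius)$return_time
  n <- length(rt)
  prop <- vapply(times, function(tg) sum(!is.na(rt) & rt <= tg) / n,
                 numeric(1))
  out <- data.frame(t = times, prop = prop, source = "data")
  class(out) <- c("return_curve", "data.frame")
  out
}

#' Compare pull and leap-frog return mechanisms within a radius
#'
#' Solves both fitted return mechanisms and reports their within-radius
#' return curves on a common time grid:
#' \itemize{
#'   \item pull: the non-autonomous convection-diffusion model at `theta`;
#'   \item leap frog: diffusion on the apically shrinking domain whose
#'     radius schedule \eqn{R(t) = \sqrt{2(a_{22}t^2 + a_{21}t + a_{20})}}
#'     comes from the piecewise fit, with `D = a11/4`. Once `R(t)` falls
#'     below the comparison radius the proportion is 1 by construction;
#'   \item data (optional): the empirical cumulative return curve.
#' }
#' Dawn is taken as the collapse time of the fitted `R(t)` rather than a
#' hard-coded clock time. The summary reports each curve's terminal value
#' at dawn and its first crossing of 0.5 after the phase switch.
#'
#' @param fit a `piecewise_fit` (e.g. [survey_piecewise_fit()]).
#' @param theta non-autonomous parameters: named vector or list with
#'   `D_c`, `t_c`, `chi_c` (default [survey_nonautonomous_fit()]).
#' @param pull_t_s drift activation time (s) for the pull solve. Default 0:
#'   the non-autonomous drift speed `chi_c * t` is continuous in time and
#'   negligible early in the night, so no gate is needed.
#' @param tracks optional detection table for the empirical curve.
#' @param radius comparison radius (m), default 100.
#' @param R_pull disk radius (m) for the pull solve.
#' @param n_cells radial cells for both solves.
#' @param dt_out output grid spacing (s).
#' @return An object of class `mechanism_comparison`: a `curves` data frame
#'   (`t`, `pull`, `leapfrog`, optionally `data`) and a `summary` table of
#'   terminal values and 0.5-crossing times.
#' @export
compare_mechanisms <- function(fit, theta = survey_nonautonomous_fit()$par,
                               tracks = NULL, radius = 100, R_pull = 2000,
                               n_cells = 400L, dt_out = 200, pull_t_s = 0) {
  stopifnot(inherits(fit, "piecewise_fit"))
  theta <- unlist(theta)[c("D_c", "t_c", "chi_c")]
  dp <- derived_parameters(fit)
  if (!is.finite(dp$dawn)) stop("fitted R(t) never collapses: no dawn time")
  dawn <- dp$dawn
  t_s <- unname(fit$coef["ts"])
  times <- unique(c(seq(dt_out, dawn, by = dt_out), dawn))

  pull <- solve_nonautonomous(theta["D_c"], theta["t_c"], theta["chi_c"],
                              t_s = pull_t_s, R = R_pull, t_out = times,
                              n_cells = n_cells)
  pull_curve <- proportion_within_radius(pull, radius, label = "pull")

  # leap frog: solve while R(t) > radius; all mass is inside afterwards
  a <- fit$coef
  t_stop <- stop_time_at_radius(a, radius, dawn)
  Rfun <- domain_radius(dp$Rt, t_max = t_stop)
  t_solve <- times[times <= t_stop]
  lf <- solve_shrinking_domain(dp$D, Rfun, t_out = t_solve,
                               n_cells = n_cells)
  lf_prop <- proportion_within_radius(lf, radius, label = "leapfrog")$prop
  leap <- c(lf_prop, rep(1, length(times) - length(t_solve)))

  curves <- data.frame(t = times, pull = pull_curve$prop, leapfrog = leap)
  if (!is.null(tracks))
    curves$data <- empirical_return_curve(tracks, radius, times)$prop

  cross <- function(p) {
    idx <- which(times >= t_s & p >= 0.5)
    if (length(idx)) times[min(idx)] else NA_real_
  }
  src <- setdiff(names(curves), "t")
  summary <- data.frame(
    source = src,
    terminal = vapply(src, function(s) curves[[s]][nrow(curves)], numeric(1)),
    t_half = vapply(src, function(s) cross(curves[[s]]), numeric(1))
  )
  rownames(summary) <- NULL
  structure(list(curves = curves, summary = summary, dawn = dawn,
                 radius = radius),
            class = "mechanism_comparison")
}

# time at which the fitted R(t) = sqrt(2 * quad(t)) first drops to `radius`
# (largest root below dawn)
stop_time_at_radius <- function(a, radius, dawn) {
  c2 <- unname(a["a22"]); c1 <- unname(a["a21"])
  c0 <- unname(a["a20"]) - radius^2 / 2
  disc <- c1^2 - 4 * c2 * c0
  if (disc <= 0 || c2 >= 0) return(dawn)
  roots <- (-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2)
  cand <- roots[roots > 0 & roots < dawn]
  if (length(cand)) min(max(cand), dawn) else dawn
}

#' @export
print.mechanism_comparison <- function(x, ...) {
  cat(sprintf("Return-curve comparison within %g m (dawn = %.2f h)\n",
              x$radius, x$dawn / 3600))
  print(transform(x$summary, t_half = t_half / 3600), digits = 3)
  invisible(x)
}

#' Export a mechanism comparison as CSV
#'
#' Columns `t_s,pull,leapfrog[,data]`.
#'
#' @param cmp a `mechanism_comparison`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(cmp, path) {
  out <- cmp$curves
  names(out)[1] <- "t_s"
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
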