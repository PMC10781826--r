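#' Configuration for synthetic bat-night trajectory simulations
#'
#' Bundles the parameters of the agent-based generators. Defaults describe a
#' typical maternity-roost night: 25 tracked bat-nights of 8 hours, a
#' departure delay of about 700 s after sunset, free dispersal at
#' \eqn{D = 100} m\eqn{^2}/s inside a 2000 m core sustenance zone, and a
#' return phase starting 1.5 h after sunset.
#'
#' @param n_bats number of bats (one track each per night), >= 1.
#' @param night_length night duration in seconds (default 8 h).
#' @param step Euler--Maruyama time step in seconds. A resolution parameter:
#'   steps larger than `R0^2 / (100 * D)` are rejected as under-resolved.
#' @param D diffusion rate during the dispersal phase (m^2/s).
#' @param R0 core sustenance zone radius (m); walkers reflect here.
#' @param t_s phase-switch time (s): return behaviour activates at `t_s`.
#' @param t_d departure delay (s): walkers are held at the roost for
#'   `t < t_d`. Must satisfy `0 <= t_d < t_s < night_length`.
#' @param mechanism one of `"dispersal_only"`, `"leapfrog"`, `"pull"`.
#' @param leapfrog_speed inward convection speed of the furthest-out bat
#'   (m/s), a scalar or a function of time. Default: `1.25 * R0 /
#'   (night_length - t_s)`, fast enough that the envelope empties the domain
#'   by dawn with margin.
#' @param R_t envelope radius schedule for the leap-frog mechanism: a
#'   function `R(t)` or the string `"parabolic"` (the default when no
#'   `leapfrog_speed` is given) for the apical schedule `R(t) = R0` before
#'   `t_s` and `R0 * sqrt(1 - ((t - t_s)/(night_length - t_s))^2)` after,
#'   collapsing at dawn. The leader's convection speed at time `t` is the
#'   schedule's shrinkage rate.
#' @param D_c,t_c,chi_c pull-mechanism (non-autonomous) parameters:
#'   diffusion scale (m^2/s), diffusion turnover time (s) in
#'   `D(t) = D_c * |1 - t/t_c|`, and inward acceleration (m/s^2) in the
#'   drift speed `chi_c * t`. `D_c` and `chi_c` must be positive.
#' @param capture_radius walkers within this distance (m) of the roost after
#'   `t_s` are absorbed there (default 10 m, below data resolution).
#' @param condition_on_return if `TRUE` (default), walkers still away from
#'   the roost at `night_length` are snapped to the roost in the final
#'   record, emulating a survey restricted to nights on which the bat's
#'   first and last roost coincide.
#' @param record_every interval (s) at which positions are retained in the
#'   output (default: every step).
#' @param seed master integer seed; per-bat streams are derived from it by
#'   fixed offsets, so earlier bats' tracks do not change when `n_bats`
#'   grows.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_bats = 25L,
                       night_length = 28800,
                       step = 1,
                       D = 100,
                       R0 = 2000,
                       t_s = 5400,
                       t_d = 698,
                       mechanism = c("dispersal_only", "leapfrog", "pull"),
                       leapfrog_speed = NULL,
                       R_t = NULL,
                       D_c = NULL, t_c = NULL, chi_c = NULL,
                       capture_radius = 10,
                       condition_on_return = TRUE,
                       record_every = NULL,
                       seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(n_bats) || n_bats < 1) stop("'n_bats' must be >= 1")
  if (night_length <= 0 || step <= 0 || D < 0 || R0 <= 0)
    stop("durations, rates and radii must be positive")
  if (!(t_d >= 0 && t_d < t_s && t_s < night_length))
    stop("need 0 <= t_d < t_s < night_length")
  if (D > 0 && step > R0^2 / (100 * D))
    stop("'step' = ", step, " s is under-resolved for D = ", D,
         ", R0 = ", R0, " (limit ", R0^2 / (100 * D), " s)")
  if (mechanism == "leapfrog") {
    if (is.null(R_t) && is.null(leapfrog_speed)) R_t <- "parabolic"
    if (identical(R_t, "parabolic")) {
      tau2 <- night_length - t_s
      ts_loc <- t_s
      R0_loc <- R0
      R_t <- function(t)
        ifelse(t < ts_loc, R0_loc,
               R0_loc * sqrt(pmax(1 - ((t - ts_loc) / tau2)^2, 0)))
    }
    if (!is.null(R_t) && !is.function(R_t))
      stop("'R_t' must be a function of time or \"parabolic\"")
  }
  if (mechanism == "pull") {
    if (is.null(D_c)) D_c <- D
    if (is.null(t_c)) t_c <- 8.23 * 3600
    if (is.null(chi_c)) chi_c <- 0.83e-5
    if (chi_c < 0) stop("'chi_c' must be non-negative")
    if (D_c <= 0 || t_c <= 0) stop("'D_c' and 't_c' must be positive")
  }
  structure(list(
    n_bats = as.integer(n_bats), night_length = night_length, step = step,
    D = D, R0 = R0, t_s = t_s, t_d = t_d, mechanism = mechanism,
    leapfrog_speed = leapfrog_speed, R_t = R_t,
    D_c = D_c, t_c = t_c, chi_c = chi_c,
    capture_radius = capture_radius,
    condition_on_return = isTRUE(condition_on_return),
    record_every = if (is.null(record_every)) step else record_every,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Detection model for sampling irregular radio-tracking fixes
#'
#' Describes the distribution of time intervals between consecutive
#' detections of a tracked bat, and an independent per-fix failure
#' probability. The default gamma distribution (shape 0.9, scale 2600 s)
#' peaks in the 0--400 s band where field inter-detection intervals peak,
#' with a heavy tail giving roughly 12 fixes per 8 h night, matching the
#' recording rate of the motivating survey.
#'
#' @param family `"gamma"` (shape/scale) or `"constant"` (fixed interval).
#' @param shape,scale gamma parameters (s); the density mode is
#'   `max(0, (shape - 1) * scale)`.
#' @param interval fixed interval (s) for `family = "constant"`.
#' @param failure_prob probability that a scheduled fix is missed.
#' @param seed integer seed for the sampling stream.
#' @return An object of class `"detection_model"`.
#' @export
detection_model <- function(family = c("gamma", "constant"),
                            shape = 0.9, scale = 2600,
                            interval = 200,
                            failure_prob = 0, seed = 1L) {
  family <- match.arg(family)
  if (family == "gamma") {
    if (shape <= 0 || scale <= 0) stop("gamma parameters must be positive")
  } else if (interval <= 0) {
    stop("'interval' must be positive")
  }
  if (failure_prob < 0 || failure_prob > 1)
    stop("'failure_prob' must be in [0, 1]")
  structure(list(family = family, shape = shape, scale = scale,
                 interval = interval, failure_prob = failure_prob,
                 seed = as.integer(seed)),
            class = "detection_model")
}
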