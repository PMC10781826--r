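# Agent-based generators of roost-anchored bat-night trajectories.
#
# All walkers use a fixed Euler--Maruyama step (per-axis increment variance
# 2*D*step), specular reflection in radius (r -> 2B - r) at the bounding
# circle, and per-bat random streams derived from the master seed by fixed
# offsets.

radii <- function(pos) sqrt(pos[, 1]^2 + pos[, 2]^2)

# Pre-draw each bat's standard-normal increments from its own stream.
bat_increments <- function(seed, n_bats, n_steps) {
  inc <- array(0, dim = c(n_steps, n_bats, 2))
  for (b in seq_len(n_bats)) {
    set.seed(derive_seed(seed, b))
    inc[, b, ] <- rnorm(2L * n_steps)
  }
  inc
}

reflect_radial <- function(pos, bound) {
  r <- radii(pos)
  out <- which(r > bound)
  if (length(out)) {
    fac <- pmax(2 * bound - r[out], 0) / r[out]
    pos[out, ] <- pos[out, ] * fac
  }
  pos
}

tracks_from_array <- function(out, times, record_every, step, night_id = 1L) {
  keep <- which(times %% record_every < step / 2 | seq_along(times) == length(times))
  keep <- unique(keep)
  n_bats <- dim(out)[2]
  df <- data.frame(
    bat_id = rep(seq_len(n_bats), each = length(keep)),
    night_id = night_id,
    t = rep(times[keep], times = n_bats),
    x = as.vector(out[keep, , 1]),
    y = as.vector(out[keep, , 2])
  )
  class(df) <- c("bat_tracks", "data.frame")
  df
}

#' Simulate freely dispersing random walkers in the core sustenance zone
#'
#' Unbiased 2-D random walks started at the roost after the departure delay
#' `t_d`, reflected at radius `R0`. This is the stochastic analogue of
#' radial diffusion on a disk with zero-flux boundary: the ensemble MSD
#' grows as \eqn{4Dt} until the boundary is felt.
#'
#' @param config a [sim_config()] with `mechanism = "dispersal_only"`.
#' @return A `bat_tracks` data frame (`bat_id`, `night_id`, `t`, `x`, `y`).
#' @export
simulate_dispersal_walkers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mechanism != "dispersal_only")
    stop("config mechanism is not 'dispersal_only'")
  with_walkers(config, phase2 = "none")
}

#' Simulate a leap-frogging bat night
#'
#' Before `t_s` all bats diffuse as in [simulate_dispersal_walkers()]. From
#' `t_s` onward, at each step the bat currently furthest from the roost
#' flies radially inward at the configured convection speed while the others
#' keep diffusing, reflecting at the furthest bat's radius (the moving
#' envelope). Ties in the furthest radius (within 1e-9 m) go to the lowest
#' `bat_id` for reproducibility. Bats within `capture_radius` of the roost
#' after `t_s` are absorbed there.
#'
#' @inheritParams simulate_dispersal_walkers
#' @return A `bat_tracks` data frame.
#' @export
simulate_leapfrog_night <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mechanism != "leapfrog")
    stop("config mechanism is not 'leapfrog'")
  if (config$n_bats == 1L)
    warning("n_bats = 1: leap frog degenerates to pure inward convection ",
            "after t_s")
  with_walkers(config, phase2 = "leapfrog")
}

#' Simulate a pulled (non-autonomous convection-diffusion) bat night
#'
#' Walkers diffuse with the time-dependent rate
#' `D(t) = D_c * |1 - t/t_c|` and, for `t >= t_s`, drift radially toward
#' the roost at speed `chi_c * t`, reflecting at `R0`. Bats within
#' `capture_radius` after `t_s` are absorbed at the roost.
#'
#' @inheritParams simulate_dispersal_walkers
#' @return A `bat_tracks` data frame.
#' @export
simulate_pull_night <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mechanism != "pull")
    stop("config mechanism is not 'pull'")
  with_walkers(config, phase2 = "pull")
}

# Shared walker engine. phase2 selects the return behaviour.
with_walkers <- function(config, phase2) {
  n_bats <- config$n_bats
  step <- config$step
  n_steps <- ceiling(config$night_length / step)
  times <- seq(0, by = step, length.out = n_steps + 1L)
  inc <- bat_increments(config$seed, n_bats, n_steps)
  out <- array(0, dim = c(n_steps + 1L, n_bats, 2))
  pos <- matrix(0, n_bats, 2)
  absorbed <- rep(FALSE, n_bats)

  lf_speed <- config$leapfrog_speed
  if (phase2 == "leapfrog" && is.null(lf_speed) && !is.null(config$R_t)) {
    # envelope schedule: convect at the schedule's shrinkage rate
    Rt <- config$R_t
    eps <- step / 2
    lf_speed <- function(t) max(0, (Rt(max(t - eps, 0)) - Rt(t + eps)) / (2 * eps))
  }

  for (k in seq_len(n_steps)) {
    t0 <- times[k]
    t1 <- times[k + 1L]
    if (t1 <= config$t_d) next  # held at the roost until departure
    Dk <- if (phase2 == "pull") config$D_c * abs(1 - t0 / config$t_c) else config$D
    sd_step <- sqrt(2 * Dk * step)
    in_phase2 <- t1 > config$t_s

    if (phase2 == "leapfrog" && in_phase2) {
      active <- which(!absorbed)
      if (length(active)) {
        r <- radii(pos)
        env <- max(r[active])
        leader <- active[which(r[active] >= env - 1e-9)]
        leader <- min(leader)  # deterministic tie-break: lowest bat_id
        spd <- if (is.function(lf_speed)) lf_speed(t0) else lf_speed
        followers <- setdiff(active, leader)
        if (length(followers)) {
          pnew <- pos[followers, , drop = FALSE] +
            inc[k, followers, ] * sd_step
          pos[followers, ] <- reflect_radial(pnew, env)
        }
        rl <- r[leader]
        if (rl > 0) {
          rnew <- max(rl - spd * step, 0)
          pos[leader, ] <- pos[leader, ] * (rnew / rl)
        }
        hit <- !absorbed & radii(pos) <= config$capture_radius
        if (any(hit)) {
          absorbed[hit] <- TRUE
          pos[hit, ] <- 0
        }
      }
    } else {
      active <- which(!absorbed)
      if (length(active)) {
        pnew <- pos[active, , drop = FALSE] + inc[k, active, ] * sd_step
        if (phase2 == "pull" && in_phase2) {
          r <- radii(pnew)
          shift <- config$chi_c * t0 * step
          fac <- ifelse(r > 0, pmax(r - shift, 0) / r, 0)
          pnew <- pnew * fac
        }
        pos[active, ] <- reflect_radial(pnew, config$R0)
        if (phase2 != "none" && in_phase2) {
          hit <- !absorbed & radii(pos) <= config$capture_radius
          if (any(hit)) {
            absorbed[hit] <- TRUE
            pos[hit, ] <- 0
          }
        }
      }
    }
    out[k + 1L, , ] <- pos
  }

  if (phase2 != "none" && config$condition_on_return) {
    # survey emulation: only same-roost nights are analysed, so the final
    # record of every track is the roost
    out[n_steps + 1L, , ] <- 0
  }
  tracks_from_array(out, times, config$record_every, step)
}

#' Sample irregular detection records from continuous tracks
#'
#' Draws detection times for each track by accumulating intervals from the
#' detection model's distribution over the track's span, reads positions off
#' the (linearly interpolated) continuous track, and optionally drops fixes
#' with the model's failure probability. The roost record at `t = 0` is
#' always retained, and the track's endpoint record is scheduled as a fix
#' (field tracking follows a bat until it is lost or returns to the roost),
#' subject to the same failure probability.
#'
#' @param tracks a `bat_tracks` data frame (see
#'   [simulate_dispersal_walkers()]).
#' @param model a [detection_model()].
#' @return A detection table: data frame with columns `bat_id`, `night_id`,
#'   `t`, `x`, `y`, sorted by (bat, night, time).
#' @export
sample_detections <- function(tracks, model = detection_model()) {
  stopifnot(is.data.frame(tracks), nrow(tracks) > 0)
  groups <- split(tracks, list(tracks$bat_id, tracks$night_id), drop = TRUE)
  res <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    tr <- groups[[g]]
    tr <- tr[order(tr$t), ]
    span <- max(tr$t)
    set.seed(derive_seed(model$seed, g))
    if (model$family == "constant") {
      det_t <- seq(model$interval, span, by = model$interval)
    } else {
      # draw in blocks until the cumulative time exceeds the span
      iv <- numeric(0)
      exp_n <- ceiling(span / (model$shape * model$scale)) + 10L
      while (sum(iv) <= span)
        iv <- c(iv, rgamma(exp_n, shape = model$shape, scale = model$scale))
      det_t <- cumsum(iv)
      det_t <- det_t[det_t <= span]
    }
    det_t <- c(det_t, span)   # the track's endpoint fix (ending roost)
    if (model$failure_prob > 0 && length(det_t))
      det_t <- det_t[runif(length(det_t)) >= model$failure_prob]
    det_t <- unique(c(0, det_t))
    res[[g]] <- data.frame(
      bat_id = tr$bat_id[1], night_id = tr$night_id[1], t = det_t,
      x = approx(tr$t, tr$x, xout = det_t)$y,
      y = approx(tr$t, tr$y, xout = det_t)$y
    )
  }
  tab <- do.call(rbind, res)
  tab <- tab[order(tab$bat_id, tab$night_id, tab$t), ]
  rownames(tab) <- NULL
  class(tab) <- c("detection_table", "data.frame")
  tab
}
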