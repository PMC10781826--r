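# Shared fixture builders. Everything is generated in code; no stored data.

# Noiseless MSD curve from a piecewise coefficient set, sampled like a
# regularised night (dt grid up to just before the curve's zero crossing).
make_piecewise_curve <- function(coefs = survey_piecewise_fit("fixed")$coef,
                                 dt = 200, t_max = 27000, noise_sd = 0,
                                 seed = NULL) {
  tt <- seq(dt, t_max, by = dt)
  msd <- predict_piecewise(coefs, tt)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    msd <- msd + rnorm(length(tt), 0, noise_sd)
  }
  out <- data.frame(t = tt, msd = msd, se = 0, n = 25L)
  attr(out, "dt") <- dt
  class(out) <- c("msd_curve", "data.frame")
  out
}

# Hand-built regular track at constant displacement `dist` from its first
# position (which is the roost), on a dt grid.
make_constant_track <- function(bat_id, dist, t_end = 2000, dt = 200) {
  tt <- seq(0, t_end, by = dt)
  out <- data.frame(bat_id = bat_id, night_id = 1L, t = tt,
                    x = c(0, rep(dist, length(tt) - 1L)), y = 0)
  attr(out, "dt") <- dt
  out
}

bind_regular_tracks <- function(..., dt = 200) {
  out <- do.call(rbind, list(...))
  attr(out, "dt") <- dt
  class(out) <- c("regular_tracks", "data.frame")
  out
}

# Tiny handwritten detection table.
make_toy_detections <- function() {
  tab <- data.frame(
    bat_id = c(1L, 1L, 1L, 2L, 2L),
    night_id = 1L,
    t = c(0, 400, 800, 0, 600),
    x = c(0, 400, 100, 0, -300),
    y = c(0, 0, 50, 0, 400)
  )
  class(tab) <- c("detection_table", "data.frame")
  tab
}
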