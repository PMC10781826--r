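# Mean squared displacement estimation from regularised tracks.

#' Compute the ensemble mean squared displacement curve
#'
#' At each grid time `t`, averages the squared displacement from each
#' track's own first position over the `N(t)` tracks whose observed span
#' covers `t`:
#' \deqn{\langle r^2(t)\rangle = \frac{1}{N(t)} \sum_{i=1}^{N(t)}
#'   |x_i(t) - x_i(0)|^2.}
#' The ribbon is the standard error: the sample standard deviation of the
#' squared displacements divided by \eqn{\sqrt{N(t)}}. Where only one track
#' covers a time, the standard error is reported as 0 (with a warning).
#'
#' @param tracks a `regular_tracks` data frame (all sharing the same `dt`;
#'   see [interpolate_tracks()]).
#' @return An `msd_curve` data frame with columns `t` (s), `msd` (m^2),
#'   `se` (m^2) and `n` (tracks contributing), and attribute `dt`.
#' @export
compute_msd <- function(tracks) {
  dt <- attr(tracks, "dt")
  groups <- split(tracks, list(tracks$bat_id, tracks$night_id), drop = TRUE)
  stacked <- do.call(rbind, lapply(groups, function(tr) {
    tr <- tr[order(tr$t), ]
    data.frame(t = tr$t,
               d2 = (tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2)
  }))
  tt <- sort(unique(stacked$t))
  f <- factor(stacked$t, levels = tt)
  msd <- tapply(stacked$d2, f, mean)
  n <- tapply(stacked$d2, f, length)
  sdv <- tapply(stacked$d2, f, sd)   # NA when n = 1
  if (any(n == 1L))
    warning("standard error undefined where N(t) = 1; reported as 0")
  se <- ifelse(n > 1L, sdv / sqrt(n), 0)
  out <- data.frame(t = tt, msd = as.numeric(msd), se = as.numeric(se),
                    n = as.integer(n))
  rownames(out) <- NULL
  attr(out, "dt") <- dt
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Write / read an MSD curve as CSV
#'
#' Uses the header `t_s,msd_m2,se_m2,n_tracks`.
#'
#' @param curve an `msd_curve` data frame.
#' @param path CSV path.
#' @return `path` invisibly (write) or an `msd_curve` (read).
#' @export
write_msd_curve <- function(curve, path) {
  out <- data.frame(t_s = sprintf("%.17g", curve$t),
                    msd_m2 = sprintf("%.17g", curve$msd),
                    se_m2 = sprintf("%.17g", curve$se),
                    n_tracks = curve$n)
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_msd_curve
#' @export
read_msd_curve <- function(path) {
  raw <- read.csv(path)
  need <- c("t_s", "msd_m2", "se_m2", "n_tracks")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  out <- data.frame(t = as.numeric(raw$t_s), msd = as.numeric(raw$msd_m2),
                    se = as.numeric(raw$se_m2), n = as.integer(raw$n_tracks))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Extract per-track final return times
#'
#' For each (bat, night) track, finds the earliest recorded time after which
#' every subsequent recorded position lies within `radius` of the roost
#' (i.e. the bat is detected within the radius and never detected beyond it
#' thereafter). Tracks that never enter the radius get `NA`.
#'
#' @param tracks a detection table or regular tracks (columns `bat_id`,
#'   `night_id`, `t`, `x`, `y`).
#' @param radius comparison radius in metres (default 100).
#' @return Data frame with columns `bat_id`, `night_id`, `return_time`
#'   (s; `NA` if the track never settles within the radius).
#' @export
extract_return_times <- function(tracks, radius = 100) {
  groups <- split(tracks, list(tracks$bat_id, tracks$night_id), drop = TRUE)
  res <- lapply(groups, function(tr) {
    tr <- tr[order(tr$t), ]
    r <- sqrt(tr$x^2 + tr$y^2)
    inside <- r <= radius
    rt <- NA_real_
    if (any(inside)) {
      last_out <- if (any(!inside)) max(which(!inside)) else 0L
      if (last_out < nrow(tr)) rt <- tr$t[last_out + 1L]
    }
    data.frame(bat_id = tr$bat_id[1], night_id = tr$night_id[1],
               return_time = rt)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
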