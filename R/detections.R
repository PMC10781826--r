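# Detection-table I/O and track regularisation.

DETECTION_COLS <- c("bat_id", "night_id", "t_s", "x_m", "y_m")

validate_detection_table <- function(tab) {
  if (any(!is.finite(tab$t)) || any(!is.finite(tab$x)) || any(!is.finite(tab$y)))
    stop("detection table contains non-finite values")
  if (any(tab$t < 0))
    stop("detection times must be >= 0 (seconds after sunset)")
  key <- paste(tab$bat_id, tab$night_id, tab$t)
  if (anyDuplicated(key))
    stop("duplicate (bat, night, t) detection keys")
  tab <- tab[order(tab$bat_id, tab$night_id, tab$t), ]
  rownames(tab) <- NULL
  class(tab) <- c("detection_table", "data.frame")
  tab
}

#' Read a detection table from CSV
#'
#' Expects the header `bat_id,night_id,t_s,x_m,y_m`: times in seconds after
#' sunset and coordinates in metres with the roost at the origin. Rows are
#' returned canonically sorted by (bat, night, time).
#'
#' @param path path to a CSV file.
#' @return A `detection_table` data frame with columns `bat_id`, `night_id`,
#'   `t`, `x`, `y`.
#' @export
read_detection_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(DETECTION_COLS, names(raw))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  num <- c("t_s", "x_m", "y_m")
  bad <- num[!vapply(raw[num], is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "))
  tab <- data.frame(bat_id = raw$bat_id, night_id = raw$night_id,
                    t = as.numeric(raw$t_s), x = as.numeric(raw$x_m),
                    y = as.numeric(raw$y_m))
  validate_detection_table(tab)
}

#' Write a detection table to CSV
#'
#' Numeric fields are written with 17 significant digits so that
#' write-then-read round-trips doubles exactly.
#'
#' @param table a `detection_table` data frame (columns `bat_id`,
#'   `night_id`, `t`, `x`, `y`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detection_table <- function(table, path) {
  tab <- validate_detection_table(table)
  out <- data.frame(
    bat_id = tab$bat_id, night_id = tab$night_id,
    t_s = sprintf("%.17g", tab$t),
    x_m = sprintf("%.17g", tab$x),
    y_m = sprintf("%.17g", tab$y)
  )
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Regularise one track by linear interpolation
#'
#' Linearly interpolates a single (bat, night) detection sequence
#' componentwise onto the grid `t_k = k * dt`, keeping only grid times
#' inside the observed span (no extrapolation). A detection lying exactly on
#' a grid time is reproduced exactly.
#'
#' @param track data frame with columns `t`, `x`, `y` (and optionally
#'   `bat_id`, `night_id`) for one track; at least 2 detections.
#' @param dt grid spacing in seconds (default 200, matching the peak of
#'   field inter-detection intervals).
#' @return Data frame of interpolated positions with attribute `dt`.
#' @export
interpolate_track <- function(track, dt = 200) {
  if (nrow(track) < 2L)
    stop("track has a single detection: no interval to interpolate")
  track <- track[order(track$t), ]
  tmin <- track$t[1]
  tmax <- track$t[nrow(track)]
  grid <- seq(0, tmax, by = dt)
  grid <- grid[grid >= tmin]
  out <- data.frame(
    bat_id = if ("bat_id" %in% names(track)) track$bat_id[1] else 1L,
    night_id = if ("night_id" %in% names(track)) track$night_id[1] else 1L,
    t = grid,
    x = approx(track$t, track$x, xout = grid)$y,
    y = approx(track$t, track$y, xout = grid)$y
  )
  attr(out, "dt") <- dt
  out
}

#' Regularise every track in a detection table
#'
#' Applies [interpolate_track()] independently to each (bat, night) group.
#' Tracks with fewer than 2 detections are dropped with a warning.
#'
#' @param table a `detection_table` data frame.
#' @param dt grid spacing in seconds.
#' @return A `regular_tracks` data frame with attribute `dt`.
#' @export
interpolate_tracks <- function(table, dt = 200) {
  groups <- split(table, list(table$bat_id, table$night_id), drop = TRUE)
  ok <- vapply(groups, nrow, integer(1)) >= 2L
  if (any(!ok))
    warning(sum(!ok), " track(s) with a single detection dropped")
  out <- do.call(rbind, lapply(groups[ok], interpolate_track, dt = dt))
  rownames(out) <- NULL
  attr(out, "dt") <- dt
  class(out) <- c("regular_tracks", "data.frame")
  out
}
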