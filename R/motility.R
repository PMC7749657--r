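## Single-cell migration statistics from time-lapse tracks.
##
## Speed is total path length over tracked time. Persistence is the ratio of
## net displacement to path length (directionality ratio), multiplied by
## sqrt(t_tracked / t_max) so that cells tracked only briefly — whose
## directionality ratio is upward-biased — are penalized.

#' Construct a single-cell track
#'
#' @param track_id Label.
#' @param times Observation times in minutes, strictly increasing; frames
#'   may be missing (gaps) — steps are taken between available consecutive
#'   observations, without interpolation.
#' @param x,y Coordinates in micrometers, same length as `times`.
#' @param t_max Maximal possible tracking time in minutes (the acquisition
#'   duration), `>= max(times) - min(times)`. Default 2880 (48 h).
#' @return Object of class `cell_track`.
#' @export
cell_track <- function(track_id, times, x, y, t_max = 2880) {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times)) {
    stop_field("times", "must be a non-empty numeric vector")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop_field("times", "must be strictly increasing")
  }
  if (length(x) != length(times) || length(y) != length(times)) {
    stop_field("x", "coordinates must match length of 'times'")
  }
  if (anyNA(x) || anyNA(y)) stop_field("x", "coordinates must not be missing")
  check_scalar_number(t_max, "t_max", lower = 0, strict_lower = TRUE)
  t_tracked <- times[length(times)] - times[1L]
  if (t_tracked > t_max) {
    stop_field("t_max", "tracked duration exceeds maximal tracking time")
  }
  structure(list(track_id = as.character(track_id), times = as.numeric(times),
                 x = as.numeric(x), y = as.numeric(y),
                 t_max = as.numeric(t_max)),
            class = "cell_track")
}

path_length <- function(track) {
  if (length(track$times) < 2L) return(0)
  sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
}

net_displacement <- function(track) {
  n <- length(track$times)
  sqrt((track$x[n] - track$x[1L])^2 + (track$y[n] - track$y[1L])^2)
}

#' Migration speed of a tracked cell
#'
#' Total travelled distance (sum of Euclidean step lengths between
#' consecutive observations) divided by the total time the cell was tracked.
#'
#' @param track A [cell_track()] with at least 2 points.
#' @return Speed in um/min.
#' @export
track_speed <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  if (length(track$times) < 2L) {
    stop("speed requires at least 2 track points", call. = FALSE)
  }
  t_tracked <- track$times[length(track$times)] - track$times[1L]
  path_length(track) / t_tracked
}

#' Time-penalized directional persistence of a tracked cell
#'
#' Net displacement (first to last observed position) divided by the total
#' travelled distance, multiplied by \eqn{\sqrt{t_{tracked} / t_{max}}} so
#' that briefly tracked cells cannot dominate: a perfectly straight track
#' observed over the full acquisition scores 1; the same path shape tracked
#' for a quarter of the acquisition scores 0.5. A stationary cell (zero path
#' length) is assigned persistence 0 with attribute `degenerate = TRUE`.
#'
#' @param track A [cell_track()].
#' @return Persistence in \[0, 1\].
#' @export
track_persistence <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  pl <- path_length(track)
  t_tracked <- track$times[length(track$times)] - track$times[1L]
  if (pl == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (net_displacement(track) / pl) * sqrt(t_tracked / track$t_max)
}

#' Split a track table into cell_track objects
#'
#' @param tracks Data frame with columns `track_id`, `t_min`, `x_um`,
#'   `y_um` (the track CSV dialect written by [simulate_tracks()]).
#' @param t_max Maximal possible tracking time in minutes.
#' @return Named list of [cell_track()] objects, in order of first
#'   appearance.
#' @export
tracks_from_table <- function(tracks, t_max = 2880) {
  need <- c("track_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    stop_field("tracks", sprintf("must have columns %s",
                                 paste(need, collapse = ", ")))
  }
  ids <- unique(tracks$track_id)
  idx <- split(seq_len(nrow(tracks)),
               factor(tracks$track_id, levels = ids))
  out <- lapply(ids, function(id) {
    tr <- tracks[idx[[id]], , drop = FALSE]
    tr <- tr[order(tr$t_min), , drop = FALSE]
    cell_track(id, tr$t_min, tr$x_um, tr$y_um, t_max = t_max)
  })
  names(out) <- ids
  out
}

#' Per-condition summary of migration statistics
#'
#' Computes speed and persistence per track, then mean, standard deviation
#' and count per condition group. Groups with fewer than 2 tracks report
#' `NA` standard deviations.
#'
#' @param tracks List of [cell_track()] objects (e.g. from
#'   [tracks_from_table()]).
#' @param grouping Condition label per track (recycled if length 1; default
#'   one group `"all"`).
#' @return List with `per_track` (track-level statistics) and `per_condition`
#'   (group summaries) data frames.
#' @export
summarize_condition <- function(tracks, grouping = "all") {
  stopifnot(is.list(tracks))
  if (!length(tracks)) stop("no tracks supplied", call. = FALSE)
  if (length(grouping) == 1L) grouping <- rep(grouping, length(tracks))
  if (length(grouping) != length(tracks)) {
    stop_field("grouping", "must have one label per track")
  }
  per_track <- data.frame(
    track_id = vapply(tracks, function(t) t$track_id, character(1)),
    condition = as.character(grouping),
    speed = vapply(tracks, track_speed, numeric(1)),
    persistence = vapply(tracks, function(t) as.numeric(track_persistence(t)),
                         numeric(1)),
    t_tracked = vapply(tracks, function(t) {
      t$times[length(t$times)] - t$times[1L]
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(per_track) <- NULL
  groups <- split(per_track, per_track$condition)
  per_condition <- do.call(rbind, lapply(groups, function(g) {
    data.frame(condition = g$condition[1L], n = nrow(g),
               speed_mean = mean(g$speed),
               speed_sd = if (nrow(g) > 1L) stats::sd(g$speed) else NA_real_,
               persistence_mean = mean(g$persistence),
               persistence_sd = if (nrow(g) > 1L) stats::sd(g$persistence)
                                else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_condition) <- NULL
  list(per_track = per_track, per_condition = per_condition)
}
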