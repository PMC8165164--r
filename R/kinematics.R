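#' Drop the initial seconds of a session
#'
#' Removes all frames with time below `seconds` from the start of the session
#' (the focal bird and, in the social condition, its neighbour are not placed
#' simultaneously, so the first moments are not comparable across conditions).
#' Times remain reported relative to the original session start.
#'
#' @param traj a [trajectory()].
#' @param seconds trim window in seconds (>= 0); default 2.
#' @return The trimmed trajectory.
#' @export
trim_initial <- function(traj, seconds = 2) {
  stopifnot(inherits(traj, "trajectory"))
  if (seconds < 0) stop_mf("seconds must be >= 0", class = "config_error")
  keep <- traj$time >= seconds
  if (!any(keep))
    stop_mf("trajectory is shorter than the trim window", class = "empty_trajectory")
  subset_trajectory(traj, keep)
}

#' Filter low-confidence frames and interpolate short gaps
#'
#' Frames where the tracker confidence for a required bodypart falls below
#' `threshold` are marked missing, then linearly interpolated across gaps of
#' at most `max_gap` seconds. Longer gaps stay missing and are excluded from
#' the downstream statistics.
#'
#' @param traj a [trajectory()].
#' @param threshold likelihood threshold in `[0, 1]`; default 0.6.
#' @param max_gap maximum gap (seconds) bridged by linear interpolation.
#' @param bodyparts parts to filter; defaults to the required parts.
#' @return The trajectory with filtered/interpolated coordinates; interpolated
#'   frames keep their original likelihood values.
#' @export
filter_low_likelihood <- function(traj, threshold = 0.6, max_gap = 0.5,
                                  bodyparts = required_bodyparts()) {
  stopifnot(inherits(traj, "trajectory"))
  if (threshold < 0 || threshold > 1)
    stop_mf("threshold must lie in [0, 1]", class = "config_error")
  gap_frames <- max(1L, round(max_gap * traj$fps))
  for (p in intersect(bodyparts, traj$bodyparts)) {
    bad <- !is.na(traj$likelihood[, p]) & traj$likelihood[, p] < threshold
    xs <- traj$x[, p]; ys <- traj$y[, p]
    xs[bad] <- NA_real_; ys[bad] <- NA_real_
    if (all(is.na(xs)))
      stop_mf("all frames of bodypart '", p, "' fall below the threshold",
              class = "empty_trajectory")
    traj$x[, p] <- as.numeric(zoo::na.approx(xs, x = traj$time,
                                             maxgap = gap_frames, na.rm = FALSE))
    traj$y[, p] <- as.numeric(zoo::na.approx(ys, x = traj$time,
                                             maxgap = gap_frames, na.rm = FALSE))
  }
  traj
}

#' LOESS smoothing of a coordinate series
#'
#' Locally weighted linear regression with tricube weights (degree 1, no
#' robustness iterations), the classical LOESS/LOWESS smoother. Missing values
#' are left missing; the fit uses the non-missing points only.
#'
#' @param values numeric vector to smooth.
#' @param span fraction of the data in each local window, in (0, 1].
#' @param time optional numeric time axis (defaults to the index).
#' @return Numeric vector of the same length.
#' @export
loess_smooth <- function(values, span = 0.05, time = NULL) {
  if (span <= 0 || span > 1)
    stop_mf("span must lie in (0, 1]", class = "parameter_error")
  if (is.null(time)) time <- seq_along(values)
  ok <- !is.na(values) & !is.na(time)
  n_ok <- sum(ok)
  if (n_ok < 2 || floor(span * n_ok) < 2)
    stop_mf("span too small for a local linear fit (window < 2 points)",
            class = "parameter_error")
  sm <- stats::lowess(time[ok], values[ok], f = span, iter = 0, delta = 0)
  out <- values
  out[ok] <- sm$y
  out
}

#' Smooth all required bodypart coordinates of a trajectory
#'
#' @param traj a [trajectory()].
#' @param span LOESS span, see [loess_smooth()].
#' @param bodyparts parts to smooth.
#' @return The smoothed trajectory.
#' @export
smooth_trajectory <- function(traj, span = 0.05,
                              bodyparts = required_bodyparts()) {
  stopifnot(inherits(traj, "trajectory"))
  for (p in intersect(bodyparts, traj$bodyparts)) {
    traj$x[, p] <- loess_smooth(traj$x[, p], span = span, time = traj$time)
    traj$y[, p] <- loess_smooth(traj$y[, p], span = span, time = traj$time)
  }
  traj
}

#' Body-orientation index
#'
#' Cosine of the angle between the body-to-head vector and the body-to-target
#' vector: 1 when the bird is oriented straight toward the target (the feeder,
#' and with it the mirror or the neighbouring bird), 0 when it stands at 90
#' degrees, and -1 when it turns its back to it. Degenerate (zero-length)
#' vectors yield `NA` rather than an error.
#'
#' @param body,head n x 2 matrices (or length-2 vectors) of positions.
#' @param target length-2 target point, typically the feeder centre.
#' @return Numeric vector of values in `[-1, 1]` (NA where undefined).
#' @export
#' @examples
#' orientation_index(c(0, 0), c(1, 0), c(2, 0))   # 1, aligned
#' orientation_index(c(0, 0), c(1, 0), c(0, 5))   # 0, perpendicular
#' orientation_index(c(0, 0), c(1, 0), c(-3, 0))  # -1, facing away
orientation_index <- function(body, head, target) {
  body <- unname(rbind(body)); head <- unname(rbind(head))
  v1x <- head[, 1] - body[, 1]; v1y <- head[, 2] - body[, 2]
  v2x <- target[1] - body[, 1]; v2y <- target[2] - body[, 2]
  n1 <- sqrt(v1x^2 + v1y^2); n2 <- sqrt(v2x^2 + v2y^2)
  out <- (v1x * v2x + v1y * v2y) / (n1 * n2)
  out[n1 == 0 | n2 == 0] <- NA_real_
  pmin(pmax(out, -1), 1)
}

#' Convert an orientation index to degrees
#'
#' Sign-preserving arcsine mapping, `asin(x) * 180 / pi`: an index difference
#' of 0 maps to 0 degrees and a full index of 1 to 90 degrees.
#'
#' @param x numeric in `[-1, 1]`.
#' @return Degrees.
#' @export
#' @examples
#' index_to_degrees(0.32)  # 18.66 (2 dp)
index_to_degrees <- function(x) {
  if (any(abs(x) > 1 + 1e-12, na.rm = TRUE))
    stop_mf("orientation index must lie in [-1, 1]", class = "domain_error")
  asin(pmin(pmax(x, -1), 1)) * 180 / pi
}

#' Detect feeding episodes
#'
#' A frame is a feeding frame when the head keypoint lies within the feeder
#' zone; runs of feeding frames shorter than `min_bout` seconds are removed
#' (debounce) to suppress single-frame zone crossings.
#'
#' @param traj a [trajectory()] in cm.
#' @param geom an [arena_geometry()].
#' @param min_bout minimum bout duration in seconds.
#' @return Logical per-frame feeding mask (missing head frames are `FALSE`).
#' @export
detect_feeding <- function(traj, geom, min_bout = 0.3) {
  stopifnot(inherits(traj, "trajectory"), inherits(geom, "arena_geometry"))
  if (traj$units != "cm")
    stop_mf("detect_feeding requires arena (cm) coordinates; see to_arena_coords()",
            class = "config_error")
  d <- sqrt((traj$x[, "head"] - geom$feeder_center[1])^2 +
            (traj$y[, "head"] - geom$feeder_center[2])^2)
  mask <- !is.na(d) & d <= geom$feeder_zone_radius
  min_frames <- max(1L, round(min_bout * traj$fps))
  r <- rle(mask)
  r$values[r$values & r$lengths < min_frames] <- FALSE
  inverse.rle(r)
}

#' Activity rate (log mean non-feeding speed)
#'
#' Mean body-center speed over consecutive frame pairs in which the bird is
#' not feeding, in cm/s, then natural-log transformed (the log restores
#' approximate normality for the group statistics). The mean speed is floored
#' at 1e-3 cm/s before the log so a stationary bird yields a finite value.
#'
#' @param traj a [trajectory()] in cm.
#' @param mask logical feeding mask (from [detect_feeding()]).
#' @param fps frame rate; defaults to the trajectory's.
#' @return `log(mean speed in cm/s)`, or `NA` (with a warning) when no valid
#'   non-feeding frame pair exists.
#' @export
activity_rate <- function(traj, mask, fps = traj$fps) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$units != "cm")
    stop_mf("activity_rate requires arena (cm) coordinates", class = "config_error")
  x <- traj$x[, "body-center"]; y <- traj$y[, "body-center"]
  n <- length(x)
  if (n < 2 || all(mask)) {
    warning("no non-feeding frame pair; activity rate undefined")
    return(NA_real_)
  }
  i <- seq_len(n - 1L)
  use <- !mask[i] & !mask[i + 1L] &
    !is.na(x[i]) & !is.na(x[i + 1L]) & !is.na(y[i]) & !is.na(y[i + 1L])
  if (!any(use)) {
    warning("no non-feeding frame pair; activity rate undefined")
    return(NA_real_)
  }
  sp <- sqrt((x[i + 1L] - x[i])^2 + (y[i + 1L] - y[i])^2)[use] * fps
  log(max(mean(sp), 1e-3))
}

#' Latency to feed
#'
#' Time of the first frame of the first (debounced) feeding episode, measured
#' from the original session start. When the bird never feeds the latency is
#' right-censored at the session length.
#'
#' @param traj a [trajectory()] in cm (typically after [trim_initial()]).
#' @param geom an [arena_geometry()].
#' @param min_bout debounce window passed to [detect_feeding()].
#' @return A list with `latency_s` and logical `censored`.
#' @export
latency_to_feed <- function(traj, geom, min_bout = 0.3) {
  if (length(traj$time) == 0)
    stop_mf("empty trajectory", class = "empty_trajectory")
  mask <- detect_feeding(traj, geom, min_bout = min_bout)
  i <- which(mask)[1]
  if (is.na(i)) {
    list(latency_s = max(traj$time) + 1 / traj$fps, censored = TRUE)
  } else {
    list(latency_s = traj$time[i], censored = FALSE)
  }
}

#' Per-session kinematic statistics
#'
#' Runs the full preprocessing chain — initial trim, likelihood filtering with
#' gap interpolation, pixel-to-cm calibration, LOESS smoothing — and derives
#' the session's behavioural statistics: latency to feed, log activity rate,
#' and the body-orientation index series toward the feeder.
#'
#' @param traj a [trajectory()] in pixels (or cm).
#' @param geom an [arena_geometry()].
#' @param trim_s seconds removed from the session start.
#' @param likelihood_threshold,max_gap_s see [filter_low_likelihood()].
#' @param span LOESS span, see [loess_smooth()]; when `NULL` (default) it is
#'   derived from `smooth_window_s`.
#' @param smooth_window_s width of the local smoothing window in seconds
#'   (default 0.25 s). Keypoint jitter lives at the frame scale while real
#'   postural dynamics (head swings, approach turns) unfold over fractions of
#'   a second, so the window must stay well below the bout timescale or the
#'   head-to-body offset geometry is averaged away.
#' @param min_bout_s feeding debounce, see [detect_feeding()].
#' @return A list: scalars `latency_s`, `censored`, `log_activity`,
#'   `mean_orientation`; series `orientation` (tibble `time_s`, `value`) and
#'   `feeding_mask`; plus the preprocessed `trajectory`.
#' @export
session_stats <- function(traj, geom, trim_s = 2, likelihood_threshold = 0.6,
                          max_gap_s = 0.5, span = NULL,
                          smooth_window_s = 0.25, min_bout_s = 0.3) {
  traj <- trim_initial(traj, trim_s)
  traj <- filter_low_likelihood(traj, threshold = likelihood_threshold,
                                max_gap = max_gap_s)
  traj <- to_arena_coords(traj, geom)
  if (is.null(span))
    span <- min(1, max(3, smooth_window_s * traj$fps) / length(traj$time))
  traj <- smooth_trajectory(traj, span = span)
  mask <- detect_feeding(traj, geom, min_bout = min_bout_s)
  lat <- latency_to_feed(traj, geom, min_bout = min_bout_s)
  oi <- orientation_index(cbind(traj$x[, "body-center"], traj$y[, "body-center"]),
                          cbind(traj$x[, "head"], traj$y[, "head"]),
                          geom$feeder_center)
  list(
    latency_s = lat$latency_s, censored = lat$censored,
    log_activity = activity_rate(traj, mask),
    mean_orientation = mean(oi, na.rm = TRUE),
    orientation = tibble::tibble(time_s = traj$time, value = oi),
    feeding_mask = mask,
    trajectory = traj
  )
}

#' Analyse every session of a manifest
#'
#' @param manifest tibble from [read_manifest()] (columns `bird_id`,
#'   `condition`, `session`, `path`, `fps`).
#' @param geom an [arena_geometry()].
#' @param ... preprocessing parameters passed to [session_stats()].
#' @return A list with `sessions` (one row per session: `bird_id`,
#'   `condition`, `session`, `latency_s`, `censored`, `log_activity`,
#'   `mean_orientation`) and `frames` (per-frame orientation: `bird_id`,
#'   `condition`, `session`, `time_s`, `orientation`).
#' @export
analyze_sessions <- function(manifest, geom, ...) {
  rows <- vector("list", nrow(manifest))
  frames <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    traj <- read_trajectory(m$path, fps = m$fps)
    st <- session_stats(traj, geom, ...)
    rows[[i]] <- tibble::tibble(
      bird_id = m$bird_id, condition = m$condition, session = m$session,
      latency_s = st$latency_s, censored = st$censored,
      log_activity = st$log_activity, mean_orientation = st$mean_orientation)
    frames[[i]] <- tibble::tibble(
      bird_id = m$bird_id, condition = m$condition, session = m$session,
      time_s = st$orientation$time_s, orientation = st$orientation$value)
  }
  list(sessions = dplyr::bind_rows(rows), frames = dplyr::bind_rows(frames))
}
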