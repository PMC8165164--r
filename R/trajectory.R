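#' Keypoint trajectory container
#'
#' A `trajectory` holds per-frame keypoint positions and tracker confidences
#' for a set of named bodyparts, together with the frame rate and the units of
#' the coordinates. Positions are stored as frame x bodypart matrices so that
#' kinematic operations stay vectorised.
#'
#' @param x,y,likelihood numeric matrices (frames x bodyparts) with identical
#'   dimnames; `likelihood` values must lie in `[0, 1]` (NA allowed).
#' @param fps frames per second (> 0).
#' @param units `"px"` or `"cm"`.
#' @param frames integer vector of original frame numbers (0-based). Defaults
#'   to `0:(n-1)`.
#' @param extra_bodyparts character vector of bodyparts present in the source
#'   file but not required by the pipeline (kept, flagged).
#'
#' @return An object of class `trajectory` with elements `x`, `y`,
#'   `likelihood`, `frames`, `time` (seconds, `frames / fps`), `fps`, `units`,
#'   `bodyparts`.
#' @export
trajectory <- function(x, y, likelihood, fps, units = c("px", "cm"),
                       frames = NULL, extra_bodyparts = character()) {
  units <- match.arg(units)
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  if (!all(dim(x) == dim(y)) || !all(dim(x) == dim(likelihood)))
    stop_mf("x, y and likelihood must have identical dimensions",
            class = "schema_error")
  if (is.null(colnames(x)))
    stop_mf("bodypart names (column names) are required", class = "schema_error")
  if (!is.numeric(fps) || fps <= 0)
    stop_mf("fps must be > 0", class = "config_error")
  lk <- likelihood[!is.na(likelihood)]
  if (length(lk) && (min(lk) < 0 || max(lk) > 1))
    stop_mf("likelihood values must lie in [0, 1]", class = "schema_error")
  if (is.null(frames)) frames <- seq_len(nrow(x)) - 1L
  if (length(frames) != nrow(x))
    stop_mf("frames must match the number of rows", class = "schema_error")
  structure(
    list(x = x, y = y, likelihood = likelihood,
         frames = as.integer(frames), time = as.numeric(frames) / fps,
         fps = fps, units = units, bodyparts = colnames(x),
         extra_bodyparts = extra_bodyparts),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames @ %g fps (%.1f s), units %s, bodyparts: %s\n",
              nrow(x$x), x$fps, length(x$time) / x$fps, x$units,
              paste(x$bodyparts, collapse = ", ")))
  invisible(x)
}

#' @export
length.trajectory <- function(x) nrow(x$x)

#' Default bodypart alias table
#'
#' Tracking projects name keypoints inconsistently; this table maps common
#' variants onto the two canonical parts the pipeline requires, `head` and
#' `body-center`.
#'
#' @return Named character vector: names are lower-cased source names, values
#'   the canonical names.
#' @export
default_bodypart_aliases <- function() {
  c(head = "head", center = "body-center", body = "body-center",
    bodycenter = "body-center", "body-center" = "body-center",
    body_center = "body-center", torso = "body-center")
}

required_bodyparts <- function() c("head", "body-center")

#' Read a keypoint trajectory in the DeepLabCut CSV dialect
#'
#' The dialect has three header rows (`scorer`, `bodyparts`, `coords`) followed
#' by one row per frame: the 0-based frame index, then an `x`, `y`,
#' `likelihood` triplet per bodypart. Bodyparts are resolved to the canonical
#' names via `bodypart_aliases`; unresolved parts are retained and listed in
#' the result's `extra_bodyparts`. Missing coordinate cells are kept as `NA`
#' (handled later by the likelihood filter), not rejected.
#'
#' @param path path to the CSV file.
#' @param fps frame rate of the recording (not stored in the file; usually
#'   taken from the session manifest).
#' @param bodypart_aliases named character vector mapping source bodypart names
#'   (case-insensitive) to canonical names; see [default_bodypart_aliases()].
#' @param units units of the coordinates in the file (default `"px"`).
#'
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, fps = 30,
                            bodypart_aliases = default_bodypart_aliases(),
                            units = "px") {
  if (!file.exists(path))
    stop_mf("trajectory file not found: ", path, class = "io_error")
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L)
    stop_mf("malformed header in ", path, ": fewer than 3 header lines (line ",
            length(hdr) + 1L, ")", class = "format_error")
  split1 <- strsplit(hdr, ",", fixed = TRUE)
  labels <- vapply(split1, `[[`, "", 1L)
  expect <- c("scorer", "bodyparts", "coords")
  bad <- which(tolower(labels) != expect)
  if (length(bad))
    stop_mf("malformed header in ", path, ": line ", bad[1], " should start with '",
            expect[bad[1]], "' but starts with '", labels[bad[1]], "'",
            class = "format_error")
  parts_row <- split1[[2]][-1]
  coords_row <- split1[[3]][-1]
  ncols <- length(parts_row)
  if (ncols == 0L || ncols %% 3L != 0L)
    stop_mf("malformed header in ", path,
            ": bodypart columns not in x/y/likelihood triplets (line 2)",
            class = "format_error")
  dat <- utils::read.csv(path, skip = 3L, header = FALSE,
                         colClasses = "numeric", check.names = FALSE)
  if (ncol(dat) != ncols + 1L)
    stop_mf("data rows of ", path, " have ", ncol(dat),
            " columns, header implies ", ncols + 1L, class = "format_error")
  src_parts <- parts_row[seq(1, ncols, by = 3L)]
  # resolve aliases (case-insensitive)
  canon <- unname(bodypart_aliases[tolower(src_parts)])
  canon[is.na(canon)] <- src_parts[is.na(canon)]
  missing_req <- setdiff(required_bodyparts(), canon)
  if (length(missing_req))
    stop_mf("required bodypart(s) missing from ", path, ": ",
            paste(missing_req, collapse = ", "), class = "schema_error")
  extra <- setdiff(canon, required_bodyparts())
  frames <- as.integer(dat[[1]])
  m <- function(k) {
    out <- as.matrix(dat[, 1L + seq(k, ncols, by = 3L), drop = FALSE])
    colnames(out) <- canon
    rownames(out) <- NULL
    out
  }
  trajectory(x = m(1L), y = m(2L), likelihood = m(3L),
             fps = fps, units = units, frames = frames,
             extra_bodyparts = extra)
}

#' Write a trajectory in the DeepLabCut CSV dialect
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @param scorer scorer label written in the first header row.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, scorer = "mirrorforage") {
  parts <- traj$bodyparts
  hdr1 <- paste(c("scorer", rep(scorer, 3L * length(parts))), collapse = ",")
  hdr2 <- paste(c("bodyparts", rep(parts, each = 3L)), collapse = ",")
  hdr3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))),
                collapse = ",")
  cols <- vector("list", 3L * length(parts))
  for (j in seq_along(parts)) {
    cols[[3L * j - 2L]] <- traj$x[, parts[j]]
    cols[[3L * j - 1L]] <- traj$y[, parts[j]]
    cols[[3L * j]] <- traj$likelihood[, parts[j]]
  }
  chr_cols <- lapply(cols, function(v) formatC(v, format = "g", digits = 10))
  lines <- c(hdr1, hdr2, hdr3,
             do.call(paste, c(list(traj$frames), chr_cols, sep = ",")))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_mf("failed to write trajectory file: ", path, class = "io_error")
  invisible(path)
}

#' Read a session manifest
#'
#' The manifest is a CSV with one row per session and columns `bird_id`,
#' `condition`, `session`, `path`, `fps`. Relative `path` entries are resolved
#' against the manifest's own directory.
#'
#' @param path path to the manifest CSV.
#' @return A tibble with the manifest columns, paths resolved.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_mf("manifest not found: ", path, class = "io_error")
  man <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("bird_id", "condition", "session", "path", "fps")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop_mf("manifest ", path, " missing column(s): ",
            paste(miss, collapse = ", "), class = "schema_error")
  root <- dirname(path)
  abs <- file.path(root, man$path)
  man$path <- ifelse(file.exists(man$path), man$path, abs)
  man
}

#' Convert a pixel trajectory to arena (cm) coordinates
#'
#' Applies the linear calibration `cm = px / px_per_cm` to all coordinates.
#' The y axis follows the package convention "toward the separation panel =
#' increasing y"; files written by the synthetic generator already use it, and
#' recordings with an inverted camera axis should be flipped upstream.
#'
#' @param traj a [trajectory()] in pixel units.
#' @param geom an [arena_geometry()] carrying `px_per_cm`.
#' @return The trajectory with coordinates in cm (`units = "cm"`).
#' @export
to_arena_coords <- function(traj, geom) {
  stopifnot(inherits(traj, "trajectory"), inherits(geom, "arena_geometry"))
  if (traj$units == "cm") return(traj)
  traj$x <- traj$x / geom$px_per_cm
  traj$y <- traj$y / geom$px_per_cm
  traj$units <- "cm"
  traj
}

# subset a trajectory to a logical/integer frame index, keeping absolute times
subset_trajectory <- function(traj, keep) {
  traj$x <- traj$x[keep, , drop = FALSE]
  traj$y <- traj$y[keep, , drop = FALSE]
  traj$likelihood <- traj$likelihood[keep, , drop = FALSE]
  traj$frames <- traj$frames[keep]
  traj$time <- traj$time[keep]
  traj
}
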