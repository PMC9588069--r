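#' Trajectory table container
#'
#' The canonical trajectory representation: a tibble with one row per
#' localization, columns `track` (id), `frame` (0-based, consecutive within
#' a track), `x_um`, `y_um` and, for 3D data, `z_um`. Acquisition metadata
#' (`frame_interval` in seconds and `dims`) travel as attributes.
#'
#' @param df data frame with columns `track`, `frame`, `x_um`, `y_um`
#'   (and `z_um` when `dims = 3`).
#' @param frame_interval frame interval, seconds.
#' @param dims spatial dimensionality (2 or 3).
#' @return a tibble of class `spt_tracks`.
#' @export
spt_tracks <- function(df, frame_interval, dims = if ("z_um" %in% names(df)) 3L else 2L) {
  stopifnot(frame_interval > 0, dims %in% c(2L, 3L))
  need <- c("track", "frame", pos_cols(dims))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("missing trajectory columns: ", paste(missing, collapse = ", "))
  }
  df <- tibble::as_tibble(df[need])
  df <- df[order(df$track, df$frame), ]
  by_track <- split(df$frame, df$track)
  bad <- names(by_track)[vapply(by_track, function(f) any(diff(f) != 1L), logical(1))]
  if (length(bad) > 0) {
    stop("non-consecutive frames within track(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(is.finite(as.matrix(df[pos_cols(dims)])))) {
    stop("non-finite coordinates in trajectory table")
  }
  structure(df, class = c("spt_tracks", class(tibble::tibble())),
            frame_interval = frame_interval, dims = as.integer(dims))
}

pos_cols <- function(dims) c("x_um", "y_um", "z_um")[seq_len(dims)]

#' @export
print.spt_tracks <- function(x, ...) {
  cat(sprintf("<spt_tracks> %d tracks, %d localizations, %dD, dt = %g s\n",
              length(unique(x$track)), nrow(x), track_dims(x),
              frame_interval(x)))
  NextMethod()
}

#' Trajectory metadata accessors
#'
#' @param tracks an `spt_tracks` table.
#' @return `frame_interval()` the frame interval in seconds; `track_dims()`
#'   the dimensionality; `track_lengths()` a named integer vector of
#'   per-track lengths in frames.
#' @export
frame_interval <- function(tracks) attr(tracks, "frame_interval", exact = TRUE)

#' @rdname frame_interval
#' @export
track_dims <- function(tracks) attr(tracks, "dims", exact = TRUE)

#' @rdname frame_interval
#' @export
track_lengths <- function(tracks) {
  tab <- table(tracks$track)
  stats::setNames(as.integer(tab), names(tab))
}

# Split an spt_tracks table into per-track position matrices, preserving
# first-appearance order of track ids.
track_matrices <- function(tracks) {
  cols <- pos_cols(track_dims(tracks))
  ids <- unique(tracks$track)
  m <- as.matrix(tracks[cols])
  lapply(split(seq_len(nrow(tracks)), factor(tracks$track, levels = ids)),
         function(i) m[i, , drop = FALSE])
}
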