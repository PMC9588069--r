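#' Link per-frame detections into trajectories
#'
#' Reconstructs trajectories frame by frame with a link range of one frame
#' (no gap closing). For every consecutive frame pair, detections are
#' assigned to active tracks by optimal bipartite assignment (Hungarian
#' algorithm) minimizing the total squared displacement, subject to a hard
#' gate: no link may exceed `max_displacement`. Unmatched detections start
#' new tracks; a track with no admissible continuation terminates. Every
#' detection ends up in exactly one track (possibly of length 1, removed
#' later by [filter_min_length()]).
#'
#' @param detections a data frame with columns `frame`, `x_um`, `y_um`
#'   (and `z_um` for 3D); extra columns are ignored.
#' @param max_displacement gate in um (e.g. 0.5 for fast 3D acquisitions,
#'   0.3 for slow 2D acquisitions).
#' @param dims dimensionality; defaults to 3 if a `z_um` column is present.
#' @param frame_interval frame interval in seconds, stored on the result.
#' @return an [spt_tracks()] table (empty input gives an empty table).
#' @export
link_detections <- function(detections, max_displacement,
                            dims = if ("z_um" %in% names(detections)) 3L else 2L,
                            frame_interval = 1) {
  stopifnot(max_displacement > 0, dims %in% c(2L, 3L))
  cols <- pos_cols(dims)
  missing <- setdiff(c("frame", cols), names(detections))
  if (length(missing) > 0) {
    stop("detection table lacks columns: ", paste(missing, collapse = ", "))
  }
  empty <- tibble::tibble(track = integer(), frame = integer(),
                          x_um = numeric(), y_um = numeric())
  if (dims == 3L) empty$z_um <- numeric()
  if (nrow(detections) == 0) {
    return(spt_tracks(empty, frame_interval, dims))
  }
  ord <- order(detections$frame)
  frame <- as.integer(detections$frame[ord])
  xyz <- as.matrix(detections[ord, cols, drop = FALSE])
  rows_by_frame <- split(seq_along(frame), frame)
  frames <- as.integer(names(rows_by_frame))

  track_of <- integer(length(frame))
  n_tracks <- 0L
  gate2 <- max_displacement^2

  prev_rows <- rows_by_frame[[1]]
  track_of[prev_rows] <- n_tracks + seq_along(prev_rows)
  n_tracks <- n_tracks + length(prev_rows)

  for (k in seq_along(frames)[-1]) {
    cur_rows <- rows_by_frame[[k]]
    consecutive <- frames[k] == frames[k - 1] + 1L
    linked_to <- rep(NA_integer_, length(cur_rows))
    if (consecutive) {
      d2 <- sq_dist_matrix(xyz[prev_rows, , drop = FALSE],
                           xyz[cur_rows, , drop = FALSE])
      pairing <- gated_assignment(d2, gate2)
      linked_to[pairing$col] <- pairing$row
    }
    for (j in seq_along(cur_rows)) {
      if (is.na(linked_to[j])) {
        n_tracks <- n_tracks + 1L
        track_of[cur_rows[j]] <- n_tracks
      } else {
        track_of[cur_rows[j]] <- track_of[prev_rows[linked_to[j]]]
      }
    }
    prev_rows <- cur_rows
  }

  out <- tibble::tibble(track = track_of, frame = frame,
                        as.data.frame(xyz))
  # renumber tracks by first appearance
  first_seen <- !duplicated(out$track)
  relabel <- integer(n_tracks)
  relabel[out$track[first_seen]] <- seq_len(sum(first_seen))
  out$track <- relabel[out$track]
  spt_tracks(out, frame_interval, dims)
}

sq_dist_matrix <- function(a, b) {
  # rows of a x rows of b squared Euclidean distances
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  outer(an, bn, `+`) - 2 * tcrossprod(a, b)
}

# Optimal gated assignment between two detection sets given squared
# distances. Pads the cost matrix so that leaving a detection unmatched
# costs just more than any admissible link, which makes the minimum-cost
# solution also maximize the number of admissible links. Returns the
# admissible (row, col) pairs.
gated_assignment <- function(d2, gate2) {
  n1 <- nrow(d2)
  n2 <- ncol(d2)
  if (n1 == 0 || n2 == 0) return(list(row = integer(), col = integer()))
  big <- gate2 * 1.0001 + 1          # "no link" cost
  forbid <- big * (n1 + n2 + 1)      # exceeds any full dummy assignment
  cost <- d2
  cost[cost > gate2] <- forbid
  m <- n1 + n2
  padded <- matrix(big, m, m)
  padded[seq_len(n1), seq_len(n2)] <- cost
  sol <- as.integer(clue::solve_LSAP(padded))
  rows <- seq_len(n1)
  cols <- sol[rows]
  keep <- cols <= n2
  keep[keep] <- d2[cbind(rows[keep], cols[keep])] <= gate2
  list(row = rows[keep], col = cols[keep])
}

#' Discard tracks shorter than a minimum length
#'
#' Retains exactly the tracks with at least `min_frames` localizations,
#' preserving ids and order. The standard gate is 10 frames for fast 3D
#' acquisitions (400 ms at 25 Hz) and 5 frames for slow 2D acquisitions.
#'
#' @param tracks an [spt_tracks()] table.
#' @param min_frames minimum track length in frames (>= 2).
#' @return the filtered `spt_tracks` table.
#' @export
filter_min_length <- function(tracks, min_frames) {
  stopifnot(inherits(tracks, "spt_tracks"), min_frames >= 2)
  len <- track_lengths(tracks)
  keep_ids <- names(len)[len >= min_frames]
  out <- tracks[as.character(tracks$track) %in% keep_ids, , drop = FALSE]
  spt_tracks(out, frame_interval(tracks), track_dims(tracks))
}

#' Drop the first frames of an acquisition
#'
#' Removes all detections before frame `n_discard` and re-bases frame
#' numbers to 0. Early frames of single-molecule movies are typically too
#' densely labeled for robust tracking and are discarded (500 frames in the
#' reference acquisitions).
#'
#' @param detections detection table with a `frame` column.
#' @param n_discard number of leading frames to drop (>= 0).
#' @return the trimmed detection table, frames re-based to 0.
#' @export
discard_leading_frames <- function(detections, n_discard) {
  stopifnot(n_discard >= 0)
  if (n_discard == 0) return(detections)
  out <- detections[detections$frame >= n_discard, , drop = FALSE]
  out$frame <- out$frame - as.integer(n_discard)
  out
}
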